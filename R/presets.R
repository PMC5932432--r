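#' Named GMF parameterizations from the vessel-detection literature
#'
#' Returns the scale list and template parameters of well-known single-scale
#' Gaussian matched-filter configurations, plus the multiscale default
#' (`"mgmf"`). Single-scale presets carry one sigma; `"mgmf"` carries eleven
#' scales from 1.5 to 2.5 in steps of 0.1 with `L = 13`, `T = 15`,
#' `kappa = 12`.
#'
#' The `"alrawi"` and `"gmf_evol"` entries are approximations: those methods
#' tuned `(L, T, sigma)` by search on their own data and the optimized values
#' are not public, so the midpoints of their published search spaces are
#' shipped (rounded to odd template sizes). `"gmf_entropy"` likewise ships
#' representative values. They are provided so the comparative baselines can
#' be run, not as faithful reproductions.
#'
#' @param name one of `"chaudhuri"`, `"cinsdikici"`, `"kang"`, `"alrawi"`,
#'   `"gmf_evol"`, `"gmf_entropy"`, `"mgmf"`.
#' @return a list with elements `name`, `sigmas`, `L`, `T`, `kappa`, and
#'   `approximate` (logical).
#' @examples
#' gmf_preset("chaudhuri")
#' gmf_preset("mgmf")$sigmas
#' @export
gmf_preset <- function(name = c("mgmf", "chaudhuri", "cinsdikici", "kang",
                                "alrawi", "gmf_evol", "gmf_entropy")) {
  name <- match.arg(name)
  p <- switch(name,
    chaudhuri   = list(sigmas = 2.0, L = 9L,  T = 13L, kappa = 12L, approximate = FALSE),
    cinsdikici  = list(sigmas = 2.0, L = 9L,  T = 13L, kappa = 18L, approximate = FALSE),
    kang        = list(sigmas = 1.5, L = 9L,  T = 13L, kappa = 6L,  approximate = FALSE),
    # search-space midpoints; published optima not available
    alrawi      = list(sigmas = 2.25, L = 9L, T = 7L,  kappa = 12L, approximate = TRUE),
    gmf_evol    = list(sigmas = 3.0, L = 11L, T = 11L, kappa = 12L, approximate = TRUE),
    gmf_entropy = list(sigmas = 1.5, L = 9L,  T = 13L, kappa = 6L,  approximate = TRUE),
    mgmf        = list(sigmas = seq(1.5, 2.5, by = 0.1), L = 13L, T = 15L,
                       kappa = 12L, approximate = FALSE)
  )
  c(list(name = name), p)
}

#' Compute the response stack for a named preset
#'
#' Convenience wrapper around [multiscale_response()] using a preset's scale
#' list and template parameters.
#'
#' @param image numeric matrix.
#' @param preset preset name or the list returned by [gmf_preset()].
#' @return a `response_stack` (single-layer for single-scale presets).
#' @export
preset_response <- function(image, preset = "mgmf") {
  if (is.character(preset)) preset <- gmf_preset(preset)
  multiscale_response(image, preset$sigmas, preset$L, preset$T, preset$kappa)
}
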