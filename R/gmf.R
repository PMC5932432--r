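#' Gaussian matched-filter parameters
#'
#' Bundles the four parameters of the oriented Gaussian matched filter (GMF)
#' used for vessel detection in X-ray angiograms: `sigma`, the spread of the
#' Gaussian cross-sectional profile (a proxy for the average vessel
#' half-width, in pixels); `L`, the template length along the vessel axis;
#' `T`, the template width across the vessel axis (where the Gaussian trails
#' are cut); and `kappa`, the number of evenly spaced orientations covering
#' 180 degrees.
#'
#' Even `L` or `T` are rounded up to the next odd integer so templates are
#' odd-sided and centred on a pixel. Orientation `i` of a bank has angle
#' `-90 + i * 180 / kappa` degrees, `i = 0 ... kappa - 1`.
#'
#' @param sigma positive numeric, Gaussian profile spread in pixels.
#' @param L template length in pixels (integer >= 1).
#' @param T template width in pixels (integer >= 1).
#' @param kappa number of orientations (integer >= 1).
#' @return an object of class `gmf_params`.
#' @examples
#' gmf_params(sigma = 2, L = 9, T = 13, kappa = 12)
#' @export
gmf_params <- function(sigma, L = 13L, T = 15L, kappa = 12L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a single positive number")
  }
  for (nm in c("L", "T", "kappa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 1 ||
        v != round(v)) {
      stop("`", nm, "` must be a single integer >= 1")
    }
  }
  to_odd <- function(v) { v <- as.integer(v); if (v %% 2L == 0L) v + 1L else v }
  structure(
    list(sigma = as.numeric(sigma), L = to_odd(L), T = to_odd(T),
         kappa = as.integer(kappa)),
    class = "gmf_params"
  )
}

#' @export
print.gmf_params <- function(x, ...) {
  cat(sprintf("GMF parameters: sigma = %g, L = %d, T = %d, kappa = %d\n",
              x$sigma, x$L, x$T, x$kappa))
  invisible(x)
}

#' Orientation angles of a filter bank
#'
#' @param kappa number of evenly spaced orientations.
#' @return numeric vector of `kappa` angles in degrees, `-90 + i * 180/kappa`.
#' @export
bank_angles <- function(kappa) {
  -90 + (seq_len(kappa) - 1L) * (180 / kappa)
}

# Raw (pre-normalization) template value at back-rotated coordinates:
# -exp(-x^2 / (2 sigma^2)) inside the rectangle |x| <= (T-1)/2,
# |y| <= (L-1)/2, zero outside. The profile varies across the vessel (x)
# and is constant along it (y).
template_cells <- function(params, theta_deg) {
  D <- max(params$L, params$T)           # L, T already odd
  h <- (D - 1L) %/% 2L
  u <- matrix(rep(-h:h, each = D), D, D)     # column offset = x direction
  v <- matrix(rep(-h:h, times = D), D, D)    # row offset    = y direction
  th <- theta_deg * pi / 180
  x <- u * cos(th) + v * sin(th)
  y <- -u * sin(th) + v * cos(th)
  tol <- 1e-9
  support <- abs(x) <= (params$T - 1) / 2 + tol &
             abs(y) <= (params$L - 1) / 2 + tol
  raw <- matrix(0, D, D)
  raw[support] <- -exp(-x[support]^2 / (2 * params$sigma^2))
  list(raw = raw, support = support)
}

#' Build the unrotated Gaussian matched-filter template
#'
#' Evaluates the inverted Gaussian cross-section `-exp(-x^2 / (2 sigma^2))`
#' on an odd square grid of side `D = max(L, T)`, with support
#' `|x| <= (T-1)/2`, `|y| <= (L-1)/2`, then subtracts the mean of the
#' in-support values so the kernel has zero sum (zero response on flat
#' background). Cells outside the support have weight zero and are excluded
#' from the mean.
#'
#' @param params a [gmf_params()] object.
#' @return an object of class `gmf_kernel` with elements `weights` (D x D
#'   numeric matrix), `support` (D x D logical), `angle` (degrees) and
#'   `params`.
#' @export
build_template <- function(params) {
  rotate_template(params, 0)
}

#' Rotate the matched-filter template to a given orientation
#'
#' The rotated kernel is resampled analytically: each grid cell `(u, v)`
#' takes the raw template value at the back-rotated coordinate
#' `(x, y) = R(-theta) (u, v)`, with the support rectangle rotated likewise;
#' no pixel interpolation is involved. Mean subtraction over the rotated
#' support enforces the zero-sum property at every angle.
#'
#' @param params a [gmf_params()] object.
#' @param theta_deg orientation in degrees.
#' @return a `gmf_kernel` (see [build_template()]).
#' @export
rotate_template <- function(params, theta_deg) {
  stopifnot(inherits(params, "gmf_params"))
  cells <- template_cells(params, theta_deg)
  w <- cells$raw
  w[cells$support] <- w[cells$support] - mean(w[cells$support])
  structure(
    list(weights = w, support = cells$support,
         angle = as.numeric(theta_deg), params = params),
    class = "gmf_kernel"
  )
}

#' Build the full oriented filter bank
#'
#' @param params a [gmf_params()] object.
#' @return a list of `kappa` `gmf_kernel` objects at angles
#'   `-90 + i * 180/kappa` degrees, ascending.
#' @export
build_filter_bank <- function(params) {
  stopifnot(inherits(params, "gmf_params"))
  lapply(bank_angles(params$kappa), function(a) rotate_template(params, a))
}

validate_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L) {
    stop("`image` must be a non-empty numeric matrix")
  }
  if (any(!is.finite(image))) stop("`image` contains non-finite pixels")
  invisible(image)
}

#' Single-scale Gaussian matched-filter response
#'
#' Correlates the image with every kernel of the oriented bank and keeps the
#' per-pixel maximum over orientations. Vessels darker than their
#' surroundings produce positive responses (the template is a negative
#' Gaussian); the input image is used as-is, without inversion. Borders are
#' handled by reflect padding.
#'
#' @param image non-empty numeric matrix with finite values.
#' @param params a [gmf_params()] object.
#' @return numeric matrix of the same shape as `image`.
#' @examples
#' img <- matrix(1, 32, 32); img[, 15:17] <- 0.4   # dark vertical bar
#' r <- gmf_response(img, gmf_params(sigma = 1.5, L = 7, T = 7, kappa = 4))
#' which.max(apply(r, 2, max))   # peaks at the bar centre
#' @export
gmf_response <- function(image, params) {
  validate_image(image)
  stopifnot(inherits(params, "gmf_params"))
  bank <- build_filter_bank(params)
  D <- nrow(bank[[1L]]$weights)
  plan <- prepare_correlation_plan(image, D)
  out <- matrix(-Inf, nrow(image), ncol(image))
  for (k in bank) {
    out <- pmax(out, correlate_planned(plan, kernel_fft(k$weights, plan)))
  }
  out
}

#' Multiscale Gaussian matched-filter response stack
#'
#' Computes one [gmf_response()] per scale, sharing `L`, `T` and `kappa`
#' across scales. The per-pixel vectors across the stack are the feature
#' vectors consumed by the neural-network fusion stage.
#'
#' @param image non-empty numeric matrix.
#' @param sigmas non-empty, strictly increasing vector of scales.
#' @param L,T,kappa shared discrete template parameters.
#' @return an object of class `response_stack`: list with `responses` (list
#'   of matrices, one per scale), `sigmas`, and the shared `L`, `T`, `kappa`.
#' @export
multiscale_response <- function(image, sigmas, L = 13L, T = 15L, kappa = 12L) {
  validate_image(image)
  if (length(sigmas) == 0L) stop("`sigmas` must be non-empty")
  if (any(diff(sigmas) <= 0)) stop("`sigmas` must be strictly increasing")
  params0 <- gmf_params(sigmas[1L], L, T, kappa)
  banks <- lapply(sigmas, function(s) build_filter_bank(gmf_params(s, L, T, kappa)))
  D <- nrow(banks[[1L]][[1L]]$weights)
  plan <- prepare_correlation_plan(image, D)
  responses <- lapply(banks, function(bank) {
    out <- matrix(-Inf, nrow(image), ncol(image))
    for (k in bank) {
      out <- pmax(out, correlate_planned(plan, kernel_fft(k$weights, plan)))
    }
    out
  })
  structure(
    list(responses = responses, sigmas = as.numeric(sigmas),
         L = params0$L, T = params0$T, kappa = params0$kappa),
    class = "response_stack"
  )
}

#' @export
print.response_stack <- function(x, ...) {
  cat(sprintf(
    "Multiscale GMF response stack: %d scale(s) [%s], image %d x %d, L = %d, T = %d, kappa = %d\n",
    length(x$sigmas), paste(format(x$sigmas), collapse = ", "),
    nrow(x$responses[[1L]]), ncol(x$responses[[1L]]), x$L, x$T, x$kappa))
  invisible(x)
}

#' Flatten a response stack into a pixel-by-scale feature matrix
#'
#' @param stack a `response_stack`.
#' @return numeric matrix with one row per pixel (column-major pixel order)
#'   and one column per scale.
#' @export
stack_features <- function(stack) {
  stopifnot(inherits(stack, "response_stack"))
  vapply(stack$responses, as.vector,
         numeric(length(stack$responses[[1L]])))
}
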