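# Synthetic angiogram phantoms: dark tubular structures of varying width on
# an unevenly illuminated noisy background, with pixel-exact ground truth.
# Stands in for clinical angiogram sets, which are rarely shareable.

#' Phantom generator configuration
#'
#' @param size image side in pixels (>= 64; clinical frames are 300).
#' @param n_vessels number of vessel branches.
#' @param width_range `(min, max)` Gaussian profile spreads sigma_v in
#'   pixels; each vessel draws its width uniformly from this interval.
#' @param contrast vessel depth relative to the background, in `(0, 1]`.
#' @param illumination_amplitude amplitude of the low-frequency background
#'   modulation (sum of two sinusoids), in `[0, 1)`.
#' @param noise_sigma standard deviation of the additive Gaussian pixel
#'   noise.
#' @param background background intensity level.
#' @param seed integer seed; the full phantom is reproducible from it.
#' @return an object of class `phantom_config`.
#' @examples
#' phantom_config(seed = 7)
#' @export
phantom_config <- function(size = 300L, n_vessels = 5L,
                           width_range = c(1.5, 2.5), contrast = 0.4,
                           illumination_amplitude = 0.1, noise_sigma = 0.02,
                           background = 0.8, seed = 1L) {
  stopifnot(size >= 64L, n_vessels >= 1L, length(width_range) == 2L,
            width_range[1L] <= width_range[2L])
  if (width_range[1L] <= 0.5 || width_range[2L] >= 6) {
    stop("`width_range` must lie within (0.5, 6)")
  }
  if (contrast <= 0 || contrast > 1) stop("`contrast` must be in (0, 1]")
  if (illumination_amplitude < 0 || illumination_amplitude >= 1) {
    stop("`illumination_amplitude` must be in [0, 1)")
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be non-negative")
  structure(
    list(size = as.integer(size), n_vessels = as.integer(n_vessels),
         width_range = as.numeric(width_range), contrast = contrast,
         illumination_amplitude = illumination_amplitude,
         noise_sigma = noise_sigma, background = background,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Minimum distance from every pixel to a polyline (row, col vertices),
# exact point-to-segment distances. Returns a size x size matrix.
polyline_distance <- function(size, verts) {
  px <- matrix(rep(seq_len(size), times = size), ncol = 1)   # rows
  py <- matrix(rep(seq_len(size), each = size), ncol = 1)    # cols
  dmin <- rep(Inf, size * size)
  for (s in seq_len(nrow(verts) - 1L)) {
    a <- verts[s, ]; b <- verts[s + 1L, ]
    v <- b - a; vv <- sum(v^2)
    if (vv == 0) next
    t <- ((px - a[1L]) * v[1L] + (py - a[2L]) * v[2L]) / vv
    t <- pmin(pmax(t, 0), 1)
    dx <- px - (a[1L] + t * v[1L]); dy <- py - (a[2L] + t * v[2L])
    dmin <- pmin(dmin, dx * dx + dy * dy)
  }
  matrix(sqrt(dmin), size, size)
}

# Random smooth centerline crossing the frame: a cubic Bezier whose
# endpoints sit just outside two different edges, sampled as a polyline.
random_centerline <- function(size, n_samples = 80L) {
  edges <- sample(4L, 2L)                      # distinct entry/exit edges
  edge_point <- function(e) {
    u <- stats::runif(1, 0.1, 0.9) * size
    switch(e, c(-3, u), c(size + 3, u), c(u, -3), c(u, size + 3))
  }
  p0 <- edge_point(edges[1L]); p3 <- edge_point(edges[2L])
  p1 <- stats::runif(2, 0.15, 0.85) * size
  p2 <- stats::runif(2, 0.15, 0.85) * size
  t <- seq(0, 1, length.out = n_samples)
  bez <- function(i) (1 - t)^3 * p0[i] + 3 * (1 - t)^2 * t * p1[i] +
    3 * (1 - t) * t^2 * p2[i] + t^3 * p3[i]
  cbind(bez(1L), bez(2L))
}

#' Render vessels with known geometry into a phantom image
#'
#' Low-level renderer used by [generate_phantom()]; exposed so tests and
#' experiments can build phantoms with hand-chosen centerlines (e.g. one
#' perfectly straight vessel). Each vessel subtracts a Gaussian
#' cross-sectional profile `contrast * exp(-d^2 / (2 sigma_v^2))` of its
#' true perpendicular distance `d` to the centerline from the background.
#'
#' @param size image side.
#' @param centerlines list of two-column (row, col) polyline matrices.
#' @param widths vector of per-vessel profile spreads sigma_v.
#' @param contrast,background as in [phantom_config()].
#' @return list with `image` (no illumination or noise), `gt_mask` (pixels
#'   within `2 sigma_v` of a centerline), `sigma_map` (true sigma_v of the
#'   nearest covering vessel, 0 outside the mask) and `distance_maps`.
#' @export
render_vessels <- function(size, centerlines, widths, contrast = 0.4,
                           background = 0.8) {
  stopifnot(length(centerlines) == length(widths))
  depth <- matrix(0, size, size)
  gt <- matrix(FALSE, size, size)
  sigma_map <- matrix(0, size, size)
  best_d <- matrix(Inf, size, size)
  dists <- vector("list", length(widths))
  for (v in seq_along(widths)) {
    d <- polyline_distance(size, centerlines[[v]])
    dists[[v]] <- d
    depth <- depth + contrast * exp(-d^2 / (2 * widths[v]^2))
    inside <- d <= 2 * widths[v]
    gt <- gt | inside
    take <- inside & d < best_d
    sigma_map[take] <- widths[v]
    best_d[take] <- d[take]
  }
  list(image = pmin(pmax(background - depth, 0), 1), gt_mask = gt,
       sigma_map = sigma_map, distance_maps = dists)
}

#' Generate one synthetic angiogram phantom
#'
#' Samples smooth random centerlines crossing the frame, draws a width
#' sigma_v per vessel from `width_range`, renders dark Gaussian-profile
#' vessels on a bright background, then adds a smooth illumination field
#' (two random low-frequency sinusoids) and i.i.d. Gaussian noise. The
#' ground-truth mask contains exactly the pixels within `2 sigma_v` of a
#' centerline, and `sigma_map` records the true width at each mask pixel.
#'
#' @param cfg a [phantom_config()].
#' @return list with `image` (matrix in `[0, 1]`), `gt_mask` (logical),
#'   `sigma_map` (numeric), `widths` (per-vessel sigma_v), `centerlines`,
#'   and `config`.
#' @examples
#' ph <- generate_phantom(phantom_config(size = 100, n_vessels = 2, seed = 3))
#' mean(ph$gt_mask)
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    widths <- stats::runif(cfg$n_vessels, cfg$width_range[1L],
                           cfg$width_range[2L])
    centerlines <- lapply(seq_len(cfg$n_vessels), function(i)
      random_centerline(cfg$size))
    r <- render_vessels(cfg$size, centerlines, widths, cfg$contrast,
                        cfg$background)
    img <- r$image
    if (cfg$illumination_amplitude > 0) {
      co <- seq_len(cfg$size) / cfg$size
      illum <- matrix(0, cfg$size, cfg$size)
      for (k in 1:2) {
        f <- stats::runif(2, 0.5, 1.5)          # cycles per image side
        ph <- stats::runif(2, 0, 2 * pi)
        illum <- illum + outer(sin(2 * pi * f[1L] * co + ph[1L]),
                               sin(2 * pi * f[2L] * co + ph[2L]))
      }
      img <- img + cfg$illumination_amplitude * illum / 2
    }
    if (cfg$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(cfg$size^2, 0, cfg$noise_sigma),
                          cfg$size, cfg$size)
    }
    list(image = pmin(pmax(img, 0), 1), gt_mask = r$gt_mask,
         sigma_map = r$sigma_map, widths = widths,
         centerlines = centerlines, config = cfg)
  })
}

# Deterministic per-image seed derived from a master seed; stays within
# 32-bit integer range.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 10007 + i * 7919) %% 2147483647)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_images` image/mask PNG pairs plus a CSV manifest (filename,
#' mask filename, per-image seed, vessel statistics). Per-image seeds are
#' derived deterministically from `cfg$seed`, so rerunning reproduces every
#' file byte-identically.
#'
#' @param n_images number of phantoms.
#' @param cfg a [phantom_config()]; its `seed` acts as the master seed.
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame, invisibly; also written to
#'   `manifest.csv`.
#' @export
generate_dataset <- function(n_images, cfg = phantom_config(), out_dir) {
  stopifnot(n_images >= 1L)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  rows <- vector("list", n_images)
  for (i in seq_len(n_images)) {
    ci <- cfg; ci$seed <- derive_seed(cfg$seed, i)
    ph <- generate_phantom(ci)
    img_file <- sprintf("phantom_%03d.png", i)
    mask_file <- sprintf("phantom_%03d_mask.png", i)
    write_image(ph$image, file.path(out_dir, img_file))
    write_mask(ph$gt_mask, file.path(out_dir, mask_file))
    rows[[i]] <- data.frame(
      image = img_file, mask = mask_file, seed = ci$seed,
      n_vessels = ci$n_vessels,
      vessel_fraction = mean(ph$gt_mask),
      width_min = min(ph$widths), width_max = max(ph$widths))
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
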