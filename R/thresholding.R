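# Global and local thresholding of the vessel-detection response. All global
# methods operate on a 256-bin histogram of the min-max rescaled response and
# return a bin index t; the binary mask keeps pixels whose bin index exceeds
# t (vessels are the HIGH values of the detection response). Ties among
# optimal t are broken toward the smallest t, so every method is a pure
# function of the histogram.

#' 256-bin histogram of a response image
#'
#' Min-max rescales the response to `[0, 255]`, rounds half-up to integer
#' bins and counts. The affine bin map is recorded so a bin-index threshold
#' can be converted back to a response value. A constant image puts all mass
#' in bin 0 and is flagged degenerate.
#'
#' @param image non-empty numeric matrix (or vector) with finite values.
#' @return an object of class `response_histogram`: `counts` (length 256),
#'   `bin_map` (list with `min`, `max`, `step`), `total`, `degenerate`.
#' @export
make_histogram <- function(image) {
  x <- as.vector(image)
  if (length(x) == 0L) stop("empty image")
  if (any(!is.finite(x))) stop("non-finite values in image")
  lo <- min(x); hi <- max(x)
  degenerate <- hi <= lo
  bins <- if (degenerate) rep(0L, length(x))
          else as.integer(floor((x - lo) / (hi - lo) * 255 + 0.5))
  counts <- tabulate(bins + 1L, nbins = 256L)
  structure(
    list(counts = counts,
         bin_map = list(min = lo, max = hi,
                        step = if (degenerate) 0 else (hi - lo) / 255),
         total = length(x), degenerate = degenerate),
    class = "response_histogram"
  )
}

#' Build a histogram directly from 256 bin counts
#'
#' Wraps raw counts (bin values taken as the identity map on `0..255`)
#' into the histogram object the global thresholding methods consume.
#'
#' @param counts length-256 vector of non-negative counts.
#' @return a `response_histogram`.
#' @export
histogram_from_counts <- function(counts) {
  stopifnot(length(counts) == 256L, all(counts >= 0))
  counts <- as.integer(counts)
  structure(
    list(counts = counts, bin_map = list(min = 0, max = 255, step = 1),
         total = sum(counts), degenerate = sum(counts > 0) < 2L),
    class = "response_histogram"
  )
}

# Bin indices of an image under the same map as make_histogram.
image_bins <- function(image, hist) {
  if (hist$degenerate) return(matrix(0L, nrow(image), ncol(image)))
  b <- floor((image - hist$bin_map$min) / (hist$bin_map$max - hist$bin_map$min) *
               255 + 0.5)
  matrix(as.integer(b), nrow(image), ncol(image))
}

#' Convert a bin-index threshold back to a response value
#'
#' @param hist a `response_histogram`.
#' @param t bin index in `0..255`.
#' @return the response value of bin `t`'s centre.
#' @export
threshold_value <- function(hist, t) {
  hist$bin_map$min + t * hist$bin_map$step
}

check_hist <- function(hist) {
  stopifnot(inherits(hist, "response_histogram"))
  if (sum(hist$counts > 0) < 2L) {
    stop("degenerate histogram: fewer than two non-empty bins")
  }
  invisible(hist)
}

# Class statistics for every candidate t: class 0 = bins <= t.
class_stats <- function(counts) {
  i <- 0:255
  n <- sum(counts)
  c0 <- cumsum(counts)                   # class-0 mass at each t
  s0 <- cumsum(i * counts)
  list(w0 = c0 / n, w1 = 1 - c0 / n,
       mu0 = ifelse(c0 > 0, s0 / c0, 0),
       mu1 = ifelse(n - c0 > 0, (sum(i * counts) - s0) / (n - c0), 0),
       c0 = c0, n = n)
}

#' Otsu's between-class-variance threshold
#'
#' Returns the bin index `t` maximizing
#' `w0(t) w1(t) (mu0(t) - mu1(t))^2` with class 0 = bins `<= t`; the
#' smallest maximizer wins ties.
#'
#' @param hist a `response_histogram`.
#' @return integer bin threshold in `0..254`.
#' @export
otsu <- function(hist) {
  check_hist(hist)
  st <- class_stats(hist$counts)
  obj <- st$w0 * st$w1 * (st$mu0 - st$mu1)^2
  obj[st$c0 == 0 | st$c0 == st$n] <- -Inf   # one class empty
  as.integer(which.max(obj) - 1L)
}

#' Ridler-Calvard iterative (isodata) threshold
#'
#' Fixed point of `t <- round((mu0(t) + mu1(t)) / 2)` (round half-up),
#' started at the histogram mean; iteration stops at the first repeated
#' state, so it terminates within 256 steps.
#'
#' @param hist a `response_histogram`.
#' @return integer bin threshold; the iteration count is attached as
#'   attribute `"iterations"`.
#' @export
ridler_calvard <- function(hist) {
  check_hist(hist)
  st <- class_stats(hist$counts)
  t <- as.integer(floor(sum((0:255) * hist$counts) / st$n + 0.5))
  seen <- logical(256L)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    seen[t + 1L] <- TRUE
    tn <- as.integer(floor((st$mu0[t + 1L] + st$mu1[t + 1L]) / 2 + 0.5))
    if (tn == t || seen[tn + 1L]) { t <- tn; break }
    t <- tn
  }
  structure(t, iterations = iter)
}

#' Kapur maximum-entropy threshold
#'
#' Maximizes the sum of the Shannon entropies of the two renormalized
#' within-class distributions; candidates leaving a class empty are
#' skipped and `0 log 0 = 0`.
#'
#' @param hist a `response_histogram`.
#' @return integer bin threshold.
#' @export
kapur <- function(hist) {
  check_hist(hist)
  p <- hist$counts / sum(hist$counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P0 <- cumsum(p); S0 <- cumsum(plogp)
  P1 <- 1 - P0; S1 <- sum(plogp) - S0
  H0 <- ifelse(P0 > 0, log(P0) - S0 / P0, -Inf)
  H1 <- ifelse(P1 > 0, log(P1) - S1 / P1, -Inf)
  obj <- H0 + H1
  obj[P0 == 0 | P1 == 0] <- -Inf
  as.integer(which.max(obj) - 1L)
}

#' Pal exponential-entropy threshold
#'
#' Maximizes the sum over both classes of the exponential entropy
#' `sum_i p_{i|c} exp(1 - p_{i|c})` of the renormalized within-class
#' distributions.
#'
#' @param hist a `response_histogram`.
#' @return integer bin threshold.
#' @export
pal_entropy <- function(hist) {
  check_hist(hist)
  p <- hist$counts / sum(hist$counts)
  P0 <- cumsum(p)
  obj <- rep(-Inf, 256L)
  for (t in 0:254) {
    if (P0[t + 1L] <= 0 || P0[t + 1L] >= 1) next
    p0 <- p[1:(t + 1L)] / P0[t + 1L]
    p1 <- p[(t + 2L):256L] / (1 - P0[t + 1L])
    obj[t + 1L] <- sum(p0 * exp(1 - p0)) + sum(p1 * exp(1 - p1))
  }
  as.integer(which.max(obj) - 1L)
}

#' Tsai moment-preserving threshold
#'
#' Finds the two representative levels `z0 < z1` and foreground fraction
#' that preserve the first three gray-level moments of the image, then
#' returns the smallest bin index where the cumulative histogram fraction
#' reaches the background fraction `p0`.
#'
#' @param hist a `response_histogram`.
#' @return integer bin threshold; attributes `"p0"`, `"z0"`, `"z1"` carry
#'   the moment solution.
#' @export
moments <- function(hist) {
  check_hist(hist)
  i <- 0:255
  p <- hist$counts / sum(hist$counts)
  m1 <- sum(i * p); m2 <- sum(i^2 * p); m3 <- sum(i^3 * p)
  if (m2 - m1^2 <= 0) stop("zero-variance histogram")
  # z^2 + c1 z + c0 = 0 with (c0, c1) solving the moment equations
  A <- matrix(c(1, m1, m1, m2), 2L, 2L)
  cc <- solve(A, -c(m2, m3))
  disc <- cc[2L]^2 - 4 * cc[1L]
  if (disc < 0) {
    warning("complex moment roots; clamping discriminant to zero")
    disc <- 0
  }
  z0 <- (-cc[2L] - sqrt(disc)) / 2
  z1 <- (-cc[2L] + sqrt(disc)) / 2
  p0 <- (z1 - m1) / (z1 - z0)
  p0 <- min(max(p0, 0), 1)
  cumfrac <- cumsum(p)
  t <- as.integer(which(cumfrac >= p0 - 1e-12)[1L] - 1L)
  structure(t, p0 = p0, z0 = z0, z1 = z1)
}

# Upper convex hull of the histogram polyline, evaluated at every bin.
upper_hull <- function(counts) {
  x <- 0:255; y <- as.numeric(counts)
  hx <- c(); hy <- c()
  for (k in seq_along(x)) {
    while (length(hx) >= 2L) {
      n <- length(hx)
      cross <- (hx[n] - hx[n - 1L]) * (y[k] - hy[n - 1L]) -
               (hy[n] - hy[n - 1L]) * (x[k] - hx[n - 1L])
      if (cross >= 0) { hx <- hx[-n]; hy <- hy[-n] } else break
    }
    hx <- c(hx, x[k]); hy <- c(hy, y[k])
  }
  stats::approx(hx, hy, xout = x)$y
}

#' Histogram-concavity (Rosenfeld-De la Torre) threshold
#'
#' Computes the upper convex hull of the histogram and returns the bin with
#' the largest hull-histogram difference among local maxima of that
#' difference. A histogram coinciding with its hull (no concavity) raises a
#' condition of class `mgmf_no_concavity`.
#'
#' @param hist a `response_histogram`.
#' @return integer bin threshold.
#' @export
concavity <- function(hist) {
  check_hist(hist)
  d <- upper_hull(hist$counts) - hist$counts
  d[d < 1e-9] <- 0
  if (all(d == 0)) {
    stop(structure(
      class = c("mgmf_no_concavity", "error", "condition"),
      list(message = "histogram has no concavity (hull equals histogram)",
           call = sys.call(-1))))
  }
  dl <- c(-Inf, d[-256L]); dr <- c(d[-1L], -Inf)
  local_max <- d > 0 & d >= dl & d >= dr
  cand <- which(local_max)
  as.integer(cand[which.max(d[cand])] - 1L)
}

#' Rutherford-Appleton (RATS) gradient-weighted threshold
#'
#' Weights every pixel by the maximum of its absolute central-difference
#' gradients and returns the gradient-weighted mean intensity
#' `sum(g * I) / sum(g)`, in response units.
#'
#' @param image numeric matrix.
#' @return threshold in response-value units.
#' @export
rats <- function(image) {
  validate_image(image)
  n <- nrow(image); m <- ncol(image)
  if (n < 3L || m < 3L) stop("image too small for central differences")
  P <- pad_reflect(image, 1L)
  dx <- (P[2:(n + 1), 3:(m + 2)] - P[2:(n + 1), 1:m]) / 2
  dy <- (P[3:(n + 2), 2:(m + 1)] - P[1:n, 2:(m + 1)]) / 2
  g <- pmax(abs(dx), abs(dy))
  sg <- sum(g)
  if (sg == 0) stop("constant image: no gradient support")
  sum(g * image) / sg
}

#' Local-window parameters for adaptive thresholding
#'
#' @param window odd neighborhood side (>= 3), default 15.
#' @param k method weight: Niblack default -0.2, Sauvola default 0.5.
#' @param R Sauvola dynamic-range constant (responses in `[0, 1]`:
#'   default 0.5).
#' @param bias White-Rohrer multiplicative factor, default 1.
#' @return an object of class `local_params`.
#' @export
local_params <- function(window = 15L, k = NULL, R = 0.5, bias = 1.0) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("`window` must be odd and >= 3")
  structure(list(window = window, k = k, R = R, bias = bias),
            class = "local_params")
}

# Local mean and standard deviation over an odd square window, reflect
# padding. Summed-area tables keep the arithmetic exact enough that a
# constant image yields a local mean identical to the constant (the local
# methods compare with strict inequalities).
local_stats <- function(image, window) {
  if (window > min(dim(image))) stop("window larger than image")
  h <- (window - 1L) %/% 2L
  n <- nrow(image); m <- ncol(image)
  box_mean <- function(M) {
    P <- pad_reflect(M, h)
    S <- matrix(0, nrow(P) + 1L, ncol(P) + 1L)
    S[-1L, -1L] <- apply(apply(P, 2L, cumsum), 1L, cumsum) |> t()
    ri <- seq_len(n); ci <- seq_len(m)
    (S[ri + 2L * h + 1L, ci + 2L * h + 1L, drop = FALSE] -
       S[ri, ci + 2L * h + 1L, drop = FALSE] -
       S[ri + 2L * h + 1L, ci, drop = FALSE] +
       S[ri, ci, drop = FALSE]) / window^2
  }
  mu <- box_mean(image)
  s <- sqrt(pmax(box_mean(image^2) - mu^2, 0))
  list(mean = mu, sd = s)
}

#' Niblack local threshold
#'
#' Pixel `p` is foreground iff `response(p) > m(p) + k * s(p)` with local
#' mean `m` and standard deviation `s` over the window.
#'
#' @param image numeric response matrix.
#' @param params a [local_params()]; `k` defaults to -0.2.
#' @return logical mask.
#' @export
niblack <- function(image, params = local_params()) {
  validate_image(image)
  k <- if (is.null(params$k)) -0.2 else params$k
  ls <- local_stats(image, params$window)
  image > ls$mean + k * ls$sd
}

#' Sauvola local threshold
#'
#' Pixel `p` is foreground iff
#' `response(p) > m(p) * (1 + k * (s(p)/R - 1))`. Note the standard formula
#' lowers the threshold where the local spread is small (for `k > 0`,
#' `m > 0`), which is the usual published form even though the method is
#' often described the other way around.
#'
#' @param image numeric response matrix.
#' @param params a [local_params()]; `k` defaults to 0.5, `R` to 0.5.
#' @return logical mask.
#' @export
sauvola <- function(image, params = local_params()) {
  validate_image(image)
  k <- if (is.null(params$k)) 0.5 else params$k
  if (params$R <= 0) stop("`R` must be positive")
  ls <- local_stats(image, params$window)
  image > ls$mean * (1 + k * (ls$sd / params$R - 1))
}

#' White-Rohrer local threshold
#'
#' Pixel `p` is foreground iff `bias * response(p) > m(p)` with `m` the
#' local mean (the expected intensity of the neighborhood).
#'
#' @param image numeric response matrix.
#' @param params a [local_params()]; `bias` defaults to 1.
#' @return logical mask.
#' @export
white_rohrer <- function(image, params = local_params()) {
  validate_image(image)
  if (params$bias <= 0) stop("`bias` must be positive")
  ls <- local_stats(image, params$window)
  params$bias * image > ls$mean
}

#' Names of the available thresholding methods
#' @return character vector of the ten method names accepted by [segment()].
#' @export
threshold_methods <- function() {
  c("otsu", "ridler_calvard", "kapur", "pal", "moments", "concavity",
    "rats", "niblack", "sauvola", "white_rohrer")
}

#' Binarize a detection response
#'
#' Dispatches to one of the ten thresholding methods. Global methods build
#' the 256-bin histogram, pick a bin threshold `t` and keep pixels with bin
#' index `> t`; `rats` thresholds in response units; local methods compute
#' per-pixel thresholds directly. Degenerate inputs (constant response)
#' yield an all-background mask with a warning, and a histogram with no
#' concavity makes `concavity` fall back to Otsu with a warning.
#'
#' @param image numeric response matrix (vessels = high values).
#' @param method one of [threshold_methods()].
#' @param params a [local_params()] for the local methods.
#' @return logical mask, `TRUE` = vessel.
#' @examples
#' r <- matrix(rnorm(64 * 64), 64, 64); r[20:40, 30:34] <- r[20:40, 30:34] + 4
#' mean(segment(r, "otsu"))
#' @export
segment <- function(image, method = "otsu", params = local_params()) {
  validate_image(image)
  method <- match.arg(method, threshold_methods())
  if (method %in% c("niblack", "sauvola", "white_rohrer")) {
    return(switch(method,
                  niblack = niblack(image, params),
                  sauvola = sauvola(image, params),
                  white_rohrer = white_rohrer(image, params)))
  }
  if (method == "rats") {
    tv <- tryCatch(rats(image), error = function(e) NA_real_)
    if (!is.finite(tv)) {
      warning("degenerate response; returning all-background mask")
      return(matrix(FALSE, nrow(image), ncol(image)))
    }
    return(image > tv)
  }
  hist <- make_histogram(image)
  if (hist$degenerate || sum(hist$counts > 0) < 2L) {
    warning("degenerate response; returning all-background mask")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  t <- switch(method,
    otsu = otsu(hist),
    ridler_calvard = as.integer(ridler_calvard(hist)),
    kapur = kapur(hist),
    pal = pal_entropy(hist),
    moments = as.integer(moments(hist)),
    concavity = tryCatch(concavity(hist), mgmf_no_concavity = function(e) {
      warning("no histogram concavity; falling back to Otsu")
      otsu(hist)
    })
  )
  image_bins(image, hist) > t
}
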