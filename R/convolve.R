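# Internal 2-D correlation machinery shared by the filter bank and the local
# thresholding methods. Correlation is computed as a circular cross-correlation
# on a reflect-padded image, via the FFT, with the padded plane zero-extended
# to a highly composite size so stats::fft stays fast for any image size.

#' Reflect-pad a matrix
#'
#' Pads `x` by `h` rows/columns on every side, mirroring with the edge value
#' repeated (the `reflect` convention: `c b a | a b c ...`).
#'
#' @param x numeric matrix.
#' @param h non-negative integer pad width; must not exceed either dimension.
#' @return a `(nrow(x) + 2h) x (ncol(x) + 2h)` matrix.
#' @keywords internal
#' @noRd
pad_reflect <- function(x, h) {
  if (h == 0L) return(x)
  n <- nrow(x); m <- ncol(x)
  if (h > n || h > m) {
    stop("pad width ", h, " exceeds image size ", n, "x", m)
  }
  ri <- c(h:1, 1:n, n:(n - h + 1L))
  ci <- c(h:1, 1:m, m:(m - h + 1L))
  x[ri, ci, drop = FALSE]
}

# Precompute the FFT of the reflect-padded, zero-extended image plus the
# geometry needed to correlate it with any odd square kernel of side D.
prepare_correlation_plan <- function(image, D) {
  h <- (D - 1L) %/% 2L
  n <- nrow(image); m <- ncol(image)
  P0 <- pad_reflect(image, h)
  N1 <- stats::nextn(n + 2L * h, c(2L, 3L, 5L))
  N2 <- stats::nextn(m + 2L * h, c(2L, 3L, 5L))
  P <- matrix(0, N1, N2)
  P[seq_len(n + 2L * h), seq_len(m + 2L * h)] <- P0
  list(FP = stats::fft(P), N1 = N1, N2 = N2, n = n, m = m, h = h)
}

# Wrap a D x D kernel into the circular N1 x N2 frequency-domain layout:
# the kernel cell at offset (dy, dx), dy/dx in -h..h, lands at index
# (dy mod N1, dx mod N2).
kernel_fft <- function(weights, plan) {
  h <- plan$h
  Kc <- matrix(0, plan$N1, plan$N2)
  ri <- ((-h:h) %% plan$N1) + 1L
  ci <- ((-h:h) %% plan$N2) + 1L
  Kc[ri, ci] <- weights
  stats::fft(Kc)
}

# Correlation (no kernel flip): out(r, c) = sum_{dy,dx} K(dy,dx) I(r+dy, c+dx)
# with reflect border handling, same shape as the planned image.
correlate_planned <- function(plan, FK) {
  R <- Re(stats::fft(plan$FP * Conj(FK), inverse = TRUE)) / (plan$N1 * plan$N2)
  R[plan$h + seq_len(plan$n), plan$h + seq_len(plan$m), drop = FALSE]
}

#' Correlate an image with a single odd square kernel (reflect padding)
#' @keywords internal
#' @noRd
correlate2d <- function(image, weights) {
  D <- nrow(weights)
  stopifnot(D == ncol(weights), D %% 2L == 1L)
  plan <- prepare_correlation_plan(image, D)
  correlate_planned(plan, kernel_fft(weights, plan))
}
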