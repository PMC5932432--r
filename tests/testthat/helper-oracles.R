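# Independent oracles and shared fixtures. The oracles deliberately use
# naive loops / direct formula evaluation so they share no code path with
# the implementation they check.

# Quadruple-loop correlation with explicit max over orientations.
brute_force_bank_response <- function(image, bank) {
  D <- nrow(bank[[1L]]$weights)
  h <- (D - 1L) %/% 2L
  pad <- mgmf:::pad_reflect(image, h)
  n <- nrow(image); m <- ncol(image)
  out <- matrix(-Inf, n, m)
  for (k in bank) {
    for (r in seq_len(n)) for (c in seq_len(m)) {
      s <- 0
      for (a in -h:h) for (b in -h:h) {
        s <- s + k$weights[a + h + 1L, b + h + 1L] * pad[r + h + a, c + h + b]
      }
      out[r, c] <- max(out[r, c], s)
    }
  }
  out
}

# Exhaustive 256-candidate scan of a histogram objective; smallest
# maximizer wins (strict-improvement comparison).
brute_scan <- function(counts, objective) {
  best <- -Inf; bt <- NA_integer_
  for (t in 0:254) {
    v <- objective(counts, t)
    if (is.finite(v) && v > best + 1e-12) { best <- v; bt <- t }
  }
  bt
}

oracle_otsu_obj <- function(counts, t) {
  n <- sum(counts); i <- 0:255
  c0 <- sum(counts[1:(t + 1)]); c1 <- n - c0
  if (c0 == 0 || c1 == 0) return(-Inf)
  mu0 <- sum(i[1:(t + 1)] * counts[1:(t + 1)]) / c0
  mu1 <- sum(i[(t + 2):256] * counts[(t + 2):256]) / c1
  (c0 / n) * (c1 / n) * (mu0 - mu1)^2
}

oracle_kapur_obj <- function(counts, t) {
  p <- counts / sum(counts)
  P0 <- sum(p[1:(t + 1)]); P1 <- 1 - P0
  if (P0 <= 0 || P1 <= 0) return(-Inf)
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  H(p[1:(t + 1)] / P0) + H(p[(t + 2):256] / P1)
}

oracle_pal_obj <- function(counts, t) {
  p <- counts / sum(counts)
  P0 <- sum(p[1:(t + 1)]); P1 <- 1 - P0
  if (P0 <= 0 || P1 <= 0) return(-Inf)
  q0 <- p[1:(t + 1)] / P0; q1 <- p[(t + 2):256] / P1
  sum(q0 * exp(1 - q0)) + sum(q1 * exp(1 - q1))
}

# Hull-difference objective restricted to local maxima of the difference,
# recomputed from scratch with chull() on a lifted point set.
oracle_concavity <- function(counts) {
  x <- 0:255; y <- as.numeric(counts)
  ch <- grDevices::chull(c(x, x), c(y, rep(min(y) - 1, 256)))
  up <- sort(unique(ch[ch <= 256]))          # indices of upper-boundary points
  hull <- stats::approx(x[up], y[up], xout = x)$y
  d <- hull - y
  d[d < 1e-9] <- 0
  if (all(d == 0)) return(NA_integer_)
  dl <- c(-Inf, d[-256]); dr <- c(d[-1], -Inf)
  cand <- which(d > 0 & d >= dl & d >= dr)
  as.integer(cand[which.max(d[cand])] - 1L)
}

random_histogram <- function() {
  counts <- stats::rpois(256, stats::runif(1, 0.5, 30))
  if (sum(counts > 0) < 2L) counts[c(1, 256)] <- counts[c(1, 256)] + 1L
  as.integer(counts)
}

# Pairwise Mann-Whitney AUC on (sub)samples of continuous scores.
mann_whitney_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# Small clean phantom helpers used across test files.
clean_phantom <- function(seed, size = 128L, sigma = 2.0, n_vessels = 3L) {
  generate_phantom(phantom_config(
    size = size, n_vessels = n_vessels, width_range = c(sigma, sigma),
    noise_sigma = 0, illumination_amplitude = 0, seed = seed))
}
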