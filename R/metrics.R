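#' Pixelwise confusion counts for a binary segmentation
#'
#' Tabulates true/false positives and negatives of a predicted mask against
#' a ground-truth mask, with vessel pixels as the positive class.
#'
#' @param pred_mask,gt_mask logical or 0/1 numeric matrices of equal shape.
#' @return an object of class `confusion_counts`: list with `TP`, `FP`,
#'   `TN`, `FN` (their sum equals the number of evaluated pixels).
#' @export
confusion <- function(pred_mask, gt_mask) {
  pred <- as_binary(pred_mask, "pred_mask")
  gt <- as_binary(gt_mask, "gt_mask")
  if (!identical(dim(pred), dim(gt))) stop("mask shapes differ")
  structure(
    list(TP = sum(pred & gt), FP = sum(pred & !gt),
         TN = sum(!pred & !gt), FN = sum(!pred & gt)),
    class = "confusion_counts"
  )
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x) && all(x %in% c(0, 1))) return(x == 1)
  stop("`", what, "` must be logical or strictly 0/1")
}

#' Segmentation accuracy
#'
#' The fraction of correctly classified pixels,
#' `(TP + TN) / (TP + FP + TN + FN)`.
#'
#' @param counts a `confusion_counts` object (or a mask pair via `...`).
#' @return a number in `[0, 1]`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$TP + counts$FP + counts$TN + counts$FN
  if (total == 0) stop("empty confusion counts")
  (counts$TP + counts$TN) / total
}

#' ROC curve of a gray-scale detection response
#'
#' Sweeps `n_thresholds + 1` evenly spaced cutoffs over the response range;
#' at each cutoff, pixels with response `>= cutoff` are called vessels, giving
#' one (false-positive fraction, true-positive fraction) point. The sweep is
#' ordered from the highest cutoff down, so both coordinates are
#' non-decreasing, and the endpoints (0, 0) and (1, 1) are included.
#'
#' @param response numeric matrix (or vector) of detection scores.
#' @param gt_mask ground-truth mask of the same shape, containing both
#'   classes.
#' @param n_thresholds number of sweep intervals (default 256).
#' @return an object of class `roc_curve`: list with `points` (two-column
#'   matrix `FPF`, `TPF`) and `thresholds` (the sweep cutoffs, `NA` for the
#'   appended endpoints).
#' @export
roc <- function(response, gt_mask, n_thresholds = 256L) {
  gt <- as_binary(gt_mask, "gt_mask")
  if (length(response) != length(gt)) stop("shapes differ")
  if (!is.null(dim(response)) && !is.null(dim(gt)) &&
      !identical(dim(response), dim(gt))) stop("shapes differ")
  scores <- as.vector(response)
  g <- as.vector(gt)
  n1 <- sum(g); n0 <- sum(!g)
  if (n1 == 0L || n0 == 0L) stop("ground truth must contain both classes")
  lo <- min(scores); hi <- max(scores)
  cuts <- if (hi > lo) seq(lo, hi, length.out = n_thresholds + 1L) else lo
  cuts <- rev(cuts)                       # high cutoff first: (0,0) -> (1,1)
  pos <- sort(scores[g]); neg <- sort(scores[!g])
  tpf <- (n1 - findInterval(cuts, pos, left.open = TRUE)) / n1
  fpf <- (n0 - findInterval(cuts, neg, left.open = TRUE)) / n0
  pts <- cbind(FPF = c(0, fpf, 1), TPF = c(0, tpf, 1))
  structure(list(points = pts, thresholds = c(NA, cuts, NA)),
            class = "roc_curve")
}

#' Area under the ROC curve (A_z)
#'
#' Integrates the ROC curve over the false-positive fraction by the
#' trapezoidal Riemann sum (default) or the literal left-endpoint sum.
#'
#' @param curve a `roc_curve` object.
#' @param rule `"trapezoid"` (default) or `"left"`.
#' @return the area `A_z` in `[0, 1]`.
#' @export
auc <- function(curve, rule = c("trapezoid", "left")) {
  stopifnot(inherits(curve, "roc_curve"))
  rule <- match.arg(rule)
  p <- curve$points[order(curve$points[, "FPF"], curve$points[, "TPF"]), ,
                    drop = FALSE]
  if (nrow(p) < 2L) stop("ROC curve needs at least 2 points")
  dx <- diff(p[, "FPF"])
  y <- p[, "TPF"]
  if (rule == "trapezoid") {
    sum(dx * (y[-1L] + y[-length(y)]) / 2)
  } else {
    sum(dx * y[-length(y)])
  }
}

#' Pooled A_z over a set of response/ground-truth pairs
#'
#' Pools all pixels of all images into one ROC sweep (the convention used
#' for whole-set figures); per-image averaging is available via
#' `pool = FALSE`.
#'
#' @param responses list of response matrices (or a single matrix).
#' @param masks list of matching ground-truth masks.
#' @param n_thresholds sweep resolution, as in [roc()].
#' @param pool pool pixels across images (default) or average per-image A_z.
#' @return a single A_z value.
#' @export
dataset_auc <- function(responses, masks, n_thresholds = 256L, pool = TRUE) {
  if (is.matrix(responses)) responses <- list(responses)
  if (is.matrix(masks) || is.logical(masks)) masks <- list(masks)
  stopifnot(length(responses) == length(masks))
  if (pool) {
    r <- unlist(lapply(responses, as.vector), use.names = FALSE)
    g <- unlist(lapply(masks, as.vector), use.names = FALSE)
    auc(roc(r, g, n_thresholds))
  } else {
    mean(vapply(seq_along(responses), function(i) {
      auc(roc(responses[[i]], masks[[i]], n_thresholds))
    }, numeric(1)))
  }
}
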