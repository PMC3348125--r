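#' Match estimated centroids to ground truth
#'
#' One-to-one greedy matching inside a spherical window: every GT-estimate
#' pair with Euclidean distance at most `radius` (closed ball) is listed,
#' pairs are sorted by ascending distance, and accepted in order skipping
#' any pair whose GT or estimate is already used — so when a window holds
#' several estimates the closest one is the correct detection, and no
#' estimate is counted twice.  Ties are broken by GT then estimate label
#' for determinism.
#'
#' @param gt Ground-truth centroid tibble.
#' @param est Estimated centroid tibble.
#' @param radius Matching window radius in voxels (default 10).
#' @return An object of class `nuc_match`: list with `pairs` (tibble of
#'   `gt_label`, `est_label`, `distance`), `unmatched_gt`, `unmatched_est`
#'   and `window_radius`.
#' @export
match_centroids <- function(gt, est, radius = 10) {
  if (!is.numeric(radius) || radius <= 0)
    stop_validation("`radius` must be > 0")
  ng <- nrow(gt); ne <- nrow(est)
  pairs <- tibble(gt_label = integer(), est_label = integer(),
                  distance = numeric())
  if (ng > 0 && ne > 0) {
    gm <- as.matrix(gt[, c("x", "y", "z")])
    em <- as.matrix(est[, c("x", "y", "z")])
    dmat <- outer(rowSums(gm^2), rep(1, ne)) +
      outer(rep(1, ng), rowSums(em^2)) - 2 * gm %*% t(em)
    dmat <- sqrt(pmax(dmat, 0))
    cand <- which(dmat <= radius, arr.ind = TRUE)
    if (nrow(cand) > 0) {
      ord <- order(dmat[cand], gt$label[cand[, 1]], est$label[cand[, 2]])
      cand <- cand[ord, , drop = FALSE]
      used_g <- logical(ng); used_e <- logical(ne)
      keep_g <- integer(); keep_e <- integer(); keep_d <- numeric()
      for (r in seq_len(nrow(cand))) {
        i <- cand[r, 1]; j <- cand[r, 2]
        if (used_g[i] || used_e[j]) next
        used_g[i] <- TRUE; used_e[j] <- TRUE
        keep_g <- c(keep_g, gt$label[i])
        keep_e <- c(keep_e, est$label[j])
        keep_d <- c(keep_d, dmat[i, j])
      }
      pairs <- tibble(gt_label = keep_g, est_label = keep_e,
                      distance = keep_d)
    }
  }
  structure(list(
    pairs = pairs,
    unmatched_gt = setdiff(gt$label, pairs$gt_label),
    unmatched_est = setdiff(est$label, pairs$est_label),
    window_radius = radius),
    class = "nuc_match")
}

#' @export
print.nuc_match <- function(x, ...) {
  cat(sprintf("<nuc_match> %d matched, %d missed GT, %d false detections (radius %g)\n",
              nrow(x$pairs), length(x$unmatched_gt), length(x$unmatched_est),
              x$window_radius))
  invisible(x)
}

#' Tidy the matched-pair table
#'
#' @param x A `nuc_match` from [match_centroids()].
#' @param ... Unused.
#' @return The pair tibble (`gt_label`, `est_label`, `distance`).
#' @method tidy nuc_match
#' @export
tidy.nuc_match <- function(x, ...) x$pairs

#' One-row count summary of a matching
#'
#' @param x A `nuc_match` from [match_centroids()].
#' @param ... Unused.
#' @return A one-row tibble with TP/FP/FN counts and the window radius.
#' @method glance nuc_match
#' @export
glance.nuc_match <- function(x, ...) {
  tibble(tp = nrow(x$pairs), fn = length(x$unmatched_gt),
         fp = length(x$unmatched_est), window_radius = x$window_radius)
}

#' Detection metrics from a matching
#'
#' Sensitivity `100 * TP / N_GT`, precision `100 * TP / N_est` (0 with a
#' warning when nothing was detected), RMSE over the matched pairs'
#' Euclidean distances, and — when the volume shape is supplied — the
#' voxel-level specificity `100 * TN / (TN + FP)` with
#' `TN = total voxels - N_GT - FP` (each nucleus is represented by its
#' centroid voxel, so almost every voxel is a true negative).
#'
#' @param match A `nuc_match` from [match_centroids()].
#' @param gt,est The centroid tibbles that were matched.
#' @param volume_shape Optional integer length-3 shape for specificity.
#' @return A one-row tibble with counts (`tp`, `fp`, `fn`, `n_gt`, `n_est`)
#'   and metrics (`sensitivity`, `precision`, `rmse`, `specificity`),
#'   percentages on the 0-100 scale.
#' @export
detection_metrics <- function(match, gt, est, volume_shape = NULL) {
  n_gt <- nrow(gt); n_est <- nrow(est)
  if (n_gt == 0)
    stop_validation("empty ground-truth set")
  tp <- nrow(match$pairs)
  fp <- n_est - tp
  fn <- n_gt - tp
  sens <- 100 * tp / n_gt
  if (n_est == 0) {
    warn("no estimated centroids: precision reported as 0")
    prec <- 0
  } else prec <- 100 * tp / n_est
  rmse <- if (tp > 0) sqrt(mean(match$pairs$distance^2)) else NA_real_
  specificity <- NA_real_
  if (!is.null(volume_shape)) {
    tn <- prod(as.numeric(volume_shape)) - n_gt - fp
    specificity <- 100 * tn / (tn + fp)
  }
  tibble(tp = tp, fp = fp, fn = fn, n_gt = n_gt, n_est = n_est,
         sensitivity = sens, precision = prec, rmse = rmse,
         specificity = specificity)
}

#' Standard error of a metric series
#'
#' `SE = sd(x) / sqrt(n)`, i.e. `sqrt(sum((x - mean)^2) / (n (n - 1)))`,
#' used to quantify the temporal variability of a per-time-point metric.
#'
#' @param series Numeric vector of length >= 2.
#' @return The standard error.
#' @export
standard_error <- function(series) {
  if (length(series) < 2)
    stop_validation("need at least 2 values")
  sd(series) / sqrt(length(series))
}
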