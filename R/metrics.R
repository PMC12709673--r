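#' F1 score for binary predictions
#'
#' `F1 = 2PR / (P + R) = 2TP / (2TP + FP + FN)`.  Returns `NA` when there
#' are neither true nor predicted positives (precision and recall are both
#' undefined).
#'
#' @param truth,pred Logical / 0-1 vectors (or matrices, pooled element-wise
#'   for a micro-average).
#' @return F1 in \[0, 1\], or `NA`.
#' @export
f1_score <- function(truth, pred) {
  truth <- as.logical(truth); pred <- as.logical(pred)
  tp <- sum(truth & pred)
  fp <- sum(!truth & pred)
  fn <- sum(truth & !pred)
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: scores are swept from
#' the highest unique value downward and the precision at each threshold is
#' weighted by the recall gained there,
#' `AP = sum_i (R_i - R_{i-1}) * P_i`.  Requires at least one positive;
#' returns `NA` otherwise.
#'
#' @param truth Logical / 0-1 vector.
#' @param scores Numeric prediction scores (higher = more positive).
#' @return Average precision in \[0, 1\], or `NA` when no positives exist.
#' @export
auprc <- function(truth, scores) {
  truth <- as.logical(truth)
  n_pos <- sum(truth)
  if (n_pos == 0L) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; t <- truth[ord]
  ## collapse tied scores into single thresholds
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(t)[last_of_run]
  np <- seq_along(t)[last_of_run]
  prec <- tp / np
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

## Tidy per-cell metrics for one validation fold: rows for overall
## ("all"/"all"), per-target, per-stratum, and per-(stratum, target) cells.
## Cells with no positives (AUPRC) or no positives-or-predictions (F1) are
## recorded as NA, not zero.
fold_metric_rows <- function(truth, prob, k, targets,
                             threshold = 0.5, per_stratum = TRUE) {
  pred <- prob >= threshold
  rows <- list()
  add <- function(stratum, target, truth_, prob_, pred_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = stratum, target = target,
      f1 = f1_score(truth_, pred_),
      auprc = auprc(truth_, prob_),
      n = if (is.matrix(truth_)) nrow(truth_) else length(truth_),
      stringsAsFactors = FALSE)
  }
  add("all", "all", truth, prob, pred)          # micro over all cells
  for (j in seq_along(targets)) {
    add("all", targets[j], truth[, j], prob[, j], pred[, j])
  }
  if (per_stratum) {
    for (kk in sort(unique(k))) {
      sel <- k == kk
      add(as.character(kk), "all",
          truth[sel, , drop = FALSE], prob[sel, , drop = FALSE],
          pred[sel, , drop = FALSE])
    }
  }
  do.call(rbind, rows)
}
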