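# Evaluation metrics: midpoint-bracketing sensitivity and midpoint-distance
# accuracy against ground-truth state annotations.

new_eval_report <- function(tp, fn, sensitivity, mean_midpoint_error_s1,
                            mean_midpoint_error_s2, n_truth_s1, n_truth_s2) {
  structure(
    list(tp = tp, fn = fn, sensitivity = sensitivity,
         mean_midpoint_error_s1 = mean_midpoint_error_s1,
         mean_midpoint_error_s2 = mean_midpoint_error_s2,
         n_truth_s1 = n_truth_s1, n_truth_s2 = n_truth_s2),
    class = "pcg_eval"
  )
}

#' Build an evaluation report from TP/FN counts
#'
#' Computes sensitivity as `TP / (TP + FN)`; useful for pooling published
#' or externally tabulated counts.
#'
#' @param tp,fn True-positive and false-negative counts.
#' @param mean_midpoint_error_s1,mean_midpoint_error_s2 Optional mean
#'   absolute midpoint errors in seconds.
#' @param n_truth_s1,n_truth_s2 Optional ground-truth sound counts.
#' @return A `pcg_eval` report.
#' @export
eval_report <- function(tp, fn, mean_midpoint_error_s1 = NA_real_,
                        mean_midpoint_error_s2 = NA_real_,
                        n_truth_s1 = NA_integer_, n_truth_s2 = NA_integer_) {
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  new_eval_report(tp, fn, sens, mean_midpoint_error_s1,
                  mean_midpoint_error_s2, n_truth_s1, n_truth_s2)
}

#' @export
print.pcg_eval <- function(x, ...) {
  cat(sprintf(
    "<pcg_eval> TP %d, FN %d, sensitivity %.2f%%; midpoint error S1 %.2f ms, S2 %.2f ms\n",
    x$tp, x$fn, 100 * x$sensitivity, 1000 * x$mean_midpoint_error_s1,
    1000 * x$mean_midpoint_error_s2))
  invisible(x)
}

# predictions of one sound type restricted to the truth-annotated span;
# returns midpoints. Predicted sounds wholly outside the span are
# disregarded (the segmenter can find more cycles than truth covers).
pred_midpoints_in_span <- function(pred, state, span) {
  p <- pred[pred$state == state & pred$offset > span[1] &
              pred$onset < span[2], , drop = FALSE]
  (p$onset + p$offset) / 2
}

#' Midpoint-bracketing sensitivity
#'
#' A ground-truth sound counts as a true positive when the midpoint of
#' some predicted sound of the same type (S1 or S2) falls inside the truth
#' interval `[onset, offset)` (half-open: a midpoint exactly at the onset
#' is inside, one at the offset is not). Unmatched truth sounds are false
#' negatives; `sensitivity = TP / (TP + FN)`. Predicted sounds outside the
#' truth-annotated span (first truth onset to last truth offset) are
#' disregarded. S1 and S2 are pooled in the reported counts.
#'
#' @param pred A segmentation object or annotation table (predictions).
#' @param truth A ground-truth annotation table, same time base.
#' @return A `pcg_eval` report; with empty truth, sensitivity is `NaN` and
#'   the counts are zero.
#' @export
sensitivity_eval <- function(pred, truth) {
  pred <- as_annotation(pred)
  truth <- as_annotation(truth)
  if (nrow(truth) == 0L) {
    return(new_eval_report(0L, 0L, NaN, NA_real_, NA_real_, 0L, 0L))
  }
  span <- c(min(truth$onset), max(truth$offset))
  tp <- 0L
  fn <- 0L
  n_truth <- c(`1` = 0L, `3` = 0L)
  for (state in c(1L, 3L)) {
    tr <- truth[truth$state == state, , drop = FALSE]
    n_truth[as.character(state)] <- nrow(tr)
    if (nrow(tr) == 0L) next
    mids <- pred_midpoints_in_span(pred, state, span)
    hit <- vapply(seq_len(nrow(tr)), function(i) {
      any(mids >= tr$onset[i] & mids < tr$offset[i])
    }, logical(1))
    tp <- tp + sum(hit)
    fn <- fn + sum(!hit)
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NaN
  new_eval_report(tp, fn, sens, NA_real_, NA_real_,
                  n_truth[["1"]], n_truth[["3"]])
}

# greedy one-to-one matching by ascending midpoint distance; returns the
# matched absolute distances
greedy_match_distances <- function(truth_mids, pred_mids) {
  if (length(truth_mids) == 0L || length(pred_mids) == 0L) return(numeric(0))
  d <- abs(outer(truth_mids, pred_mids, "-"))
  ord <- order(d)
  used_t <- logical(length(truth_mids))
  used_p <- logical(length(pred_mids))
  out <- numeric(0)
  for (k in ord) {
    i <- (k - 1L) %% length(truth_mids) + 1L
    j <- (k - 1L) %/% length(truth_mids) + 1L
    if (!used_t[i] && !used_p[j]) {
      used_t[i] <- TRUE
      used_p[j] <- TRUE
      out <- c(out, d[i, j])
      if (all(used_t) || all(used_p)) break
    }
  }
  out
}

#' Midpoint-distance accuracy
#'
#' Matches each ground-truth S1 (resp. S2) to a predicted S1 (resp. S2)
#' one-to-one, greedily by ascending midpoint distance, and reports the
#' mean absolute midpoint difference per sound type in seconds. Predicted
#' sounds outside the truth-annotated span are disregarded, as for
#' [sensitivity_eval()].
#'
#' @inheritParams sensitivity_eval
#' @return A `pcg_eval` report carrying `mean_midpoint_error_s1` and
#'   `mean_midpoint_error_s2` (seconds; `NaN` when no pair matches).
#' @export
accuracy_eval <- function(pred, truth) {
  pred <- as_annotation(pred)
  truth <- as_annotation(truth)
  if (nrow(truth) == 0L) {
    return(new_eval_report(0L, 0L, NaN, NaN, NaN, 0L, 0L))
  }
  span <- c(min(truth$onset), max(truth$offset))
  err <- c(NaN, NaN)
  n_truth <- c(0L, 0L)
  for (k in 1:2) {
    state <- c(1L, 3L)[k]
    tr <- truth[truth$state == state, , drop = FALSE]
    n_truth[k] <- nrow(tr)
    dm <- greedy_match_distances((tr$onset + tr$offset) / 2,
                                 pred_midpoints_in_span(pred, state, span))
    err[k] <- if (length(dm)) mean(dm) else NaN
  }
  new_eval_report(NA_integer_, NA_integer_, NaN, err[1], err[2],
                  n_truth[1], n_truth[2])
}

#' Full evaluation of a segmentation against ground truth
#'
#' Convenience wrapper combining [sensitivity_eval()] and
#' [accuracy_eval()] into one report.
#'
#' @inheritParams sensitivity_eval
#' @return A `pcg_eval` report with counts, sensitivity and both mean
#'   midpoint errors.
#' @export
evaluate_segmentation <- function(pred, truth) {
  s <- sensitivity_eval(pred, truth)
  a <- accuracy_eval(pred, truth)
  new_eval_report(s$tp, s$fn, s$sensitivity, a$mean_midpoint_error_s1,
                  a$mean_midpoint_error_s2, s$n_truth_s1, s$n_truth_s2)
}

#' Pool evaluation reports over recordings
#'
#' TP/FN counts are summed (pooled sensitivity); midpoint errors are
#' averaged over the recordings that produced one.
#'
#' @param reports A list of `pcg_eval` reports.
#' @return A single pooled `pcg_eval` report.
#' @export
pool_eval <- function(reports) {
  stopifnot(length(reports) > 0)
  g <- function(f) vapply(reports, function(r) as.numeric(r[[f]]), numeric(1))
  tp <- sum(g("tp"), na.rm = TRUE)
  fn <- sum(g("fn"), na.rm = TRUE)
  mean_ok <- function(v) if (any(is.finite(v))) mean(v[is.finite(v)]) else NaN
  new_eval_report(
    tp, fn, if (tp + fn > 0) tp / (tp + fn) else NaN,
    mean_ok(g("mean_midpoint_error_s1")), mean_ok(g("mean_midpoint_error_s2")),
    sum(g("n_truth_s1"), na.rm = TRUE), sum(g("n_truth_s2"), na.rm = TRUE)
  )
}

#' Relative error of a midpoint accuracy against a nominal sound duration
#'
#' Expresses a mean midpoint error as a percentage of the nominal primary
#' heart sound duration (250 ms).
#'
#' @param error_ms Mean midpoint error in milliseconds.
#' @param nominal_ms Nominal sound duration in milliseconds.
#' @return The relative error in percent.
#' @export
relative_error_pct <- function(error_ms, nominal_ms = 250) {
  100 * error_ms / nominal_ms
}
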