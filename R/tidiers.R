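# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmentation into its labeled intervals
#'
#' @param x A `pcg_segmentation`.
#' @param ... Unused.
#' @return A tibble with `start_s`, `end_s`, `label` and the integer
#'   `state` code of the annotation dialect.
#' @method tidy pcg_segmentation
#' @export
tidy.pcg_segmentation <- function(x, ...) {
  iv <- x$intervals
  tibble::tibble(start_s = iv$start_s, end_s = iv$end_s, label = iv$label,
                 state = unname(STATE_CODES[iv$label]))
}

#' One-row summary of a segmentation
#'
#' @param x A `pcg_segmentation`.
#' @param ... Unused.
#' @return A one-row tibble: `success`, `n_s1`, `n_s2`, `cycle_length_s`,
#'   `systole_s`.
#' @method glance pcg_segmentation
#' @export
glance.pcg_segmentation <- function(x, ...) {
  tibble::tibble(
    success = x$success,
    n_s1 = sum(x$intervals$label == "S1"),
    n_s2 = sum(x$intervals$label == "S2"),
    cycle_length_s = x$cycle_length_s,
    systole_s = x$systole_s
  )
}

#' Tidy an evaluation report
#'
#' @param x A `pcg_eval`.
#' @param ... Unused.
#' @return A one-row tibble of counts, sensitivity and midpoint errors.
#' @method tidy pcg_eval
#' @export
tidy.pcg_eval <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fn = x$fn, sensitivity = x$sensitivity,
    mean_midpoint_error_s1 = x$mean_midpoint_error_s1,
    mean_midpoint_error_s2 = x$mean_midpoint_error_s2,
    n_truth_s1 = x$n_truth_s1, n_truth_s2 = x$n_truth_s2
  )
}

#' @rdname tidy.pcg_eval
#' @method glance pcg_eval
#' @export
glance.pcg_eval <- tidy.pcg_eval

#' Tidy per-lobe outlier statistics
#'
#' @param x An [outlier_stats()] result.
#' @param ... Unused.
#' @return A tibble with one row per lobe: `lobe`, `area`, `zscore`,
#'   `outlier`.
#' @method tidy outlier_stats
#' @export
tidy.outlier_stats <- function(x, ...) {
  tibble::tibble(
    lobe = seq_len(x$M), area = x$areas, zscore = x$zscores,
    outlier = seq_len(x$M) %in% x$outlier_idx
  )
}
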