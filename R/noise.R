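# Noise-robust layer: flag outlier lobes by the z-score of their envelope
# area, crop them out, and segment each remaining clean interval
# independently.

#' Outlier statistics of lobe areas
#'
#' High-energy artifacts (crying, stethoscope motion, speech) produce
#' envelope lobes whose area dwarfs the heart sound lobes. With `M` lobes
#' of areas `A_i`, the population mean and standard deviation (both divide
#' by `M`) give z-scores `z_i = (A_i - mean) / sd`; a lobe with
#' `z_i > cutoff` (default 2.75) is flagged as an outlier. When the areas
#' are all equal (`sd = 0`) nothing is flagged.
#'
#' @param areas Numeric vector of lobe areas (at least one), or a lobe
#'   tibble from [detect_lobes()] (its `area` column is used).
#' @param cutoff Z-score cutoff.
#' @return A list of class `outlier_stats` with fields `areas`,
#'   `mean_area`, `std_area`, `zscores`, `cutoff`, `outlier_idx` (1-based
#'   indices of flagged lobes) and `M`.
#' @export
outlier_stats <- function(areas, cutoff = 2.75) {
  if (is.data.frame(areas)) areas <- areas$area
  areas <- as.numeric(areas)
  if (length(areas) == 0L) stop("need at least one lobe")
  M <- length(areas)
  mean_area <- mean(areas)
  std_area <- sqrt(mean((areas - mean_area)^2))  # population (1/M) form
  z <- if (std_area > 0) (areas - mean_area) / std_area else numeric(M)
  structure(
    list(areas = areas, mean_area = mean_area, std_area = std_area,
         zscores = z, cutoff = cutoff, outlier_idx = which(z > cutoff),
         M = M),
    class = "outlier_stats"
  )
}

#' @export
print.outlier_stats <- function(x, ...) {
  cat(sprintf(
    "<outlier_stats> M = %d lobes, mean area %.4g, sd %.4g, cutoff %.2f: %d outlier(s)\n",
    x$M, x$mean_area, x$std_area, x$cutoff, length(x$outlier_idx)))
  invisible(x)
}

#' Clean intervals after cropping outlier lobes
#'
#' Removes `[start - margin, end + margin]` of every flagged lobe from the
#' recording's time span and returns the maximal remaining intervals;
#' intervals shorter than `min_clean_s` (too short to hold a cardiac
#' cycle) are dropped.
#'
#' @param rec The (preprocessed) [pcg_recording()], used for its duration.
#' @param lobes Lobe tibble the statistics were computed from.
#' @param stats An [outlier_stats()] object for those lobes.
#' @param margin_s Guard margin in seconds on each side of a cropped lobe.
#' @param min_clean_s Minimum retained interval length in seconds.
#' @return A tibble of disjoint, sorted clean intervals (`start_s`,
#'   `end_s`); possibly zero rows.
#' @export
crop_noise <- function(rec, lobes, stats, margin_s = 0.050,
                       min_clean_s = 2.0) {
  stopifnot(inherits(stats, "outlier_stats"))
  dur <- pcg_duration(rec)
  out <- stats$outlier_idx
  if (length(out) == 0L) {
    iv <- tibble::tibble(start_s = 0, end_s = dur)
  } else {
    bad <- tibble::tibble(
      start_s = pmax(0, lobes$start_s[out] - margin_s),
      end_s = pmin(dur, lobes$end_s[out] + margin_s)
    )
    bad <- bad[order(bad$start_s), ]
    # merge overlapping cropped regions
    ms <- bad$start_s[1]; me <- bad$end_s[1]
    merged <- list()
    for (i in seq_len(nrow(bad))[-1]) {
      if (bad$start_s[i] <= me) me <- max(me, bad$end_s[i])
      else { merged[[length(merged) + 1L]] <- c(ms, me); ms <- bad$start_s[i]; me <- bad$end_s[i] }
    }
    merged[[length(merged) + 1L]] <- c(ms, me)
    m <- do.call(rbind, merged)
    edges <- c(0, as.vector(t(m)), dur)
    iv <- tibble::tibble(start_s = edges[seq(1, length(edges), by = 2)],
                         end_s = edges[seq(2, length(edges), by = 2)])
  }
  iv[(iv$end_s - iv$start_s) >= min_clean_s, , drop = FALSE]
}

#' Noise-robust segmentation
#'
#' The artifact-tolerant variant of [segment_base()]: after
#' preprocessing, lobes are detected on the whole recording and their
#' areas screened with [outlier_stats()]; flagged lobes are cropped out
#' with [crop_noise()], the envelope is recomputed on each clean interval
#' independently, each interval is segmented with the base routine, and
#' the labeled intervals are merged in time order with cropped gaps
#' carried as `NOISE` (state 0). Cycle tracking restarts per clean
#' interval: no S1/S2 alternation is forced across a noise gap. When no
#' lobe is flagged the result is identical to [segment_base()] (same code
#' path on the full recording).
#'
#' @param rec A raw [pcg_recording()].
#' @param params A [seg_params()] object; `area_cutoff`, `crop_margin_s`,
#'   `min_clean_s` and `outlier_iterate` control this layer.
#' @return A `pcg_segmentation`; success means at least one clean interval
#'   segmented successfully. When no clean interval can hold a cardiac
#'   cycle a failure segmentation is returned, not an error.
#' @export
segment_noise_robust <- function(rec, params = seg_params()) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (max(abs(rec$samples)) == 0) return(empty_segmentation())
  pre <- preprocess(rec)
  N <- round(params$frame_len_s * pre$rate)
  if (length(pre$samples) < N) return(empty_segmentation())
  env <- compute_nase(compute_ase(pre, params$frame_len_s, params$overlap))
  lobes <- detect_lobes(env, pre)
  if (nrow(lobes) == 0L) return(empty_segmentation())

  keep <- rep(TRUE, nrow(lobes))
  repeat {
    st <- outlier_stats(lobes$area[keep], cutoff = params$area_cutoff)
    if (length(st$outlier_idx) == 0L) break
    keep[which(keep)[st$outlier_idx]] <- FALSE
    if (!params$outlier_iterate) break
  }
  stats_full <- outlier_stats(lobes$area, cutoff = params$area_cutoff)
  stats_full$outlier_idx <- which(!keep)

  if (all(keep)) {
    return(segment_block(pre$samples, pre$rate, params))
  }
  clean <- crop_noise(pre, lobes, stats_full, margin_s = params$crop_margin_s,
                      min_clean_s = params$min_clean_s)
  if (nrow(clean) == 0L) return(empty_segmentation())

  segs <- purrr::pmap(clean, function(start_s, end_s) {
    i0 <- floor(start_s * pre$rate) + 1L
    i1 <- min(length(pre$samples), floor(end_s * pre$rate))
    segment_block(pre$samples[i0:i1], pre$rate, params,
                  t_offset = (i0 - 1L) / pre$rate)
  })
  iv <- dplyr::bind_rows(lapply(segs, function(s) s$intervals))

  # cropped gaps between clean intervals become NOISE intervals
  dur <- pcg_duration(pre)
  gap_edges <- c(0, as.vector(t(as.matrix(clean[, c("start_s", "end_s")]))), dur)
  gaps <- matrix(gap_edges, ncol = 2, byrow = TRUE)
  noise_iv <- tibble::tibble(start_s = gaps[, 1], end_s = gaps[, 2],
                             label = "NOISE")
  noise_iv <- noise_iv[noise_iv$end_s - noise_iv$start_s > 1e-9, ,
                       drop = FALSE]
  iv <- dplyr::bind_rows(iv, noise_iv)

  ok <- vapply(segs, function(s) s$success, logical(1))
  cyc <- vapply(segs, function(s) s$cycle_length_s, numeric(1))
  sys <- vapply(segs, function(s) s$systole_s, numeric(1))
  new_segmentation(iv, success = any(ok),
                   cycle_length_s = mean(cyc[ok]),
                   systole_s = mean(sys[ok]))
}
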