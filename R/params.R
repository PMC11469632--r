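#' Segmentation parameters
#'
#' Bundles every tunable threshold of the segmentation pipeline. Defaults
#' encode the a-priori physiological rules: primary heart sounds are
#' shorter than 250 ms; a split sound's two sub-lobes are separated by less
#' than 50 ms with the quieter lobe under 40% of the louder one's RMS; and
#' artifact lobes are flagged when their envelope-area z-score exceeds
#' 2.75.
#'
#' @param max_sound_ms Maximum plausible S1/S2 duration (ms); longer lobes
#'   are rejected as candidates.
#' @param max_split_ms Maximum gap between the two sub-lobes of a split
#'   sound (ms).
#' @param split_rms_ratio RMS ratio below which the quieter of two closely
#'   spaced lobes is discarded as a split remnant.
#' @param area_cutoff Z-score cutoff above which a lobe's envelope area
#'   marks it as a noise outlier.
#' @param corr_weight,cycle_weight,sys_weight Weights of the three pairing
#'   measurements (envelope correlation, cardiac-cycle deviation, systolic
#'   -interval deviation); must sum to 1.
#' @param min_pair_score Acceptance floor for extending the S1/S2 chain.
#' @param frame_len_s Envelope window length in seconds (20 ms default).
#' @param overlap Fractional overlap of successive envelope windows (0.5).
#' @param crop_margin_s Guard margin cropped on each side of an outlier
#'   lobe (seconds).
#' @param min_clean_s Minimum length of a clean interval worth segmenting
#'   (seconds); must admit at least one full cardiac cycle.
#' @param cycle_window Relative search window for the next S1 onset, as a
#'   multiple of the running cycle estimate.
#' @param sys_window Relative plausibility window for a candidate systolic
#'   interval, as a multiple of the running systole estimate.
#' @param outlier_iterate If `TRUE`, outlier statistics are recomputed
#'   after each removal until no lobe is flagged (default is the single
#'   pass).
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(max_sound_ms = 250,
                       max_split_ms = 50,
                       split_rms_ratio = 0.40,
                       area_cutoff = 2.75,
                       corr_weight = 1 / 3,
                       cycle_weight = 1 / 3,
                       sys_weight = 1 / 3,
                       min_pair_score = 0.5,
                       frame_len_s = 0.020,
                       overlap = 0.5,
                       crop_margin_s = 0.050,
                       min_clean_s = 2.0,
                       cycle_window = c(0.5, 1.5),
                       sys_window = c(0.3, 2.0),
                       outlier_iterate = FALSE) {
  p <- list(max_sound_ms = max_sound_ms, max_split_ms = max_split_ms,
            split_rms_ratio = split_rms_ratio, area_cutoff = area_cutoff,
            corr_weight = corr_weight, cycle_weight = cycle_weight,
            sys_weight = sys_weight, min_pair_score = min_pair_score,
            frame_len_s = frame_len_s, overlap = overlap,
            crop_margin_s = crop_margin_s, min_clean_s = min_clean_s,
            cycle_window = cycle_window, sys_window = sys_window,
            outlier_iterate = isTRUE(outlier_iterate))
  num <- p[!names(p) %in% "outlier_iterate"]
  if (!all(unlist(num) > 0)) stop("all numeric parameters must be positive")
  w <- corr_weight + cycle_weight + sys_weight
  if (abs(w - 1) > 1e-9) stop("pairing weights must sum to 1 (got ", w, ")")
  if (cycle_window[1] >= cycle_window[2] || sys_window[1] >= sys_window[2]) {
    stop("search windows must be increasing intervals")
  }
  structure(p, class = "seg_params")
}

#' Read segmentation parameters from a key=value file
#'
#' Lines are `name = value`; blank lines and `#` comments are ignored.
#' Vector parameters (`cycle_window`, `sys_window`) take comma-separated
#' values. Unknown keys are an error.
#'
#' @param path Path to the parameter file.
#' @return A [seg_params()] object.
#' @export
read_seg_params <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defaults <- seg_params()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("cannot parse parameter line: ", ln)
    key <- trimws(kv[1])
    if (!key %in% names(unclass(defaults))) stop("unknown parameter: ", key)
    val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
    args[[key]] <- if (key == "outlier_iterate") as.logical(val) else as.numeric(val)
  }
  do.call(seg_params, args)
}

#' Write segmentation parameters to a key=value file
#' @param params A [seg_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_seg_params <- function(params, path) {
  stopifnot(inherits(params, "seg_params"))
  p <- unclass(params)
  lines <- vapply(names(p), function(k) {
    paste0(k, " = ", paste(p[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
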