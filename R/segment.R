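# Base Shannon-energy segmentation: a-priori lobe validation, then
# sequential S1/S2 identification from an anchor pair using envelope
# correlation plus running cardiac-cycle and systolic-interval estimates.

SEG_LABELS <- c("S1", "SYSTOLE", "S2", "DIASTOLE", "NOISE")

new_segmentation <- function(intervals, success, cycle_length_s = NA_real_,
                             systole_s = NA_real_) {
  if (nrow(intervals) > 0L) {
    intervals <- intervals[order(intervals$start_s), , drop = FALSE]
  }
  structure(
    list(intervals = tibble::as_tibble(intervals), success = isTRUE(success),
         cycle_length_s = cycle_length_s, systole_s = systole_s),
    class = "pcg_segmentation"
  )
}

empty_segmentation <- function() {
  new_segmentation(
    tibble::tibble(start_s = numeric(), end_s = numeric(),
                   label = character()),
    success = FALSE
  )
}

#' @export
print.pcg_segmentation <- function(x, ...) {
  n1 <- sum(x$intervals$label == "S1")
  n2 <- sum(x$intervals$label == "S2")
  cat(sprintf(
    "<pcg_segmentation> %s: %d S1, %d S2; cycle %.3f s, systole %.3f s\n",
    if (x$success) "success" else "FAILED", n1, n2,
    x$cycle_length_s, x$systole_s))
  invisible(x)
}

#' Validate candidate sound lobes with a-priori rules
#'
#' Two physiological rules prune the candidate list. (1) Duration: S1 and
#' S2 are shorter than 250 ms, so longer lobes are removed. (2) Split
#' sounds: when two adjacent lobes are separated by less than 50 ms and
#' the quieter one's RMS is below 40% of the louder one's, the pair is a
#' split sound and only the higher-energy lobe is kept; lobes of similar
#' energy both remain candidates (one could be a murmur or noise).
#'
#' @param lobes Lobe tibble from [detect_lobes()], sorted and disjoint.
#' @param params A [seg_params()] object.
#' @return The surviving lobes, same columns.
#' @export
validate_lobes <- function(lobes, params = seg_params()) {
  lobes <- lobes[(lobes$end_s - lobes$start_s) < params$max_sound_ms / 1000, ,
                 drop = FALSE]
  n <- nrow(lobes)
  if (n <= 1L) return(lobes)
  keep <- rep(TRUE, n)
  prev <- 1L
  for (i in 2L:n) {
    gap <- lobes$start_s[i] - lobes$end_s[prev]
    if (gap < params$max_split_ms / 1000) {
      r <- c(lobes$rms[prev], lobes$rms[i])
      if (min(r) / max(r) < params$split_rms_ratio) {
        if (r[1] >= r[2]) {
          keep[i] <- FALSE
          next  # `prev` stays the surviving lobe
        } else {
          keep[prev] <- FALSE
        }
      }
    }
    prev <- i
  }
  lobes[keep, , drop = FALSE]
}

#' Choose the initial S1/S2 anchor pair
#'
#' The diastolic interval (S2 to the next S1) is generally the longest
#' inter-lobe interval, so the pair of adjacent lobes bounding the longest
#' onset-to-onset interval is read as (S2, S1): the lobe after the gap is
#' the anchor S1 and its immediate successor the anchor S2. Ties resolve
#' to the earliest qualifying pair.
#'
#' @param lobes Validated lobe tibble (at least 3 rows).
#' @return A list with integer indices `s1` and `s2` (rows of `lobes`) and
#'   `diastole_s`, the anchoring interval length; `NULL` if fewer than 3
#'   lobes are available.
#' @export
find_initial_pair <- function(lobes) {
  n <- nrow(lobes)
  if (n < 3L) return(NULL)
  gaps <- diff(lobes$start_s)  # onset-to-onset intervals
  # the post-gap lobe needs a successor to serve as S2
  usable <- seq_len(n - 2L)
  best <- usable[which.max(gaps[usable])]
  list(s1 = best + 1L, s2 = best + 2L, diastole_s = gaps[best])
}

# envelope stretch spanning a lobe pair (frames of s1 start .. s2 end)
pair_stretch <- function(env, s1, s2) {
  env$values[(s1$start_frame + 1L):(s2$end_frame + 1L)]
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Score a candidate S1/S2 pair against the reference pair
#'
#' Three measurements are combined as a weighted sum: (a) the linear
#' correlation between the envelope stretch of the candidate pair and that
#' of the reference pair (the shorter stretch is linearly resampled to the
#' longer one's length; correlation is computed on the envelope, not the
#' raw sound, since adjacent cycles can differ slightly in frequency);
#' (b) `1 - |candidate cycle - cycle_s| / cycle_s`, clipped to \[0, 1\],
#' where the candidate cycle is the onset distance between candidate and
#' reference S1 (a zero distance — scoring a pair against itself — counts
#' as a perfect cycle match); (c) the same deviation measure for the
#' candidate systolic interval against `sys_s`.
#'
#' @param cand,ref Two-row lobe tibbles (S1 row then S2 row).
#' @param env The NASE envelope the lobes were detected on.
#' @param cycle_s,sys_s Running cardiac-cycle and systolic-interval
#'   estimates in seconds.
#' @param params A [seg_params()] object (supplies the three weights).
#' @return A score in \[-1, 1\]; degenerate zero-variance envelope
#'   stretches contribute a correlation of 0.
#' @export
pair_score <- function(cand, ref, env, cycle_s, sys_s,
                       params = seg_params()) {
  stopifnot(nrow(cand) == 2L, nrow(ref) == 2L)
  a <- pair_stretch(env, cand[1, ], cand[2, ])
  b <- pair_stretch(env, ref[1, ], ref[2, ])
  if (length(a) < length(b)) {
    a <- stats::approx(seq_along(a), a, n = length(b))$y
  } else if (length(b) < length(a)) {
    b <- stats::approx(seq_along(b), b, n = length(a))$y
  }
  corr <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  cand_cycle <- abs(cand$start_s[1] - ref$start_s[1])
  cyc_term <- if (cand_cycle == 0) 1 else {
    clip01(1 - abs(cand_cycle - cycle_s) / cycle_s)
  }
  cand_sys <- cand$start_s[2] - cand$start_s[1]
  sys_term <- clip01(1 - abs(cand_sys - sys_s) / sys_s)
  params$corr_weight * corr + params$cycle_weight * cyc_term +
    params$sys_weight * sys_term
}

#' Identify S1 and S2 lobes sequentially
#'
#' Starting from the anchor pair of [find_initial_pair()], the chain of
#' S1/S2 pairs is extended greedily forward then backward. At each step
#' every candidate pair inside the plausibility windows (next S1 onset in
#' `cycle_window` times the running cycle estimate; systolic interval in
#' `sys_window` times the running systole estimate) is scored with
#' [pair_score()] against the previously accepted pair, and the best-
#' scoring pair is accepted if it reaches `min_pair_score`; otherwise the
#' extension stops in that direction. Running estimates are the cumulative
#' means of accepted cycle and systole lengths. Score ties resolve to the
#' earliest-onset pair.
#'
#' @param lobes Validated lobe tibble.
#' @param env The NASE envelope the lobes were detected on.
#' @param params A [seg_params()] object.
#' @return A `pcg_segmentation`: accepted lobes labeled `S1`/`S2` at their
#'   lobe extents, with `SYSTOLE` between an S1 and its S2 and `DIASTOLE`
#'   between an S2 and the following S1. Success requires at least one
#'   complete S1-S2-S1 span (two accepted pairs). Never-chosen lobes stay
#'   unlabeled.
#' @export
identify_s1_s2 <- function(lobes, env, params = seg_params()) {
  init <- find_initial_pair(lobes)
  if (is.null(init)) return(empty_segmentation())
  sys0 <- lobes$start_s[init$s2] - lobes$start_s[init$s1]
  if (sys0 <= 0) return(empty_segmentation())
  pairs <- list(c(init$s1, init$s2))
  cycles <- init$diastole_s + sys0  # anchor cycle: diastole + systole
  syses <- sys0

  candidate_pairs <- function(t_lo, t_hi) {
    s1_idx <- which(lobes$start_s >= t_lo & lobes$start_s <= t_hi)
    out <- list()
    s_est <- mean(syses)
    for (i in s1_idx) {
      sys_cand <- lobes$start_s - lobes$start_s[i]
      j_idx <- which(sys_cand >= params$sys_window[1] * s_est &
                     sys_cand <= params$sys_window[2] * s_est)
      for (j in j_idx) out[[length(out) + 1L]] <- c(i, j)
    }
    out
  }

  extend <- function(dir) {
    repeat {
      anchor <- if (dir > 0) pairs[[length(pairs)]] else pairs[[1L]]
      c_est <- mean(cycles)
      t1 <- lobes$start_s[anchor[1]]
      win <- sort(t1 + dir * params$cycle_window * c_est)
      cands <- candidate_pairs(win[1], win[2])
      # candidates must not reuse or cross the current chain
      used <- unlist(pairs)
      cands <- Filter(function(p) {
        !any(p %in% used) &&
          (if (dir > 0) p[1] > max(used) else p[2] < min(used))
      }, cands)
      if (length(cands) == 0L) break
      ref <- lobes[anchor, ]
      scores <- vapply(cands, function(p) {
        pair_score(lobes[p, ], ref, env, c_est, mean(syses), params)
      }, numeric(1))
      best <- which.max(scores)  # first max = earliest-onset tie-break
      if (scores[best] < params$min_pair_score) break
      p <- cands[[best]]
      if (dir > 0) pairs[[length(pairs) + 1L]] <<- p
      else pairs <<- c(list(p), pairs)
      cycles <<- c(cycles, abs(lobes$start_s[p[1]] - t1))
      syses <<- c(syses, lobes$start_s[p[2]] - lobes$start_s[p[1]])
    }
  }
  extend(+1)
  extend(-1)

  rows <- list()
  np <- length(pairs)
  for (k in seq_len(np)) {
    p <- pairs[[k]]
    s1 <- lobes[p[1], ]
    s2 <- lobes[p[2], ]
    rows[[length(rows) + 1L]] <-
      tibble::tibble(start_s = s1$start_s, end_s = s1$end_s, label = "S1")
    if (s2$start_s > s1$end_s) {
      rows[[length(rows) + 1L]] <-
        tibble::tibble(start_s = s1$end_s, end_s = s2$start_s,
                       label = "SYSTOLE")
    }
    rows[[length(rows) + 1L]] <-
      tibble::tibble(start_s = s2$start_s, end_s = s2$end_s, label = "S2")
    if (k < np) {
      nxt <- lobes[pairs[[k + 1L]][1], ]
      if (nxt$start_s > s2$end_s) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(start_s = s2$end_s, end_s = nxt$start_s,
                         label = "DIASTOLE")
      }
    }
  }
  # success needs a complete S1-S2-S1 span and a physiologically plausible
  # rhythm (40-220 bpm); a pseudo-rhythm chained through unstructured noise
  # typically lands outside that range
  plausible <- mean(cycles) >= 60 / 220 && mean(cycles) <= 60 / 40
  new_segmentation(dplyr::bind_rows(rows), success = np >= 2L && plausible,
                   cycle_length_s = mean(cycles), systole_s = mean(syses))
}

# shared pipeline tail: envelope -> lobes -> validate -> identify, on an
# already-preprocessed sample block; `t_offset` shifts reported times
segment_block <- function(samples, rate, params, t_offset = 0) {
  rec <- pcg_recording(samples, rate, "block")
  N <- round(params$frame_len_s * rate)
  if (length(samples) < N) return(empty_segmentation())
  env <- compute_nase(compute_ase(rec, params$frame_len_s, params$overlap))
  lobes <- detect_lobes(env, rec)
  lobes <- validate_lobes(lobes, params)
  seg <- identify_s1_s2(lobes, env, params)
  if (t_offset != 0 && nrow(seg$intervals) > 0L) {
    seg$intervals$start_s <- seg$intervals$start_s + t_offset
    seg$intervals$end_s <- seg$intervals$end_s + t_offset
  }
  seg
}

#' Base Shannon-energy segmentation of a raw recording
#'
#' Runs the full chain: preprocess (resample, bandpass, normalize), ASE,
#' NASE, lobe detection, a-priori validation, sequential S1/S2
#' identification. Deterministic for fixed input and parameters. A silent
#' recording or one yielding too few lobes returns a failure segmentation
#' (empty labels, `success = FALSE`), not an error.
#'
#' @param rec A raw [pcg_recording()] at any sampling rate.
#' @param params A [seg_params()] object.
#' @return A `pcg_segmentation`.
#' @seealso [segment_noise_robust()] for the artifact-tolerant variant.
#' @export
segment_base <- function(rec, params = seg_params()) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (max(abs(rec$samples)) == 0) return(empty_segmentation())
  pre <- preprocess(rec)
  segment_block(pre$samples, pre$rate, params)
}
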