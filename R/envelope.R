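# Shannon-energy envelope: framewise average Shannon energy (ASE), its
# zero-mean normalization (NASE), and lobe localization by thresholding
# the NASE at 0.

# samplewise Shannon energy -x^2 log(x^2), with 0 * log(0) := 0.
# The envelope definition lives here in one place: average Shannon energy
# is the frame mean of these values (natural log).
shannon_energy <- function(x) {
  s <- numeric(length(x))
  x2 <- x^2
  nz <- x2 > 0  # guards both exact zeros and squared-underflow
  s[nz] <- -x2[nz] * log(x2[nz])
  s
}

new_envelope <- function(values, frame_hop, frame_len, t0, kind, rate,
                         ase_mean = NA_real_) {
  structure(
    list(values = as.numeric(values), frame_hop = frame_hop,
         frame_len = frame_len, t0 = t0, kind = kind, rate = rate,
         ase_mean = ase_mean),
    class = "pcg_envelope"
  )
}

#' @export
print.pcg_envelope <- function(x, ...) {
  cat(sprintf("<pcg_envelope> %s: %d frames (len %g ms, hop %g ms)\n",
              x$kind, length(x$values), 1000 * x$frame_len,
              1000 * x$frame_hop))
  invisible(x)
}

#' @export
as.data.frame.pcg_envelope <- function(x, ...) {
  data.frame(frame = seq_along(x$values) - 1L,
             time_s = x$t0 + (seq_along(x$values) - 1L) * x$frame_hop,
             value = x$values)
}

#' Average Shannon energy envelope
#'
#' Computes the framewise average Shannon energy of a preprocessed
#' recording: over each window, `E_s = -(1/N) * sum(x^2 * log(x^2))` with
#' `0 * log(0) := 0` and natural logarithm. Windows are 20 ms with 50%
#' overlap by default (80 samples, hop 40 at 4 kHz), giving
#' `floor((n - N) / hop) + 1` frames.
#'
#' @param rec A preprocessed [pcg_recording()] (rate 4,000 Hz, samples in
#'   \[-1, 1\]).
#' @param frame_len Window length in seconds.
#' @param overlap Fractional window overlap in \[0, 1).
#' @return A `pcg_envelope` of kind `"ASE"`. The frame time stamp `t0` is
#'   the center of the first window.
#' @export
compute_ase <- function(rec, frame_len = 0.020, overlap = 0.5) {
  stopifnot(inherits(rec, "pcg_recording"))
  N <- round(frame_len * rec$rate)
  hop <- round(N * (1 - overlap))
  n <- length(rec$samples)
  if (n < N) stop("recording shorter than one envelope frame")
  n_frames <- (n - N) %/% hop + 1L
  cs <- c(0, cumsum(shannon_energy(rec$samples)))
  starts <- (seq_len(n_frames) - 1L) * hop  # 0-based sample offsets
  vals <- (cs[starts + N + 1L] - cs[starts + 1L]) / N
  new_envelope(vals, frame_hop = hop / rec$rate, frame_len = N / rec$rate,
               t0 = frame_len / 2, kind = "ASE", rate = rec$rate)
}

#' Normalized average Shannon energy
#'
#' Subtracts the mean over all frames from the ASE, so candidate sound
#' lobes become the regions where the result exceeds zero.
#'
#' @param env An `"ASE"` envelope from [compute_ase()].
#' @return A `pcg_envelope` of kind `"NASE"` with zero mean; the original
#'   ASE mean is retained in the `ase_mean` field so lobe areas can be
#'   computed on the ASE scale.
#' @export
compute_nase <- function(env) {
  stopifnot(inherits(env, "pcg_envelope"))
  if (!identical(env$kind, "ASE")) stop("input must be an ASE envelope")
  if (length(env$values) == 0L) stop("empty envelope")
  m <- mean(env$values)
  new_envelope(env$values - m, env$frame_hop, env$frame_len, env$t0,
               kind = "NASE", rate = env$rate, ase_mean = m)
}

#' Localize candidate sound lobes
#'
#' A lobe is a maximal run of frames with NASE strictly greater than 0.
#' Each lobe is reported with its frame span, its extent in signal time
#' (`start_s = start_frame * hop`, `end_s = end_frame * hop + frame_len`,
#' i.e. the full extent of contributing windows), its area (plain sum of
#' ASE values over its frames) and the RMS of the bandpassed signal within
#' its extent.
#'
#' @param nase A `"NASE"` envelope from [compute_nase()].
#' @param bandpassed The bandpassed [pcg_recording()] the envelope was
#'   computed from (used for the RMS).
#' @return A tibble with columns `start_frame`, `end_frame` (0-based,
#'   inclusive), `start_s`, `end_s`, `area`, `rms`; zero rows when no frame
#'   is supra-threshold. Lobes are disjoint and sorted.
#' @export
detect_lobes <- function(nase, bandpassed) {
  stopifnot(inherits(nase, "pcg_envelope"))
  if (!identical(nase$kind, "NASE")) stop("input must be a NASE envelope")
  stopifnot(inherits(bandpassed, "pcg_recording"))
  pos <- nase$values > 0
  empty <- tibble::tibble(start_frame = integer(), end_frame = integer(),
                          start_s = numeric(), end_s = numeric(),
                          area = numeric(), rms = numeric())
  if (!any(pos)) return(empty)
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  sf <- starts[keep] - 1L  # 0-based frame indices
  ef <- ends[keep] - 1L
  hop <- nase$frame_hop
  start_s <- sf * hop
  end_s <- ef * hop + nase$frame_len
  ase <- nase$values + nase$ase_mean
  cs <- c(0, cumsum(ase))
  area <- cs[ef + 2L] - cs[sf + 1L]
  x <- bandpassed$samples
  rate <- bandpassed$rate
  rms <- mapply(function(s, e) {
    i0 <- floor(s * rate) + 1L
    i1 <- min(length(x), ceiling(e * rate))
    sqrt(mean(x[i0:i1]^2))
  }, start_s, end_s)
  tibble::tibble(start_frame = sf, end_frame = ef, start_s = start_s,
                 end_s = end_s, area = area, rms = as.numeric(rms))
}
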