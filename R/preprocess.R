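# Preprocessing: resample to 4 kHz, bandpass 40-500 Hz, normalize to [-1, 1].

TARGET_RATE <- 4000

#' Resample a recording to 4,000 Hz
#'
#' Fourier-domain resampling: the spectrum is truncated (downsampling,
#' which acts as an ideal anti-alias filter) or zero-padded (upsampling) so
#' that the output has `round(n * 4000 / rate)` samples. Duration is
#' preserved to within one output sample.
#'
#' @param rec A [pcg_recording()]. Rates below 80 Hz cannot carry the
#'   40 Hz lower band edge and are an error.
#' @return A [pcg_recording()] at 4,000 Hz. Already-4 kHz input is returned
#'   unchanged.
#' @export
resample_to_4khz <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (rec$rate < 80) {
    stop("sampling rate ", rec$rate,
         " Hz is too low: cannot represent the 40 Hz band edge")
  }
  if (rec$rate == TARGET_RATE) return(rec)
  n_out <- round(length(rec$samples) * TARGET_RATE / rec$rate)
  if (n_out < 1) stop("recording too short to resample")
  pcg_recording(fft_resample(rec$samples, n_out), TARGET_RATE, rec$source_id)
}

#' Bandpass-filter a recording (40-500 Hz by default)
#'
#' Zero-phase filtering (forward-backward, so sound onsets are not
#' delayed) with a cascade of 4th-order Butterworth highpass and lowpass
#' sections. The passband retains the primary heart sound energy; rumble
#' below 40 Hz and high-frequency noise above 500 Hz are rejected.
#'
#' @param rec A [pcg_recording()] (normally at 4,000 Hz).
#' @param low,high Cutoff frequencies in Hz, `0 < low < high < rate/2`.
#' @param order Butterworth order of each cascade section.
#' @return The filtered [pcg_recording()].
#' @export
bandpass <- function(rec, low = 40, high = 500, order = 4) {
  stopifnot(inherits(rec, "pcg_recording"))
  if (!(low > 0 && low < high && high < rec$rate / 2)) {
    stop("need 0 < low < high < rate/2")
  }
  hp <- butter_coeffs(order, low, rec$rate, "high")
  lp <- butter_coeffs(order, high, rec$rate, "low")
  y <- filtfilt(hp$b, hp$a, rec$samples)
  y <- filtfilt(lp$b, lp$a, y)
  pcg_recording(y, rec$rate, rec$source_id)
}

#' Normalize a recording to the \[-1, 1\] range
#'
#' Divides by the maximum absolute amplitude, preserving waveform shape.
#'
#' @param rec A [pcg_recording()]. An all-zero (silent) recording is an
#'   error.
#' @return The normalized [pcg_recording()] with `max(abs(samples)) == 1`.
#' @export
normalize <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  m <- max(abs(rec$samples))
  if (m == 0) stop("cannot normalize a silent (all-zero) recording")
  pcg_recording(rec$samples / m, rec$rate, rec$source_id)
}

#' Full preprocessing chain
#'
#' Resample to 4,000 Hz, bandpass 40-500 Hz, normalize to \[-1, 1\] — in
#' that order. The result is amplitude-scale invariant: `preprocess(c * x)`
#' equals `preprocess(x)` for any `c > 0`.
#'
#' @param rec A [pcg_recording()].
#' @inheritParams bandpass
#' @return The preprocessed [pcg_recording()] at 4,000 Hz.
#' @export
preprocess <- function(rec, low = 40, high = 500, order = 4) {
  normalize(bandpass(resample_to_4khz(rec), low = low, high = high,
                     order = order))
}
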