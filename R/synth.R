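# Synthetic phonocardiogram generator with exact ground truth. Emulates
# the structure the segmenter assumes — quasi-periodic S1/S2 bursts under
# 250 ms, a systolic interval more stable than the diastolic one, optional
# split sounds and murmur bands — and the artifacts it must survive
# (high-energy noise bursts anywhere in the recording).

#' Configuration for the synthetic phonocardiogram generator
#'
#' @param duration_s Recording length in seconds.
#' @param bpm Heart rate in beats per minute (40-220).
#' @param systole_fraction Systolic interval (S1 onset to S2 onset) as a
#'   fraction of the nominal cycle. Held constant across beats: beat-to-
#'   beat variability is applied to the diastolic interval only, matching
#'   the physiological premise that systole is the stabler of the two.
#' @param cycle_jitter Relative standard deviation of the cycle length
#'   (realized entirely in diastole).
#' @param s1_ms,s2_ms Sound durations in milliseconds (< 250).
#' @param s1_hz,s2_hz Carrier frequencies in Hz (inside the 40-500 Hz
#'   passband).
#' @param s1_amp,s2_amp Peak amplitudes (S2 conventionally softer).
#' @param split_s1 Optional `list(gap_ms =, rms_ratio =)` turning each S1
#'   into two sub-bursts separated by `gap_ms` (< 50) with the second at
#'   `rms_ratio` times the RMS of the first.
#' @param murmur Optional `list(band = c(lo, hi), gain =)` adding
#'   band-limited noise across each systolic interval.
#' @param bursts List of `c(t0, t1, gain)` high-energy broadband noise
#'   bursts (speech/motion artifacts); `gain` scales a noise floor whose
#'   RMS is `0.3 * gain` relative to the unit S1 peak.
#' @param snr_db Signal-to-background-noise ratio in dB (white noise).
#' @param rate Sampling rate of the generated waveform in Hz.
#' @param seed Integer seed; fixed seed gives an identical waveform and
#'   truth.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 10, bpm = 100, systole_fraction = 0.35,
                         cycle_jitter = 0.05, s1_ms = 100, s2_ms = 80,
                         s1_hz = 80, s2_hz = 140, s1_amp = 1, s2_amp = 0.75,
                         split_s1 = NULL, murmur = NULL, bursts = list(),
                         snr_db = 30, rate = 4000, seed = NULL) {
  if (bpm < 40 || bpm > 220) stop("bpm must be in [40, 220]")
  if (s1_ms >= 250 || s2_ms >= 250) stop("sound durations must be < 250 ms")
  if (!is.null(split_s1)) {
    if (split_s1$gap_ms >= 50) stop("split gap must be < 50 ms")
    if (split_s1$rms_ratio <= 0 || split_s1$rms_ratio >= 1) {
      stop("split rms_ratio must be in (0, 1)")
    }
  }
  cycle <- 60 / bpm
  sys_int <- systole_fraction * cycle
  if (s1_ms / 1000 >= sys_int) {
    stop("infeasible timing: S1 duration exceeds the systolic interval")
  }
  if (sys_int + s2_ms / 1000 >= cycle * (1 - 3 * cycle_jitter)) {
    stop("infeasible timing: systole plus S2 exceeds the shortest cycle")
  }
  structure(
    list(duration_s = duration_s, bpm = bpm,
         systole_fraction = systole_fraction, cycle_jitter = cycle_jitter,
         s1_ms = s1_ms, s2_ms = s2_ms, s1_hz = s1_hz, s2_hz = s2_hz,
         s1_amp = s1_amp, s2_amp = s2_amp, split_s1 = split_s1,
         murmur = murmur, bursts = bursts, snr_db = snr_db, rate = rate,
         seed = seed),
    class = "synth_config"
  )
}

# Gaussian-windowed sinusoidal burst added in place
add_burst_tone <- function(x, rate, onset, dur, freq, amp, phase = 0) {
  i0 <- max(1L, floor(onset * rate) + 1L)
  i1 <- min(length(x), ceiling((onset + dur) * rate))
  if (i1 < i0) return(x)
  t <- (i0:i1 - 1L) / rate
  ctr <- onset + dur / 2
  envl <- exp(-0.5 * ((t - ctr) / (dur / 6))^2)
  x[i0:i1] <- x[i0:i1] + amp * envl * sin(2 * pi * freq * (t - ctr) + phase)
  x
}

# white noise restricted to [lo, hi] Hz via FFT masking
bandlimited_noise <- function(n, rate, lo, hi) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- (seq_len(n) - 1L) * rate / n
  f <- pmin(f, rate - f)  # two-sided frequency axis
  X[f < lo | f > hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

#' Generate a synthetic phonocardiogram with exact ground truth
#'
#' Builds S1/S2 as amplitude-modulated band-limited bursts on the timing
#' grid of the configuration, applies cycle jitter to the diastolic
#' interval only, optionally adds split S1 sounds, murmur bands, and
#' high-energy noise bursts, plus white background noise at the configured
#' SNR. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @return A list with `recording` (a [pcg_recording()]) and `truth` (an
#'   annotation tibble with states 1-4 exactly matching construction).
#' @export
synth_pcg <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed_local(config$seed, synth_pcg_impl(config))
}

synth_pcg_impl <- function(cfg) {
  rate <- cfg$rate
  n <- round(cfg$duration_s * rate)
  x <- numeric(n)
  cycle <- 60 / cfg$bpm
  sys_int <- cfg$systole_fraction * cycle
  s1d <- cfg$s1_ms / 1000
  s2d <- cfg$s2_ms / 1000

  onsets <- numeric(0)
  t <- 0.1  # first S1 onset
  while (t + sys_int + s2d <= cfg$duration_s) {
    onsets <- c(onsets, t)
    dia <- (cycle - sys_int) * (1 + cfg$cycle_jitter * stats::rnorm(1) *
                                  cycle / (cycle - sys_int))
    dia <- max(dia, s2d + 0.05)
    t <- t + sys_int + dia
  }
  if (length(onsets) == 0L) stop("duration too short for one cardiac cycle")

  rows <- list()
  for (k in seq_along(onsets)) {
    on <- onsets[k]
    a1 <- cfg$s1_amp * (1 + 0.05 * stats::rnorm(1))
    a2 <- cfg$s2_amp * (1 + 0.05 * stats::rnorm(1))
    ph1 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    if (is.null(cfg$split_s1)) {
      x <- add_burst_tone(x, rate, on, s1d, cfg$s1_hz, a1, ph1)
      s1_end <- on + s1d
    } else {
      gap <- cfg$split_s1$gap_ms / 1000
      sub <- (s1d - gap) / 2
      x <- add_burst_tone(x, rate, on, sub, cfg$s1_hz, a1, ph1)
      x <- add_burst_tone(x, rate, on + sub + gap, sub, cfg$s1_hz,
                          a1 * cfg$split_s1$rms_ratio, ph1)
      s1_end <- on + s1d
    }
    s2_on <- on + sys_int
    x <- add_burst_tone(x, rate, s2_on, s2d, cfg$s2_hz, a2, ph2)
    s2_end <- s2_on + s2d
    if (!is.null(cfg$murmur)) {
      i0 <- floor(s1_end * rate) + 1L
      i1 <- min(n, ceiling(s2_on * rate))
      if (i1 > i0) {
        mn <- bandlimited_noise(i1 - i0 + 1L, rate, cfg$murmur$band[1],
                                cfg$murmur$band[2])
        x[i0:i1] <- x[i0:i1] + cfg$murmur$gain * mn
      }
    }
    nxt <- if (k < length(onsets)) onsets[k + 1] else cfg$duration_s
    rows[[k]] <- tibble::tibble(
      onset = c(on, s1_end, s2_on, s2_end),
      offset = c(s1_end, s2_on, s2_end, nxt),
      state = c(1L, 2L, 3L, 4L)
    )
  }
  truth <- dplyr::bind_rows(rows)
  truth <- truth[truth$offset > truth$onset + 1e-9, , drop = FALSE]

  # background noise at the configured SNR
  sig_rms <- sqrt(mean(x^2))
  x <- x + stats::rnorm(n, sd = sig_rms * 10^(-cfg$snr_db / 20))

  # high-energy broadband bursts with a short cosine taper
  for (b in cfg$bursts) {
    i0 <- max(1L, floor(b[1] * rate) + 1L)
    i1 <- min(n, ceiling(b[2] * rate))
    if (i1 <= i0) next
    m <- i1 - i0 + 1L
    taper_n <- min(m %/% 2, round(0.005 * rate))
    w <- rep(1, m)
    if (taper_n > 0) {
      ramp <- 0.5 * (1 - cos(pi * seq_len(taper_n) / taper_n))
      w[seq_len(taper_n)] <- ramp
      w[m - seq_len(taper_n) + 1L] <- ramp
    }
    x[i0:i1] <- x[i0:i1] + 0.3 * b[3] * w * stats::rnorm(m)
  }

  list(recording = pcg_recording(x, rate, "synthetic"),
       truth = validate_annotation(truth))
}

#' Generate a reproducible suite of synthetic recordings
#'
#' Draws per-recording heart rate and cycle jitter uniformly from the
#' given ranges, optionally injects one high-gain noise burst at a random
#' position in each recording, and derives one sub-seed per recording from
#' `seed` so any single recording can be regenerated independently.
#'
#' @param n Number of recordings.
#' @param config Base [synth_config()]; per-recording draws override
#'   `bpm`, `cycle_jitter`, `bursts` and `seed`.
#' @param seed Master integer seed.
#' @param bpm_range,jitter_range Ranges for the uniform per-recording
#'   draws.
#' @param burst_gain If non-`NULL`, each recording receives one burst of
#'   this gain and `burst_dur_s` duration at a uniform random onset.
#' @param burst_dur_s Burst duration in seconds.
#' @return A list of `n` elements, each a list with `recording`, `truth`
#'   and the realized `config`.
#' @export
synth_suite <- function(n, config = synth_config(), seed = 1L,
                        bpm_range = c(60, 140), jitter_range = c(0.02, 0.08),
                        burst_gain = NULL, burst_dur_s = 1) {
  stopifnot(n >= 1)
  draws <- with_seed_local(seed, {
    tibble::tibble(
      sub_seed = sample.int(.Machine$integer.max - 1L, n),
      bpm = stats::runif(n, bpm_range[1], bpm_range[2]),
      jitter = stats::runif(n, jitter_range[1], jitter_range[2]),
      burst_t0 = stats::runif(n, 0.5,
                              config$duration_s - 0.5 - burst_dur_s)
    )
  })
  lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$bpm <- draws$bpm[i]
    cfg$cycle_jitter <- draws$jitter[i]
    cfg$seed <- draws$sub_seed[i]
    if (!is.null(burst_gain)) {
      cfg$bursts <- c(cfg$bursts,
                      list(c(draws$burst_t0[i],
                             draws$burst_t0[i] + burst_dur_s, burst_gain)))
    }
    out <- synth_pcg(cfg)
    out$config <- cfg
    out
  })
}
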