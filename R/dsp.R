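# Internal DSP primitives: Butterworth design, zero-phase filtering,
# Fourier-domain resampling. No DSP package ships with this R stack, so
# these are implemented here and kept deliberately small.

# polynomial coefficients (highest order first) from roots, complex-safe
poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0i) - ri * c(0i, p)
  p
}

# Digital Butterworth lowpass/highpass via analog prototype + bilinear
# transform. Returns list(b, a) with a[1] = 1.
butter_coeffs <- function(order, fc, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fc > 0, fc < fs / 2)
  n <- order
  k <- seq_len(n)
  # analog prototype poles on the unit circle, left half-plane
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  fs2 <- 2 * fs
  wc <- fs2 * tan(pi * fc / fs)  # pre-warped analog cutoff (rad/s)
  if (type == "low") {
    pa <- wc * p
    za <- complex(0)
    ka <- wc^n
  } else {
    pa <- wc / p
    za <- rep(0 + 0i, n)
    ka <- 1
  }
  # bilinear transform to the z-domain
  pz <- (fs2 + pa) / (fs2 - pa)
  zz <- if (length(za)) (fs2 + za) / (fs2 - za) else complex(0)
  zz <- c(zz, rep(-1 + 0i, n - length(zz)))  # zeros at Nyquist fill
  kz <- ka * Re(prod(fs2 - za)) / Re(prod(fs2 - pa))
  b <- Re(poly_from_roots(zz)) * kz
  a <- Re(poly_from_roots(pz))
  list(b = b / a[1], a = a / a[1])
}

# single-pass IIR filter (direct form), zero initial conditions
iir_filter <- function(b, a, x) {
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

# Zero-phase forward-backward filtering with odd-reflection padding.
# The pad absorbs the zero-state transient of both passes.
filtfilt <- function(b, a, x) {
  n <- length(x)
  min_pad <- 3 * (max(length(a), length(b)) - 1)
  if (n <= min_pad) {
    stop("signal too short to filter: need more than ", min_pad, " samples")
  }
  pad <- min(n - 1, max(min_pad, 1000L))
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  ext <- c(left, x, right)
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

# Fourier-domain resampling of a real signal to n_out samples (assumes the
# signal is treated as one period; spectrum truncation acts as an ideal
# anti-alias filter).
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_out)
  N <- min(n, n_out)
  half <- (N + 1) %/% 2  # bins 0 .. half-1 strictly below Nyquist
  Y[seq_len(half)] <- X[seq_len(half)]
  if (half > 1) {
    Y[n_out - seq_len(half - 1) + 1] <- X[n - seq_len(half - 1) + 1]
  }
  if (N %% 2 == 0) {
    kn <- N %/% 2  # shared Nyquist bin index (0-based)
    if (n_out > n) {
      Y[kn + 1] <- X[kn + 1] / 2
      Y[n_out - kn + 1] <- Conj(X[kn + 1]) / 2
    } else {
      Y[kn + 1] <- X[kn + 1] + Conj(X[n - kn + 1])
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}
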