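# Independent brute-force oracles used to check the implementation. These
# deliberately avoid the package's own code paths.

# population-moment z-score outlier flagging, element by element
oracle_outlier <- function(areas, cutoff = 2.75) {
  M <- length(areas)
  m <- sum(areas) / M
  sd_pop <- sqrt(sum((areas - m)^2) / M)
  z <- if (sd_pop > 0) (areas - m) / sd_pop else rep(0, M)
  list(mean = m, sd = sd_pop, z = z, outliers = which(z > cutoff))
}

# exhaustive midpoint-bracketing count: for each truth sound, scan every
# in-span predicted midpoint of the same type
oracle_sensitivity <- function(pred, truth) {
  span <- c(min(truth$onset), max(truth$offset))
  tp <- 0L; fn <- 0L
  for (state in c(1L, 3L)) {
    tr <- truth[truth$state == state, , drop = FALSE]
    pr <- pred[pred$state == state, , drop = FALSE]
    pr <- pr[pr$offset > span[1] & pr$onset < span[2], , drop = FALSE]
    mids <- (pr$onset + pr$offset) / 2
    for (i in seq_len(nrow(tr))) {
      ok <- FALSE
      for (m in mids) if (m >= tr$onset[i] && m < tr$offset[i]) ok <- TRUE
      if (ok) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  list(tp = tp, fn = fn)
}

# greedy ascending-distance one-to-one matching, naive O(n^3) loop
oracle_match_mean <- function(tm, pm) {
  if (length(tm) == 0L || length(pm) == 0L) return(NaN)
  used_t <- logical(length(tm)); used_p <- logical(length(pm))
  dists <- c()
  repeat {
    best <- Inf; bi <- 0L; bj <- 0L
    for (i in which(!used_t)) for (j in which(!used_p)) {
      d <- abs(tm[i] - pm[j])
      if (d < best) { best <- d; bi <- i; bj <- j }
    }
    if (bi == 0L) break
    used_t[bi] <- TRUE; used_p[bj] <- TRUE
    dists <- c(dists, best)
  }
  mean(dists)
}

# dominant frequency of a real signal by discrete Fourier magnitude
oracle_dominant_freq <- function(x, rate) {
  X <- Mod(stats::fft(x))[1:(length(x) %/% 2)]
  (which.max(X) - 1L) * rate / length(x)
}

rms <- function(x) sqrt(mean(x^2))

# random valid annotation table (sorted, disjoint, states 0-4)
random_annotation <- function(n_rows, states = 0:4) {
  bounds <- sort(runif(2 * n_rows, 0, 10))
  tibble::tibble(
    onset = bounds[seq(1, 2 * n_rows, by = 2)],
    offset = bounds[seq(2, 2 * n_rows, by = 2)],
    state = sample(states, n_rows, replace = TRUE)
  )
}

# lobe tibble from explicit extents (seconds), for unit tests that bypass
# envelope computation; frame mapping assumes the 10 ms default hop
make_lobes <- function(start_s, end_s, rms = NULL, area = NULL) {
  tibble::tibble(
    start_frame = as.integer(round(start_s / 0.010)),
    end_frame = as.integer(round((end_s - 0.020) / 0.010)),
    start_s = start_s, end_s = end_s,
    area = if (is.null(area)) rep(1, length(start_s)) else area,
    rms = if (is.null(rms)) rep(1, length(start_s)) else rms
  )
}
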