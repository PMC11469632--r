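#' Construct a phonocardiogram recording
#'
#' A `pcg_recording` is the package's carrier for a single-channel heart
#' sound signal at any pipeline stage: a numeric sample vector plus its
#' sampling rate in Hz.
#'
#' @param samples Numeric vector of amplitudes (dimensionless). All values
#'   must be finite.
#' @param rate Sampling frequency in Hz (> 0).
#' @param source_id Free-text identifier carried through the pipeline.
#' @return An object of class `pcg_recording`.
#' @examples
#' rec <- pcg_recording(sin(2 * pi * 100 * seq(0, 1, by = 1 / 4000)), 4000)
#' rec
#' @export
pcg_recording <- function(samples, rate, source_id = "pcg") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)")
  }
  if (length(samples) == 0L) stop("`samples` must be non-empty")
  if (!all(is.finite(samples))) stop("all samples must be finite")
  structure(
    list(samples = samples, rate = as.numeric(rate),
         source_id = as.character(source_id)),
    class = "pcg_recording"
  )
}

#' @export
print.pcg_recording <- function(x, ...) {
  cat(sprintf("<pcg_recording> %s: %d samples @ %g Hz (%.3f s)\n",
              x$source_id, length(x$samples), x$rate, pcg_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec A [pcg_recording()].
#' @return Duration in seconds (`n_samples / rate`).
#' @export
pcg_duration <- function(rec) {
  stopifnot(inherits(rec, "pcg_recording"))
  length(rec$samples) / rec$rate
}

# run `code` under `seed` without disturbing the caller's RNG stream;
# seed = NULL means "use the ambient stream"
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
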