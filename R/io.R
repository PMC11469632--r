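# WAV and annotation input/output. No WAV reader ships with this R stack,
# so a minimal RIFF/WAVE parser lives here: PCM16 and IEEE float32 are
# accepted on read, float32 is written.

#' Read a WAV file as a phonocardiogram recording
#'
#' Accepts 16-bit PCM and 32-bit IEEE float WAV. Multi-channel files are
#' reduced to their first channel with a warning. PCM samples are rescaled
#' to \[-1, 1) by dividing by 32768.
#'
#' @param path Path to a WAV file.
#' @return A [pcg_recording()] with the rate taken from the file header.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      chunk <- readBin(con, "raw", size + size %% 2L)
      if (length(chunk) < 16L) stop("truncated fmt chunk in ", path)
      u16 <- function(i) sum(as.integer(chunk[i:(i + 1)]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(chunk[i:(i + 3)]) * 256^(0:3))
      fmt <- list(format = u16(1), channels = u16(3), rate = u32(5),
                  bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) stop("truncated data chunk in ", path)
    } else {
      seek(con, size + size %% 2L, origin = "current")
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in ", path)
  if (is.null(data_raw)) stop("no data chunk in ", path)
  if (fmt$rate <= 0) stop("invalid sampling rate in header of ", path)

  if (fmt$format == 1L && fmt$bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) / 2L, size = 2,
                    signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 3L && fmt$bits == 32L) {
    vals <- readBin(data_raw, "numeric", length(data_raw) / 4L, size = 4,
                    endian = "little")
  } else {
    stop("unsupported WAV encoding (format ", fmt$format, ", ",
         fmt$bits, " bit) in ", path)
  }
  if (length(vals) == 0L) stop("zero-length audio in ", path)
  if (fmt$channels > 1L) {
    warning("multi-channel WAV: keeping first of ", fmt$channels, " channels")
    vals <- vals[seq(1L, length(vals), by = fmt$channels)]
  }
  pcg_recording(vals, fmt$rate, source_id = basename(path))
}

#' Write a recording as a 32-bit float WAV file
#'
#' @param rec A [pcg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "pcg_recording"))
  n <- length(rec$samples)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + 4L * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")  # IEEE float
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(round(rec$rate)), con, size = 4, endian = "little")
  writeBin(as.integer(round(rec$rate) * 4L), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(4L * n), con, size = 4, endian = "little")
  writeBin(rec$samples, con, size = 4, endian = "little")
  invisible(path)
}

# state codes of the annotation dialect
STATE_CODES <- c(NOISE = 0L, S1 = 1L, SYSTOLE = 2L, S2 = 3L, DIASTOLE = 4L)

state_to_label <- function(state) {
  names(STATE_CODES)[match(state, STATE_CODES)]
}

#' Coerce predictions or annotations to a state table
#'
#' Normalizes either a [segment_base()] result or an annotation tibble to a
#' tibble with columns `onset`, `offset` (seconds, half-open intervals) and
#' integer `state` (0 noise/unlabeled, 1 S1, 2 systole, 3 S2, 4 diastole).
#'
#' @param x A segmentation object or a data frame with onset/offset/state
#'   columns (a `start_s`/`end_s`/`label` layout is also accepted).
#' @return A tibble with columns `onset`, `offset`, `state`.
#' @export
as_annotation <- function(x) {
  if (inherits(x, "pcg_segmentation")) {
    iv <- x$intervals
    return(tibble::tibble(
      onset = iv$start_s, offset = iv$end_s,
      state = unname(STATE_CODES[iv$label])
    ))
  }
  x <- tibble::as_tibble(x)
  if (all(c("onset", "offset", "state") %in% names(x))) {
    return(x[, c("onset", "offset", "state")])
  }
  if (all(c("start_s", "end_s", "label") %in% names(x))) {
    return(tibble::tibble(onset = x$start_s, offset = x$end_s,
                          state = unname(STATE_CODES[x$label])))
  }
  stop("cannot interpret object as an annotation table")
}

validate_annotation <- function(ann) {
  if (nrow(ann) == 0L) return(ann)
  if (!all(ann$state %in% STATE_CODES)) {
    bad <- setdiff(unique(ann$state), STATE_CODES)
    stop("unknown state code(s): ", paste(bad, collapse = ", "))
  }
  if (any(ann$onset >= ann$offset)) stop("annotation rows must have onset < offset")
  if (is.unsorted(ann$onset)) stop("annotation rows must be sorted by onset")
  if (nrow(ann) > 1L && any(ann$onset[-1L] < ann$offset[-nrow(ann)] - 1e-9)) {
    stop("annotation rows must not overlap")
  }
  ann
}

#' Read a tab-separated segmentation annotation file
#'
#' The dialect is three tab-separated columns without a header: onset
#' seconds, offset seconds, integer state code (0 noise/unlabeled, 1 S1,
#' 2 systole, 3 S2, 4 diastole) — the convention used by the CirCor
#' DigiScope segmentation files, which load directly. Extra columns are
#' ignored with a warning.
#'
#' @param path Path to the annotation file.
#' @return A validated annotation tibble (`onset`, `offset`, `state`).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    return(tibble::tibble(onset = numeric(), offset = numeric(),
                          state = integer()))
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "numeric", comment.char = "")
  if (ncol(df) < 3L) stop("annotation file needs 3 tab-separated columns")
  if (ncol(df) > 3L) {
    warning("ignoring ", ncol(df) - 3L, " extra column(s) in ", path)
  }
  ann <- tibble::tibble(onset = df[[1]], offset = df[[2]],
                        state = as.integer(round(df[[3]])))
  validate_annotation(ann)
}

#' Write a segmentation or annotation table to a tab-separated file
#'
#' @param seg A segmentation object or annotation tibble (see
#'   [as_annotation()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(seg, path) {
  ann <- validate_annotation(as_annotation(seg))
  lines <- sprintf("%.6f\t%.6f\t%d", ann$onset, ann$offset, ann$state)
  writeLines(lines, path)
  invisible(path)
}
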