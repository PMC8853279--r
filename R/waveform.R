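#' Waveform container
#'
#' A thin container for a mono audio signal: a numeric vector of samples in
#' \[-1, 1\] plus its sample rate.  All time quantities in the package are
#' milliseconds, with 0 ms at the first sample.
#'
#' @param samples numeric vector of amplitudes.
#' @param sample_rate sample rate in Hz.
#' @return object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate) {
  if (length(samples) == 0) input_error("waveform must be non-empty")
  if (!all(is.finite(samples))) input_error("waveform contains non-finite samples")
  structure(list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("waveform: %d samples @ %g Hz (%.1f ms), peak %.3f\n",
              length(x$samples), x$sample_rate,
              duration_ms(x), max(abs(x$samples))))
  invisible(x)
}

#' @rdname waveform
#' @param wave a `waveform`.
#' @export
duration_ms <- function(wave) length(wave$samples) / wave$sample_rate * 1000

# ---------------------------------------------------------------------------
# WAV I/O.  Minimal RIFF/WAVE codec: reads PCM 16/24/32-bit and IEEE float32,
# writes IEEE float32 (so tests round-trip without quantization error).
# Multi-channel files are averaged down to mono.

#' Read a WAV file
#'
#' Reads a RIFF/WAVE file (PCM 16/24/32 bit or 32-bit IEEE float).
#' Multi-channel recordings are averaged to mono; samples are scaled to
#' \[-1, 1\].
#'
#' @param path path to a `.wav` file.
#' @return a [waveform].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) input_error(sprintf("not a readable WAV file: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    input_error(sprintf("not a RIFF/WAVE file: %s", path))
  }
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    len <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", len + len %% 2)
      fmt <- list(
        audio_format = readBin(fmt_raw[1:2], "integer", 1, 2, endian = "little"),
        n_channels   = readBin(fmt_raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(fmt_raw[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", len)
      break
    } else {
      invisible(readBin(con, "raw", len + len %% 2))
    }
  }
  if (is.null(fmt) || is.null(data)) input_error(sprintf("malformed WAV file: %s", path))
  bytes <- fmt$bits %/% 8
  n_frames <- length(data) %/% (bytes * fmt$n_channels)
  if (n_frames == 0) input_error(sprintf("WAV file has no samples: %s", path))
  n_vals <- n_frames * fmt$n_channels
  if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data, "numeric", n_vals, size = 4, endian = "little")
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data, "integer", n_vals, size = 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 32L) {
    x <- readBin(data, "integer", n_vals, size = 4, endian = "little") / 2147483648
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    m <- matrix(as.integer(data[seq_len(n_vals * 3)]), nrow = 3)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else {
    input_error(sprintf("unsupported WAV encoding (format %d, %d bit): %s",
                        fmt$audio_format, fmt$bits, path))
  }
  if (fmt$n_channels > 1L) {
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }
  waveform(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' Writes a mono 32-bit IEEE float WAV file, chosen so that a write/read
#' round trip is exact.
#'
#' @param wave a [waveform].
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "waveform"))
  x <- wave$samples
  n <- length(x)
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- n * 4L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")          # IEEE float
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(as.integer(wave$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(wave$sample_rate * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")          # block align
  writeBin(32L, con, size = 2, endian = "little")         # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_len), con, size = 4, endian = "little")
  writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Onset lists: times in ms, stored as plain CSV (one value per row, header
# optional) or a JSON array.

#' Read a list of onset times
#'
#' Accepts a CSV file with one millisecond value per row (a single header
#' line is tolerated) or a JSON array of numbers.  Times are returned
#' sorted; unsorted input triggers a warning.
#'
#' @param path file path (`.json` parsed as JSON, anything else as CSV).
#' @return numeric vector of onset times in ms, sorted ascending.
#' @export
read_onsets <- function(path) {
  if (!file.exists(path)) input_error(sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::fromJSON(path)
    if (length(vals) == 0) return(numeric(0))
    if (!is.numeric(vals)) input_error(sprintf("non-numeric onset in %s", path))
    vals <- as.numeric(vals)
  } else {
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(numeric(0))
    suppressWarnings(vals <- as.numeric(lines))
    if (is.na(vals[1]) && length(lines) > 1) {    # header line
      lines <- lines[-1]
      suppressWarnings(vals <- as.numeric(lines))
    }
    bad <- which(is.na(vals))
    if (length(bad)) {
      input_error(sprintf("non-numeric onset at row %d of %s: '%s'",
                          bad[1], path, lines[bad[1]]))
    }
  }
  if (is.unsorted(vals)) {
    warning("onset list was not sorted; sorting")
    vals <- sort(vals)
  }
  vals
}

#' @rdname read_onsets
#' @param onsets numeric vector of onset times in ms.
#' @export
write_onsets <- function(onsets, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.numeric(onsets), path, digits = NA)
  } else {
    writeLines(format(as.numeric(onsets), trim = TRUE, scientific = FALSE), path)
  }
  invisible(path)
}
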