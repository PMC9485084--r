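#' Construct an audio segment
#'
#' @param samples numeric vector of samples in \[-1, 1\] (values are checked
#'   finite; reconstruction clips, synthesis scales).
#' @param sample_rate_hz sampling rate, Hz (positive integer).
#' @param start_offset_s time of the first sample relative to the recording
#'   start (default 0).
#' @return Object of class `audio_segment`.
#' @export
audio_segment <- function(samples, sample_rate_hz, start_offset_s = 0) {
  samples <- as.numeric(samples)
  if (length(samples) && !all(is.finite(samples))) {
    stop("samples must all be finite", call. = FALSE)
  }
  sample_rate_hz <- as.integer(round(sample_rate_hz))
  if (is.na(sample_rate_hz) || sample_rate_hz < 1) {
    stop("sample_rate_hz must be a positive integer", call. = FALSE)
  }
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz,
                 start_offset_s = as.numeric(start_offset_s)),
            class = "audio_segment")
}

#' @export
print.audio_segment <- function(x, ...) {
  cat(sprintf("<audio_segment: %d samples @ %d Hz (%.3f s), offset %.3f s>\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz, x$start_offset_s))
  invisible(x)
}

#' Duration of an audio segment in seconds
#' @param segment an [audio_segment()].
#' @return duration in seconds.
#' @export
audio_duration <- function(segment) {
  length(segment$samples) / segment$sample_rate_hz
}

#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader for the dialect used throughout the package:
#' PCM, 16-bit, little-endian. Multi-channel files are accepted; one channel
#' is extracted.
#'
#' @param path WAV file path.
#' @param channel channel to extract from multi-channel files (default 1).
#' @return An [audio_segment()] with samples scaled to \[-1, 1\].
#' @export
read_wav <- function(path, channel = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  readBin(con, "integer", 1, 4, endian = "little")  # RIFF chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop("'", path, "' is not a RIFF/WAVE file", call. = FALSE)
  }
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) stop("no data chunk in '", path, "'", call. = FALSE)
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little"),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little"),
        sample_rate  = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little"),
        bits         = readBin(con, "integer", 1, 2, endian = "little"))
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt in '", path, "'",
                             call. = FALSE)
      if (fmt$audio_format != 1L || fmt$bits != 16L) {
        stop("unsupported WAV encoding in '", path,
             "': only 16-bit PCM is handled", call. = FALSE)
      }
      n <- size %/% 2L
      x <- readBin(con, "integer", n, 2, signed = TRUE, endian = "little")
      nc <- fmt$n_channels
      if (channel < 1 || channel > nc) {
        stop("channel ", channel, " not present (file has ", nc, ")",
             call. = FALSE)
      }
      x <- x[seq.int(channel, length(x), by = nc)]
      return(audio_segment(pmax(-1, x / 32767), fmt$sample_rate))
    } else {
      readBin(con, "raw", size + (size %% 2L))  # skip, chunks are word-aligned
    }
  }
}

#' Write a WAV file (mono, 16-bit PCM)
#'
#' @param segment an [audio_segment()]; samples are clipped to \[-1, 1\] and
#'   quantized to 16 bits.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(segment, path) {
  stopifnot(inherits(segment, "audio_segment"))
  x <- pmax(-1, pmin(1, segment$samples))
  pcm <- as.integer(round(x * 32767))
  n_bytes <- length(pcm) * 2L
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot write WAV to '", path, "'",
                                           call. = FALSE))
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(segment$sample_rate_hz), con, size = 4,
           endian = "little")
  writeBin(as.integer(segment$sample_rate_hz * 2L), con, size = 4,
           endian = "little")
  writeBin(2L, con, size = 2, endian = "little")   # block align
  writeBin(16L, con, size = 2, endian = "little")  # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
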