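#' Construct an audio recording
#'
#' Container for a mono waveform with sampling-rate metadata. Amplitudes
#' must already be normalized to \[-1, 1\] (integer PCM is divided by
#' 2^(bits-1) on load, so thresholds downstream are bit-depth independent).
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\]. Must be
#'   non-empty.
#' @param sample_rate Sampling frequency in Hz (positive).
#' @param subject_id,session_id Opaque identifier strings carried through
#'   the pipeline.
#' @return An object of class `audio_recording`: a list with elements
#'   `samples`, `sample_rate`, `subject_id`, `session_id`.
#' @export
#' @examples
#' rec <- audio_recording(sin(2 * pi * 440 * (0:11024) / 11025), 11025)
#' duration_s(rec)
audio_recording <- function(samples, sample_rate, subject_id = "",
                            session_id = "") {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("empty audio: 'samples' must be a non-empty numeric vector",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      sample_rate <= 0) {
    stop("'sample_rate' must be a single positive number", call. = FALSE)
  }
  if (max(abs(samples)) > 1 + 1e-9) {
    stop("amplitudes must lie in [-1, 1]; normalize before constructing",
         call. = FALSE)
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate),
         subject_id = as.character(subject_id),
         session_id = as.character(session_id)),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.3f s)",
              length(x$samples), x$sample_rate, duration_s(x)))
  if (nzchar(x$subject_id)) cat(sprintf("  subject=%s", x$subject_id))
  if (nzchar(x$session_id)) cat(sprintf(" session=%s", x$session_id))
  cat("\n")
  invisible(x)
}

#' Recording duration in seconds
#'
#' @param rec An [audio_recording()].
#' @return Sample count divided by sampling rate.
#' @export
duration_s <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  length(rec$samples) / rec$sample_rate
}

# Reads one sub-chunk header; returns list(id, size) or NULL at EOF.
read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  if (length(id) == 0L || nchar(id, type = "bytes") < 4L) return(NULL)
  size <- readBin(con, integer(), n = 1L, size = 4L, endian = "little")
  if (length(size) == 0L) return(NULL)
  list(id = id, size = size)
}

#' Read a PCM WAV file
#'
#' Parses a RIFF/WAVE container with integer PCM samples (8 or 16 bit,
#' any channel count). Multi-channel audio is downmixed to mono by
#' averaging channels; 16-bit samples are normalized by 2^15 and 8-bit
#' (unsigned) by centring at 128 and dividing by 2^7. Any sample rate is
#' accepted; a notice is emitted when it differs from the 11,025 Hz used
#' by the clinical recordings this workflow was designed around, since
#' segmentation parameters are expressed in seconds and remain valid.
#'
#' @param path Path to a `.wav` file.
#' @param subject_id,session_id Identifiers to attach; default to the
#'   file name stem and `""`.
#' @return An [audio_recording()].
#' @export
load_wav <- function(path, subject_id = NULL, session_id = "") {
  if (!file.exists(path)) {
    stop(sprintf("WAV file not found: '%s'", path), call. = FALSE)
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[wW][aA][vV]$", "", basename(path))
  }
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, integer(), n = 1L, size = 4L, endian = "little") # RIFF size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop(sprintf("'%s' is not a RIFF/WAVE file", path), call. = FALSE)
  }

  fmt <- NULL
  samples <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (is.null(hdr)) break
    if (identical(hdr$id, "fmt ")) {
      audio_format <- readBin(con, integer(), 1L, size = 2L, signed = FALSE,
                              endian = "little")
      n_channels <- readBin(con, integer(), 1L, size = 2L, signed = FALSE,
                            endian = "little")
      sample_rate <- readBin(con, integer(), 1L, size = 4L, endian = "little")
      readBin(con, integer(), 1L, size = 4L, endian = "little") # byte rate
      readBin(con, integer(), 1L, size = 2L, signed = FALSE,
              endian = "little")                                # block align
      bits <- readBin(con, integer(), 1L, size = 2L, signed = FALSE,
                      endian = "little")
      if (hdr$size > 16L) readBin(con, raw(), hdr$size - 16L)
      if (!identical(audio_format, 1L)) {
        stop(sprintf("unsupported WAV encoding (format tag %d); only integer PCM is supported",
                     audio_format), call. = FALSE)
      }
      fmt <- list(n_channels = n_channels, sample_rate = sample_rate,
                  bits = bits)
    } else if (identical(hdr$id, "data")) {
      if (is.null(fmt)) {
        stop("corrupt WAV: 'data' chunk precedes 'fmt '", call. = FALSE)
      }
      if (fmt$bits == 16L) {
        n <- hdr$size %/% 2L
        raw16 <- readBin(con, integer(), n = n, size = 2L, signed = TRUE,
                         endian = "little")
        samples <- raw16 / 32768
      } else if (fmt$bits == 8L) {
        raw8 <- readBin(con, integer(), n = hdr$size, size = 1L,
                        signed = FALSE, endian = "little")
        samples <- (raw8 - 128) / 128
      } else {
        stop(sprintf("unsupported bit depth: %d (8 or 16 expected)",
                     fmt$bits), call. = FALSE)
      }
      if (hdr$size %% 2L == 1L) readBin(con, raw(), 1L) # chunk padding
    } else {
      skip <- hdr$size + hdr$size %% 2L
      readBin(con, raw(), skip)
    }
  }

  if (is.null(fmt)) stop("corrupt WAV: no 'fmt ' chunk", call. = FALSE)
  if (is.null(samples) || length(samples) == 0L) {
    stop(sprintf("'%s' contains no audio samples", path), call. = FALSE)
  }
  if (fmt$n_channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$n_channels))
  }
  if (fmt$sample_rate != 11025L) {
    message(sprintf("note: sample rate %d Hz differs from the 11,025 Hz reference format",
                    fmt$sample_rate))
  }
  audio_recording(samples, fmt$sample_rate, subject_id, session_id)
}

#' Write a 16-bit PCM WAV file
#'
#' Amplitudes are clipped to \[-1, 1\], scaled by 2^15 and rounded, so a
#' write/read round trip reproduces samples within one quantization step.
#'
#' @param rec An [audio_recording()] or a numeric vector of amplitudes.
#' @param path Output path.
#' @param sample_rate Required when `rec` is a bare numeric vector.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, sample_rate = NULL) {
  if (inherits(rec, "audio_recording")) {
    samples <- rec$samples
    sample_rate <- rec$sample_rate
  } else {
    if (is.null(sample_rate)) {
      stop("'sample_rate' is required for a bare sample vector", call. = FALSE)
    }
    samples <- as.numeric(rec)
  }
  q <- as.integer(pmax(-32768, pmin(32767, round(pmax(-1, pmin(1, samples)) * 32768))))
  n_bytes <- length(q) * 2L

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")          # PCM
  writeBin(1L, con, size = 2L, endian = "little")          # mono
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate) * 2L, con, size = 4L, endian = "little")
  writeBin(2L, con, size = 2L, endian = "little")          # block align
  writeBin(16L, con, size = 2L, endian = "little")         # bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4L, endian = "little")
  writeBin(q, con, size = 2L, endian = "little")
  invisible(path)
}
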