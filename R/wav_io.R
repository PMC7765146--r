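#' Read a WAV file as an audio clip
#'
#' Reads RIFF/WAVE PCM audio (16-bit signed or 8-bit unsigned). Multi-channel
#' input is downmixed to mono by channel averaging; input at a sampling rate
#' other than `target_rate` is resampled (polyphase, via the signal package).
#' Both conversions emit a warning so that silent format drift is visible in
#' pipeline logs.
#'
#' @param path path to a `.wav` file.
#' @param target_rate sample rate the clip should be delivered at, in Hz.
#'   `NULL` keeps the file's native rate. Default 8000 Hz, the rate assumed by
#'   the feature extractors.
#' @return an [audio_clip()] with samples scaled to `[-1, 1)`.
#' @seealso [write_wav()]
#' @export
read_wav <- function(path, target_rate = 8000) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      hdr <- readBin(body, "integer", 4, size = 2, endian = "little", signed = TRUE)
      rates <- readBin(body[5:12], "integer", 2, size = 4, endian = "little")
      bits <- readBin(body[15:16], "integer", 1, size = 2, endian = "little", signed = TRUE)
      fmt <- list(
        audio_format = hdr[1], n_channels = hdr[2],
        sample_rate = rates[1], bits = bits
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      # skip unknown chunk (pad byte if odd size)
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV (missing fmt/data chunk): ", path)
  if (fmt$audio_format != 1) stop("unsupported WAV codec (only PCM supported): format ", fmt$audio_format)
  if (length(data_raw) == 0) stop("WAV file has an empty data chunk: ", path)

  if (fmt$bits == 16) {
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2,
                 size = 2, signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 8) {
    x <- (readBin(data_raw, "integer", length(data_raw),
                  size = 1, signed = FALSE) - 128) / 128
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits)
  }

  if (fmt$n_channels > 1) {
    warning(sprintf("downmixing %d channels to mono", fmt$n_channels))
    x <- colMeans(matrix(x, nrow = fmt$n_channels))
  }

  sr <- fmt$sample_rate
  if (!is.null(target_rate) && sr != target_rate) {
    warning(sprintf("resampling from %d Hz to %d Hz", sr, as.integer(target_rate)))
    x <- resample_to(x, sr, target_rate)
    sr <- target_rate
  }
  audio_clip(x, sr)
}

# Rational-factor resampler; output length is round(n * to / from).
resample_to <- function(x, from, to) {
  g <- gcd_int(as.integer(to), as.integer(from))
  p <- as.integer(to) %/% g
  q <- as.integer(from) %/% g
  y <- signal::resample(x, p, q)
  n_out <- round(length(x) * to / from)
  if (length(y) >= n_out) y[seq_len(n_out)] else c(y, rep(y[length(y)], n_out - length(y)))
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Write an audio clip as a 16-bit PCM WAV file
#'
#' Samples are clamped to the representable 16-bit range; the round trip
#' `read_wav(write_wav(...))` changes no sample by more than `2^-15`.
#'
#' @param clip an [audio_clip()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(clip, path) {
  stopifnot(inherits(clip, "audio_clip"))
  pcm <- as.integer(pmax(-32768, pmin(32767, round(clip$samples * 32768))))
  n_bytes <- length(pcm) * 2L
  sr <- as.integer(clip$sample_rate)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n_bytes, con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")          # PCM, mono
  writeBin(sr, con, size = 4, endian = "little")                 # sample rate
  writeBin(sr * 2L, con, size = 4, endian = "little")            # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")         # block align, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
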