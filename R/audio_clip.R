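#' Construct an audio clip
#'
#' A lightweight container for mono PCM audio: a numeric sample vector in
#' `[-1, 1)` plus a sample rate. All acoustic analysis in the package operates
#' on `audio_clip` objects.
#'
#' @param samples numeric vector of samples, nominally in `[-1, 1)`.
#' @param sample_rate sampling frequency in Hz (default 8000, the recording
#'   rate assumed throughout the pipeline).
#' @return an object of class `audio_clip` with elements `samples` and
#'   `sample_rate`.
#' @examples
#' clip <- audio_clip(sin(2 * pi * 440 * (0:7999) / 8000) * 0.9)
#' clip_duration(clip)
#' @export
audio_clip <- function(samples, sample_rate = 8000) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop("samples must be a non-empty numeric vector")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop("sample_rate must be a positive scalar")
  }
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate)),
    class = "audio_clip"
  )
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf(
    "<audio_clip> %d samples @ %g Hz (%.3f s), peak %.3f\n",
    length(x$samples), x$sample_rate,
    length(x$samples) / x$sample_rate, max(abs(x$samples))
  ))
  invisible(x)
}

#' Duration of an audio clip in seconds
#'
#' @param clip an [audio_clip()].
#' @return duration in seconds.
#' @export
clip_duration <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  length(clip$samples) / clip$sample_rate
}
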