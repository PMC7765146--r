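#' Short-term Fourier transform of an audio clip
#'
#' Frames the signal with a hop, windows each frame and returns the one-sided
#' magnitude spectrogram. Frame count follows the standard non-padded
#' convention `floor((n - frame_len) / hop) + 1`.
#'
#' @param clip an [audio_clip()].
#' @param frame_len frame length in samples (>= 64). Default 256 (32 ms at
#'   8 kHz), at least two periods of a 100 Hz fundamental.
#' @param hop hop size in samples. Default 80 (10 ms at 8 kHz).
#' @param window window name: `"hann"` (periodic), `"hamming"` or
#'   `"rectangular"`.
#' @param nfft FFT length (>= frame_len); frames are zero-padded to `nfft`.
#'   Defaults to `frame_len`.
#' @return an object of class `spectrogram`: list with `frame_times` (frame
#'   centers, s), `freqs` (Hz, one-sided), `magnitude` (bins x frames),
#'   `frame_len`, `hop`, `window`, `nfft`, `sample_rate`.
#' @export
stft <- function(clip, frame_len = 256, hop = 80, window = "hann", nfft = frame_len) {
  stopifnot(inherits(clip, "audio_clip"))
  x <- clip$samples
  n <- length(x)
  if (frame_len < 64) stop("frame_len must be >= 64")
  if (hop < 1) stop("hop must be >= 1")
  if (n < frame_len) stop("clip shorter than one frame")
  if (nfft < frame_len) stop("nfft must be >= frame_len")

  w <- switch(window,
    hann = 0.5 * (1 - cos(2 * pi * (0:(frame_len - 1)) / frame_len)),
    hamming = 0.54 - 0.46 * cos(2 * pi * (0:(frame_len - 1)) / frame_len),
    rectangular = rep(1, frame_len),
    stop("unknown window: ", window)
  )

  n_frames <- floor((n - frame_len) / hop) + 1
  starts <- (seq_len(n_frames) - 1) * hop
  frames <- matrix(0, nrow = nfft, ncol = n_frames)
  for (j in seq_len(n_frames)) {
    frames[seq_len(frame_len), j] <- x[starts[j] + seq_len(frame_len)] * w
  }
  spec <- mvfft(frames)
  n_bins <- nfft %/% 2 + 1
  mag <- abs(spec[seq_len(n_bins), , drop = FALSE])

  structure(
    list(
      frame_times = (starts + frame_len / 2) / clip$sample_rate,
      freqs = (seq_len(n_bins) - 1) * clip$sample_rate / nfft,
      magnitude = mag,
      frame_len = frame_len, hop = hop, window = window, nfft = nfft,
      sample_rate = clip$sample_rate
    ),
    class = "spectrogram"
  )
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d frames x %d bins, frame %d / hop %d samples, %s window, %g Hz\n",
    ncol(x$magnitude), nrow(x$magnitude), x$frame_len, x$hop, x$window, x$sample_rate
  ))
  invisible(x)
}
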