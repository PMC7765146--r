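#' Psychoacoustic roughness of one spectral frame
#'
#' Partial-pair roughness model: every unordered pair of spectral peaks
#' contributes
#' \deqn{(a_1 a_2)^{0.1} \cdot 0.5\,\bigl(2\min(a_1,a_2)/(a_1+a_2)\bigr)^{3.11}
#'       \cdot \bigl(e^{-b_1 s \Delta f} - e^{-b_2 s \Delta f}\bigr)}
#' with \eqn{s = s^*/(s_1 f_{min} + s_2)}, where \eqn{f_{min}} is the lower
#' frequency of the pair and \eqn{\Delta f} the separation. The amplitude term
#' makes roughness grow slowly with level (total scales as \eqn{c^{0.2}} when
#' both amplitudes scale by \eqn{c}); the exponential difference peaks when the
#' separation is a fixed fraction of the critical band at \eqn{f_{min}}
#' (about 70 Hz near 1 kHz) and vanishes for widely separated partials.
#'
#' @param peaks data.frame with columns `freq` (Hz, ascending) and `amp`
#'   (linear amplitudes, >= 0), e.g. from [spectral_peaks()].
#' @param b1,b2,s_star,s1,s2 model constants (defaults from the cited
#'   partial-pair roughness literature).
#' @return nonnegative scalar; 0 if fewer than two nonzero peaks.
#' @export
roughness_frame <- function(peaks, b1 = 3.5, b2 = 5.75, s_star = 0.24,
                            s1 = 0.0207, s2 = 18.96) {
  if (is.null(peaks) || nrow(peaks) == 0) return(0)
  if (any(peaks$amp < 0)) stop("peak amplitudes must be >= 0")
  if (is.unsorted(peaks$freq)) stop("peaks must be sorted by frequency")
  peaks <- peaks[peaks$amp > 0, , drop = FALSE]
  n <- nrow(peaks)
  if (n < 2) return(0)

  ij <- combn(n, 2)
  a1 <- peaks$amp[ij[1, ]]; a2 <- peaks$amp[ij[2, ]]
  f1 <- peaks$freq[ij[1, ]]; f2 <- peaks$freq[ij[2, ]]
  fmin <- pmin(f1, f2)
  df <- abs(f2 - f1)
  s <- s_star / (s1 * fmin + s2)
  x <- (a1 * a2)^0.1
  y <- 0.5 * (2 * pmin(a1, a2) / (a1 + a2))^3.11
  z <- exp(-b1 * s * df) - exp(-b2 * s * df)
  sum(x * y * z)
}

#' Pick spectral peaks (partials) from one spectrogram frame
#'
#' Local magnitude maxima at least `floor_db` below the frame maximum AND at
#' least `contrast` of the frame maximum in linear amplitude, capped at the
#' `max_peaks` largest (bounds the quadratic pair cost of
#' [roughness_frame()]); returned sorted by frequency.
#'
#' The linear contrast floor follows the convention of spectral peak pickers
#' in music-information-retrieval toolboxes: partials are peaks that carry a
#' non-negligible fraction of the frame's amplitude. Its default (0.04, i.e.
#' -28 dB) sits just above the first-sidelobe level of the Hann analysis
#' window (-31.5 dB), so windowing artifacts never register as partials while
#' genuine components — harmonics, modulation sidebands of depth >~ 0.1 — do.
#' Without it, the roughness model's scale-free amplitude terms let pairs of
#' tiny equal-amplitude sidelobe peaks dominate the estimate.
#'
#' @param mag magnitude vector for one frame.
#' @param freqs frequency axis, Hz.
#' @param floor_db dB threshold relative to frame max (default -60).
#' @param contrast linear amplitude threshold relative to frame max
#'   (default 0.04).
#' @param max_peaks maximum number of peaks kept (default 20).
#' @return data.frame with columns `freq`, `amp` (possibly zero rows).
#' @export
spectral_peaks <- function(mag, freqs, floor_db = -60, contrast = 0.04,
                           max_peaks = 20) {
  stopifnot(length(mag) == length(freqs))
  n <- length(mag)
  if (n < 3 || max(mag) <= 0) return(data.frame(freq = numeric(0), amp = numeric(0)))
  inner <- 2:(n - 1)
  is_peak <- mag[inner] > mag[inner - 1] & mag[inner] >= mag[inner + 1]
  idx <- inner[is_peak]
  idx <- idx[mag[idx] >= max(mag) * max(10^(floor_db / 20), contrast)]
  if (length(idx) == 0) return(data.frame(freq = numeric(0), amp = numeric(0)))
  if (length(idx) > max_peaks) idx <- idx[order(mag[idx], decreasing = TRUE)[seq_len(max_peaks)]]
  idx <- sort(idx)
  data.frame(freq = freqs[idx], amp = mag[idx])
}
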