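#' Tristimulus timbre descriptors of one spectral frame
#'
#' Energy-partition descriptors adapted from color perception: `t1` is the
#' fraction of total spectral energy at the fundamental, `t2` the fraction in
#' harmonics 2-4, and `t3` the fraction in all higher harmonics. Each bin is
#' assigned to its nearest harmonic `k = round(f / f0)` when it falls within
#' the harmonic's band; the band half-width is `band * k * f0` (relative,
#' about half a semitone by default) widened to at least `min_band_hz` so that
#' the analysis window's main lobe — over which a partial's energy is spread —
#' is captured whole. The denominator is the frame's total spectral energy,
#' so inharmonic energy (noise, modulation sidebands outside the bands)
#' leaves `t1 + t2 + t3 <= 1`.
#'
#' @param mag magnitude vector for one frame.
#' @param freqs frequency axis, Hz.
#' @param f0 fundamental frequency for the frame, Hz (> 0).
#' @param band relative half-width of each harmonic band (default 0.03).
#' @param min_band_hz absolute minimum half-width, Hz; default 62.5, the
#'   main-lobe half-width (`2 * fs / frame_len`) of the default Hann analysis
#'   frame (256 samples at 8 kHz).
#' @return named numeric `c(t1, t2, t3)`; all `NA` for a zero-energy frame
#'   (such frames are dropped from aggregation).
#' @export
tristimulus_frame <- function(mag, freqs, f0, band = 0.03, min_band_hz = 62.5) {
  stopifnot(length(mag) == length(freqs))
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be a positive number")
  e_total <- sum(mag^2)
  if (e_total <= 0) return(c(t1 = NA_real_, t2 = NA_real_, t3 = NA_real_))

  k_near <- round(freqs / f0)
  in_band <- k_near >= 1 &
    abs(freqs - k_near * f0) <= pmax(band * k_near * f0, min_band_hz)
  e2 <- mag^2
  e1 <- sum(e2[in_band & k_near == 1])
  e24 <- sum(e2[in_band & k_near >= 2 & k_near <= 4])
  e5p <- sum(e2[in_band & k_near >= 5])
  c(t1 = e1 / e_total, t2 = e24 / e_total, t3 = e5p / e_total)
}
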