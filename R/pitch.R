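#' Framewise pitch estimation with a confidence score
#'
#' Sawtooth-spectrum kernel correlation in the spirit of SWIPE': for each
#' pitch candidate on a log-spaced grid, a spectral template with cosine lobes
#' at the fundamental and at prime-numbered harmonics (weights decaying as
#' `1/sqrt(k)`, matching the square-root amplitude compression applied to the
#' spectrum) is correlated with the square-root magnitude spectrum of each
#' frame. Pitch strength is the cosine similarity between template and
#' spectrum — a value in `[-1, 1]`, rectified to `[0, 1]` and reported as the
#' confidence. The winning candidate is refined by parabolic interpolation of
#' strength over log-frequency.
#'
#' Silent or non-harmonic frames yield low confidence rather than an error;
#' frames with exactly zero energy get `f0 = NA` and confidence 0.
#'
#' @param clip an [audio_clip()].
#' @param fmin,fmax pitch search range, Hz; `50 <= fmin < fmax <= 2000`.
#' @param frame_len,hop framing in samples (defaults 256/80: 32 ms / 10 ms at
#'   8 kHz).
#' @param nfft FFT length for the analysis spectrogram (zero-padded for
#'   spectral interpolation accuracy).
#' @param steps_per_octave resolution of the log-spaced candidate grid.
#' @return data.frame with columns `time`, `f0` (Hz, in `[fmin, fmax]` or NA),
#'   `confidence` (in `[0, 1]`).
#' @export
estimate_pitch <- function(clip, fmin = 100, fmax = 1000, frame_len = 256,
                           hop = 80, nfft = 1024, steps_per_octave = 48) {
  stopifnot(inherits(clip, "audio_clip"))
  sg <- stft(clip, frame_len = frame_len, hop = hop, window = "hann", nfft = nfft)
  pitch_from_spectrogram(sg, fmin = fmin, fmax = fmax,
                         steps_per_octave = steps_per_octave)
}

pitch_from_spectrogram <- function(sg, fmin = 100, fmax = 1000,
                                   steps_per_octave = 48) {
  if (fmin < 50 || fmax > 2000 || fmin >= fmax) {
    stop("pitch range must satisfy 50 <= fmin < fmax <= 2000")
  }
  cand <- fmin * 2^seq(0, log2(fmax / fmin), by = 1 / steps_per_octave)
  K <- pitch_kernels(sg$freqs, cand, band_max = min(4000, max(sg$freqs)))

  L <- sqrt(sg$magnitude)
  norms <- sqrt(colSums(L^2))
  nz <- norms > 0
  Ln <- L
  Ln[, nz] <- sweep(L[, nz, drop = FALSE], 2, norms[nz], "/")
  S <- crossprod(K, Ln) # candidates x frames

  n_frames <- ncol(S)
  f0 <- rep(NA_real_, n_frames)
  conf <- rep(0, n_frames)
  logc <- log2(cand)
  for (j in seq_len(n_frames)) {
    if (!nz[j]) next
    i <- which.max(S[, j])
    s <- S[i, j]
    p <- cand[i]
    if (i > 1 && i < length(cand)) {
      # parabolic refinement on the log2-frequency grid
      y1 <- S[i - 1, j]; y2 <- s; y3 <- S[i + 1, j]
      denom <- y1 - 2 * y2 + y3
      if (is.finite(denom) && denom < 0) {
        d <- 0.5 * (y1 - y3) / denom
        d <- max(-0.5, min(0.5, d))
        p <- 2^(logc[i] + d * (logc[2] - logc[1]))
        s <- y2 - 0.25 * (y1 - y3) * d
      }
    }
    f0[j] <- min(fmax, max(fmin, p))
    conf[j] <- min(1, max(0, s))
  }
  data.frame(time = sg$frame_times, f0 = f0, confidence = conf)
}

# Template matrix (bins x candidates): cosine lobes at the fundamental and at
# prime harmonics, 1/sqrt(k) weights, mean-removed and unit-normalized so that
# a flat (noise) spectrum correlates to ~0 and a sawtooth-like harmonic stack
# correlates strongly.
pitch_kernels <- function(freqs, candidates, band_max = 4000) {
  allowed_k <- c(1L, primes_up_to(ceiling(band_max / min(candidates))))
  K <- matrix(0, nrow = length(freqs), ncol = length(candidates))
  for (i in seq_along(candidates)) {
    p <- candidates[i]
    k_near <- round(freqs / p)
    ok <- k_near >= 1 & (k_near %in% allowed_k) & (k_near * p) < band_max
    v <- numeric(length(freqs))
    v[ok] <- cos(2 * pi * freqs[ok] / p) / sqrt(k_near[ok])
    v <- v - mean(v)
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    K[, i] <- v
  }
  K
}

primes_up_to <- function(n) {
  if (n < 2) return(integer(0))
  sieve <- rep(TRUE, n)
  sieve[1] <- FALSE
  for (i in 2:floor(sqrt(n))) {
    if (i > n) break
    if (sieve[i]) sieve[seq(i * i, n, by = i)] <- FALSE
  }
  which(sieve)
}
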