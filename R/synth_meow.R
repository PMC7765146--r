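#' Specification of a synthetic meow
#'
#' Parameterizes a harmonic, pitch-glided, amplitude-modulated vocalization
#' used as a stand-in for a recorded meow. The fundamental frequency glides
#' linearly from `f0_start` to `f0_end` (rising contours are associated with
#' positive emission contexts, falling with negative ones); `n_harmonics`
#' harmonics decay at `harmonic_rolloff` dB per octave; sinusoidal amplitude
#' modulation at `am_rate` Hz with depth `am_depth` controls perceived
#' roughness; broadband Gaussian noise is added at `noise_snr` dB.
#'
#' @param f0_start,f0_end fundamental frequency at clip start/end, Hz; both in
#'   (50, 2000). Rising contour if `f0_end > f0_start`.
#' @param n_harmonics requested number of harmonics; harmonics at or above the
#'   4 kHz Nyquist limit (for 8 kHz audio) are truncated.
#' @param harmonic_rolloff spectral decay of harmonic amplitudes, dB/octave.
#' @param am_rate amplitude-modulation rate, Hz.
#' @param am_depth amplitude-modulation depth, in `[0, 1]`. The modulated
#'   envelope is normalized by `1 + am_depth` so that peak amplitude — and
#'   hence overall level — stays comparable while roughness varies.
#' @param noise_snr signal-to-noise ratio of added Gaussian noise, dB;
#'   `Inf` adds no noise.
#' @param duration clip length in seconds, in (0.1, 10].
#' @param seed integer seed; synthesis is deterministic given the spec.
#' @return an object of class `meow_spec`.
#' @export
meow_spec <- function(f0_start = 450, f0_end = 600, n_harmonics = 6,
                      harmonic_rolloff = 6, am_rate = 70, am_depth = 0.3,
                      noise_snr = 25, duration = 1, seed = 1L) {
  spec <- list(
    f0_start = f0_start, f0_end = f0_end, n_harmonics = as.integer(n_harmonics),
    harmonic_rolloff = harmonic_rolloff, am_rate = am_rate, am_depth = am_depth,
    noise_snr = noise_snr, duration = duration, seed = as.integer(seed)
  )
  validate_meow_spec(spec)
  structure(spec, class = "meow_spec")
}

validate_meow_spec <- function(spec) {
  with(spec, {
    if (f0_start <= 50 || f0_start >= 2000 || f0_end <= 50 || f0_end >= 2000) {
      stop("f0_start and f0_end must lie in (50, 2000) Hz")
    }
    if (duration <= 0.1 || duration > 10) stop("duration must lie in (0.1, 10] seconds")
    if (am_depth < 0 || am_depth > 1) stop("am_depth must lie in [0, 1]")
    if (n_harmonics < 1) stop("n_harmonics must be >= 1")
    if (am_rate < 0) stop("am_rate must be >= 0")
  })
  invisible(spec)
}

#' @export
print.meow_spec <- function(x, ...) {
  cat(sprintf(
    "<meow_spec> F0 %g -> %g Hz (%s), %d harmonics @ -%g dB/oct, AM %g Hz depth %g, SNR %g dB, %.2f s, seed %d\n",
    x$f0_start, x$f0_end, if (x$f0_end >= x$f0_start) "rising" else "falling",
    x$n_harmonics, x$harmonic_rolloff, x$am_rate, x$am_depth, x$noise_snr,
    x$duration, x$seed
  ))
  invisible(x)
}

#' Synthesize a meow-like audio clip
#'
#' Renders the additive-harmonic model described in [meow_spec()]: the
#' instantaneous fundamental interpolates linearly between the endpoint
#' frequencies, harmonic `k` has amplitude `10^(-rolloff * log2(k) / 20)`,
#' the envelope is `(1 + am_depth * sin(2 pi am_rate t)) / (1 + am_depth)`,
#' and Gaussian noise is added at the requested SNR. Harmonics at or above
#' 4 kHz are truncated; output is peak-normalized to 0.9 before noise and
#' rescaled if noise pushes any sample outside `(-1, 1)`.
#'
#' @param spec a [meow_spec()].
#' @param sample_rate output rate, Hz (default 8000).
#' @return an [audio_clip()]; bit-identical across calls with the same spec.
#' @examples
#' clip <- synth_meow(meow_spec(f0_start = 300, f0_end = 600, seed = 7))
#' clip_duration(clip)
#' @export
synth_meow <- function(spec, sample_rate = 8000) {
  stopifnot(inherits(spec, "meow_spec"))
  validate_meow_spec(spec)
  fs <- sample_rate
  n <- round(spec$duration * fs)
  t <- (seq_len(n) - 1) / fs
  f0_t <- seq(spec$f0_start, spec$f0_end, length.out = n)
  nyq <- fs / 2
  k_max <- max(which(seq_len(spec$n_harmonics) * max(f0_t) < nyq), 0L)
  if (k_max < 1) stop("no harmonic below the Nyquist frequency for this spec")
  k <- seq_len(min(spec$n_harmonics, k_max))
  amps <- 10^(-spec$harmonic_rolloff * log2(k) / 20)

  # phase[1] = 0 so the instantaneous frequency at sample i is f0_t[i]
  phase <- 2 * pi * (cumsum(f0_t) - f0_t[1]) / fs
  sig <- rep(0, n)
  for (i in seq_along(k)) sig <- sig + amps[i] * sin(k[i] * phase)
  env <- (1 + spec$am_depth * sin(2 * pi * spec$am_rate * t)) / (1 + spec$am_depth)
  x <- sig * env
  x <- x / max(abs(x)) * 0.9

  if (is.finite(spec$noise_snr)) {
    p_sig <- mean(x^2)
    noise_sd <- sqrt(p_sig / 10^(spec$noise_snr / 10))
    x <- x + with_seed(spec$seed, rnorm(n, 0, noise_sd))
    peak <- max(abs(x))
    if (peak > 0.999) x <- x / peak * 0.999
  }
  audio_clip(x, fs)
}

#' Distributions of meow parameters for one emission context
#'
#' Each acoustic parameter is given either as a single value (held constant)
#' or as `c(mean, sd)` (drawn from a normal distribution, clamped to the valid
#' range) when clips are sampled with [synth_corpus()].
#'
#' @param f0_start,f0_end,am_depth,am_rate,duration length-1 or length-2
#'   numeric (`value` or `c(mean, sd)`).
#' @param n_harmonics,harmonic_rolloff,noise_snr constants shared by all draws.
#' @return an object of class `meow_spec_dist`.
#' @export
meow_spec_dist <- function(f0_start = c(450, 40), f0_end = c(600, 50),
                           am_depth = c(0.3, 0.1), am_rate = c(70, 10),
                           duration = c(1, 0.2), n_harmonics = 6,
                           harmonic_rolloff = 6, noise_snr = 25) {
  structure(
    list(
      f0_start = f0_start, f0_end = f0_end, am_depth = am_depth,
      am_rate = am_rate, duration = duration, n_harmonics = n_harmonics,
      harmonic_rolloff = harmonic_rolloff, noise_snr = noise_snr
    ),
    class = "meow_spec_dist"
  )
}

#' Default per-context meow distributions
#'
#' Plausible acoustic conditions for the three emission contexts: positive
#' contexts (waiting for food, brushing) get rising pitch contours and mild
#' amplitude modulation; the negative context (isolation) gets a falling
#' contour, higher pitch, longer calls and deeper modulation (hence higher
#' roughness). Modulation rates sit in the 60-90 Hz band where perceived
#' roughness is maximal for carriers in the meow F0 range (and where
#' modulation sidebands are resolvable by the 32 ms analysis frame). The
#' per-context parameter ranges are design choices of this package, not
#' calibrated to any recorded corpus.
#'
#' @return named list of [meow_spec_dist()], one per context.
#' @export
default_class_specs <- function() {
  list(
    waiting_for_food = meow_spec_dist(
      f0_start = c(480, 40), f0_end = c(640, 50),
      am_depth = c(0.25, 0.10), am_rate = c(70, 8), duration = c(1.0, 0.2)
    ),
    isolation = meow_spec_dist(
      f0_start = c(640, 50), f0_end = c(440, 40),
      am_depth = c(0.60, 0.15), am_rate = c(85, 8), duration = c(1.4, 0.3)
    ),
    brushing = meow_spec_dist(
      f0_start = c(400, 35), f0_end = c(520, 45),
      am_depth = c(0.15, 0.08), am_rate = c(60, 8), duration = c(0.9, 0.2)
    )
  )
}

draw_spec <- function(dist, seed) {
  draw <- function(par, lo, hi) {
    v <- if (length(par) == 2) rnorm(1, par[1], par[2]) else par[1]
    min(hi, max(lo, v))
  }
  with_seed(seed, {
    meow_spec(
      f0_start = draw(dist$f0_start, 60, 1900),
      f0_end = draw(dist$f0_end, 60, 1900),
      am_depth = draw(dist$am_depth, 0, 1),
      am_rate = draw(dist$am_rate, 1, 200),
      duration = draw(dist$duration, 0.2, 5),
      n_harmonics = dist$n_harmonics,
      harmonic_rolloff = dist$harmonic_rolloff,
      noise_snr = dist$noise_snr,
      seed = seed + 1L
    )
  })
}

#' Generate a labeled synthetic meow corpus
#'
#' Draws `n_per_class` clips per context from per-context parameter
#' distributions. Each clip gets a deterministic seed derived from the master
#' seed, so the corpus is fully reproducible.
#'
#' @param class_specs named list of [meow_spec_dist()], one per context
#'   (default [default_class_specs()]).
#' @param n_per_class clips per context; at least 2 (medioid and outlier
#'   selection needs two candidates).
#' @param seed master integer seed.
#' @param sample_rate output rate, Hz.
#' @return a list with `clips` (named list of [audio_clip()]) and `labels`
#'   (data.frame with columns `clip_id`, `context`).
#' @export
synth_corpus <- function(class_specs = default_class_specs(), n_per_class = 10,
                         seed = 1L, sample_rate = 8000) {
  if (n_per_class < 2) stop("n_per_class must be >= 2")
  if (is.null(names(class_specs)) || any(names(class_specs) == "")) {
    stop("class_specs must be a named list (context -> meow_spec_dist)")
  }
  clips <- list()
  labels <- data.frame(clip_id = character(), context = character())
  for (ci in seq_along(class_specs)) {
    context <- names(class_specs)[ci]
    for (j in seq_len(n_per_class)) {
      clip_seed <- as.integer(seed) + 1000L * ci + j
      spec <- draw_spec(class_specs[[ci]], clip_seed)
      id <- sprintf("%s_%02d", context, j)
      clips[[id]] <- synth_meow(spec, sample_rate)
      labels <- rbind(labels, data.frame(clip_id = id, context = context))
    }
  }
  list(clips = clips, labels = labels)
}

#' Write a corpus to WAV files plus a labels CSV
#'
#' @param corpus result of [synth_corpus()].
#' @param dir output directory (created if needed).
#' @return path of the labels CSV, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(corpus$labels))
  for (i in seq_len(nrow(corpus$labels))) {
    id <- corpus$labels$clip_id[i]
    paths[i] <- file.path(dir, paste0(id, ".wav"))
    write_wav(corpus$clips[[id]], paths[i])
  }
  labels <- cbind(corpus$labels, path = paths)
  out <- file.path(dir, "labels.csv")
  write.csv(labels, out, row.names = FALSE)
  invisible(out)
}
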