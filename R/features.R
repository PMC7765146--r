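#' Framewise acoustic feature track for a clip
#'
#' Computes, frame by frame: fundamental frequency and confidence
#' ([estimate_pitch()]), psychoacoustic roughness ([roughness_frame()] over
#' the frame's spectral peaks), and tristimulus descriptors
#' ([tristimulus_frame()] at the frame's estimated F0). The voiced mask is set
#' by the inclusive confidence gate `confidence >= conf_threshold`; F0 and
#' tristimulus values on unvoiced frames are excluded from aggregation, while
#' roughness — defined regardless of voicing — is kept on every frame.
#'
#' @param clip an [audio_clip()].
#' @param frame_len,hop framing in samples (defaults: 32 ms / 10 ms at 8 kHz).
#' @param conf_threshold pitch-confidence floor in `[0, 1]`; frames below it
#'   are treated as unvoiced (default 0.15).
#' @param fmin,fmax pitch search range, Hz.
#' @param nfft FFT length for the analysis spectrogram.
#' @return a data.frame of class `feature_track` with columns `time`, `f0`,
#'   `f0_confidence`, `voiced_mask`, `roughness`, `t1`, `t2`, `t3`.
#' @export
feature_track <- function(clip, frame_len = 256, hop = 80, conf_threshold = 0.15,
                          fmin = 100, fmax = 1000, nfft = 1024) {
  stopifnot(inherits(clip, "audio_clip"))
  sg <- stft(clip, frame_len = frame_len, hop = hop, window = "hann", nfft = nfft)
  pitch <- pitch_from_spectrogram(sg, fmin = fmin, fmax = fmax)

  n_frames <- ncol(sg$magnitude)
  rough <- numeric(n_frames)
  t1 <- t2 <- t3 <- rep(NA_real_, n_frames)
  for (j in seq_len(n_frames)) {
    mag_j <- sg$magnitude[, j]
    rough[j] <- roughness_frame(spectral_peaks(mag_j, sg$freqs))
    if (is.finite(pitch$f0[j])) {
      tt <- tristimulus_frame(mag_j, sg$freqs, pitch$f0[j],
                              min_band_hz = 2 * clip$sample_rate / frame_len)
      t1[j] <- tt[1]; t2[j] <- tt[2]; t3[j] <- tt[3]
    }
  }

  track <- data.frame(
    time = pitch$time, f0 = pitch$f0, f0_confidence = pitch$confidence,
    voiced_mask = NA, roughness = rough, t1 = t1, t2 = t2, t3 = t3
  )
  class(track) <- c("feature_track", "data.frame")
  mask_low_confidence(track, conf_threshold)
}

#' Apply the pitch-confidence gate to a feature track
#'
#' Sets `voiced_mask <- f0_confidence >= threshold` (inclusive comparison:
#' values strictly below the floor are ignored, the floor itself is kept).
#'
#' @param track a [feature_track()].
#' @param threshold confidence floor in `[0, 1]` (default 0.15).
#' @return the track with `voiced_mask` updated.
#' @export
mask_low_confidence <- function(track, threshold = 0.15) {
  stopifnot(inherits(track, "feature_track"))
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  track$voiced_mask <- track$f0_confidence >= threshold
  track
}

#' Aggregate a feature track to the 10-value feature vector
#'
#' Per-recording summary: mean and sample standard deviation (denominator
#' n - 1) of each time-varying feature. F0 and tristimulus statistics are
#' computed over voiced frames only (and skip frames where tristimulus was
#' undefined); roughness statistics use all frames.
#'
#' @param track a [feature_track()].
#' @param clip_id optional clip identifier carried into the output.
#' @param context optional context label carried into the output.
#' @return a one-row data.frame with columns `clip_id`, `context` and the 10
#'   feature columns `f0_mean, f0_sd, r_mean, r_sd, t1_mean, t1_sd, t2_mean,
#'   t2_sd, t3_mean, t3_sd`.
#' @export
aggregate_track <- function(track, clip_id = NA_character_, context = NA_character_) {
  stopifnot(inherits(track, "feature_track"))
  voiced <- track$voiced_mask & is.finite(track$f0)
  f0_v <- track$f0[voiced]
  if (length(f0_v) < 2 || nrow(track) < 2) {
    stop("recording unusable: fewer than 2 voiced frames (or < 2 frames total)")
  }
  m_sd <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) < 2) stop("recording unusable: fewer than 2 usable frames for a feature")
    c(mean(x), sd(x))
  }
  f0 <- m_sd(f0_v)
  r <- m_sd(track$roughness)
  t1 <- m_sd(track$t1[voiced])
  t2 <- m_sd(track$t2[voiced])
  t3 <- m_sd(track$t3[voiced])
  out <- data.frame(
    clip_id = clip_id, context = context,
    f0_mean = f0[1], f0_sd = f0[2], r_mean = r[1], r_sd = r[2],
    t1_mean = t1[1], t1_sd = t1[2], t2_mean = t2[1], t2_sd = t2[2],
    t3_mean = t3[1], t3_sd = t3[2]
  )
  rownames(out) <- NULL
  out
}

#' Extract per-recording feature vectors for a whole corpus
#'
#' Runs [feature_track()] and [aggregate_track()] on every clip. Clips that
#' are unusable (too few voiced frames) are dropped with a warning naming the
#' clip.
#'
#' @param corpus list with `clips` (named list of [audio_clip()]) and `labels`
#'   (data.frame `clip_id`, `context`), as produced by [synth_corpus()].
#' @param ... passed to [feature_track()].
#' @return data.frame with one row per usable clip: `clip_id`, `context`, and
#'   the 10 feature columns.
#' @export
corpus_features <- function(corpus, ...) {
  rows <- vector("list", nrow(corpus$labels))
  for (i in seq_len(nrow(corpus$labels))) {
    id <- corpus$labels$clip_id[i]
    ctx <- corpus$labels$context[i]
    rows[[i]] <- tryCatch(
      aggregate_track(feature_track(corpus$clips[[id]], ...), clip_id = id, context = ctx),
      error = function(e) {
        warning(sprintf("clip %s dropped: %s", id, conditionMessage(e)))
        NULL
      }
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) stop("no usable clips in corpus")
  rownames(out) <- NULL
  out
}
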