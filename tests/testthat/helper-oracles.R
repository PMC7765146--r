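# Independent oracles used to cross-check package implementations.
# These deliberately share no code with the functions they check.

# Normalized-autocorrelation voicing clarity, framewise: max autocorrelation
# over lags corresponding to 50-2000 Hz, as a [0,1]-ish clarity score. An
# independent route to "is this frame periodic?" used to validate the
# spectral pitch tracker's confidence behavior.
autocorr_clarity <- function(clip, frame_len = 256, hop = 80) {
  x <- clip$samples
  fs <- clip$sample_rate
  n_frames <- floor((length(x) - frame_len) / hop) + 1
  lag_min <- max(2, floor(fs / 2000))
  lag_max <- min(frame_len - 1, ceiling(fs / 50))
  vapply(seq_len(n_frames), function(j) {
    fr <- x[(j - 1) * hop + seq_len(frame_len)]
    fr <- fr - mean(fr)
    denom <- sum(fr^2)
    if (denom == 0) return(0)
    ac <- vapply(lag_min:lag_max, function(l) {
      a <- fr[1:(frame_len - l)]
      b <- fr[(l + 1):frame_len]
      sum(a * b) / sqrt(sum(a^2) * sum(b^2) + 1e-12)
    }, 0)
    max(0, max(ac))
  }, 0)
}

# Brute-force Pearson chi-square statistic: sum (O - E)^2 / E.
chisq_oracle <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Exhaustive medioid/outlier search: per class, compute every member's
# Euclidean distance to the class mean and take argmin/argmax, breaking ties
# toward the lexicographically lowest id.
exemplar_oracle <- function(x, labels, ids) {
  out <- NULL
  for (ctx in unique(labels)) {
    rows <- which(labels == ctx)
    cen <- colMeans(x[rows, , drop = FALSE])
    d <- apply(x[rows, , drop = FALSE], 1, function(r) sqrt(sum((r - cen)^2)))
    id_ctx <- as.character(ids[rows])
    med <- sort(id_ctx[d == min(d)])[1]
    outl <- sort(id_ctx[d == max(d)])[1]
    out <- rbind(out, data.frame(
      context = ctx, role = c("medioid", "outlier"), clip_id = c(med, outl)
    ))
  }
  out
}

# Random per-recording feature table in the 10-column acoustic schema.
# `effect` adds a per-class mean shift to the named columns.
make_feature_table <- function(n_per_class = 10, effect_cols = character(),
                               effect_size = 3, seed = 1) {
  set.seed(seed)
  contexts <- c("waiting_for_food", "isolation", "brushing")
  cols <- c("f0_mean", "f0_sd", "r_mean", "r_sd", "t1_mean", "t1_sd",
            "t2_mean", "t2_sd", "t3_mean", "t3_sd")
  n <- n_per_class * length(contexts)
  df <- data.frame(
    clip_id = sprintf("c%03d", seq_len(n)),
    context = rep(contexts, each = n_per_class)
  )
  for (col in cols) {
    shift <- if (col %in% effect_cols) {
      rep(effect_size * (seq_along(contexts) - 2), each = n_per_class)
    } else 0
    df[[col]] <- rnorm(n) + shift
  }
  df
}
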