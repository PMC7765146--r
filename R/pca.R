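#' Principal component analysis of emotion-descriptor ratings
#'
#' PCA of the 11 descriptor scores, with one observation per participant x
#' meow response. Can be run on all responses or restricted to responses whose
#' context was correctly assigned. Correlation-mode (default) standardizes the
#' descriptors; covariance mode uses centered raw scores.
#'
#' Sign convention: PC1 is oriented so that the `calm_relaxed` descriptor
#' loads non-positively, which places positive-valence responses on the
#' negative (left) side of PC1 and negative-valence ones on the right. Higher
#' components are oriented so their largest-magnitude loading is positive
#' (a determinism device only).
#'
#' @param responses data.frame with the 11 descriptor columns plus `context`,
#'   `variant` and `correct` (see [synth_cohort()]).
#' @param subset `"all"` or `"correct_only"` (keep only correctly assigned
#'   responses).
#' @param mode `"correlation"` (default) or `"covariance"`.
#' @param min_obs minimum observations required after subsetting (default 12).
#' @return object of class `descriptor_pca`: list with `loadings`
#'   (descriptors x components), `scores` (observations x components),
#'   `explained_variance_pct` (sums to 100 over all components), `mode`,
#'   `subset`, and `metadata` (context/variant/correct per observation).
#' @export
pca_descriptors <- function(responses, subset = c("all", "correct_only"),
                            mode = c("correlation", "covariance"),
                            min_obs = 12) {
  subset <- match.arg(subset)
  mode <- match.arg(mode)
  desc_names <- names(DESCRIPTORS)
  missing_cols <- setdiff(desc_names, names(responses))
  if (length(missing_cols) > 0) {
    stop("responses lack descriptor columns: ", paste(missing_cols, collapse = ", "))
  }
  rows <- if (subset == "correct_only") responses[responses$correct, ] else responses
  x <- as.matrix(rows[, desc_names])
  if (anyNA(x)) stop("missing descriptor scores in used rows")
  if (nrow(x) < min_obs) stop("need at least ", min_obs, " observations after subsetting")
  if (mode == "correlation" && any(apply(x, 2, sd) == 0)) {
    stop("constant descriptor column; correlation-mode PCA undefined")
  }

  fit <- prcomp(x, center = TRUE, scale. = (mode == "correlation"))
  loadings <- fit$rotation
  scores <- fit$x

  # orient components deterministically
  for (j in seq_len(ncol(loadings))) {
    flip <- if (j == 1) {
      loadings["calm_relaxed", 1] > 0
    } else {
      loadings[which.max(abs(loadings[, j])), j] < 0
    }
    if (flip) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }

  ev <- fit$sdev^2
  structure(
    list(
      loadings = loadings, scores = scores,
      explained_variance_pct = 100 * ev / sum(ev),
      mode = mode, subset = subset,
      metadata = rows[, intersect(c("participant_id", "context", "variant", "correct"),
                                  names(rows)), drop = FALSE]
    ),
    class = "descriptor_pca"
  )
}

#' @export
print.descriptor_pca <- function(x, ...) {
  cat(sprintf(
    "<descriptor_pca> %d observations (%s, %s mode); PC1 %.1f%%, PC2 %.1f%% of variance\n",
    nrow(x$scores), x$subset, x$mode,
    x$explained_variance_pct[1], x$explained_variance_pct[2]
  ))
  invisible(x)
}

#' Valence summary of a descriptor PCA
#'
#' Per-context mean and SD of the PC1/PC2 scores, plus the partition of the
#' descriptors by the sign of their PC1 loading. Under the sign convention of
#' [pca_descriptors()], descriptors loading negatively on PC1 mark the
#' positive-valence side.
#'
#' @param result a [pca_descriptors()] result carrying context metadata.
#' @return list with `context_summary` (data.frame: context, n, pc1_mean,
#'   pc1_sd, pc2_mean, pc2_sd) and `loading_table` (data.frame: descriptor,
#'   pc1_loading, pc2_loading, valence_side).
#' @export
valence_summary <- function(result) {
  stopifnot(inherits(result, "descriptor_pca"))
  if (!"context" %in% names(result$metadata)) stop("result carries no context metadata")
  ctx <- result$metadata$context
  lv <- unique(ctx)
  cs <- do.call(rbind, lapply(lv, function(l) {
    s1 <- result$scores[ctx == l, 1]
    s2 <- result$scores[ctx == l, 2]
    data.frame(
      context = l, n = sum(ctx == l),
      pc1_mean = mean(s1), pc1_sd = if (length(s1) > 1) sd(s1) else NA_real_,
      pc2_mean = mean(s2), pc2_sd = if (length(s2) > 1) sd(s2) else NA_real_
    )
  }))
  rownames(cs) <- NULL
  lt <- data.frame(
    descriptor = rownames(result$loadings),
    pc1_loading = result$loadings[, 1],
    pc2_loading = result$loadings[, 2],
    valence_side = ifelse(result$loadings[, 1] <= 0, "positive", "negative")
  )
  rownames(lt) <- NULL
  list(context_summary = cs, loading_table = lt)
}

#' Score and loading plots for a descriptor PCA
#'
#' Two ggplot panels mirroring the usual PCA presentation: observation scores
#' on PC1/PC2 colored by context, and descriptor loadings as labeled arrows.
#'
#' @param result a [pca_descriptors()] result.
#' @return list with ggplot objects `scores` and `loadings`.
#' @export
plot_descriptor_pca <- function(result) {
  stopifnot(inherits(result, "descriptor_pca"))
  sc <- data.frame(
    PC1 = result$scores[, 1], PC2 = result$scores[, 2],
    context = result$metadata$context
  )
  ld <- data.frame(
    descriptor = rownames(result$loadings),
    PC1 = result$loadings[, 1], PC2 = result$loadings[, 2]
  )
  lab <- function(i) sprintf("PC%d (%.1f%%)", i, result$explained_variance_pct[i])
  p_scores <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                               color = .data$context)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = lab(1), y = lab(2), title = "Descriptor PCA: scores") +
    ggplot2::theme_minimal()
  p_loadings <- ggplot2::ggplot(ld, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = 0), color = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$descriptor), size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2), title = "Descriptor PCA: loadings") +
    ggplot2::theme_minimal()
  list(scores = p_scores, loadings = p_loadings)
}
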