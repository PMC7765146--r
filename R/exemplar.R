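#' One-way ANOVA screen of feature columns across contexts
#'
#' Tests every feature column independently with a classic one-way ANOVA
#' (equal-variance F test; Welch's correction available behind `welch = TRUE`)
#' against the context labels. A column is kept when `p < alpha`. Columns with
#' zero variance everywhere (F undefined) are dropped with a warning.
#'
#' @param features data.frame with a `context` column and numeric feature
#'   columns.
#' @param alpha significance level (default 0.05).
#' @param feature_cols character vector of columns to screen; defaults to the
#'   10-value acoustic feature space present in `features`.
#' @param welch use Welch's unequal-variance ANOVA instead of the classic
#'   equal-variance F test.
#' @return data.frame of class `screen_result` with columns `feature`,
#'   `statistic` (F), `p_value`, `kept`, and attribute `alpha`.
#' @export
anova_screen <- function(features, alpha = 0.05, feature_cols = NULL, welch = FALSE) {
  if (!"context" %in% names(features)) stop("features must have a 'context' column")
  if (is.null(feature_cols)) {
    feature_cols <- intersect(FEATURE_COLS, names(features))
    if (length(feature_cols) == 0) {
      feature_cols <- setdiff(names(features)[vapply(features, is.numeric, logical(1))],
                              c("clip_id", "context"))
    }
  }
  groups <- factor(features$context)
  if (nlevels(groups) < 2) stop("need at least 2 contexts")
  if (min(table(groups)) < 2) stop("need at least 2 recordings per context")

  res <- lapply(feature_cols, function(col) {
    x <- features[[col]]
    out <- tryCatch(
      {
        ft <- oneway.test(x ~ groups, var.equal = !welch)
        data.frame(feature = col, statistic = unname(ft$statistic),
                   p_value = unname(ft$p.value))
      },
      error = function(e) data.frame(feature = col, statistic = NA_real_,
                                     p_value = NA_real_)
    )
    if (!is.finite(out$p_value)) {
      warning(sprintf("feature '%s' dropped: F statistic undefined (degenerate variance)", col))
      out$p_value <- NA_real_
    }
    out
  })
  screen <- do.call(rbind, res)
  screen$kept <- !is.na(screen$p_value) & screen$p_value < alpha
  attr(screen, "alpha") <- alpha
  class(screen) <- c("screen_result", "data.frame")
  screen
}

#' Feature-family summary of a screen result
#'
#' Aggregates the per-column decisions to the five feature families
#' (f0, r, t1, t2, t3): a family is discarded when none of its columns
#' (mean and SD) survived the screen.
#'
#' @param screen a [anova_screen()] result.
#' @return data.frame with columns `family`, `n_columns`, `n_kept`,
#'   `discarded`.
#' @export
screen_family_summary <- function(screen) {
  fam <- sub("_(mean|sd)$", "", screen$feature)
  agg <- aggregate(screen$kept, by = list(family = fam), FUN = function(k) c(length(k), sum(k)))
  out <- data.frame(
    family = agg$family,
    n_columns = agg$x[, 1],
    n_kept = agg$x[, 2]
  )
  out$discarded <- out$n_kept == 0
  out[order(match(out$family, c("f0", "r", "t1", "t2", "t3"))), , drop = FALSE]
}

#' Per-context centroids of a feature matrix
#'
#' @param x numeric matrix (recordings x features), already reduced to the
#'   kept feature set (and standardized if distances will be standardized).
#' @param labels context label per row.
#' @return matrix (contexts x features) of arithmetic mean vectors.
#' @export
class_centroids <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x)) stop("labels must match rows of x")
  if (anyNA(labels)) stop("labels must not contain NA (empty class)")
  contexts <- unique(labels)
  cent <- do.call(rbind, lapply(contexts, function(ctx) {
    colMeans(x[labels == ctx, , drop = FALSE])
  }))
  rownames(cent) <- contexts
  colnames(cent) <- colnames(x)
  cent
}

#' Select medioid and outlier recordings per context
#'
#' For each context, the medioid is the recording whose (reduced,
#' optionally standardized) feature vector lies closest to the context
#' centroid in Euclidean distance, and the outlier the one farthest from it.
#' Exact distance ties are broken toward the lexicographically lowest
#' `clip_id`, independently for each role.
#'
#' @param x numeric matrix (recordings x features) in the space distances are
#'   measured in.
#' @param labels context label per row.
#' @param clip_ids recording identifier per row.
#' @param centroids optional centroid matrix from [class_centroids()];
#'   computed from `x` and `labels` when `NULL`.
#' @return data.frame of class `exemplar_set` with columns `context`, `role`
#'   (`medioid`/`outlier`), `clip_id`, `distance`; centroids attached as
#'   attribute `"centroids"`.
#' @export
select_exemplars <- function(x, labels, clip_ids, centroids = NULL) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x), length(clip_ids) == nrow(x))
  if (is.null(centroids)) centroids <- class_centroids(x, labels)

  rows <- list()
  for (ctx in rownames(centroids)) {
    in_ctx <- which(labels == ctx)
    if (length(in_ctx) < 2) stop("context '", ctx, "' has fewer than 2 recordings")
    d <- sqrt(colSums((t(x[in_ctx, , drop = FALSE]) - centroids[ctx, ])^2))
    ids <- as.character(clip_ids[in_ctx])
    med <- ids[d == min(d)]
    out <- ids[d == max(d)]
    med_id <- sort(med)[1]
    out_id <- sort(out)[1]
    rows[[ctx]] <- data.frame(
      context = ctx,
      role = c("medioid", "outlier"),
      clip_id = c(med_id, out_id),
      distance = c(min(d), max(d))
    )
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "centroids") <- centroids
  class(res) <- c("exemplar_set", "data.frame")
  res
}

#' Screen features and select exemplars in one step
#'
#' Convenience wrapper chaining [anova_screen()], optional z-scoring of the
#' kept columns (mean 0, SD 1 over all recordings — Hz, roughness and energy
#' ratios are incommensurate, so distances default to the standardized space),
#' [class_centroids()] and [select_exemplars()].
#'
#' @param features data.frame from [corpus_features()] (columns `clip_id`,
#'   `context`, features).
#' @param alpha screen significance level.
#' @param standardize z-score kept columns before distances (default TRUE);
#'   `FALSE` reproduces raw-space behavior.
#' @param welch passed to [anova_screen()].
#' @return list with `screen` ([anova_screen()] result), `family_summary`,
#'   `exemplars` ([select_exemplars()] result), `kept_features`.
#' @export
screen_and_select <- function(features, alpha = 0.05, standardize = TRUE, welch = FALSE) {
  screen <- anova_screen(features, alpha = alpha, welch = welch)
  kept <- screen$feature[screen$kept]
  if (length(kept) == 0) stop("no feature survived the ANOVA screen")
  x <- as.matrix(features[, kept, drop = FALSE])
  if (standardize) {
    x <- scale(x)
    # a zero-variance kept column cannot happen (zero variance fails the screen)
  }
  exemplars <- select_exemplars(x, features$context, features$clip_id)
  list(
    screen = screen,
    family_summary = screen_family_summary(screen),
    exemplars = exemplars,
    kept_features = kept
  )
}
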