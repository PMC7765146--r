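#' Default polarity key for the 22-item Animal Empathy Scale
#'
#' The scale has 11 empathic and 11 unempathic (reverse-scored) items; the
#' published key is distributed with the instrument, not reproduced here, so
#' the package ships a synthetic default — odd items empathic (+1), even items
#' unempathic (-1) — and accepts any user-supplied key with the 11/11 split.
#'
#' @return integer vector of length 22 with values +1 (empathic) and -1
#'   (unempathic, reverse-scored).
#' @export
default_aes_key <- function() rep(c(1L, -1L), 11)

validate_aes_key <- function(key) {
  if (length(key) != 22 || !all(key %in% c(-1L, 1L)) ||
      sum(key == 1L) != 11 || sum(key == -1L) != 11) {
    stop("AES key must have 22 entries in {-1, +1}, exactly 11 of each")
  }
  invisible(key)
}

#' Score the Animal Empathy Scale
#'
#' 22 items on a 9-point agreement scale. Agreement with empathic statements
#' scores high; unempathic items are reverse-scored (`10 - x`) before summing,
#' so the total ranges from 22 (least empathic) to 198 (most empathic).
#'
#' @param items integer vector of 22 raw responses in 1..9.
#' @param key polarity per item (+1 empathic, -1 unempathic); default
#'   [default_aes_key()].
#' @return integer total in `[22, 198]`, or `NA` with a warning if any item is
#'   missing or out of range (the record is to be excluded).
#' @export
score_aes <- function(items, key = default_aes_key()) {
  validate_aes_key(key)
  if (length(items) != 22) stop("AES needs exactly 22 items")
  if (anyNA(items) || any(items < 1 | items > 9) || any(items != round(items))) {
    warning("AES items missing or out of range; record excluded (NA)")
    return(NA_integer_)
  }
  scored <- ifelse(key < 0, 10 - items, items)
  as.integer(sum(scored))
}

#' Score the Cat Empathy Scale
#'
#' Three 9-point items summed directly; total in `[3, 27]`.
#'
#' @param items integer vector of 3 responses in 1..9.
#' @return integer total, or `NA` with a warning for invalid input.
#' @export
score_ces <- function(items) {
  if (length(items) != 3) stop("CES needs exactly 3 items")
  if (anyNA(items) || any(items < 1 | items > 9) || any(items != round(items))) {
    warning("CES items missing or out of range; record excluded (NA)")
    return(NA_integer_)
  }
  as.integer(sum(items))
}

#' Cronbach's alpha
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total))`, with sample
#' variances. Reverse-scoring must already be applied to the item matrix.
#'
#' @param items numeric matrix or data.frame, participants x items (k >= 2
#'   items, n >= 3 participants).
#' @return scalar alpha.
#' @export
cronbach_alpha <- function(items) {
  x <- as.matrix(items)
  k <- ncol(x)
  if (k < 2) stop("need at least 2 items")
  if (nrow(x) < 3) stop("need at least 3 participants")
  v_total <- var(rowSums(x))
  if (v_total == 0) stop("zero variance of total scores; alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2, var)) / v_total)
}

#' Context-classification accuracy table
#'
#' Counts correct and incorrect context assignments for one meow (a
#' context/variant pair), overall or split by a participant attribute, with
#' percentages to 2 decimals.
#'
#' @param responses data.frame with one row per participant x meow, columns
#'   `participant_id`, `context` (true), `variant` (`medioid`/`outlier`),
#'   `correct` (logical).
#' @param context true context of the meow of interest.
#' @param variant `"medioid"` (default) or `"outlier"`.
#' @param participants optional data.frame of participant attributes (must
#'   have `participant_id`), needed when `group_by` is given.
#' @param group_by optional attribute column in `participants` to split rows
#'   by (e.g. `"cat_owner"`, `"gender"`).
#' @return data.frame with columns `group` (or `"all"`), `correct`,
#'   `incorrect`, `pct_correct`, `pct_incorrect`.
#' @export
accuracy_table <- function(responses, context, variant = "medioid",
                           participants = NULL, group_by = NULL) {
  rows <- responses[responses$context == context & responses$variant == variant, ]
  if (nrow(rows) == 0) stop("no responses for context '", context, "' / variant '", variant, "'")
  if (!is.null(group_by)) {
    if (is.null(participants)) stop("participants table required for group_by")
    rows <- merge(rows, participants[, c("participant_id", group_by)], by = "participant_id")
    grp <- as.character(rows[[group_by]])
  } else {
    grp <- rep("all", nrow(rows))
  }
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    sel <- rows$correct[grp == g]
    n_cor <- sum(sel)
    n_inc <- sum(!sel)
    data.frame(
      group = g, correct = n_cor, incorrect = n_inc,
      pct_correct = round(100 * n_cor / (n_cor + n_inc), 2),
      pct_incorrect = round(100 * n_inc / (n_cor + n_inc), 2)
    )
  }))
  rownames(out) <- NULL
  out
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Thin wrapper around [stats::chisq.test()] returning a stable result
#' schema; continuity correction defaults off (both conventions are reported
#' by the pipeline where it matters).
#'
#' @param observed 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param correction apply Yates' continuity correction (default FALSE).
#' @return object of class `contingency_result`: list with `observed`,
#'   `expected`, `statistic`, `df`, `p_value`, `correction`.
#' @export
chisq_2x2 <- function(observed, correction = FALSE) {
  m <- as.matrix(observed)
  if (!all(dim(m) == c(2, 2))) stop("observed must be 2x2")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) stop("zero margin in contingency table")
  ht <- suppressWarnings(chisq.test(m, correct = correction))
  structure(
    list(
      observed = m, expected = ht$expected,
      statistic = unname(ht$statistic), df = unname(ht$parameter),
      p_value = unname(ht$p.value), correction = correction
    ),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> chi-square = %.4f, df = %d, p = %.4g%s\n",
              x$statistic, x$df, x$p_value,
              if (x$correction) " (Yates-corrected)" else ""))
  invisible(x)
}

#' Exact binomial test against a chance level
#'
#' Tests an observed number of correct assignments against guessing among
#' three alternatives (default chance level 1/3). Both the one-sided
#' (greater-than-chance) and two-sided exact p-values are reported.
#'
#' @param correct number of correct assignments.
#' @param n number of trials.
#' @param p0 chance probability (default 1/3).
#' @return list with `correct`, `n`, `p0`, `estimate`, `p_greater`,
#'   `p_two_sided`.
#' @export
chance_test <- function(correct, n, p0 = 1 / 3) {
  if (correct < 0 || correct > n) stop("need 0 <= correct <= n")
  list(
    correct = correct, n = n, p0 = p0, estimate = correct / n,
    p_greater = binom.test(correct, n, p0, alternative = "greater")$p.value,
    p_two_sided = binom.test(correct, n, p0, alternative = "two.sided")$p.value
  )
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. Exact p-value for small (both groups
#' <= 20) untied samples; normal approximation with tie correction otherwise.
#' The switch used is recorded in the output.
#'
#' @param a,b numeric score vectors (both non-empty).
#' @return list with `U`, `p_value`, `method` (`"exact"` or `"approximate"`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  has_ties <- anyDuplicated(c(a, b)) > 0
  exact <- length(a) <= 20 && length(b) <= 20 && !has_ties
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact, correct = !exact)
  )
  list(U = unname(ht$statistic), p_value = ht$p.value,
       method = if (exact) "exact" else "approximate")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and t-approximation p-value.
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5) stop("need at least 5 observations")
  if (length(unique(rank(x))) == 1 || length(unique(rank(y))) == 1) {
    stop("zero variance in ranks; correlation undefined")
  }
  ht <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Number of correctly assigned medioid meows per participant
#'
#' Counts correct context assignments over the three medioid meows
#' (0 = none ... 3 = all), the quantity correlated with the empathy scores.
#'
#' @param responses data.frame as in [accuracy_table()].
#' @return data.frame with `participant_id`, `n_correct_medioids`.
#' @export
n_correct_medioids <- function(responses) {
  med <- responses[responses$variant == "medioid", ]
  agg <- aggregate(med$correct, by = list(participant_id = med$participant_id), FUN = sum)
  names(agg)[2] <- "n_correct_medioids"
  agg
}

#' Full survey statistical battery
#'
#' Runs, on a cohort (responses + participants + AES key), the analyses
#' applied to the listener survey: accuracy tables per context and variant
#' with medioid-vs-outlier chi-squares; accuracy by participant attribute with
#' chi-squares; exact binomial chance tests on medioid accuracy; AES/CES
#' scoring with Mann-Whitney comparisons by gender and cat ownership;
#' Cronbach's alpha of the (reverse-scored) AES items; and Spearman
#' correlations of AES/CES with the number of correct medioid assignments.
#'
#' @param responses data.frame, one row per participant x meow (see
#'   [synth_cohort()] for the schema).
#' @param participants data.frame of participant attributes including AES/CES
#'   item columns `aes_01..aes_22`, `ces_01..ces_03`.
#' @param aes_key polarity key for AES items.
#' @param chisq_correction use Yates' correction in all 2x2 tests.
#' @return a nested list of tables and test results (see names of the return
#'   value); serializable to JSON.
#' @export
survey_report <- function(responses, participants, aes_key = default_aes_key(),
                          chisq_correction = FALSE) {
  validate_aes_key(aes_key)
  contexts <- unique(responses$context)

  aes_items <- as.matrix(participants[, sprintf("aes_%02d", 1:22)])
  ces_items <- as.matrix(participants[, sprintf("ces_%02d", 1:3)])
  aes_scored <- sweep_reverse(aes_items, aes_key)
  aes_total <- rowSums(aes_scored)
  ces_total <- rowSums(ces_items)

  # Table 1 analogue: accuracy per context/variant + medioid-vs-outlier chisq
  tab1 <- list()
  for (ctx in contexts) {
    med <- accuracy_table(responses, ctx, "medioid")
    out <- accuracy_table(responses, ctx, "outlier")
    test <- chisq_2x2(rbind(c(med$correct, med$incorrect),
                            c(out$correct, out$incorrect)),
                      correction = chisq_correction)
    tab1[[ctx]] <- list(medioid = med, outlier = out,
                        chisq = test$statistic, p_value = test$p_value)
  }

  # Table 2 analogue: medioid accuracy by attribute within context
  attrs <- intersect(c("gender", "parent", "cat_owner", "grew_up_with_cats"),
                     names(participants))
  tab2 <- list()
  for (ctx in contexts) {
    tab2[[ctx]] <- list()
    for (a in attrs) {
      t <- accuracy_table(responses, ctx, "medioid", participants, group_by = a)
      test <- chisq_2x2(as.matrix(t[, c("correct", "incorrect")]),
                        correction = chisq_correction)
      tab2[[ctx]][[a]] <- list(table = t, chisq = test$statistic, p_value = test$p_value)
    }
  }

  # chance-level tests on medioid accuracy
  chance <- lapply(setNames(contexts, contexts), function(ctx) {
    t <- accuracy_table(responses, ctx, "medioid")
    chance_test(t$correct, t$correct + t$incorrect)
  })

  # Table 3 analogue: AES/CES by gender and ownership
  scales_by <- function(attr) {
    g <- participants[[attr]]
    lv <- sort(unique(as.character(g)))
    list(
      levels = lv,
      aes_mean = vapply(lv, function(l) mean(aes_total[g == l]), 0),
      aes_sd = vapply(lv, function(l) sd(aes_total[g == l]), 0),
      ces_mean = vapply(lv, function(l) mean(ces_total[g == l]), 0),
      ces_sd = vapply(lv, function(l) sd(ces_total[g == l]), 0),
      aes_test = mann_whitney(aes_total[g == lv[1]], aes_total[g == lv[2]]),
      ces_test = mann_whitney(ces_total[g == lv[1]], ces_total[g == lv[2]])
    )
  }
  tab3 <- lapply(setNames(intersect(c("gender", "cat_owner"), attrs),
                          intersect(c("gender", "cat_owner"), attrs)), scales_by)

  nc <- n_correct_medioids(responses)
  ord <- match(participants$participant_id, nc$participant_id)
  ncv <- nc$n_correct_medioids[ord]

  list(
    accuracy = tab1,
    accuracy_by_attribute = tab2,
    chance_tests = chance,
    scales = tab3,
    cronbach_alpha_aes = cronbach_alpha(aes_scored),
    spearman_aes_vs_correct = spearman_cor(aes_total, ncv),
    spearman_ces_vs_correct = spearman_cor(ces_total, ncv),
    spearman_aes_vs_ces = spearman_cor(aes_total, ces_total),
    aes_overall = c(mean = mean(aes_total), sd = sd(aes_total)),
    ces_overall = c(mean = mean(ces_total), sd = sd(ces_total))
  )
}

# reverse-score the unempathic columns of a raw AES item matrix
sweep_reverse <- function(items, key) {
  validate_aes_key(key)
  out <- items
  out[, key < 0] <- 10 - items[, key < 0]
  out
}
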