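test_that("AES scoring attains the documented bounds and reversal behavior", {
  key <- default_aes_key()
  # maximal empathy: empathic items 9, unempathic items 1 (reversed to 9)
  hi <- ifelse(key > 0, 9L, 1L)
  expect_equal(score_aes(hi, key), 198L)
  # minimal empathy
  lo <- ifelse(key > 0, 1L, 9L)
  expect_equal(score_aes(lo, key), 22L)
  # neutral: 5 is the reversal fixed point -> 22 * 5
  expect_equal(score_aes(rep(5L, 22), key), 110L)
  # a single unempathic item answered 9 contributes 1
  one <- rep(5L, 22)
  unemp <- which(key < 0)[1]
  one[unemp] <- 9L
  expect_equal(score_aes(one, key), 110L - 5L + 1L)
  # invalid input excludes the record
  expect_warning(out <- score_aes(c(rep(5L, 21), 12L), key), "excluded")
  expect_true(is.na(out))
})

test_that("reversing twice restores raw AES items", {
  set.seed(2)
  key <- default_aes_key()
  raw <- matrix(sample(1:9, 22 * 10, replace = TRUE), nrow = 10)
  rev1 <- ifelse(matrix(key, 10, 22, byrow = TRUE) < 0, 10 - raw, raw)
  rev2 <- ifelse(matrix(key, 10, 22, byrow = TRUE) < 0, 10 - rev1, rev1)
  expect_equal(rev2, raw)
})

test_that("CES scoring attains its bounds", {
  expect_equal(score_ces(c(9L, 9L, 9L)), 27L)
  expect_equal(score_ces(c(1L, 1L, 1L)), 3L)
  expect_equal(score_ces(c(5L, 5L, 5L)), 15L)
  expect_warning(out <- score_ces(c(5L, NA, 5L)), "excluded")
  expect_true(is.na(out))
})

test_that("Cronbach's alpha limit cases and closed form", {
  # perfectly correlated equal-variance items -> alpha = 1
  base <- rnorm(50)
  perfect <- cbind(base, base + 3, base - 1)
  expect_equal(cronbach_alpha(perfect), 1, tolerance = 1e-12)

  # independent items -> alpha near 0 (k = 22, n = 2000)
  set.seed(5)
  indep <- matrix(rnorm(2000 * 22), nrow = 2000)
  expect_lt(abs(cronbach_alpha(indep)), 0.1)

  # two items with correlation 0.5 -> population alpha = 2 (1 - 2/3) = 2/3
  set.seed(6)
  n <- 50000
  z <- rnorm(n)
  two <- cbind(sqrt(0.5) * z + sqrt(0.5) * rnorm(n),
               sqrt(0.5) * z + sqrt(0.5) * rnorm(n))
  expect_equal(cronbach_alpha(two), 2 / 3, tolerance = 0.02)
})

test_that("accuracy tables report correct counts and percentages", {
  co <- synth_cohort(cohort_spec(n_participants = 30, seed = 8))
  at <- accuracy_table(co$responses, "isolation", "medioid")
  expect_equal(at$correct + at$incorrect, 30)
  expect_equal(at$pct_correct + at$pct_incorrect, 100, tolerance = 1e-4)
  expect_equal(at$pct_correct, round(100 * at$correct / 30, 2))

  # all-correct cohort -> 100.00%
  perfect <- synth_cohort(cohort_spec(
    n_participants = 10,
    accuracy_by_group_context = list(
      owner = c(waiting_for_food = 1, isolation = 1, brushing = 1),
      nonowner = c(waiting_for_food = 1, isolation = 1, brushing = 1)
    ),
    outlier_accuracy_ratio = 1, seed = 1
  ))
  expect_equal(accuracy_table(perfect$responses, "brushing", "outlier")$pct_correct, 100)

  # grouped table splits by a participant attribute
  gt <- accuracy_table(co$responses, "brushing", "medioid", co$participants,
                       group_by = "cat_owner")
  expect_equal(sum(gt$correct + gt$incorrect), 30)
})

test_that("chi-square equals the brute-force oracle on 200 random tables", {
  set.seed(7)
  for (i in 1:200) {
    m <- matrix(rpois(4, 40) + 1, 2)
    res <- chisq_2x2(m)
    expect_equal(res$statistic, chisq_oracle(m), tolerance = 1e-10)
    expect_equal(res$expected, outer(rowSums(m), colSums(m)) / sum(m),
                 ignore_attr = TRUE)
    expect_equal(res$df, 1)
  }
  # homogeneous table
  h <- chisq_2x2(matrix(10, 2, 2))
  expect_equal(h$statistic, 0)
  expect_equal(h$p_value, 1)
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("chance-level binomial test behaves at, above and far above chance", {
  at_chance <- chance_test(75, 225)
  expect_gt(at_chance$p_greater, 0.5)
  above <- chance_test(91, 225)
  expect_equal(above$p_greater, 0.0151, tolerance = 0.01)
  expect_lt(above$p_greater, 0.05)
  certain <- chance_test(225, 225)
  expect_lt(certain$p_greater, 1e-100)
})

test_that("Mann-Whitney: exact enumeration case, identity case, and monotone shift", {
  res <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1) # 2 / choose(6, 3)
  expect_equal(res$method, "exact")

  same <- mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p_value, 0.95)

  p_shift <- vapply(c(0, 5, 10), function(d) {
    mann_whitney(rnorm(30, 0, 1e-9) + seq(0, 1, length.out = 30),
                 seq(0, 1, length.out = 30) + d)$p_value
  }, 0)
  expect_true(all(diff(p_shift) <= 0))
})

test_that("Spearman correlation: hand-ranked example and antisymmetry", {
  res <- spearman_cor(1:5, c(1, 3, 2, 5, 4))
  expect_equal(res$rho, 0.8) # sum d^2 = 4 -> 1 - 6*4/(5*24)
  mono <- spearman_cor(1:10, exp(1:10))
  expect_equal(mono$rho, 1)
  anti <- spearman_cor(10:1, exp(1:10))
  expect_equal(anti$rho, -1)
  expect_error(spearman_cor(rep(1, 6), 1:6), "zero variance")
})

test_that("ownership accuracy gap of 0.2 is detected with high power; null gap at alpha", {
  gap_spec <- function(owner_acc, seed) cohort_spec(
    n_participants = 225,
    accuracy_by_group_context = list(
      owner = c(waiting_for_food = owner_acc, isolation = owner_acc,
                brushing = owner_acc),
      nonowner = c(waiting_for_food = owner_acc - 0.2,
                   isolation = owner_acc - 0.2, brushing = owner_acc - 0.2)
    ),
    seed = seed
  )
  reject <- function(spec) {
    co <- synth_cohort(spec)
    at <- accuracy_table(co$responses, "isolation", "medioid",
                        co$participants, group_by = "cat_owner")
    chisq_2x2(as.matrix(at[order(at$group), c("correct", "incorrect")]))$p_value < 0.05
  }
  power <- mean(vapply(1:200, function(s) reject(gap_spec(0.45, 3000 + s)), NA))
  expect_gte(power, 0.8)

  null_spec <- function(seed) cohort_spec(
    n_participants = 225,
    accuracy_by_group_context = list(
      owner = c(waiting_for_food = 0.35, isolation = 0.35, brushing = 0.35),
      nonowner = c(waiting_for_food = 0.35, isolation = 0.35, brushing = 0.35)
    ),
    seed = seed
  )
  size <- mean(vapply(1:200, function(s) reject(null_spec(6000 + s)), NA))
  se3 <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(size - 0.05), se3 + 1e-9)
})

test_that("the full survey battery runs and its pieces are mutually consistent", {
  co <- synth_cohort(cohort_spec(n_participants = 60, seed = 12))
  rep <- survey_report(co$responses, co$participants)
  expect_true(all(c("accuracy", "chance_tests", "scales", "cronbach_alpha_aes") %in%
                    names(rep)))
  # accuracy entries agree with direct accuracy_table calls
  at <- accuracy_table(co$responses, "brushing", "medioid")
  expect_equal(rep$accuracy$brushing$medioid$correct, at$correct)
  # scored totals respect scale bounds
  expect_true(all(co$participants$aes_total >= 22 & co$participants$aes_total <= 198))
  expect_true(all(co$participants$ces_total >= 3 & co$participants$ces_total <= 27))
  # n_correct_medioids is 0..3
  nc <- n_correct_medioids(co$responses)
  expect_true(all(nc$n_correct_medioids %in% 0:3))
})
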