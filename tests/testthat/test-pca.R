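desc_names <- c("agitated_anxious", "aggressive_angry", "frustrated",
                "restless_nervous", "frightened", "suffering", "friendly",
                "calm_relaxed", "happy", "curious", "playful")
desc_signs <- c(-1, -1, -1, -1, -1, -1, 1, 1, 1, 1, 1)

# build a responses-shaped data.frame directly from a latent valence vector
latent_responses <- function(latent, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n <- length(latent)
  x <- 4 + outer(3 * latent, desc_signs) +
    matrix(rnorm(n * 11, 0, noise_sd), nrow = n)
  df <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    context = rep(c("waiting_for_food", "isolation", "brushing"), length.out = n),
    variant = "medioid", correct = TRUE
  )
  colnames(x) <- desc_names
  cbind(df, as.data.frame(x))
}

test_that("rank-1 data put 100 percent of variance on PC1 and percentages sum to 100", {
  resp <- latent_responses(seq(-1, 1, length.out = 30), noise_sd = 0)
  res <- pca_descriptors(resp, subset = "all", mode = "covariance")
  expect_equal(res$explained_variance_pct[1], 100, tolerance = 1e-9)
  expect_equal(sum(res$explained_variance_pct), 100, tolerance = 1e-9)
})

test_that("centered-scaled data are reconstructed from scores and loadings", {
  co <- synth_cohort(cohort_spec(n_participants = 30, seed = 4))
  res <- pca_descriptors(co$responses, subset = "all", mode = "correlation")
  x <- as.matrix(co$responses[, desc_names])
  xs <- scale(x)
  recon <- res$scores %*% t(res$loadings)
  expect_lt(max(abs(recon - xs)), 1e-8)
  # loadings are orthonormal
  expect_equal(t(res$loadings) %*% res$loadings, diag(11),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("sign convention anchors calm_relaxed non-positive on PC1, also for flipped data", {
  resp <- latent_responses(rnorm(60), noise_sd = 0.5, seed = 2)
  res <- pca_descriptors(resp, subset = "all")
  expect_lte(res$loadings["calm_relaxed", 1], 0)

  flipped <- resp
  flipped[desc_names] <- 8 - resp[desc_names] # mirror the 1..7 scale
  res_f <- pca_descriptors(flipped, subset = "all")
  expect_lte(res_f$loadings["calm_relaxed", 1], 0)
  # identical descriptor partition after re-orientation
  expect_equal(sign(res$loadings[, 1]), sign(res_f$loadings[, 1]))
})

test_that("correct_only subset uses exactly the correctly assigned rows", {
  co <- synth_cohort(cohort_spec(n_participants = 50, seed = 6))
  res <- pca_descriptors(co$responses, subset = "correct_only")
  expect_equal(nrow(res$scores), sum(co$responses$correct))
  expect_true(all(res$metadata$correct))
})

test_that("planted context valences are recovered on PC1 with the expected ordering", {
  co <- synth_cohort(cohort_spec(n_participants = 225, seed = 9))
  res <- pca_descriptors(co$responses, subset = "all")
  latent <- c(waiting_for_food = 0.3, isolation = -0.8,
              brushing = 0.8)[res$metadata$context]
  expect_gt(abs(cor(res$scores[, 1], latent)), 0.9)

  vs <- valence_summary(res)
  m <- setNames(vs$context_summary$pc1_mean, vs$context_summary$context)
  # positive valence sits on the negative PC1 side by convention
  expect_lt(m[["brushing"]], m[["waiting_for_food"]])
  expect_lt(m[["waiting_for_food"]], m[["isolation"]])

  # descriptor partition by PC1 loading sign matches the planted signs
  lt <- vs$loading_table
  expect_true(all(lt$valence_side[match(desc_names, lt$descriptor)] ==
                    ifelse(desc_signs > 0, "positive", "negative")))
})

test_that("degenerate inputs are rejected", {
  resp <- latent_responses(rnorm(20), noise_sd = 0.5)
  expect_error(pca_descriptors(resp[1:5, ], subset = "all"), "at least")
  const <- resp
  const$happy <- 4
  expect_error(pca_descriptors(const, subset = "all", mode = "correlation"),
               "constant")
})
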