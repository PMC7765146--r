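test_that("ANOVA screen reproduces a hand-computed two-class F test", {
  # classes {0,1} and {10,11}: between-SS 100, within-SS 1, df 1 and 2 -> F = 200
  df <- data.frame(
    clip_id = c("a", "b", "c", "d"),
    context = c("x", "x", "y", "y"),
    v = c(0, 1, 10, 11)
  )
  screen <- anova_screen(df, feature_cols = "v")
  expect_equal(screen$statistic, 200, tolerance = 1e-10)
  expect_equal(screen$p_value, pf(200, 1, 2, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(screen$kept)
})

test_that("well-separated class means are kept, degenerate columns dropped with warning", {
  set.seed(1)
  df <- data.frame(
    clip_id = sprintf("c%02d", 1:30),
    context = rep(c("a", "b", "c"), each = 10),
    sep = rep(c(0, 5, 10), each = 10) + rnorm(30, 0, 0.1),
    flat = rep(1, 30)
  )
  expect_warning(screen <- anova_screen(df, feature_cols = c("sep", "flat")),
                 "degenerate")
  expect_true(screen$kept[screen$feature == "sep"])
  expect_lt(screen$p_value[screen$feature == "sep"], 1e-10)
  expect_false(screen$kept[screen$feature == "flat"])
})

test_that("raising alpha never shrinks the kept set", {
  df <- make_feature_table(8, effect_cols = c("f0_mean", "r_mean"),
                           effect_size = 0.8, seed = 4)
  kept_sets <- lapply(c(0.01, 0.05, 0.2, 1), function(a) {
    s <- anova_screen(df, alpha = a)
    s$feature[s$kept]
  })
  for (i in 1:3) expect_true(all(kept_sets[[i]] %in% kept_sets[[i + 1]]))
  # alpha = 1 keeps everything with non-degenerate variance
  expect_equal(length(kept_sets[[4]]), 10)
})

test_that("class centroids are arithmetic means with expected invariances", {
  x <- matrix(c(0, 0, 2, 2), nrow = 2, byrow = TRUE)
  expect_equal(unname(class_centroids(x, c("a", "a"))["a", ]), c(1, 1))
  # singleton class: centroid is the point
  x2 <- rbind(x, c(5, 7))
  cen <- class_centroids(x2, c("a", "a", "b"))
  expect_equal(unname(cen["b", ]), c(5, 7))
  # duplicating every point leaves centroids unchanged
  cen_dup <- class_centroids(rbind(x2, x2), rep(c("a", "a", "b"), 2))
  expect_equal(cen, cen_dup)
})

test_that("medioid/outlier selection matches hand computation and tie rule", {
  # 1-D class {0, 1, 10}: centroid 11/3; medioid 1 (d = 2.67), outlier 10 (d = 6.33)
  x <- matrix(c(0, 1, 10), ncol = 1)
  sel <- select_exemplars(x, rep("ctx", 3), c("p0", "p1", "p10"))
  expect_equal(sel$clip_id[sel$role == "medioid"], "p1")
  expect_equal(sel$clip_id[sel$role == "outlier"], "p10")
  expect_equal(sel$distance[sel$role == "medioid"], 11 / 3 - 1, tolerance = 1e-12)
  expect_equal(sel$distance[sel$role == "outlier"], 10 - 11 / 3, tolerance = 1e-12)
  expect_lte(sel$distance[sel$role == "medioid"], sel$distance[sel$role == "outlier"])

  # two equidistant points: the lower clip_id wins both roles deterministically
  x_tie <- matrix(c(-1, 1), ncol = 1)
  sel_tie <- select_exemplars(x_tie, c("c", "c"), c("b2", "a1"))
  expect_equal(sel_tie$clip_id, c("a1", "a1"))

  expect_error(select_exemplars(matrix(1), "c", "only"), "fewer than 2")
})

test_that("selection equals the exhaustive-search oracle on 100 random datasets", {
  for (s in 1:100) {
    set.seed(s)
    n_feat <- sample(2:10, 1)
    labels <- rep(c("a", "b", "c"), times = sample(2:50, 3, replace = TRUE))
    x <- matrix(rnorm(length(labels) * n_feat), ncol = n_feat)
    ids <- sprintf("id%03d", sample(seq_along(labels)))
    sel <- select_exemplars(x, labels, ids)
    ora <- exemplar_oracle(x, labels, ids)
    merged <- merge(as.data.frame(sel)[, c("context", "role", "clip_id")], ora,
                    by = c("context", "role"), suffixes = c("_sel", "_ora"))
    expect_equal(merged$clip_id_sel, merged$clip_id_ora)
  }
})

test_that("input order only matters through the documented tie rule", {
  df <- make_feature_table(6, effect_cols = "f0_mean", seed = 9)
  sel1 <- screen_and_select(df)
  set.seed(11)
  perm <- df[sample(nrow(df)), ]
  sel2 <- screen_and_select(perm)
  o1 <- sel1$exemplars[order(sel1$exemplars$context, sel1$exemplars$role), ]
  o2 <- sel2$exemplars[order(sel2$exemplars$context, sel2$exemplars$role), ]
  expect_equal(o1$clip_id, o2$clip_id)
  expect_equal(o1$distance, o2$distance, tolerance = 1e-12)
})
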