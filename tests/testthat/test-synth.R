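test_that("degenerate spec yields a pure sine and synthesis is deterministic", {
  spec <- meow_spec(f0_start = 440, f0_end = 440, n_harmonics = 1,
                    am_depth = 0, noise_snr = Inf, duration = 1, seed = 1)
  clip <- synth_meow(spec)
  expect_s3_class(clip, "audio_clip")
  expect_equal(clip$sample_rate, 8000)
  # a pure 440 Hz sine, peak-normalized to 0.9
  t <- (0:7999) / 8000
  ref <- sin(2 * pi * 440 * t)
  ref <- ref / max(abs(ref)) * 0.9
  expect_lt(max(abs(clip$samples - ref)), 1e-9)

  # determinism: same spec + seed twice -> bit-identical samples
  spec2 <- meow_spec(f0_start = 300, f0_end = 500, am_depth = 0.4,
                     noise_snr = 15, seed = 99)
  expect_identical(synth_meow(spec2)$samples, synth_meow(spec2)$samples)
})

test_that("no synthesized sample exceeds full scale", {
  for (s in 1:5) {
    clip <- synth_meow(meow_spec(f0_start = 200 + 100 * s, f0_end = 900 - 80 * s,
                                 am_depth = s / 5, noise_snr = 10, seed = s))
    expect_lt(max(abs(clip$samples)), 1)
  }
})

test_that("rising-contour spec produces a nondecreasing median-filtered pitch track", {
  clip <- synth_meow(meow_spec(f0_start = 300, f0_end = 600, noise_snr = Inf,
                               am_depth = 0, seed = 2))
  p <- estimate_pitch(clip)
  smoothed <- stats::runmed(p$f0, 5)
  expect_false(is.unsorted(smoothed))
})

test_that("meow_spec rejects invalid parameters", {
  expect_error(meow_spec(f0_start = 30), "50")
  expect_error(meow_spec(f0_end = 2500), "50")
  expect_error(meow_spec(am_depth = 1.5), "am_depth")
  expect_error(meow_spec(duration = 0.05), "duration")
})

test_that("synth_corpus emits exactly n_per_class labeled clips per context", {
  corpus <- synth_corpus(n_per_class = 3, seed = 5)
  expect_equal(nrow(corpus$labels), 9)
  expect_equal(as.integer(table(corpus$labels$context)), rep(3L, 3))
  expect_setequal(names(corpus$clips), corpus$labels$clip_id)
  expect_error(synth_corpus(n_per_class = 1), ">= 2")

  # reproducibility of the whole corpus
  corpus2 <- synth_corpus(n_per_class = 3, seed = 5)
  expect_identical(corpus$clips, corpus2$clips)
})

test_that("cohort generation respects ranges, boundaries and determinism", {
  spec <- cohort_spec(n_participants = 40, seed = 3)
  co <- synth_cohort(spec)
  expect_identical(co, synth_cohort(spec))
  expect_equal(nrow(co$participants), 40)
  expect_equal(nrow(co$responses), 40 * 6)

  aes_mat <- as.matrix(co$participants[, sprintf("aes_%02d", 1:22)])
  ces_mat <- as.matrix(co$participants[, sprintf("ces_%02d", 1:3)])
  desc_mat <- as.matrix(co$responses[, c("agitated_anxious", "aggressive_angry",
                                         "frustrated", "restless_nervous",
                                         "frightened", "suffering", "friendly",
                                         "calm_relaxed", "happy", "curious",
                                         "playful")])
  expect_true(all(aes_mat %in% 1:9))
  expect_true(all(ces_mat %in% 1:9))
  expect_true(all(desc_mat %in% 1:7))

  # perfect accuracy boundary: every context answer correct
  perfect <- cohort_spec(
    n_participants = 15,
    accuracy_by_group_context = list(
      owner = c(waiting_for_food = 1, isolation = 1, brushing = 1),
      nonowner = c(waiting_for_food = 1, isolation = 1, brushing = 1)
    ),
    outlier_accuracy_ratio = 1, seed = 7
  )
  co_p <- synth_cohort(perfect)
  expect_true(all(co_p$responses$correct))
  expect_true(all(co_p$responses$chosen_context == co_p$responses$context))
})

test_that("cohort wrong answers fall uniformly on the two wrong contexts", {
  zero <- cohort_spec(
    n_participants = 300,
    accuracy_by_group_context = list(
      owner = c(waiting_for_food = 0, isolation = 0, brushing = 0),
      nonowner = c(waiting_for_food = 0, isolation = 0, brushing = 0)
    ),
    outlier_accuracy_ratio = 1, seed = 21
  )
  co <- synth_cohort(zero)
  expect_false(any(co$responses$correct))
  # for each true context the two wrong choices should be ~50/50
  for (ctx in unique(co$responses$context)) {
    picks <- table(co$responses$chosen_context[co$responses$context == ctx])
    expect_equal(length(picks), 2)
    expect_gt(min(picks) / sum(picks), 0.4)
  }
})
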