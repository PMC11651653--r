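# Build outcomes whose per-level d-prime crosses the 1.5 anchor mid-range.
make_psych_outcomes <- function(hit_counts, n_per_level = 20, n_catch = 40,
                                n_fa = 4, levels = seq(35, 75, by = 5)) {
  stopifnot(length(hit_counts) == length(levels))
  outcome <- character(0); level <- numeric(0)
  for (i in seq_along(levels)) {
    outcome <- c(outcome, rep(c("hit", "miss"),
                              c(hit_counts[i], n_per_level - hit_counts[i])))
    level <- c(level, rep(levels[i], n_per_level))
  }
  outcome <- c(outcome, rep(c("false_alarm", "correct_rejection"),
                            c(n_fa, n_catch - n_fa)))
  level <- c(level, rep(NA, n_catch))
  make_manual_outcomes(outcome, level)
}

test_that("trial selection keeps the anchor level plus two below and above", {
  hit_counts <- c(2, 3, 5, 8, 11, 14, 17, 19, 20)  # monotone psychometric
  oc <- make_psych_outcomes(hit_counts)
  sel <- select_trials(oc)
  ld <- sel$dprime_table
  anchor_rank <- which(ld$dprime > 1.5)[1]
  expect_equal(sel$anchor_level, ld$level_db[anchor_rank])
  expect_equal(length(sel$levels), 5)
  expect_equal(sel$levels, ld$level_db[(anchor_rank - 2):(anchor_rank + 2)])
  expect_true(all(oc$level_db[sel$trial_idx] %in% sel$levels))
  expect_false(any(oc$is_catch[sel$trial_idx]))
  # anchor at the lowest rank: truncated 3-level window, with a warning
  oc_easy <- make_psych_outcomes(c(18, 19, 19, 20, 20, 20, 20, 20, 20))
  expect_warning(sel2 <- select_trials(oc_easy), "3 levels")
  expect_equal(length(sel2$levels), 3)
  # no level exceeds threshold: session excluded
  oc_bad <- make_psych_outcomes(c(2, 2, 3, 3, 3, 4, 4, 4, 5))
  expect_error(select_trials(oc_bad), "excluded")
})

test_that("session gate requires 15 instances of each class", {
  expect_true(session_gate(rep(c("hit", "miss"), c(15, 15))))
  expect_false(session_gate(rep(c("hit", "miss"), c(40, 14))))
  expect_false(session_gate(rep(c("hit", "miss"), c(14, 40))))
})

test_that("class weights follow the inverse-frequency formula and conserve mass", {
  cw <- class_weights(rep(c("hit", "miss"), c(80, 20)))
  expect_equal(unname(cw$class_weights["hit"]), 0.625)
  expect_equal(unname(cw$class_weights["miss"]), 2.5)
  balanced <- class_weights(rep(c("hit", "miss"), 25))
  expect_equal(unname(balanced$class_weights), c(1, 1))
  # conservation identity for arbitrary label vectors
  withr::with_seed(2, {
    for (i in 1:20) {
      y <- sample(c("hit", "miss"), 5 + rpois(1, 40), replace = TRUE)
      if (length(unique(y)) < 2) next
      cw <- class_weights(y)
      expect_equal(sum(cw$trial_weights), length(y))
    }
  })
  expect_error(class_weights(rep("hit", 10)), "both classes")
})

test_that("balanced accuracy equals the mean of per-class recalls", {
  expect_equal(balanced_accuracy(10, 0, 5, 0), 1)
  expect_equal(balanced_accuracy(8, 2, 3, 1), 0.775)
  # majority-only predictor on imbalanced data sits at chance
  expect_equal(balanced_accuracy(90, 0, 0, 10), 0.5)
  withr::with_seed(5, {
    for (i in 1:50) {
      cnt <- rpois(4, 10) + c(1, 0, 1, 0)
      got <- balanced_accuracy(cnt[1], cnt[2], cnt[3], cnt[4])
      recalls <- c(cnt[1] / (cnt[1] + cnt[2]), cnt[3] / (cnt[3] + cnt[4]))
      expect_equal(got, mean(recalls))
    }
  })
  expect_error(balanced_accuracy(0, 0, 5, 5), "each class")
})

test_that("frame decoder is deterministic and learns a planted signal", {
  pl <- make_planted_frame(effect = 5, noise_sd = 0.5, seed = 12)
  a <- fit_frame_decoder(pl$X, pl$y, seed = 4, n_draws = 8)
  b <- fit_frame_decoder(pl$X, pl$y, seed = 4, n_draws = 8)
  expect_identical(a, b)
  expect_gte(a$mean_score, 0.95)
  expect_equal(length(a$fold_scores), 5)
})

test_that("dummy decoder is seeded and centred at chance", {
  y <- rep(c("hit", "miss"), c(70, 30))
  d1 <- dummy_decoder(y, seed = 5, n_repeats = 200)
  d2 <- dummy_decoder(y, seed = 5, n_repeats = 200)
  expect_identical(d1, d2)
  big <- dummy_decoder(y, seed = 6, n_repeats = 3000)
  expect_equal(big$mean_score, 0.5, tolerance = 0.01)
  expect_error(dummy_decoder(rep("hit", 10), seed = 1), "both classes")
})

test_that("timecourse interpolation preserves endpoints and linearity", {
  x <- seq(0, 1, length.out = 197)
  y <- interpolate_timecourse(x, 193)
  expect_equal(length(y), 193)
  expect_equal(y[c(1, 193)], c(0, 1))
  expect_equal(y, seq(0, 1, length.out = 193))
  cst <- interpolate_timecourse(rep(0.7, 197), 193)
  expect_true(all(cst == 0.7))
  expect_identical(interpolate_timecourse(x, 197), x)
  expect_error(interpolate_timecourse(x, 1), "length")
})

test_that("ROI-count correlation flags constants and tracks monotone trends", {
  ft <- seq(-2, 5, length.out = 50)
  acc <- matrix(0.6, 6, 50)
  n_rois <- c(10, 20, 30, 40, 50, 60)
  res <- roi_count_correlation(n_rois, acc, ft)
  expect_true(all(res$flagged))
  acc2 <- outer(seq(0.5, 0.75, length.out = 6), rep(1, 50))
  res2 <- roi_count_correlation(n_rois, acc2, ft)
  expect_true(all(res2$rho == 1))
  expect_error(roi_count_correlation(n_rois[1:3], acc[1:3, ], ft), "4 sessions")
})

test_that("session decoding separates planted post-stimulus coding from baseline", {
  ses <- make_small_session(n_trials = 90, n_neurons = 12, noise_sd = 0.02,
                            seed = 71)
  oc <- ses$outcomes
  pre_frame <- 20   # ~ -1.3 s
  post_frame <- 70  # ~ +0.5 s
  dec <- decode_session(ses$tensor, oc, seed = 3,
                        frames = c(pre_frame, post_frame),
                        n_draws = 6, dummy_repeats = 50, min_each = 10)
  expect_gte(dec$trained[2], dec$dummy[2] + 0.2)  # post-stimulus coding
  expect_equal(dec$frame_time[2], (70 - 57) / 28)
  # zero-variance activity decodes at baseline
  flat <- make_manual_tensor(array(0, dim = c(40, 4, 196)))
  oc_f <- make_manual_outcomes(rep(c("hit", "miss"), 20), rep(60, 40))
  dec_f <- decode_session(flat, oc_f, seed = 2, frames = c(10, 100),
                          n_draws = 4, dummy_repeats = 50, min_each = 10)
  expect_true(all(abs(dec_f$trained - 0.5) < 0.12))
})

test_that("neuron-subsampling control matches the full model at full size", {
  ses <- make_small_session(n_trials = 90, n_neurons = 6, noise_sd = 0.05,
                            seed = 81)
  full <- decode_session(ses$tensor, ses$outcomes, seed = 5, frames = c(80),
                         dummy_repeats = 20, min_each = 10)
  sub <- subsample_neurons_control(ses$tensor, ses$outcomes, target_n = 6,
                                   n_draws = 2, seed = 5, frames = c(80),
                                   dummy_repeats = 20, min_each = 10)
  expect_equal(sub$trained, full$trained)
  expect_error(subsample_neurons_control(ses$tensor, ses$outcomes,
                                         target_n = 1, seed = 1), "target_n")
})

test_that("level-matched control keeps balanced sets and skips failed gates", {
  oc <- make_manual_outcomes(rep(c("hit", "miss"), 20), rep(60, 40))
  vals <- array(rnorm(40 * 3 * 196, sd = 0.1), dim = c(40, 3, 196))
  tens <- make_manual_tensor(vals)
  ctrl <- level_matched_control(tens, oc, seed = 9, frames = c(100),
                                n_draws = 4, dummy_repeats = 20, min_each = 10)
  expect_equal(ctrl$n_hit, 20)
  expect_equal(ctrl$n_miss, 20)
  # fully confounded level/outcome: everything drops, gate fails
  oc_conf <- make_manual_outcomes(rep(c("hit", "miss"), c(20, 20)),
                                  rep(c(50, 70), c(20, 20)))
  expect_message(out <- level_matched_control(tens, oc_conf, seed = 9,
                                              min_each = 10),
                 "skipped")
  expect_null(out)
})
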