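test_that("neuropil correction is the stated linear rule", {
  F_mat <- matrix(10, 2, 5)
  Fneu <- matrix(10, 2, 5)
  expect_equal(neuropil_correct(F_mat, Fneu, r = 0.7), matrix(3, 2, 5))
  expect_equal(neuropil_correct(F_mat, matrix(0, 2, 5)), F_mat)
  expect_equal(neuropil_correct(F_mat, Fneu, r = 0), F_mat)
  expect_error(neuropil_correct(F_mat, matrix(0, 2, 4)), "shape")
})

test_that("dF/F uses the whole-trace median and is scale invariant", {
  x <- matrix(c(1, 1, 1, 3), 1, 4)
  expect_equal(as.numeric(compute_dff(x)), c(0, 0, 0, 2))
  const <- matrix(5, 2, 10)
  expect_true(all(compute_dff(const) == 0))
  y <- matrix(rexp(40) + 0.5, 4, 10)
  expect_equal(as.numeric(compute_dff(y)), as.numeric(compute_dff(7 * y)))
  # non-positive median ROIs are excluded with a warning
  bad <- rbind(y[1, ], rep(-1, 10))
  expect_warning(d <- compute_dff(bad), "excluded")
  expect_equal(nrow(d), 1)
  expect_equal(attr(d, "excluded"), 2L)
})

test_that("slow-baseline removal keeps fast transients and kills slow drift", {
  fs <- 28
  n <- 300 * fs
  tt <- (seq_len(n) - 1) / fs
  slow <- 0.5 * sin(2 * pi * tt / 240)
  transient <- ifelse(tt >= 150 & tt < 150.5, 1, 0)
  x <- matrix(slow + transient, 1, n)
  out <- remove_slow_baseline(x, frame_rate = fs)
  # transient amplitude preserved within 10 %
  peak <- max(out[1, tt >= 149 & tt <= 152])
  expect_gt(peak, 0.9)
  expect_lt(abs(peak - 1), 0.12)
  # slow component attenuated by > 80 % (RMS away from the transient)
  away <- tt < 140 | tt > 165
  expect_lt(sqrt(mean(out[1, away]^2)), 0.2 * sqrt(mean(slow[away]^2)))
  # constant trace maps to zero
  cst <- matrix(2, 1, 3000)
  expect_equal(max(abs(remove_slow_baseline(cst, frame_rate = fs))), 0)
  expect_error(remove_slow_baseline(matrix(1, 1, 10), frame_rate = fs),
               "longer than the recording")
  expect_error(remove_slow_baseline(matrix(numeric(0), 1, 0), frame_rate = fs),
               "zero-length")
})

test_that("trial extraction aligns, counts frames, and drops boundary trials", {
  fs <- 28
  n <- 60 * fs
  dff <- matrix(rnorm(2 * n), 2, n)
  sched <- make_manual_schedule(onsets = c(0.5, 10, 20, 58),
                                is_catch = rep(FALSE, 4),
                                level_db = rep(60, 4))
  expect_message(tens <- extract_trials(dff, sched, frame_rate = fs),
                 "dropped 2")
  expect_equal(dim(tens$values), c(2, 2, 196))  # 7 s at 28 Hz
  expect_equal(tens$kept_trials, c(2, 3))
  # conservation: kept + dropped = all scheduled trials
  expect_equal(sort(c(tens$kept_trials, tens$dropped)), 1:4)
  # identical traces across trials give identical slices
  per <- matrix(rep(sin(seq_len(fs * 10) / 5), 6), 1, byrow = TRUE)
  sch2 <- make_manual_schedule(onsets = c(10, 20, 30), rep(FALSE, 3),
                               rep(60, 3))
  t2 <- extract_trials(per, sch2, frame_rate = fs)
  expect_equal(t2$values[1, 1, ], t2$values[2, 1, ])
  expect_error(extract_trials(dff, sched, frame_rate = NULL), "frame_rate")
})

test_that("lick-contaminated hits are excluded per the stated window", {
  oc <- make_manual_outcomes(c("hit", "hit", "hit", "miss"),
                             rep(60, 4), onset_s = c(20, 40, 60, 80))
  # licks at -0.1 s (contaminated), +0.3 s (fine), and one near the miss
  licks <- c(19.9, 40.3, 79.9)
  keep <- exclude_lick_contaminated_hits(oc, licks)
  expect_equal(keep, c(2, 3, 4))  # miss unaffected even with a nearby lick
  expect_equal(exclude_lick_contaminated_hits(oc, numeric(0)), 1:4)
})

test_that("outcome averages resample to a common length with endpoints preserved", {
  vals <- array(0, dim = c(4, 2, 197))
  ramp <- seq(0, 1, length.out = 197)
  for (i in 1:4) for (j in 1:2) vals[i, j, ] <- ramp
  tens <- make_manual_tensor(vals)
  oc <- make_manual_outcomes(c("hit", "hit", "miss", "miss"), rep(60, 4))
  av <- outcome_averages(tens, oc, L = 193)
  expect_equal(dim(av$hit), c(2, 193))
  expect_equal(av$hit[1, 1], 0)
  expect_equal(av$hit[1, 193], 1)
  # length-193 input resampling is the identity
  expect_equal(resample_linear(ramp[1:193], 193), ramp[1:193])
  # constant traces stay constant
  vals[] <- 2
  av2 <- outcome_averages(make_manual_tensor(vals), oc, L = 193)
  expect_true(all(av2$miss == 2))
  # a session lacking misses cannot provide averages
  oc_all_hit <- make_manual_outcomes(rep("hit", 4), rep(60, 4))
  expect_error(outcome_averages(tens, oc_all_hit), "lacks")
})

test_that("z-motion PC check flags planted score-locked structure only", {
  withr::with_seed(8, {
    n <- 120
    pattern <- c(rep(1, 10), rep(0, 30))
    s <- rnorm(n, sd = 3)
    stack <- outer(s, pattern) + matrix(rnorm(n * 40, sd = 0.05), n, 40)
    res <- zmotion_pc_check(stack, n_extreme = 20, n_pcs = 3)
    expect_gt(res$scores[1], 10 * res$scores[2])
    # identical frames give zero differences
    flat <- matrix(1, 80, 40) + 0
    res0 <- zmotion_pc_check(flat + matrix(rnorm(80 * 40, sd = 1e-9), 80, 40),
                             n_extreme = 10, n_pcs = 2)
    expect_lt(max(res0$scores), 1e-8)
    expect_error(zmotion_pc_check(stack, n_extreme = 60), "n_extreme")
  })
})

test_that("lick-triggered movie recovers a planted lick-locked bump", {
  fs <- 10
  n <- 1200
  stack <- matrix(rnorm(n * 25, sd = 0.1), n, 25)
  lick_times <- seq(20, 100, by = 10)
  for (tm in lick_times) {
    idx <- as.integer(round(tm * fs)) + 1L
    stack[idx, ] <- stack[idx, ] + 2
  }
  res <- lick_triggered_movie(stack, lick_times, frame_rate = fs)
  lag0 <- which(res$time_s == 0)
  expect_equal(mean(res$movie[lag0, ]), 2, tolerance = 0.15)
  expect_lt(max(abs(rowMeans(res$movie)[-lag0])), 0.3)
  # a single lick reproduces the raw clip
  one <- lick_triggered_movie(stack, lick_times[1], frame_rate = fs)
  idx <- as.integer(round(lick_times[1] * fs)) + 1L
  expect_equal(one$movie, stack[(idx - 20):(idx + 20), ])
  expect_error(lick_triggered_movie(stack, 0.5, frame_rate = fs), "no lick")
})
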