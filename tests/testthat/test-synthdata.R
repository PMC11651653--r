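test_that("schedule sampler respects the ITI floor and truncated-normal mean", {
  sp <- schedule_params(n_trials = 30000)
  sched <- sample_schedule(sp, seed = 101)
  itis <- c(sched$onset_s[1], diff(sched$onset_s))
  expect_true(all(itis >= 3))
  # quadrature mean of a normal(8, 2) truncated below at 3 (frozen oracle)
  expect_equal(mean(itis), 8.035276, tolerance = 0.05 / 8.035276)
  expect_equal(mean(sched$is_catch), 0.1, tolerance = 0.1)
  expect_true(all(!is.na(sched$level_db[!sched$is_catch])))
  expect_true(all(is.na(sched$level_db[sched$is_catch])))
})

test_that("zero-variance ITIs give exactly equal gaps and invalid params error", {
  sp <- schedule_params(iti_sd = 0, n_trials = 5)
  sched <- sample_schedule(sp, seed = 1)
  expect_equal(diff(sched$onset_s), rep(8, 4))
  expect_error(schedule_params(n_trials = 0), "n_trials")
  expect_error(schedule_params(iti_floor = -1), "iti_floor")
  expect_error(schedule_params(catch_fraction = 1), "catch_fraction")
})

test_that("schedule and behaviour sampling are seed-deterministic", {
  sp <- schedule_params(n_trials = 50)
  s1 <- sample_schedule(sp, seed = 7)
  s2 <- sample_schedule(sp, seed = 7)
  expect_identical(s1, s2)
  pm <- psych_model()
  l1 <- sample_behavior(s1, pm, seed = 9)
  l2 <- sample_behavior(s2, pm, seed = 9)
  expect_identical(l1, l2)
})

test_that("saturated and degenerate psychometric regimes behave as stated", {
  sp <- schedule_params(n_trials = 80, sound_levels = c(80))
  sched <- sample_schedule(sp, seed = 3)
  # slope -> Inf, no lapse, level far above midpoint: every stimulus trial hit
  pm <- psych_model(midpoint = 40, slope = Inf, lapse_rate = 0,
                    false_alarm_rate = 0)
  licks <- sample_behavior(sched, pm, seed = 4, spont_rate = 0)
  oc <- score_trials(sched, licks)
  expect_true(all(oc$outcome[!oc$is_catch] == "hit"))
  # false_alarm_rate = 0: no licks in any catch response window, even with
  # spontaneous licking enabled
  pm2 <- psych_model(false_alarm_rate = 0)
  licks2 <- sample_behavior(sched, pm2, seed = 5, spont_rate = 2)
  oc2 <- score_trials(sched, licks2)
  expect_true(all(oc2$outcome[oc2$is_catch] == "correct_rejection"))
})

test_that("empirical hit rates track the generating sigmoid and recover the midpoint", {
  levels <- seq(41, 71, by = 5)
  sp <- schedule_params(n_trials = 1800, sound_levels = levels,
                        catch_fraction = 0.1)
  sched <- sample_schedule(sp, seed = 21)
  pm <- psych_model(midpoint = 56, slope = 0.3, lapse_rate = 0.02,
                    false_alarm_rate = 0.1)
  licks <- sample_behavior(sched, pm, seed = 22, spont_rate = 0)
  oc <- score_trials(sched, licks)
  stim <- oc[!oc$is_catch, ]
  emp <- vapply(levels, function(lv) {
    mean(stim$outcome[stim$level_db == lv] == "hit")
  }, numeric(1))
  pred <- pm$false_alarm_rate +
    (1 - pm$false_alarm_rate - pm$lapse_rate) *
    plogis(pm$slope * (levels - pm$midpoint))
  n_per <- vapply(levels, function(lv) sum(stim$level_db == lv), numeric(1))
  # each empirical rate within a ~3 SE binomial envelope of the sigmoid
  expect_true(all(abs(emp - pred) < 3 * sqrt(pred * (1 - pred) / n_per) + 0.02))
  # midpoint recovery: level where the empirical curve crosses half-height
  half <- pm$false_alarm_rate + (1 - pm$false_alarm_rate - pm$lapse_rate) / 2
  est_mid <- approx(emp, levels, xout = half, ties = mean)$y
  expect_lt(abs(est_mid - pm$midpoint), 2)
})

test_that("session synthesis is deterministic and degenerates to a constant trace", {
  sp <- schedule_params(n_trials = 10)
  sched <- sample_schedule(sp, seed = 1)
  licks <- sample_behavior(sched, psych_model(), seed = 2, spont_rate = 0)
  flat <- list(neuron_prototype(1L, function(t) rep(0, length(t)),
                                function(t) rep(0, length(t))))
  syn <- synthesize_session(sched, licks, flat, n_neurons = 1, noise_sd = 0,
                            neuropil_gain = 0,
                            drift = list(amplitude = 0, period_s = 300),
                            seed = 5)
  expect_equal(diff(range(syn$session$F)), 0)
  a <- synthesize_session(sched, licks, default_prototypes(), n_neurons = 4,
                          seed = 8)
  b <- synthesize_session(sched, licks, default_prototypes(), n_neurons = 4,
                          seed = 8)
  expect_identical(a$session$F, b$session$F)
  expect_identical(a$ground_truth$cluster_id, b$ground_truth$cluster_id)
  expect_error(synthesize_session(sched, licks, list(), n_neurons = 2, seed = 1),
               "prototype")
  expect_error(synthesize_session(sched, licks, flat, frame_rate_hz = 20, seed = 1),
               "frame_rate")
})

test_that("planted outcome coding is recovered by the modulation test end-to-end", {
  ses <- make_small_session(n_trials = 100, n_neurons = 20, noise_sd = 0.02,
                            seed = 31)
  mod <- modulation_analysis(ses$tensor, ses$outcomes, seed = 99)
  coding <- ses$ground_truth$outcome_coding
  expect_true(all(mod$significant[coding]))
})

test_that("session bundles round-trip through plain-text files", {
  ses <- make_small_session(n_trials = 15, n_neurons = 3, seed = 41)
  dir <- file.path(tempdir(), "bundle_rt")
  write_session_bundle(ses$session, ses$ground_truth, ses$schedule, ses$licks,
                       dir)
  back <- read_session_bundle(dir)
  expect_equal(back$session$F, ses$session$F, tolerance = 1e-12)
  expect_equal(back$session$frame_rate, 28)
  expect_equal(back$schedule$onset_s, ses$schedule$onset_s, tolerance = 1e-12)
  expect_equal(as.numeric(back$licks), as.numeric(ses$licks), tolerance = 1e-12)
  expect_equal(back$ground_truth$cluster_id, ses$ground_truth$cluster_id)
  expect_equal(attr(back$schedule, "params")$iti_mean, 8)
  unlink(dir, recursive = TRUE)
})
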