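# Shared fixture builders; everything is generated in code at test time.

# Full small session: schedule -> behaviour -> fluorescence -> tensor.
make_small_session <- function(n_trials = 60, n_neurons = 8, noise_sd = 0.03,
                               seed = 11, prototypes = default_prototypes(),
                               spont_rate = 0, frame_rate = 28,
                               neuropil_gain = 0.7,
                               drift = list(amplitude = 0.03, period_s = 200)) {
  sp <- schedule_params(n_trials = n_trials)
  sched <- sample_schedule(sp, seed = seed)
  licks <- sample_behavior(sched, psych_model(), seed = seed + 1,
                           spont_rate = spont_rate)
  syn <- synthesize_session(sched, licks, prototypes, n_neurons = n_neurons,
                            noise_sd = noise_sd, neuropil_gain = neuropil_gain,
                            drift = drift, frame_rate_hz = frame_rate,
                            seed = seed + 2)
  corrected <- neuropil_correct(syn$session$F, syn$session$Fneu,
                                r = neuropil_gain)
  dff <- compute_dff(corrected, frame_rate = frame_rate)
  outcomes <- score_trials(sched, licks)
  tensor <- suppressMessages(extract_trials(dff, sched))
  list(schedule = sched, licks = licks, outcomes = outcomes,
       session = syn$session, ground_truth = syn$ground_truth,
       dff = dff, tensor = tensor)
}

# Hand-built trial table with evenly spaced onsets (no RNG).
make_manual_schedule <- function(onsets, is_catch, level_db,
                                 response_window = 1.5) {
  tab <- data.frame(trial = seq_along(onsets), onset_s = onsets,
                    is_catch = is_catch, level_db = level_db, opto = FALSE)
  attr(tab, "params") <- schedule_params(n_trials = length(onsets),
                                         response_window = response_window,
                                         sound_levels = sort(unique(level_db[!is_catch])))
  class(tab) <- c("trial_table", "data.frame")
  tab
}

# Hand-built trial_outcomes (for rule-level tests that bypass scoring).
make_manual_outcomes <- function(outcome, level_db,
                                 onset_s = seq_along(outcome) * 20) {
  out <- data.frame(trial = seq_along(outcome), onset_s = onset_s,
                    is_catch = outcome %in% c("false_alarm", "correct_rejection"),
                    level_db = level_db, outcome = outcome,
                    latency_s = NA_real_)
  class(out) <- c("trial_outcomes", "data.frame")
  out
}

# Minimal trial tensor built directly from an array.
make_manual_tensor <- function(values, frame_rate = 28, onset_index = 57,
                               kept_trials = seq_len(dim(values)[1])) {
  structure(list(values = values, kept_trials = kept_trials,
                 dropped = integer(0), onset_index = onset_index,
                 frame_rate = frame_rate,
                 window = c(-(onset_index - 1) / frame_rate,
                            (dim(values)[3] - onset_index + 1) / frame_rate)),
            class = "trial_tensor")
}

# K well-separated smooth profile prototypes in feature space: returns a
# neurons x 2L matrix plus true labels (noise_frac relative to amplitude 1).
make_profile_blobs <- function(K, per_cluster = 25, L = 193,
                               noise_frac = 0.1, seed = 5) {
  withr::with_seed(seed, {
    tg <- seq(0, 1, length.out = 2 * L)
    protos <- lapply(seq_len(K), function(k) {
      sin(2 * pi * (k + 1) * tg + k) + 0.5 * cos(2 * pi * k * tg)
    })
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      t(replicate(per_cluster,
                  protos[[k]] + rnorm(2 * L, 0, noise_frac)))
    }))
    list(X = X, labels = rep(seq_len(K), each = per_cluster))
  })
}

# Single-frame decoding problem with a planted class difference.
make_planted_frame <- function(n_hit = 40, n_miss = 20, n_neurons = 8,
                               effect = 0, noise_sd = 1, seed = 3) {
  withr::with_seed(seed, {
    y <- rep(c("hit", "miss"), c(n_hit, n_miss))
    X <- matrix(rnorm((n_hit + n_miss) * n_neurons, 0, noise_sd),
                ncol = n_neurons)
    X[y == "hit", 1] <- X[y == "hit", 1] + effect
    list(X = X, y = y)
  })
}
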