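#' Trial-schedule parameters for the detection task
#'
#' Inter-trial intervals are drawn from a normal distribution truncated from
#' below, matching the task design: mean 8 s, SD 2 s, floor 3 s. Roughly one
#' tenth of trials are catch (no-stimulus) trials, and each stimulus trial
#' carries one click level (dB SPL).
#'
#' @param iti_mean,iti_sd,iti_floor Inter-trial-interval distribution
#'   (seconds): mean, SD, and lower truncation bound.
#' @param n_trials Number of trials in the session.
#' @param catch_fraction Expected proportion of catch trials in `[0, 1)`.
#' @param sound_levels Ascending vector of click levels (dB SPL) used on
#'   stimulus trials.
#' @param response_window Response window after stimulus onset (seconds).
#' @return A `schedule_params` list.
#' @export
schedule_params <- function(iti_mean = 8, iti_sd = 2, iti_floor = 3,
                            n_trials = 400, catch_fraction = 0.1,
                            sound_levels = seq(35, 75, by = 5),
                            response_window = 1.5) {
  stop_if_not(iti_floor > 0, "iti_floor must be positive")
  stop_if_not(iti_sd >= 0, "iti_sd must be non-negative")
  stop_if_not(is.numeric(n_trials) && n_trials >= 1,
              "n_trials must be a positive count")
  stop_if_not(catch_fraction >= 0 && catch_fraction < 1,
              "catch_fraction must be in [0, 1)")
  stop_if_not(!is.unsorted(sound_levels),
              "sound_levels must be sorted ascending")
  stop_if_not(response_window > 0, "response_window must be positive")
  structure(list(iti_mean = iti_mean, iti_sd = iti_sd, iti_floor = iti_floor,
                 n_trials = as.integer(n_trials),
                 catch_fraction = catch_fraction,
                 sound_levels = sound_levels,
                 response_window = response_window),
            class = "schedule_params")
}

#' Psychometric behaviour model
#'
#' Generative stand-in for the mouse: on a stimulus trial at level `x` the
#' response probability is
#' `fa + (1 - fa - lapse) * plogis(slope * (x - midpoint))`, so performance
#' falls to the false-alarm rate far below threshold and saturates at
#' `1 - lapse` far above it. Response-lick latencies are bounded below by the
#' animals' lick-latency floor (120 ms).
#'
#' @param midpoint Sigmoid midpoint (dB SPL).
#' @param slope Sigmoid slope (per dB).
#' @param lapse_rate Asymptotic miss probability on easy trials.
#' @param false_alarm_rate Response probability on catch trials.
#' @param lick_latency_floor Minimum response latency (seconds, >= 0.12).
#' @return A `psych_model` list.
#' @export
psych_model <- function(midpoint = 56, slope = 0.3, lapse_rate = 0.02,
                        false_alarm_rate = 0.15, lick_latency_floor = 0.12) {
  stop_if_not(lapse_rate >= 0 && lapse_rate <= 1, "lapse_rate must be in [0,1]")
  stop_if_not(false_alarm_rate >= 0 && false_alarm_rate <= 1,
              "false_alarm_rate must be in [0,1]")
  stop_if_not(lick_latency_floor >= 0.12,
              "lick_latency_floor must be >= 0.12 s")
  structure(list(midpoint = midpoint, slope = slope, lapse_rate = lapse_rate,
                 false_alarm_rate = false_alarm_rate,
                 lick_latency_floor = lick_latency_floor),
            class = "psych_model")
}

#' Sample a trial schedule
#'
#' Draws inter-trial intervals from the truncated normal (rejection sampling,
#' so the floor is exact and the mean is the truncated-distribution mean, not
#' a clipped one), interleaves catch trials at random, and assigns one sound
#' level per stimulus trial.
#'
#' @param params A [schedule_params()] object.
#' @param seed Integer seed; the same `(params, seed)` pair regenerates the
#'   identical schedule.
#' @return A `trial_table` data.frame with columns `trial`, `onset_s`,
#'   `is_catch`, `level_db` (NA on catch trials), `opto`; `params` is attached
#'   as an attribute.
#' @export
sample_schedule <- function(params, seed) {
  stop_if_not(inherits(params, "schedule_params"), "params must be schedule_params")
  n <- params$n_trials
  tab <- with_seed_(seed, {
    itis <- rtruncnorm_lower(n, params$iti_mean, params$iti_sd, params$iti_floor)
    onsets <- cumsum(itis)
    is_catch <- stats::runif(n) < params$catch_fraction
    level <- rep(NA_real_, n)
    level[!is_catch] <- params$sound_levels[
      sample.int(length(params$sound_levels), sum(!is_catch), replace = TRUE)]
    data.frame(trial = seq_len(n), onset_s = onsets, is_catch = is_catch,
               level_db = level, opto = FALSE)
  })
  attr(tab, "params") <- params
  attr(tab, "seed") <- seed
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Sample licking behaviour for a schedule
#'
#' Response licks on stimulus trials follow the psychometric model; catch
#' trials elicit a response lick at the false-alarm rate. Anticipatory
#' (spontaneous) licks are generated after each trial as an inhomogeneous
#' Poisson process whose intensity follows the truncated-normal inter-trial
#' interval density, i.e. the animal licks preferentially around the time the
#' next trial is expected. Anticipatory licks that would fall inside any
#' trial's response window are discarded, so the parameterised hit and
#' false-alarm probabilities are exact.
#'
#' @param schedule A `trial_table` from [sample_schedule()].
#' @param model A [psych_model()].
#' @param seed Integer seed.
#' @param response_window Response window (seconds); defaults to the
#'   schedule's own.
#' @param spont_rate Expected number of anticipatory licks per inter-trial
#'   interval (0 disables them).
#' @return Sorted numeric vector of lick times (seconds), class `lick_train`.
#' @export
sample_behavior <- function(schedule, model, seed,
                            response_window = NULL, spont_rate = 0.3) {
  stop_if_not(inherits(schedule, "trial_table"), "schedule must be a trial_table")
  stop_if_not(nrow(schedule) >= 1, "empty schedule")
  stop_if_not(inherits(model, "psych_model"), "model must be a psych_model")
  pars <- attr(schedule, "params")
  if (is.null(response_window))
    response_window <- if (!is.null(pars)) pars$response_window else 1.5
  iti_mean <- if (!is.null(pars)) pars$iti_mean else 8
  iti_sd <- if (!is.null(pars)) pars$iti_sd else 2
  iti_floor <- if (!is.null(pars)) pars$iti_floor else 3

  licks <- with_seed_(seed, {
    n <- nrow(schedule)
    # response probability per trial
    x <- schedule$level_db - model$midpoint
    sig <- stats::plogis(model$slope * x)
    sig[is.nan(sig)] <- 0.5  # slope = Inf at exactly the midpoint
    p <- ifelse(schedule$is_catch,
                model$false_alarm_rate,
                model$false_alarm_rate +
                  (1 - model$false_alarm_rate - model$lapse_rate) * sig)
    respond <- stats::rbinom(n, 1, p) == 1
    lat <- model$lick_latency_floor +
      (response_window - model$lick_latency_floor) * stats::rbeta(n, 2, 4)
    out <- schedule$onset_s[respond] + lat[respond]

    if (spont_rate > 0 && iti_sd > 0) {
      spont <- numeric(0)
      for (i in seq_len(n)) {
        k <- stats::rpois(1, spont_rate)
        if (k == 0) next
        t_rel <- rtruncnorm_lower(k, iti_mean, iti_sd, iti_floor)
        spont <- c(spont, schedule$onset_s[i] + t_rel)
      }
      # keep the generative hit/FA probabilities exact
      in_window <- vapply(spont, function(tm) {
        any(tm > schedule$onset_s & tm <= schedule$onset_s + response_window)
      }, logical(1))
      out <- c(out, spont[!in_window])
    }
    sort(out)
  })
  structure(licks, class = c("lick_train", "numeric"))
}

#' Cluster-prototype response profile for a synthetic neuron
#'
#' A prototype specifies the underlying activity drive on hit and miss trials
#' over the full -2 s...+5 s trial window, plus an optional pre-stimulus state
#' difference (extra drive in the 2 s before onset on hit trials), emulating
#' anticipatory network-state coding.
#'
#' @param cluster_id Integer identity of the prototype.
#' @param hit_kernel,miss_kernel Functions of time (seconds relative to
#'   stimulus onset, in `[-2, 5]`) returning the drive amplitude.
#' @param prestim_state_gain Extra hit-trial drive during the pre-stimulus
#'   window (dimensionless, 0 = none).
#' @return A `neuron_prototype` list.
#' @export
neuron_prototype <- function(cluster_id, hit_kernel, miss_kernel,
                             prestim_state_gain = 0) {
  stop_if_not(is.function(hit_kernel) && is.function(miss_kernel),
              "kernels must be functions of time")
  structure(list(cluster_id = as.integer(cluster_id), hit_kernel = hit_kernel,
                 miss_kernel = miss_kernel,
                 prestim_state_gain = prestim_state_gain),
            class = "neuron_prototype")
}

#' Default response-profile prototypes
#'
#' Four qualitative profiles observed in corticorecipient midbrain neurons
#' during the task: (1) sharp short-latency facilitation on hits with a weak
#' miss response, (2) suppression on hits, (3) a behaviour-invariant sharp
#' onset response (identical on hits and misses), and (4) a slow ramp peaking
#' seconds after trial onset on hits only.
#'
#' @param amplitude Peak drive amplitude (dF/F units).
#' @return List of [neuron_prototype()] objects.
#' @export
default_prototypes <- function(amplitude = 0.5) {
  sharp <- function(t, a) ifelse(t >= 0, a * exp(-pmax(t, 0) / 0.6), 0)
  ramp <- function(t, a) ifelse(t >= 0, a * pmax(t, 0) / 3 * exp(1 - pmax(t, 0) / 3), 0)
  zero <- function(t) rep(0, length(t))
  list(
    neuron_prototype(1L, hit_kernel = function(t) sharp(t, amplitude),
                     miss_kernel = function(t) sharp(t, 0.2 * amplitude)),
    neuron_prototype(2L, hit_kernel = function(t) -sharp(t, 0.6 * amplitude),
                     miss_kernel = zero),
    neuron_prototype(3L, hit_kernel = function(t) sharp(t, amplitude),
                     miss_kernel = function(t) sharp(t, amplitude)),
    neuron_prototype(4L, hit_kernel = function(t) ramp(t, amplitude),
                     miss_kernel = zero)
  )
}

#' Synthesize a two-photon session from schedule, licks and prototypes
#'
#' Builds per-ROI fluorescence as
#' `baseline * (1 + signal + drift + noise) + neuropil_gain * Fneu`, where
#' `signal` is the per-trial prototype drive (hit kernel on hit trials, miss
#' kernel on misses, nothing on catch trials) convolved with a
#' single-exponential calcium impulse response (tau = 0.5 s, GCaMP6f-like),
#' `drift` is a slow sinusoid, and `Fneu` is a shared slowly varying neuropil
#' background. Regeneration with the same arguments and seed is bit-identical.
#'
#' @param schedule A `trial_table`.
#' @param licks A `lick_train` for the same session.
#' @param prototypes Non-empty list of [neuron_prototype()] objects.
#' @param n_neurons Number of ROIs to simulate.
#' @param noise_sd Gaussian noise SD in dF/F units.
#' @param neuropil_gain Contamination coefficient mixing the neuropil channel
#'   into the somatic channel (the conditioning step removes it with the same
#'   coefficient).
#' @param drift List with `amplitude` (dF/F units) and `period_s`.
#' @param frame_rate_hz Imaging frame rate (27-30 Hz).
#' @param seed Integer seed.
#' @param tau_s Calcium decay time constant (seconds).
#' @param response_window Seconds; used to classify hit vs miss internally.
#' @return List with `session` (list: `F`, `Fneu` ROI-by-frame matrices,
#'   `frame_rate`, `group`) and `ground_truth` (per-neuron `cluster_id`,
#'   `outcome_coding` flags, the schedule parameters and seed).
#' @export
synthesize_session <- function(schedule, licks, prototypes, n_neurons = 50,
                               noise_sd = 0.05, neuropil_gain = 0.7,
                               drift = list(amplitude = 0.05, period_s = 300),
                               frame_rate_hz = 28, seed = 1, tau_s = 0.5,
                               response_window = NULL) {
  stop_if_not(length(prototypes) >= 1, "prototype list must be non-empty")
  stop_if_not(n_neurons >= 1, "n_neurons must be >= 1")
  stop_if_not(frame_rate_hz >= 27 && frame_rate_hz <= 30,
              "frame_rate_hz must be in [27, 30]")
  pars <- attr(schedule, "params")
  if (is.null(response_window))
    response_window <- if (!is.null(pars)) pars$response_window else 1.5

  fs <- frame_rate_hz
  dur <- max(schedule$onset_s) + 8
  n_frames <- as.integer(ceiling(dur * fs))
  tt <- (seq_len(n_frames) - 1) / fs

  # outcome per trial (same rule the scoring module applies)
  responded <- vapply(schedule$onset_s, function(on) {
    any(licks > on & licks <= on + response_window)
  }, logical(1))
  is_hit <- !schedule$is_catch & responded

  out <- with_seed_(seed, {
    proto_idx <- sample(seq_along(prototypes), n_neurons, replace = TRUE)
    baseline <- stats::runif(n_neurons, 80, 120)
    drift_phase <- stats::runif(n_neurons, 0, 2 * pi)
    npil_base <- stats::runif(n_neurons, 20, 40)

    shared_bg <- 0.2 * sin(2 * pi * tt / 97) + 0.1 * sin(2 * pi * tt / 311)
    a_decay <- exp(-1 / (tau_s * fs))

    Fm <- matrix(0, n_neurons, n_frames)
    Fneu <- matrix(0, n_neurons, n_frames)
    stim_idx <- which(!schedule$is_catch)
    # frame spans of each stimulus trial's -2..+5 s window
    for (j in seq_len(n_neurons)) {
      p <- prototypes[[proto_idx[j]]]
      drive <- numeric(n_frames)
      for (i in stim_idx) {
        on <- schedule$onset_s[i]
        i0 <- max(1L, as.integer(ceiling((on - 2) * fs)) + 1L)
        i1 <- min(n_frames, as.integer(floor((on + 5) * fs)) + 1L)
        if (i1 < i0) next
        rel <- tt[i0:i1] - on
        kern <- if (is_hit[i]) p$hit_kernel(rel) else p$miss_kernel(rel)
        if (is_hit[i] && p$prestim_state_gain != 0)
          kern <- kern + p$prestim_state_gain * (rel < 0)
        drive[i0:i1] <- drive[i0:i1] + kern
      }
      # exponential calcium impulse response, normalised to unit gain for a
      # sustained drive
      ca <- as.numeric(stats::filter(drive * (1 - a_decay), a_decay,
                                     method = "recursive"))
      dr <- if (drift$amplitude > 0) {
        drift$amplitude * sin(2 * pi * tt / drift$period_s + drift_phase[j])
      } else 0
      noise <- if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
      Fneu[j, ] <- npil_base[j] * (1 + shared_bg)
      Fm[j, ] <- baseline[j] * (1 + ca + dr + noise) + neuropil_gain * Fneu[j, ]
    }
    list(Fm = Fm, Fneu = Fneu, proto_idx = proto_idx)
  })

  cluster_id <- vapply(prototypes, `[[`, integer(1), "cluster_id")[out$proto_idx]
  coding <- vapply(prototypes, function(p) {
    tg <- seq(-2, 5, length.out = 50)
    !isTRUE(all.equal(p$hit_kernel(tg), p$miss_kernel(tg))) ||
      p$prestim_state_gain != 0
  }, logical(1))[out$proto_idx]

  list(
    session = list(F = out$Fm, Fneu = out$Fneu, frame_rate = fs,
                   group = "non_lesioned"),
    ground_truth = list(cluster_id = cluster_id, outcome_coding = coding,
                        prototype_index = out$proto_idx,
                        schedule_params = pars, seed = seed,
                        is_hit = is_hit)
  )
}
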