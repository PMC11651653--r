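#' Score trials from lick times
#'
#' Applies the go/no-go rule: a lick within the response window after a
#' stimulus onset scores a hit (otherwise a miss); on catch trials a lick in
#' the window scores a false alarm (otherwise a correct rejection). The
#' latency is the first lick after onset within the window.
#'
#' @param schedule A `trial_table`.
#' @param licks Sorted numeric vector of lick times (seconds).
#' @param response_window Seconds; defaults to the schedule's own parameter.
#' @return A `trial_outcomes` data.frame: `trial`, `onset_s`, `is_catch`,
#'   `level_db`, `outcome` (one of `"hit"`, `"miss"`, `"false_alarm"`,
#'   `"correct_rejection"`), `latency_s` (NA when no response lick).
#' @export
score_trials <- function(schedule, licks, response_window = NULL) {
  pars <- attr(schedule, "params")
  if (is.null(response_window))
    response_window <- if (!is.null(pars)) pars$response_window else 1.5
  licks <- as.numeric(licks)
  stop_if_not(!is.unsorted(licks), "licks must be sorted ascending")
  if (nrow(schedule) > 1 && any(diff(schedule$onset_s) < response_window))
    stop("invalid schedule: response windows overlap", call. = FALSE)

  n <- nrow(schedule)
  latency <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    on <- schedule$onset_s[i]
    in_win <- licks[licks > on & licks <= on + response_window]
    if (length(in_win)) latency[i] <- in_win[1] - on
  }
  responded <- !is.na(latency)
  outcome <- ifelse(schedule$is_catch,
                    ifelse(responded, "false_alarm", "correct_rejection"),
                    ifelse(responded, "hit", "miss"))
  out <- data.frame(trial = schedule$trial, onset_s = schedule$onset_s,
                    is_catch = schedule$is_catch, level_db = schedule$level_db,
                    outcome = outcome, latency_s = latency)
  attr(out, "response_window") <- response_window
  class(out) <- c("trial_outcomes", "data.frame")
  out
}

#' Detection sensitivity d-prime from outcome counts
#'
#' `d' = qnorm(HR) - qnorm(FAR)` with a log-linear correction (0.5 added to
#' every cell) so hit or false-alarm rates of exactly 0 or 1 still give a
#' finite value.
#'
#' @param n_hit,n_miss,n_fa,n_cr Trial counts.
#' @param correction Apply the log-linear correction (default TRUE).
#' @return d-prime (dimensionless scalar).
#' @export
dprime <- function(n_hit, n_miss, n_fa, n_cr, correction = TRUE) {
  stop_if_not(n_hit + n_miss >= 1, "need at least one stimulus trial")
  stop_if_not(n_fa + n_cr >= 1, "need at least one catch trial")
  if (correction) {
    hr <- (n_hit + 0.5) / (n_hit + n_miss + 1)
    far <- (n_fa + 0.5) / (n_fa + n_cr + 1)
  } else {
    hr <- n_hit / (n_hit + n_miss)
    far <- n_fa / (n_fa + n_cr)
  }
  stats::qnorm(hr) - stats::qnorm(far)
}

#' Per-level d-prime table
#'
#' d-prime for each distinct sound level using the level's hit/miss counts and
#' the session-wide false-alarm pool (catch trials carry no level).
#'
#' @param outcomes A `trial_outcomes` data.frame.
#' @return data.frame `level_db`, `n_hit`, `n_miss`, `dprime`, sorted by level.
#' @export
level_dprime <- function(outcomes) {
  stim <- outcomes[!outcomes$is_catch, ]
  n_fa <- sum(outcomes$outcome == "false_alarm")
  n_cr <- sum(outcomes$outcome == "correct_rejection")
  stop_if_not(n_fa + n_cr >= 1, "no catch trials to estimate the FA rate")
  levels_db <- sort(unique(stim$level_db))
  rows <- lapply(levels_db, function(lv) {
    sub <- stim[stim$level_db == lv, ]
    nh <- sum(sub$outcome == "hit"); nm <- sum(sub$outcome == "miss")
    data.frame(level_db = lv, n_hit = nh, n_miss = nm,
               dprime = dprime(nh, nm, n_fa, n_cr))
  })
  do.call(rbind, rows)
}

#' Behavioural summary with a binned psychometric function
#'
#' Hit rate, false-alarm rate and session d-prime, plus d-prime per sound-level
#' bin (default 10 dB wide, so sessions using different level sets remain
#' comparable). Bin d-prime uses the bin's hit/miss counts and the session's
#' single false-alarm pool; empty bins are omitted.
#'
#' @param outcomes A `trial_outcomes` data.frame.
#' @param bin_width_db Bin width in dB (default 10).
#' @return A `behavioral_summary` list: `hit_rate`, `fa_rate`, `dprime`, and
#'   `bins` (data.frame `bin_lo`, `bin_hi`, `n_hit`, `n_miss`, `hit_rate`,
#'   `dprime`).
#' @export
psychometric <- function(outcomes, bin_width_db = 10) {
  n_hit <- sum(outcomes$outcome == "hit")
  n_miss <- sum(outcomes$outcome == "miss")
  n_fa <- sum(outcomes$outcome == "false_alarm")
  n_cr <- sum(outcomes$outcome == "correct_rejection")
  stim <- outcomes[!outcomes$is_catch, ]
  stop_if_not(nrow(stim) >= 1, "no stimulus trials")
  # bins anchored at the lowest level; the top edge of the last bin is closed
  lo0 <- min(stim$level_db)
  span <- max(stim$level_db) - lo0
  n_bins <- max(1L, as.integer(ceiling(span / bin_width_db)))
  bin_of <- pmin(floor((stim$level_db - lo0) / bin_width_db), n_bins - 1L)
  rows <- lapply(seq_len(n_bins) - 1L, function(b) {
    lo <- lo0 + b * bin_width_db
    sub <- stim[bin_of == b, ]
    if (!nrow(sub)) return(NULL)
    nh <- sum(sub$outcome == "hit"); nm <- sum(sub$outcome == "miss")
    data.frame(bin_lo = lo, bin_hi = lo + bin_width_db, n_hit = nh,
               n_miss = nm, hit_rate = nh / (nh + nm),
               dprime = dprime(nh, nm, n_fa, n_cr))
  })
  structure(list(
    hit_rate = if (n_hit + n_miss) n_hit / (n_hit + n_miss) else NA_real_,
    fa_rate = if (n_fa + n_cr) n_fa / (n_fa + n_cr) else NA_real_,
    dprime = dprime(n_hit, n_miss, n_fa, n_cr),
    bins = do.call(rbind, rows)
  ), class = "behavioral_summary")
}

#' Two-sided chi-squared test of equal response proportions
#'
#' Compares hit proportions between two conditions (e.g. optogenetic light on
#' vs off) with a 1-df chi-squared test of equal proportions (no continuity
#' correction).
#'
#' @param hits_a,total_a,hits_b,total_b Counts for the two conditions.
#' @return List with `statistic` (chi-squared) and `p_value`.
#' @export
opto_proportion_test <- function(hits_a, total_a, hits_b, total_b) {
  stop_if_not(total_a >= 1 && total_b >= 1, "totals must be >= 1")
  res <- suppressWarnings(
    stats::prop.test(c(hits_a, hits_b), c(total_a, total_b), correct = FALSE)
  )
  list(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Peri-event lick rate
#'
#' Histogram-based lick rate (Hz) around reference events, e.g. to compare
#' post-hit anticipatory licking against the inter-trial-interval density.
#'
#' @param licks Numeric vector of lick times (seconds).
#' @param reference_times Event times to align on.
#' @param window Length-2 vector: relative window in seconds.
#' @param bin_s Histogram bin width (seconds).
#' @return data.frame with `time_s` (bin centres) and `rate_hz`.
#' @export
peri_event_lick_rate <- function(licks, reference_times, window = c(0, 15),
                                 bin_s = 0.25) {
  stop_if_not(length(reference_times) >= 1, "need at least one reference event")
  breaks <- seq(window[1], window[2], by = bin_s)
  counts <- numeric(length(breaks) - 1)
  for (ref in reference_times) {
    rel <- licks - ref
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel))
      counts <- counts + tabulate(findInterval(rel, breaks), length(counts))
  }
  data.frame(time_s = breaks[-length(breaks)] + bin_s / 2,
             rate_hz = counts / (length(reference_times) * bin_s))
}
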