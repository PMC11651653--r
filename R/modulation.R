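#' Per-trial response magnitude
#'
#' For each trial and neuron: mean activity over the 5 s after stimulus onset
#' minus the mean over the 2 s before it.
#'
#' @param tensor A `trial_tensor` whose window covers -2...+5 s.
#' @param post_s Length of the post-stimulus averaging window (seconds,
#'   default 5; the sound-response test uses 1).
#' @return trials x neurons matrix of response magnitudes.
#' @export
response_magnitude <- function(tensor, post_s = 5) {
  on <- tensor$onset_index
  len <- dim(tensor$values)[3]
  n_post <- min(len - on + 1L, as.integer(round(post_s * tensor$frame_rate)))
  stop_if_not(on > 1 && n_post >= 1, "trial window does not cover pre and post")
  pre_m <- apply(tensor$values[, , 1:(on - 1L), drop = FALSE], c(1, 2), mean)
  post_m <- apply(tensor$values[, , on:(on + n_post - 1L), drop = FALSE],
                  c(1, 2), mean)
  post_m - pre_m
}

#' Sound-level-balanced subsampling of hit and miss trials
#'
#' For each sound level present with both outcomes, randomly downsamples the
#' more frequent outcome (without replacement) to the count of the rarer one,
#' so the hit and miss sets have identical sound-level distributions. Levels
#' lacking one of the outcomes are dropped.
#'
#' @param outcomes A `trial_outcomes` data.frame (or any data.frame with
#'   `outcome` and `level_db` columns).
#' @param seed Integer seed for the draw.
#' @return Sorted integer row indices into `outcomes` (hits and misses,
#'   equal counts per level).
#' @export
balanced_subsample <- function(outcomes, seed) {
  stim <- which(!outcomes$is_catch)
  levels_db <- unique(outcomes$level_db[stim])
  picked <- with_seed_(seed, {
    out <- integer(0)
    for (lv in levels_db) {
      h <- which(outcomes$level_db == lv & outcomes$outcome == "hit")
      m <- which(outcomes$level_db == lv & outcomes$outcome == "miss")
      k <- min(length(h), length(m))
      if (k == 0) next
      if (length(h) > k) h <- sample(h, k)
      if (length(m) > k) m <- sample(m, k)
      out <- c(out, h, m)
    }
    out
  })
  stop_if_not(length(picked) > 0,
              "no sound level has both hit and miss trials")
  sort(picked)
}

#' Mann-Whitney U test for hit vs miss response magnitudes
#'
#' Two-sided rank-sum test; `direction` is "facilitated" when the hit median
#' exceeds the miss median, otherwise "suppressed". Identical samples return
#' p = 1. Ties are handled by the normal approximation with tie correction
#' (the exact distribution is used for small tie-free samples).
#'
#' @param magnitudes_hit,magnitudes_miss Numeric vectors (>= `min_n` each).
#' @param min_n Minimum samples per group (default 3).
#' @return List `U`, `p_value`, `direction`.
#' @export
hit_miss_test <- function(magnitudes_hit, magnitudes_miss, min_n = 3) {
  stop_if_not(length(magnitudes_hit) >= min_n && length(magnitudes_miss) >= min_n,
              sprintf("need at least %d samples per group", min_n))
  res <- suppressWarnings(stats::wilcox.test(magnitudes_hit, magnitudes_miss))
  list(U = unname(res$statistic), p_value = res$p.value,
       direction = if (stats::median(magnitudes_hit) >=
                       stats::median(magnitudes_miss)) "facilitated" else "suppressed")
}

#' Wilcoxon signed-rank test for a sound-evoked response on miss trials
#'
#' Pairs, per qualifying miss trial, the mean activity over the 2 s before
#' stimulus onset with the mean over the 1 s after it. Only miss trials with
#' click levels inside `level_range` (53-65 dB SPL by default; higher levels
#' are rarely missed) qualify.
#'
#' @param tensor A `trial_tensor`.
#' @param outcomes Matching `trial_outcomes`.
#' @param neuron Neuron index to test.
#' @param level_range Inclusive dB SPL range (default `c(53, 65)`).
#' @param min_pairs Minimum qualifying trials (default 5).
#' @return List `W`, `p_value`, `n_pairs`; or `NULL` (with a message) when the
#'   neuron has too few qualifying trials and is excluded.
#' @export
sound_response_test <- function(tensor, outcomes, neuron,
                                level_range = c(53, 65), min_pairs = 5) {
  idx <- tensor$kept_trials
  lab <- outcomes$outcome[idx]
  lv <- outcomes$level_db[idx]
  rows <- which(lab == "miss" & !is.na(lv) &
                  lv >= level_range[1] & lv <= level_range[2])
  if (length(rows) < min_pairs) {
    message(sprintf("neuron %d excluded from the sound-response test (%d qualifying miss trials)",
                    neuron, length(rows)))
    return(NULL)
  }
  on <- tensor$onset_index
  n_post <- as.integer(round(1 * tensor$frame_rate))
  pre <- apply(tensor$values[rows, neuron, 1:(on - 1L), drop = FALSE], 1, mean)
  post <- apply(tensor$values[rows, neuron, on:(on + n_post - 1L), drop = FALSE], 1, mean)
  d <- post - pre
  if (all(d == 0)) return(list(W = 0, p_value = 1, n_pairs = length(rows)))
  res <- suppressWarnings(stats::wilcox.test(post, pre, paired = TRUE))
  list(W = unname(res$statistic), p_value = res$p.value, n_pairs = length(rows))
}

#' Benjamini-Hochberg adjustment with significance flags
#'
#' Standard step-up false-discovery-rate adjustment; a unit is significant
#' when its adjusted p-value is below `q`.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List `p_adjusted`, `significant`.
#' @export
bh_adjust <- function(p_values, q = 0.05) {
  stop_if_not(all(is.finite(p_values)) && all(p_values >= 0 & p_values <= 1),
              "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(p_adjusted = adj, significant = adj < q)
}

#' Outcome-modulation analysis across all neurons of a session
#'
#' Applies the sound-level-balanced subsample (one draw per session — the
#' subsample is a set of trials shared by every neuron), computes per-trial
#' response magnitudes, tests hit vs miss per neuron (Mann-Whitney U), and
#' adjusts across neurons by Benjamini-Hochberg.
#'
#' @param tensor A `trial_tensor`.
#' @param outcomes Matching `trial_outcomes`.
#' @param seed Session-level seed for the balanced subsample.
#' @param q FDR level (default 0.05).
#' @param min_n Minimum per-group trial count per the test (default 3).
#' @return data.frame, one row per neuron: `neuron`, `U`, `p_raw`, `p_bh`,
#'   `significant`, `direction`, `n_hit_used`, `n_miss_used`.
#' @export
modulation_analysis <- function(tensor, outcomes, seed, q = 0.05, min_n = 3) {
  sub <- balanced_subsample(outcomes, seed)
  rows <- which(tensor$kept_trials %in% sub)
  lab <- outcomes$outcome[tensor$kept_trials[rows]]
  mags <- response_magnitude(tensor)[rows, , drop = FALSE]
  hit_rows <- lab == "hit"; miss_rows <- lab == "miss"
  stop_if_not(sum(hit_rows) >= min_n && sum(miss_rows) >= min_n,
              "too few balanced trials for the modulation test")
  n_neur <- ncol(mags)
  res <- lapply(seq_len(n_neur), function(j) {
    hit_miss_test(mags[hit_rows, j], mags[miss_rows, j], min_n = min_n)
  })
  p_raw <- vapply(res, `[[`, numeric(1), "p_value")
  adj <- bh_adjust(p_raw, q = q)
  data.frame(neuron = seq_len(n_neur),
             U = vapply(res, `[[`, numeric(1), "U"),
             p_raw = p_raw, p_bh = adj$p_adjusted,
             significant = adj$significant,
             direction = vapply(res, `[[`, character(1), "direction"),
             n_hit_used = sum(hit_rows), n_miss_used = sum(miss_rows))
}
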