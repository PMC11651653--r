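#' Neuropil correction
#'
#' Subtracts the scaled neuropil channel from the somatic channel,
#' `corrected = F - r * Fneu`, with the conventional coefficient r = 0.7.
#'
#' @param F_mat,Fneu ROI-by-frame matrices of identical shape.
#' @param r Neuropil coefficient (default 0.7).
#' @return Corrected ROI-by-frame matrix.
#' @export
neuropil_correct <- function(F_mat, Fneu, r = 0.7) {
  F_mat <- as.matrix(F_mat); Fneu <- as.matrix(Fneu)
  stop_if_not(all(dim(F_mat) == dim(Fneu)), "F and Fneu shapes differ")
  F_mat - r * Fneu
}

#' Compute dF/F with a whole-trace median F0
#'
#' `dF/F = (F - F0) / F0`, with F0 the median of each ROI's entire
#' (neuropil-corrected) trace. ROIs whose median is not positive cannot be
#' normalised; they are excluded with a warning and reported in the
#' `excluded` attribute.
#'
#' @param corrected ROI-by-frame matrix of corrected fluorescence.
#' @param frame_rate Frames per second (carried as an attribute).
#' @param neuropil_coefficient Coefficient used upstream (metadata).
#' @return A `dff_matrix`: ROI-by-frame matrix with attributes `frame_rate`,
#'   `excluded` (row indices dropped), `f0` (per kept ROI).
#' @export
compute_dff <- function(corrected, frame_rate = NA_real_,
                        neuropil_coefficient = 0.7) {
  corrected <- as.matrix(corrected)
  f0 <- apply(corrected, 1, stats::median)
  bad <- which(!is.finite(f0) | f0 <= 0)
  if (length(bad)) {
    warning(sprintf("%d ROI(s) with non-positive median F0 excluded", length(bad)))
    corrected <- corrected[-bad, , drop = FALSE]
    f0 <- f0[-bad]
  }
  stop_if_not(nrow(corrected) >= 1, "no ROI with positive F0 left")
  dff <- sweep(sweep(corrected, 1, f0, "-"), 1, f0, "/")
  structure(dff, frame_rate = frame_rate, excluded = bad, f0 = f0,
            neuropil_coefficient = neuropil_coefficient,
            f0_definition = "whole-trace median",
            class = c("dff_matrix", class(dff)))
}

#' Remove slow baseline fluctuations
#'
#' Estimates a slow baseline per ROI as
#' `max-filter(min-filter(gaussian-filter(trace)))` — Gaussian smoothing
#' followed by a running minimum then a running maximum (a morphological
#' opening of the smoothed trace) — and subtracts it. Window parameters are in
#' seconds and converted with the frame rate.
#'
#' @param dff A `dff_matrix` (or plain ROI-by-frame matrix).
#' @param gaussian_sigma_s Gaussian SD (seconds, default 10).
#' @param min_window_s,max_window_s Running min/max window lengths (seconds,
#'   default 60).
#' @param frame_rate Frames per second; taken from `dff` if available.
#' @return Baseline-subtracted matrix with the input's attributes.
#' @export
remove_slow_baseline <- function(dff, gaussian_sigma_s = 10,
                                 min_window_s = 60, max_window_s = 60,
                                 frame_rate = NULL) {
  if (is.null(frame_rate)) frame_rate <- attr(dff, "frame_rate")
  stop_if_not(is.numeric(frame_rate) && is.finite(frame_rate),
              "frame_rate missing")
  stop_if_not(gaussian_sigma_s > 0 && min_window_s > 0 && max_window_s > 0,
              "window parameters must be positive")
  x <- as.matrix(dff)
  stop_if_not(ncol(x) >= 1, "zero-length trace")
  w_min <- as.integer(round(min_window_s * frame_rate))
  w_max <- as.integer(round(max_window_s * frame_rate))
  stop_if_not(w_min <= ncol(x) && w_max <= ncol(x),
              "filter windows are longer than the recording")
  out <- x
  for (i in seq_len(nrow(x))) {
    sm <- gaussian_smooth(x[i, ], gaussian_sigma_s * frame_rate)
    base <- running_extreme(running_extreme(sm, w_min, "min"), w_max, "max")
    out[i, ] <- x[i, ] - base
  }
  attributes(out) <- attributes(dff)
  dim(out) <- dim(x)
  out
}

#' Extract the trial-aligned activity tensor
#'
#' Slices a fixed window around every stimulus onset (2 s before to 5 s after
#' by default). Time 0 maps to the first frame whose timestamp is at or after
#' the onset; trials whose window extends beyond the recording are dropped
#' (reported in `dropped`). At ~28 Hz the window holds 193-197 frames.
#'
#' @param dff ROI-by-frame `dff_matrix`.
#' @param schedule A `trial_table` (all trials, catch included).
#' @param pre,post Window extent in seconds (default 2 and 5).
#' @param frame_rate Frames per second; taken from `dff` if available.
#' @return A `trial_tensor` list: `values` (trials x ROIs x frames array),
#'   `kept_trials` (row indices into `schedule`), `dropped`, `onset_index`
#'   (frame index of time 0 within the window), `frame_rate`, `window`.
#' @export
extract_trials <- function(dff, schedule, pre = 2, post = 5,
                           frame_rate = NULL) {
  if (is.null(frame_rate)) frame_rate <- attr(dff, "frame_rate")
  stop_if_not(is.numeric(frame_rate) && is.finite(frame_rate),
              "frame_rate missing")
  x <- as.matrix(dff)
  n_frames <- ncol(x)
  n_pre <- as.integer(round(pre * frame_rate))
  n_post <- as.integer(round(post * frame_rate))
  len <- n_pre + n_post

  keep <- integer(0); starts <- integer(0)
  for (i in seq_len(nrow(schedule))) {
    # first frame with timestamp >= onset: frame k has time (k-1)/fs
    onset_idx <- as.integer(ceiling(schedule$onset_s[i] * frame_rate - 1e-9)) + 1L
    i0 <- onset_idx - n_pre
    i1 <- onset_idx + n_post - 1L
    if (i0 >= 1L && i1 <= n_frames) {
      keep <- c(keep, i)
      starts <- c(starts, i0)
    }
  }
  dropped <- setdiff(seq_len(nrow(schedule)), keep)
  if (length(dropped))
    message(sprintf("extract_trials: dropped %d trial(s) outside the recording",
                    length(dropped)))
  stop_if_not(length(keep) >= 1, "no trial window fits inside the recording")
  tens <- array(NA_real_, dim = c(length(keep), nrow(x), len))
  for (k in seq_along(keep)) {
    tens[k, , ] <- x[, starts[k]:(starts[k] + len - 1L), drop = FALSE]
  }
  structure(list(values = tens, kept_trials = keep, dropped = dropped,
                 onset_index = n_pre + 1L, frame_rate = frame_rate,
                 window = c(-pre, post)),
            class = "trial_tensor")
}

#' Indices of trials retained after lick-contamination filtering
#'
#' Hit trials with any lick between 500 ms before and 120 ms after stimulus
#' onset (the lower bound of the lick latency) are excluded, so pre-stimulus
#' activity differences cannot be a direct correlate of licking. All other
#' trials are retained.
#'
#' @param outcomes A `trial_outcomes` data.frame.
#' @param licks Numeric lick times (seconds).
#' @param window Exclusion window relative to onset (default `c(-0.5, 0.12)`).
#' @return Integer vector of retained row indices into `outcomes`.
#' @export
exclude_lick_contaminated_hits <- function(outcomes, licks,
                                           window = c(-0.5, 0.12)) {
  licks <- as.numeric(licks)
  contaminated <- vapply(seq_len(nrow(outcomes)), function(i) {
    if (outcomes$outcome[i] != "hit") return(FALSE)
    on <- outcomes$onset_s[i]
    any(licks >= on + window[1] & licks <= on + window[2])
  }, logical(1))
  which(!contaminated)
}

#' Per-neuron trial-averaged hit and miss traces at a common length
#'
#' Averages the tensor across hit trials and across miss trials (stimulus
#' trials only, pooling all sound levels) and linearly resamples each average
#' to exactly `L` points, so sessions recorded at slightly different frame
#' rates become comparable.
#'
#' @param tensor A `trial_tensor`.
#' @param outcomes `trial_outcomes` for the same schedule the tensor was cut
#'   from.
#' @param L Common trace length (default 193).
#' @param trial_subset Optional integer subset of schedule rows to use (e.g.
#'   from [exclude_lick_contaminated_hits()]).
#' @return An `outcome_averages` list: `hit` and `miss` (neurons x L
#'   matrices), `L`, `n_hit`, `n_miss`.
#' @export
outcome_averages <- function(tensor, outcomes, L = 193, trial_subset = NULL) {
  idx <- tensor$kept_trials
  if (!is.null(trial_subset)) idx_ok <- idx %in% trial_subset else idx_ok <- rep(TRUE, length(idx))
  lab <- outcomes$outcome[idx]
  hit_rows <- which(idx_ok & lab == "hit")
  miss_rows <- which(idx_ok & lab == "miss")
  stop_if_not(length(hit_rows) >= 1 && length(miss_rows) >= 1,
              "session lacks hit or miss trials; neurons excluded from clustering")
  n_neur <- dim(tensor$values)[2]
  avg_one <- function(rows) {
    m <- apply(tensor$values[rows, , , drop = FALSE], c(2, 3), mean)
    t(apply(m, 1, resample_linear, L = L))
  }
  structure(list(hit = avg_one(hit_rows), miss = avg_one(miss_rows), L = L,
                 n_hit = length(hit_rows), n_miss = length(miss_rows)),
            class = "outcome_averages")
}

#' Z-motion check from spatial principal components
#'
#' For each spatial principal component of a registered frame stack, compares
#' the mean image over the `n_extreme` highest-scoring frames with the mean
#' over the `n_extreme` lowest-scoring frames. Out-of-plane displacement shows
#' up as structured difference images; the per-PC scalar score is the mean
#' absolute difference. Thresholding for exclusion is left to the user.
#'
#' @param frame_stack frames x pixels matrix, or frames x h x w array.
#' @param n_extreme Frames in each tail (default 500).
#' @param n_pcs Number of PCs to examine (default 3).
#' @return List with `diff_images` (list of pixel vectors/matrices) and
#'   `scores` (numeric per PC).
#' @export
zmotion_pc_check <- function(frame_stack, n_extreme = 500, n_pcs = 3) {
  dims <- dim(frame_stack)
  img_dim <- NULL
  if (length(dims) == 3) {
    img_dim <- dims[2:3]
    frame_stack <- matrix(frame_stack, nrow = dims[1])
  }
  n <- nrow(frame_stack)
  stop_if_not(n > 2 * n_extreme,
              "need more than 2 * n_extreme frames")
  n_pcs <- min(n_pcs, n - 1L, ncol(frame_stack))
  pc <- stats::prcomp(frame_stack, center = TRUE, scale. = FALSE, rank. = n_pcs)
  diff_images <- vector("list", n_pcs)
  scores <- numeric(n_pcs)
  for (k in seq_len(n_pcs)) {
    ord <- order(pc$x[, k])
    lo <- colMeans(frame_stack[ord[seq_len(n_extreme)], , drop = FALSE])
    hi <- colMeans(frame_stack[ord[(n - n_extreme + 1L):n], , drop = FALSE])
    d <- hi - lo
    if (!is.null(img_dim)) dim(d) <- img_dim
    diff_images[[k]] <- d
    scores[k] <- mean(abs(d))
  }
  list(diff_images = diff_images, scores = scores)
}

#' Lick-triggered average movie
#'
#' Averages clips of the frame stack around lick events (2 s before to 2 s
#' after by default); a stereotyped lick-locked displacement or intensity
#' change becomes visible in the average. Licks whose clip would extend
#' outside the stack are skipped.
#'
#' @param frame_stack frames x pixels matrix or frames x h x w array.
#' @param lick_times Lick times (seconds).
#' @param frame_rate Frames per second.
#' @param window Clip extent, seconds (default `c(-2, 2)`).
#' @return List: `movie` (clip-frames x pixels, or x h x w), `n_events`,
#'   `time_s` (clip frame times relative to the lick).
#' @export
lick_triggered_movie <- function(frame_stack, lick_times, frame_rate,
                                 window = c(-2, 2)) {
  dims <- dim(frame_stack)
  img_dim <- NULL
  if (length(dims) == 3) {
    img_dim <- dims[2:3]
    frame_stack <- matrix(frame_stack, nrow = dims[1])
  }
  n <- nrow(frame_stack)
  n_pre <- as.integer(round(-window[1] * frame_rate))
  n_post <- as.integer(round(window[2] * frame_rate))
  len <- n_pre + n_post + 1L
  acc <- matrix(0, len, ncol(frame_stack))
  n_events <- 0L
  for (tm in lick_times) {
    ctr <- as.integer(round(tm * frame_rate)) + 1L
    if (ctr - n_pre < 1L || ctr + n_post > n) next
    acc <- acc + frame_stack[(ctr - n_pre):(ctr + n_post), , drop = FALSE]
    n_events <- n_events + 1L
  }
  stop_if_not(n_events >= 1, "no lick with a full clip inside the stack")
  movie <- acc / n_events
  if (!is.null(img_dim)) dim(movie) <- c(len, img_dim)
  list(movie = movie, n_events = n_events,
       time_s = (seq_len(len) - 1L - n_pre) / frame_rate)
}
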