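#' Select intermediate-difficulty trials for decoding
#'
#' Finds the lowest sound level whose d-prime exceeds the threshold (1.5) and
#' keeps that level plus the two levels below and the two above it (by level
#' rank) — five levels when the anchor is interior; the window is truncated
#' with a warning at the edges of the level set. Stimulus trials outside the
#' selected levels are dropped; catch trials are never included.
#'
#' @param outcomes A `trial_outcomes` data.frame (lick-contaminated hits
#'   should already have been removed via `trial_subset`).
#' @param dprime_threshold Anchor threshold (default 1.5).
#' @param trial_subset Optional integer subset of rows to consider.
#' @return List: `trial_idx` (rows of `outcomes`), `levels` (selected dB),
#'   `anchor_level`, `dprime_table`.
#' @export
select_trials <- function(outcomes, dprime_threshold = 1.5,
                          trial_subset = NULL) {
  sub <- if (is.null(trial_subset)) outcomes else outcomes[trial_subset, ]
  ld <- level_dprime(sub)
  anchor <- which(ld$dprime > dprime_threshold)[1]
  if (is.na(anchor))
    stop("session excluded: no sound level exceeds the d-prime threshold",
         call. = FALSE)
  lo <- max(1L, anchor - 2L)
  hi <- min(nrow(ld), anchor + 2L)
  if (hi - lo + 1L < 5L)
    warning(sprintf("only %d levels available around the anchor", hi - lo + 1L))
  levels_sel <- ld$level_db[lo:hi]
  rows <- which(!outcomes$is_catch & outcomes$level_db %in% levels_sel)
  if (!is.null(trial_subset)) rows <- intersect(rows, trial_subset)
  list(trial_idx = rows, levels = levels_sel,
       anchor_level = ld$level_db[anchor], dprime_table = ld)
}

#' Session inclusion gate on per-class trial counts
#'
#' A session enters the decoding analysis only with at least `min_each`
#' (default 15) hit trials and at least `min_each` miss trials among the
#' selected trials.
#'
#' @param labels Character/factor outcome labels of the selected trials.
#' @param min_each Minimum count per class (default 15).
#' @return Logical.
#' @export
session_gate <- function(labels, min_each = 15) {
  sum(labels == "hit") >= min_each && sum(labels == "miss") >= min_each
}

#' Inverse-frequency class weights
#'
#' `W_i = N_T / (N_C * N_i)` with `N_T` total training trials, `N_C` classes,
#' `N_i` the class count, so the weighted class masses are equal and
#' `sum(W_i * N_i) = N_T`.
#'
#' @param labels Vector of class labels (both classes present).
#' @return List: `class_weights` (named per class), `trial_weights` (per
#'   element of `labels`), `counts`, `n_total`.
#' @export
class_weights <- function(labels) {
  counts <- table(labels)
  stop_if_not(length(counts) >= 2, "need both classes to compute weights")
  n_t <- length(labels)
  w <- n_t / (length(counts) * as.numeric(counts))
  names(w) <- names(counts)
  list(class_weights = w, trial_weights = unname(w[as.character(labels)]),
       counts = as.numeric(counts), n_total = n_t)
}

#' Balanced accuracy from confusion counts
#'
#' Arithmetic mean of the true-positive rate and the true-negative rate;
#' chance is 0.5 for any class imbalance.
#'
#' @param tp,fn,tn,fp Confusion counts (positives = hits).
#' @return Score in `[0, 1]`.
#' @export
balanced_accuracy <- function(tp, fn, tn, fp) {
  stop_if_not(all(c(tp, fn, tn, fp) >= 0), "counts must be non-negative")
  stop_if_not(tp + fn >= 1 && tn + fp >= 1,
              "each class needs at least one evaluated trial")
  0.5 * (tp / (tp + fn) + tn / (tn + fp))
}

# Balanced accuracy from truth/prediction vectors ("hit" = positive class).
balanced_accuracy_pred <- function(truth, pred, positive = "hit") {
  balanced_accuracy(tp = sum(truth == positive & pred == positive),
                    fn = sum(truth == positive & pred != positive),
                    tn = sum(truth != positive & pred != positive),
                    fp = sum(truth != positive & pred == positive))
}

# Stratified fold assignment: shuffle within class, deal folds round-robin.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Single L2 logistic fit (glmnet ridge at a fixed lambda) returning class
# predictions for Xte. glmnet needs >= 2 feature columns (a zero column is
# appended for 1-D input) and at least one non-constant predictor; when every
# training column has zero variance there is nothing to learn and the
# prediction falls back to a single class (balanced accuracy 0.5).
fit_predict_l2 <- function(Xtr, y01, weights, lambda, Xte) {
  if (all(apply(Xtr, 2, function(v) all(v == v[1])))) {
    return(rep(TRUE, nrow(Xte)))
  }
  if (ncol(Xtr) == 1L) { Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0) }
  # glmnet warns about classes with < 8 observations, routine for the small
  # inner CV folds used here
  fit <- suppressWarnings(
    glmnet::glmnet(Xtr, y01, family = "binomial", alpha = 0,
                   lambda = lambda, weights = weights, standardize = FALSE))
  as.numeric(stats::predict(fit, newx = Xte, type = "response")) > 0.5
}

#' Cross-validated single-frame decoder
#'
#' Class-weighted L2 logistic regression decoding hit vs miss from the
#' population activity vector at one frame. Outer loop: 5 stratified folds;
#' per outer split, an inner randomized search (default 25 draws from the
#' log-uniform distribution between 1e-4 and 1e2, inner 4 stratified folds)
#' selects the regularization strength by mean inner balanced accuracy; the
#' winning setting is refit on the four training folds and the held-out fold
#' is scored by balanced accuracy.
#'
#' @param X trials x neurons activity matrix at one frame.
#' @param labels `"hit"` / `"miss"` per trial.
#' @param seed Integer seed governing fold assignment and the random search.
#' @param n_folds Outer folds (default 5).
#' @param n_inner Inner folds (default 4).
#' @param n_draws Random-search draws (default 25).
#' @param c_range Range of the inverse regularization strength searched
#'   (default `c(1e-4, 1e2)`).
#' @return List: `fold_scores` (length `n_folds`), `mean_score`,
#'   `chosen_c` per fold.
#' @export
fit_frame_decoder <- function(X, labels, seed, n_folds = 5, n_inner = 4,
                              n_draws = 25, c_range = c(1e-4, 1e2)) {
  X <- as.matrix(X)
  stop_if_not(!anyNA(X), "activity matrix contains missing values")
  labels <- as.character(labels)
  stop_if_not(all(labels %in% c("hit", "miss")), "labels must be hit/miss")
  y01 <- as.integer(labels == "hit")

  with_seed_(seed, {
    fold <- stratified_folds(labels, n_folds)
    draws <- 10^stats::runif(n_draws, log10(c_range[1]), log10(c_range[2]))
    fold_scores <- numeric(n_folds)
    chosen_c <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(unique(labels[te])) < 2 || length(unique(labels[tr])) < 2)
        stop("stratification failed: a fold is missing a class", call. = FALSE)
      inner_fold <- stratified_folds(labels[tr], n_inner)
      inner_means <- vapply(draws, function(cc) {
        lam <- 1 / (cc * length(tr))
        sc <- vapply(seq_len(n_inner), function(g) {
          itr <- tr[inner_fold != g]; ite <- tr[inner_fold == g]
          if (length(unique(labels[ite])) < 2) return(NA_real_)
          w <- class_weights(labels[itr])$trial_weights
          pred <- fit_predict_l2(X[itr, , drop = FALSE], y01[itr], w, lam,
                                 X[ite, , drop = FALSE])
          balanced_accuracy_pred(labels[ite], ifelse(pred, "hit", "miss"))
        }, numeric(1))
        mean(sc, na.rm = TRUE)
      }, numeric(1))
      best <- which.max(inner_means)
      chosen_c[f] <- draws[best]
      w <- class_weights(labels[tr])$trial_weights
      pred <- fit_predict_l2(X[tr, , drop = FALSE], y01[tr], w,
                             1 / (draws[best] * length(tr)),
                             X[te, , drop = FALSE])
      fold_scores[f] <- balanced_accuracy_pred(labels[te],
                                               ifelse(pred, "hit", "miss"))
    }
    list(fold_scores = fold_scores, mean_score = mean(fold_scores),
         chosen_c = chosen_c)
  })
}

#' Stratified dummy baseline
#'
#' Predicts labels at random according to their empirical class frequencies
#' and scores each repeat by balanced accuracy; the expectation is 0.5
#' regardless of class imbalance.
#'
#' @param labels `"hit"` / `"miss"` per trial.
#' @param seed Integer seed.
#' @param n_repeats Repeats to average over (default 100).
#' @return List `mean_score`, `scores` (per repeat).
#' @export
dummy_decoder <- function(labels, seed, n_repeats = 100) {
  labels <- as.character(labels)
  stop_if_not(length(unique(labels)) == 2, "both classes must be present")
  p_hit <- mean(labels == "hit")
  scores <- with_seed_(seed, {
    vapply(seq_len(n_repeats), function(r) {
      pred <- ifelse(stats::runif(length(labels)) < p_hit, "hit", "miss")
      balanced_accuracy_pred(labels, pred)
    }, numeric(1))
  })
  list(mean_score = mean(scores), scores = scores)
}

#' Frame-by-frame decoding of a session
#'
#' Runs [fit_frame_decoder()] independently at every frame of the trial
#' window (each frame's population vector is the feature set — no temporal
#' pooling) and computes the stratified dummy baseline for the same labels.
#'
#' @param tensor A `trial_tensor`.
#' @param outcomes Matching `trial_outcomes`.
#' @param seed Integer seed (per-frame seeds are derived from it).
#' @param trial_idx Rows of `outcomes` to decode (e.g. from
#'   [select_trials()]); default: all kept stimulus trials that are hit/miss.
#' @param frames Frame indices within the window to decode (default all).
#' @param n_draws,dummy_repeats Passed through to the decoders.
#' @param min_each Session gate (default 15; set lower only for toy runs).
#' @return A `decoding_result` list: `frame_time`, `trained` (per decoded
#'   frame), `fold_scores` (frames x folds), `dummy`, `n_rois`, `n_hit`,
#'   `n_miss`, `frames`.
#' @export
decode_session <- function(tensor, outcomes, seed, trial_idx = NULL,
                           frames = NULL, n_draws = 25, dummy_repeats = 100,
                           min_each = 15) {
  if (is.null(trial_idx)) {
    lab_all <- outcomes$outcome[tensor$kept_trials]
    trial_idx <- tensor$kept_trials[lab_all %in% c("hit", "miss")]
  }
  rows <- which(tensor$kept_trials %in% trial_idx)
  labels <- outcomes$outcome[tensor$kept_trials[rows]]
  stop_if_not(all(labels %in% c("hit", "miss")),
              "selected trials must be hit or miss trials")
  stop_if_not(session_gate(labels, min_each),
              sprintf("session gate failed: need >= %d hits and misses", min_each))
  n_frames <- dim(tensor$values)[3]
  if (is.null(frames)) frames <- seq_len(n_frames)
  frame_time <- (seq_len(n_frames) - tensor$onset_index) / tensor$frame_rate

  trained <- numeric(length(frames))
  fold_scores <- matrix(NA_real_, length(frames), 5)
  for (k in seq_along(frames)) {
    Xf <- tensor$values[rows, , frames[k], drop = TRUE]
    if (is.null(dim(Xf))) Xf <- matrix(Xf, ncol = 1)
    fit <- fit_frame_decoder(Xf, labels, seed = seed + frames[k],
                             n_draws = n_draws)
    trained[k] <- fit$mean_score
    fold_scores[k, ] <- fit$fold_scores
  }
  dum <- dummy_decoder(labels, seed = seed, n_repeats = dummy_repeats)
  structure(list(frame_time = frame_time[frames], trained = trained,
                 fold_scores = fold_scores,
                 dummy = rep(dum$mean_score, length(frames)),
                 n_rois = dim(tensor$values)[2],
                 n_hit = sum(labels == "hit"), n_miss = sum(labels == "miss"),
                 frames = frames, seed = seed),
            class = "decoding_result")
}

#' Linear interpolation of an accuracy timecourse to a common length
#'
#' @param x Numeric series (length >= 2).
#' @param target_len Output length (>= 2).
#' @return Numeric vector of length `target_len`; endpoints preserved.
#' @export
interpolate_timecourse <- function(x, target_len) {
  resample_linear(x, target_len)
}

#' Spearman correlation of decoding accuracy with ROI count
#'
#' For each 1-s window of the trial period, correlates the windowed mean
#' accuracy with the number of ROIs across sessions (Spearman). Constant
#' inputs make rho undefined; such windows are flagged.
#'
#' @param n_rois Integer vector, one per session.
#' @param accuracy sessions x frames matrix of decoding accuracy.
#' @param frame_time Frame times (seconds relative to onset), length =
#'   `ncol(accuracy)`.
#' @param window_s Window width (default 1).
#' @return data.frame `win_lo`, `win_hi`, `rho`, `p_value`, `flagged`.
#' @export
roi_count_correlation <- function(n_rois, accuracy, frame_time, window_s = 1) {
  stop_if_not(length(n_rois) >= 4, "need at least 4 sessions")
  stop_if_not(nrow(accuracy) == length(n_rois), "one accuracy row per session")
  lo_edges <- seq(min(frame_time), max(frame_time), by = window_s)
  lo_edges <- lo_edges[lo_edges < max(frame_time)]
  rows <- lapply(lo_edges, function(lo) {
    cols <- which(frame_time >= lo & frame_time < lo + window_s)
    if (!length(cols)) return(NULL)
    m <- rowMeans(accuracy[, cols, drop = FALSE])
    if (stats::sd(m) == 0 || stats::sd(n_rois) == 0) {
      return(data.frame(win_lo = lo, win_hi = lo + window_s, rho = NA_real_,
                        p_value = NA_real_, flagged = TRUE))
    }
    ct <- suppressWarnings(stats::cor.test(n_rois, m, method = "spearman"))
    data.frame(win_lo = lo, win_hi = lo + window_s,
               rho = unname(ct$estimate), p_value = ct$p.value, flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' Decoding control with a matched number of neurons
#'
#' Repeats the session decode with `target_n` randomly drawn neurons,
#' averaging over `n_draws` draws, to test whether group differences merely
#' reflect population size.
#'
#' @param tensor A `trial_tensor`.
#' @param outcomes Matching `trial_outcomes`.
#' @param target_n Neurons per draw (>= 2).
#' @param n_draws Subsample draws (default 5).
#' @param seed Integer seed.
#' @param ... Passed to [decode_session()].
#' @return List `trained` (mean over draws, per decoded frame), `per_draw`
#'   (draws x frames), plus the frame axis of the first draw.
#' @export
subsample_neurons_control <- function(tensor, outcomes, target_n, n_draws = 5,
                                      seed = 1, ...) {
  n <- dim(tensor$values)[2]
  stop_if_not(target_n >= 2, "target_n must be >= 2")
  stop_if_not(target_n <= n, "target_n exceeds the ROI count")
  picks <- with_seed_(seed, {
    lapply(seq_len(n_draws), function(d) sort(sample(n, target_n)))
  })
  # the CV seed is shared across draws, so drawing the full population
  # reproduces the full-population result exactly
  res <- lapply(seq_len(n_draws), function(d) {
    sub <- tensor
    sub$values <- tensor$values[, picks[[d]], , drop = FALSE]
    decode_session(sub, outcomes, seed = seed, ...)
  })
  per_draw <- do.call(rbind, lapply(res, `[[`, "trained"))
  list(trained = colMeans(per_draw), per_draw = per_draw,
       frame_time = res[[1]]$frame_time)
}

#' Decoding control with sound-level-matched hit/miss sets
#'
#' Equalizes hit and miss counts at every sound level (via
#' [balanced_subsample()]) before decoding, removing any sound-level confound
#' between the classes. Skipped (with a message) when the session gate fails
#' after matching.
#'
#' @param tensor A `trial_tensor`.
#' @param outcomes Matching `trial_outcomes`.
#' @param seed Integer seed.
#' @param trial_idx Optional pre-selected rows of `outcomes` to match within.
#' @param min_each Session gate after matching (default 15).
#' @param ... Passed to [decode_session()].
#' @return A `decoding_result`, or `NULL` when the gate fails after matching.
#' @export
level_matched_control <- function(tensor, outcomes, seed, trial_idx = NULL,
                                  min_each = 15, ...) {
  oc <- if (is.null(trial_idx)) outcomes else outcomes[trial_idx, , drop = FALSE]
  keep_rows <- tryCatch(balanced_subsample(oc, seed), error = function(e) integer(0))
  if (!length(keep_rows)) {
    message("level-matched control skipped: session gate failed after matching")
    return(NULL)
  }
  matched_idx <- if (is.null(trial_idx)) keep_rows else trial_idx[keep_rows]
  labels <- outcomes$outcome[intersect(tensor$kept_trials, matched_idx)]
  if (!session_gate(labels, min_each)) {
    message("level-matched control skipped: session gate failed after matching")
    return(NULL)
  }
  decode_session(tensor, outcomes, seed = seed, trial_idx = matched_idx,
                 min_each = min_each, ...)
}
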