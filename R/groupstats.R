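#' Normality gate for choosing parametric vs nonparametric tests
#'
#' Shapiro-Wilk at alpha = 0.05 decides the test family: parametric when the
#' sample (for paired comparisons, the paired differences) is compatible with
#' normality. Degenerate samples (constant, or n outside the test's support)
#' fall back to nonparametric.
#'
#' @param x Numeric sample (n >= 3).
#' @param alpha Gate level (default 0.05).
#' @return Logical: `TRUE` = use a parametric test. The Shapiro p-value is
#'   attached as attribute `p`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  stop_if_not(length(x) >= 3, "normality gate needs n >= 3")
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  if (is.na(p)) {
    message("normality gate: degenerate sample, falling back to nonparametric")
    return(structure(FALSE, p = NA_real_))
  }
  structure(p >= alpha, p = p)
}

# One-sided location test of x > 0 (paired differences), gated by normality.
paired_one_sided <- function(d) {
  if (all(d == 0)) return(list(test = "signed-rank", p = 1))
  if (isTRUE(as.logical(normality_gate(d)))) {
    list(test = "paired-t",
         p = stats::t.test(d, alternative = "greater")$p.value)
  } else {
    list(test = "signed-rank",
         p = suppressWarnings(
           stats::wilcox.test(d, alternative = "greater")$p.value))
  }
}

#' Timewise comparison of trained decoders against their dummy baselines
#'
#' Per frame, a one-sided paired test of trained > dummy across sessions
#' (paired t-test when the paired differences pass the normality gate,
#' Wilcoxon signed-rank otherwise), Bonferroni-corrected over the number of
#' tested frames.
#'
#' @param trained sessions x frames matrix of cross-validated accuracies.
#' @param dummy Matching matrix (or per-session vector, recycled over frames).
#' @param frame_time Optional frame times for the output.
#' @param alpha Familywise level (default 0.05).
#' @return A `timecourse_comparison` data.frame: `frame`, `frame_time_s`,
#'   `test_used`, `p_raw`, `significant` (p_raw < alpha / m).
#' @export
compare_to_dummy <- function(trained, dummy, frame_time = NULL, alpha = 0.05) {
  trained <- as.matrix(trained)
  if (is.null(dim(dummy)) || length(dummy) == nrow(trained))
    dummy <- matrix(dummy, nrow(trained), ncol(trained))
  stop_if_not(all(dim(trained) == dim(dummy)),
              "trained and dummy scores must be paired by session")
  stop_if_not(nrow(trained) >= 5, "need at least 5 sessions")
  m <- ncol(trained)
  res <- lapply(seq_len(m), function(f) {
    tst <- paired_one_sided(trained[, f] - dummy[, f])
    data.frame(frame = f,
               frame_time_s = if (is.null(frame_time)) NA_real_ else frame_time[f],
               test_used = tst$test, p_raw = tst$p,
               significant = tst$p < alpha / m)
  })
  out <- do.call(rbind, res)
  class(out) <- c("timecourse_comparison", "data.frame")
  out
}

#' Timewise comparison of decoding accuracy between groups
#'
#' Per (optionally binned) frame, a one-sided two-sample test of group A >
#' group B: Student's t-test when both groups pass the normality gate,
#' Mann-Whitney U otherwise; Bonferroni over the number of tested points
#' (binning by `bin` consecutive frames reduces that number and so loosens
#' the per-test level).
#'
#' @param scores_a,scores_b sessions x frames matrices for the two groups.
#' @param bin Consecutive frames averaged before testing (default 1).
#' @param frame_time Optional frame times (binned by averaging too).
#' @param alpha Familywise level (default 0.05).
#' @return A `timecourse_comparison` data.frame as in [compare_to_dummy()].
#' @export
compare_groups <- function(scores_a, scores_b, bin = 1, frame_time = NULL,
                           alpha = 0.05) {
  scores_a <- as.matrix(scores_a); scores_b <- as.matrix(scores_b)
  stop_if_not(nrow(scores_a) >= 3 && nrow(scores_b) >= 3,
              "each group needs at least 3 sessions")
  stop_if_not(ncol(scores_a) == ncol(scores_b), "frame axes differ")
  bin_cols <- function(M) {
    if (bin <= 1) return(M)
    n_bins <- floor(ncol(M) / bin)
    vapply(seq_len(n_bins), function(b) {
      rowMeans(M[, ((b - 1) * bin + 1):(b * bin), drop = FALSE])
    }, numeric(nrow(M)))
  }
  A <- bin_cols(scores_a); B <- bin_cols(scores_b)
  ft <- if (is.null(frame_time)) NULL else {
    if (bin <= 1) frame_time else
      vapply(seq_len(floor(length(frame_time) / bin)), function(b) {
        mean(frame_time[((b - 1) * bin + 1):(b * bin)])
      }, numeric(1))
  }
  m <- ncol(A)
  res <- lapply(seq_len(m), function(f) {
    a <- A[, f]; b <- B[, f]
    parametric <- isTRUE(as.logical(normality_gate(a))) &&
      isTRUE(as.logical(normality_gate(b)))
    if (parametric) {
      p <- stats::t.test(a, b, alternative = "greater")$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "greater")$p.value)
      test <- "mann-whitney"
    }
    data.frame(frame = f,
               frame_time_s = if (is.null(ft)) NA_real_ else ft[f],
               test_used = test, p_raw = p, significant = p < alpha / m)
  })
  out <- do.call(rbind, res)
  class(out) <- c("timecourse_comparison", "data.frame")
  out
}
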