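#' @importFrom stats approx dnorm pnorm qnorm rnorm runif rbinom rbeta rpois
#' @importFrom stats median prcomp kmeans dist p.adjust wilcox.test t.test
#' @importFrom stats shapiro.test prop.test cor.test plogis sd quantile rexp
NULL

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Linear resampling of a trace to a fixed length
#'
#' Resamples a numeric vector to exactly `L` points by linear interpolation
#' over its index range. The first and last samples are preserved exactly;
#' if the input already has length `L` it is returned unchanged.
#'
#' @param x Numeric vector (length >= 2).
#' @param L Target length (>= 2).
#' @return Numeric vector of length `L`.
#' @export
resample_linear <- function(x, L) {
  stop_if_not(length(x) >= 2, "resample_linear() needs at least 2 samples")
  stop_if_not(is.numeric(L) && L >= 2, "target length must be >= 2")
  if (length(x) == L) return(as.numeric(x))
  stats::approx(seq_along(x), x, xout = seq(1, length(x), length.out = L))$y
}

# Gaussian smoothing with edge replication; sigma in samples.
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(as.numeric(x))
  half <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(y)[(half + 1L):(half + n)]
}

# Running min/max over a centred window of `w` samples (monotonic-deque,
# O(n); w is clamped to the trace length).
running_extreme <- function(x, w, what = c("min", "max")) {
  what <- match.arg(what)
  n <- length(x)
  stop_if_not(n >= 1, "empty trace")
  w <- min(as.integer(w), n)
  if (w <= 1) return(as.numeric(x))
  half <- w %/% 2L
  keep <- if (what == "min") function(a, b) a <= b else function(a, b) a >= b
  out <- numeric(n)
  dq <- integer(n)
  head_i <- 1L; tail_i <- 0L; j <- 0L
  for (i in seq_len(n)) {
    hi <- min(n, i + half)
    while (j < hi) {
      j <- j + 1L
      while (tail_i >= head_i && keep(x[j], x[dq[tail_i]])) tail_i <- tail_i - 1L
      tail_i <- tail_i + 1L
      dq[tail_i] <- j
    }
    lo <- max(1L, i - half)
    while (dq[head_i] < lo) head_i <- head_i + 1L
    out[i] <- x[dq[head_i]]
  }
  out
}

# Evaluate an expression under a fixed RNG seed without disturbing the
# caller's RNG state; seed = NULL uses the current stream.
with_seed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Truncated-normal sampler (lower truncation) by rejection, so the
# distribution is the exact conditional law, not a clipped normal.
rtruncnorm_lower <- function(n, mean, sd, lower) {
  stop_if_not(n >= 0, "n must be non-negative")
  if (sd == 0) {
    stop_if_not(mean >= lower, "degenerate sampler: mean below the floor")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(max(n - length(out), 1L) * 2L, mean, sd)
    out <- c(out, draw[draw >= lower])
  }
  out[seq_len(n)]
}

# Density of the lower-truncated normal.
dtruncnorm_lower <- function(x, mean, sd, lower) {
  z <- 1 - stats::pnorm(lower, mean, sd)
  ifelse(x < lower, 0, stats::dnorm(x, mean, sd) / z)
}
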