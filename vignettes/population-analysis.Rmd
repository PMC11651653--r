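---
title: "Methods: from fluorescence traces to population decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence traces to population decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonogoCa)
```

This vignette documents the models and procedures implemented in `gonogoCa`,
the assumptions behind them, the tunable parameters and their defaults, and
the design decisions taken where the methodology left genuine freedom. It is
the package's own account of its science; every number shown here is
computed by the code in this document or by the test suite.

## The experimental setting being modelled

A head-fixed mouse performs a go/no-go click-detection task under a
two-photon microscope. Trials are stimulus trials (a brief click at one of
several sound levels, dB SPL) or catch trials (no stimulus), randomly
interleaved. Licking within a response window (default 1.5 s) after a
stimulus scores a *hit* and triggers reward; not licking scores a *miss*.
On catch trials a lick is a *false alarm*, silence a *correct rejection*.
Inter-trial intervals follow a normal distribution with mean 8 s and SD 2 s,
truncated below at 3 s. Imaging runs at roughly 28 Hz, so the −2 s … +5 s
trial window holds 193–197 frames depending on the exact frame rate.

## The synthetic-session generator

The generator exists so that every downstream stage can be validated against
known ground truth. Its defaults *are* the study conditions above; they are
configurable but not meant to be tuned per analysis.

**Trial schedule.** Inter-trial intervals are drawn by rejection sampling
from the truncated normal — not by clipping draws to the floor, which would
pile mass at 3 s and bias the mean upward of the true truncated expectation
(≈ 8.035 s for the default parameters). Catch trials are interleaved
per-trial with probability 0.1 ("approximately one tenth"), and each
stimulus trial carries one level drawn uniformly from the configured level
set (default 35–75 dB SPL in 5-dB steps, nine levels).

**Behaviour.** The response probability on a stimulus trial at level $x$ is

$$p(x) = \gamma + (1 - \gamma - \lambda)\,\sigma(k(x - m)),$$

with false-alarm rate $\gamma$ (also the catch-trial response probability),
lapse rate $\lambda$, slope $k$ and midpoint $m$; $\sigma$ is the logistic
function. The sigmoid form itself is a modelling convenience — the analysis
code never assumes it. Response-lick latencies are bounded below by the
animals' lick-latency floor (120 ms) and drawn from a scaled Beta
distribution inside the response window. Anticipatory licking is an
inhomogeneous Poisson process after each trial whose intensity follows the
truncated-normal ITI density, emulating animals that have learned the
schedule statistics; its tail is deliberately *not* truncated at the next
trial onset, so the peri-event lick rate reproduces the full ITI density
shape. Anticipatory licks that would land inside any trial's response
window are discarded — this keeps the parameterised hit and false-alarm
probabilities exact, at the cost of a small notch in the lick-rate curve.

**Neural traces.** Each neuron is assigned one prototype specifying hit- and
miss-trial drive over the trial window plus an optional pre-stimulus state
gain (extra drive before onset on hit trials, emulating anticipatory
network-state coding). The drive is convolved with a single-exponential
calcium impulse response, τ = 0.5 s (GCaMP6f-like; the analysis makes no
kinetic assumptions, so the exact τ only shapes realism). Fluorescence is

$$F_j(t) = B_j\,\bigl(1 + s_j(t) + d_j(t) + \varepsilon_j(t)\bigr) + r\,F^{neu}_j(t),$$

with per-neuron baseline $B_j$, drift $d_j$ (slow sinusoid), white noise
$\varepsilon_j$, and a shared slowly varying neuropil channel mixed in with
coefficient $r$ (default 0.7) — the same coefficient the conditioning step
subtracts, so correction is exact by construction when both agree. The
default prototype set contains four motifs: sharp short-latency facilitation
(stronger on hits), suppression on hits, a behaviour-invariant onset
response (hit and miss kernels identical — the control case the modulation
test must *not* flag), and a slow ramp peaking seconds into the trial.
Ground truth (prototype identity, outcome-coding flag, seed) is recorded
with every session, and regeneration from the same seed is bit-identical.

The generator does **not** emulate: correlated noise across neurons, motion
artifacts, z-drift, nonlinear indicator saturation, session-to-session
neuron identity, or learning within a session. Passing tests on synthetic
sessions therefore demonstrate correctness of the *analysis* under the
stated statistical structure, not robustness to every nuisance of real
recordings.

## Signal conditioning

1. `neuropil_correct()`: $F - r F^{neu}$, $r = 0.7$.
2. `compute_dff()`: ΔF/F against the whole-trace median as F0. ROIs with a
   non-positive median cannot be normalised and are excluded with a warning.
3. `remove_slow_baseline()`: baseline = max-filter(min-filter(Gaussian
   filter(trace))), then subtracted. Defaults: Gaussian σ = 10 s, min/max
   windows 60 s — common defaults of the suite2p ecosystem; only the
   operator sequence is fixed, the windows are configurable.
4. `extract_trials()`: time 0 maps to the first frame with timestamp ≥ the
   onset (half-open convention; the alternative — nearest frame — shifts
   alignment by at most half a frame). Trials whose window leaves the
   recording are dropped, not padded, and reported.
5. `outcome_averages()`: hit and miss trial averages per neuron, linearly
   resampled to L = 193 points (endpoints preserved), then concatenated to
   2L = 386 features for clustering.

Motion QC (`zmotion_pc_check()`, `lick_triggered_movie()`) returns scores
and average movies; exclusion thresholds are left to the user because the
corresponding decisions are inherently visual.

## Behavioural statistics

`dprime()` applies the log-linear correction (add 0.5 to every cell) so
sessions with perfect or empty cells stay finite; the choice matters only at
extreme rates and is documented rather than inferred. Per-level and
per-bin d′ reuse the session-wide false-alarm pool, since catch trials carry
no level. Psychometric bins are 10 dB wide and anchored at the lowest level
used in the session, with the top edge of the last bin closed.

## Per-neuron modulation statistics

Response magnitude per trial is mean ΔF/F over the 5 s after onset minus the
mean over the 2 s before. Hit/miss comparisons use a two-sided Mann–Whitney
U test ("significant difference" without a stated direction implies
two-sided) on sound-level-balanced trials: per level, the more frequent
outcome is randomly downsampled (without replacement) to the rarer one.
One balanced draw is taken per session with a logged seed and shared by all
neurons — the subsample is a set of *trials*, so per-neuron draws would add
variance without independence. Sound-evoked responses are tested on miss
trials at 53–65 dB SPL (higher levels are rarely missed) with a Wilcoxon
signed-rank test pairing the 2-s pre-mean with the 1-s post-mean; with
exact small-sample tails the two-sided p-value cannot go below $2/2^n$, so
at least ~11 pairs are needed to clear p < 0.001. Both families are
corrected by Benjamini–Hochberg at q = 0.05. Minimum trial counts (3 per
group for the U test, 5 pairs for the signed-rank) are configurable guards.

## Clustering

PCA (column-centred, unscaled) reduces the 386-feature profiles; the default
9 components follow the scree-elbow reasoning, and `pca_reduce()` reports an
advisory elbow (largest second difference of the scree) without acting on
it. Spectral clustering builds a kNN graph (union symmetrization: an edge
exists if either point lists the other), embeds with the eigenvectors of the
symmetric normalized Laplacian belonging to the smallest eigenvalues (rows
renormalized), and partitions with seeded k-means. A graph with more
connected components than requested clusters raises an error suggesting more
neighbours. The silhouette is computed **in the same space the clustering
ran in** (the PCA score space) — computing it in the raw feature space is
equally defensible but would select hyperparameters by a criterion the
algorithm never saw; the choice is configurable by passing a different
matrix. Singleton clusters get $s_i = 0$ (the standard convention; the
formula is undefined there). The grid search (defaults: neighbours 5–50 in
steps of 5, clusters 2–15) maximizes mean silhouette with ties broken toward
fewer clusters, then fewer neighbours — reproducibility over arbitrariness.
Cluster composition is tested per cluster with a two-sided one-proportion Z
test against the population lesioned fraction, and displayed as the
normalized proportion $(p/p_0)\,/\,(p/p_0 + (1-p)/(1-p_0))$, which is 0.5
when the cluster mirrors the population.

## Decoding

Only intermediate-difficulty trials enter: the anchor is the lowest sound
level with d′ > 1.5 and the window is anchor ± 2 level ranks (five levels;
truncated with a warning at the edges). Sessions need ≥ 15 hits and ≥ 15
misses. Each frame is decoded independently from the single-frame population
vector — no temporal windowing, matching the frame-by-frame design. The
model is L2 logistic regression with class weights
$W_i = N_T/(N_C N_i)$ applied to the training loss. Cross-validation is
5-fold stratified outer; per outer split an inner 4-fold stratified
randomized search (25 draws from the log-uniform distribution between 1e-4
and 1e2) selects the inverse regularization strength $C$ by mean inner
balanced accuracy, the winner is refit on the four training folds, and the
held-out fold is scored by balanced accuracy; the session score is the mean
of the five folds. The drawn $C$ maps to the ridge penalty as
$\lambda = 1/(C N)$, i.e. $C$ scales the per-sample loss. Inner fold count
and draw count are package choices, configurable and logged. If every
training predictor has zero variance there is nothing to learn and the
decoder predicts a single class, which scores exactly 0.5. Dummy baselines
predict labels at their empirical class probabilities (100 seeded repeats by
default); their expected balanced accuracy is 0.5 at any imbalance, which is
what makes them a calibrated chance reference. Controls: neuron
subsampling at a matched population size (the CV seed is shared across
draws, so drawing the full population reproduces the full result exactly),
sound-level-matched hit/miss sets (reusing the balanced subsample), and the
Spearman correlation between ROI count and windowed mean accuracy.

## Timewise group statistics

Comparisons across the trial timecourse are made per frame after linear
interpolation to a common frame count (endpoints preserved). The
Shapiro–Wilk test at p < 0.05 gates parametric vs nonparametric: for paired
comparisons the gate is applied to the paired differences; for unpaired
comparisons both groups must pass, and if either fails (including degenerate
constant samples, where Shapiro is undefined) the nonparametric test is
used. Trained-vs-dummy uses a one-sided paired t-test or Wilcoxon
signed-rank (trained > dummy); group comparisons use a one-sided t-test or
Mann–Whitney U. Significance is p < 0.05 Bonferroni-corrected over the
number of tested (binned) timepoints within the −2 … +5 s window; binning
by two reduces the family size and accordingly loosens the per-test level,
which is the intended behaviour for small cohorts.

## Numerical choices and degenerate inputs

* Running min/max filters use a monotonic-deque algorithm (exact, O(n));
  Gaussian smoothing replicates edge values.
* Identical hit and miss samples return p = 1 from the rank tests; all-zero
  paired differences likewise.
* `sample()`-style index pitfalls with length-one level sets are avoided by
  explicit `sample.int` indexing.
* All stochastic operations take an explicit seed and restore the caller's
  RNG state; per-frame decoder seeds are derived as seed + frame index.
* The session bundle is plain text (CSV matrices, CSV tables, JSON ground
  truth, YAML parameters), chosen for portability and diff-ability;
  matrices round-trip at full double precision.

## Problem sizes used by the test suite

The suite validates calibration properties at sizes chosen to keep the
statistics meaningful: schedule statistics on 10,000–30,000 intervals;
familywise-error and type-I-error simulations at 2,000 replicates;
decoder null calibration over 30 independent 40-trial problems; cluster
recovery at 20 neurons per planted prototype for K ∈ {3, 5, 10}; end-to-end
sessions of 60–120 trials and 8–40 neurons. These are the package's own
validation sizes; the functions themselves have no built-in scale limits
beyond memory.

## Known limitations

* The generator's independence assumptions (noise independent across
  neurons and trials) make decoding easier than in real data, where shared
  variability both helps and hurts; planted-signal recovery rates here are
  upper bounds.
* Silhouette-selected cluster counts on real, continuous response
  distributions are descriptive, not evidence of discrete cell types.
* The decoder is linear by design; above-chance pre-stimulus accuracy
  indicates linearly decodable state differences, nothing more specific.
* Lesion-extent estimation, image registration, ROI segmentation and spike
  inference are out of scope; the pipeline consumes extracted traces.
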