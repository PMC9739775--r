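---
title: "How epiwindow evaluates the EEG epoching window length"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How epiwindow evaluates the EEG epoching window length}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(epiwindow)
```

## The question the package answers

When a continuous EEG recording is cut into fixed-length epochs for
classification, the epoch (window) length is a free parameter with real
consequences: windows that are too short may miss the waveforms that
characterize a brain state, while windows that are too long mix states
and starve the classifier of training examples. `epiwindow` implements
a complete evaluation pipeline for this trade-off on the five-class
Z/O/N/F/S epilepsy problem (healthy eyes-closed / eyes-open, interictal
opposite-hemisphere / epileptogenic-zone, and ictal recordings): epochs
with 50% overlap are cut at window lengths of 1-24 s, a 7-dimensional
feature vector is extracted per epoch, and four classifiers are scored
by repeated stratified 10-fold cross-validation.

## Pipeline and model

**Preprocessing.** Each recording is low-pass filtered at 40 Hz with a
linear-phase FIR filter before epoching. The design is a
Hamming-windowed sinc with 101 taps, renormalized to exact unit DC
gain; filtering uses reflection padding and compensates the
`(n_taps - 1)/2`-sample group delay so epochs are time-aligned with the
raw signal. The filter order and design are configurable; 101 taps at
the Bonn rate gives a transition band comfortably inside the
40-86.8 Hz range. Windows are half-open `[start, start + w)` with
`w = round(window_s * fs)` and hop `floor(w * (1 - overlap))`; partial
tail windows are discarded rather than padded, because features such as
the variance are window-length sensitive and padding would bias them.
A nominal window up to 2 s longer than the recording clamps to the full
duration, so the 24 s sweep entry maps to the actual 23.6 s recordings.

**Features.** Per epoch: mean, median, population variance (divide by
`n`; a descriptive statistic, which also makes tests exact), and one
spectrum amplitude per EEG band - delta `[1,4)`, theta `[4,8)`, alpha
`[8,12)`, beta `[12,25)` Hz, half-open so shared edges are counted
once. Band amplitude is the *mean* one-sided FFT magnitude over the
band's bins: a sum would scale with the bin count and hence with the
window length, confounding the central comparison. The FFT is taken on
the raw epoch without tapering or detrending (both config-exposed
alternatives); a consequence worth knowing is that an off-bin sinusoid
leaks a sinc skirt into neighbouring bands, so band dominance ratios
for random in-band tones are typically 5-10x rather than the orders of
magnitude a bin-centred tone gives. No standardization happens at
feature time: z-scoring is done inside cross-validation from
training-fold statistics only, so test folds never leak into the
transform.

**Classifiers.** The network is a single-hidden-layer sigmoid net,
7 inputs, 10 hidden units, 5 outputs (135 weights including biases),
with sum-of-squared-error loss against one-hot targets; predictions are
the output argmax with ties to the lowest class index. The trainers
are:

* **BFGS** with Armijo backtracking. The direction solves
  `B d = -g` by Cholesky factorization (never forming the inverse);
  updates that fail the curvature condition `s'y > 0` are skipped so
  `B` stays positive definite; the stop rule is a `1e-6` gradient
  norm.
* **Multistart**: uniform starting points refined by BFGS, collecting
  distinct local minima (two minima are "the same" within `1e-3` in x
  and `1e-6` in f) and returning the best.
* A **modified real-coded GA**: tournament selection (size 4),
  arithmetic crossover with per-component coefficient in
  `[-0.5, 1.5]`, annealed non-uniform mutation
  (`Delta(iter, y) = y (1 - r^(1 - iter/itermax))`, so mutation decays
  to zero at the final generation), replacement of the `m` worst by
  offspring, a trial point `(1 + gamma) best - gamma y` with `gamma`
  in `[-0.5, 0.5]` accepted only if it beats the worst member, a BFGS
  local search from the best member every `Kls` generations, and the
  stopping rule "best-to-worst fitness spread at most `e`".
* **K-NN** with `K = 2` and Euclidean distance, exhaustive search
  (exactness over speed at these sizes). A split 1-1 vote falls to the
  label of the single nearest neighbour - this makes K = 2 behave as
  distance-weighted 1-NN on ties - and equal distances fall to the
  lowest training index. Per-class scores (fraction of the K
  neighbours per label) feed the threshold metrics.

**Scoring.** Accuracy is correct-over-total, averaged over folds and
then over repeats; each repeat draws a fresh stratified fold split from
its own derived seed. Cohen's kappa is computed on the confusion
matrix pooled over the folds of a repeat, then averaged over repeats,
mirroring the fold-then-repeat averaging of accuracy. AUROC and AUPRC
are macro one-vs-rest with trapezoidal integration (micro averaging
was the other candidate; macro is the symmetric default for a balanced
design). Folds are assigned at the epoch level by default, which
matches the protocol the sweep emulates but lets overlapping epochs of
one recording appear in both training and test folds; a
recording-level grouping mode is provided for leakage-free estimates,
and the difference between the two is itself informative.

## Numerical choices that mattered

Sigmoid networks trained by sum-of-squares have saturated plateaus -
most notoriously the all-outputs-zero attractor that one-hot targets
create (four of five targets are 0). A full-length first BFGS step
(`B = I`, step `-g`) routinely jumps onto such a plateau and the
gradient-based iteration never leaves it; the reference `stats::optim`
BFGS shows the same behaviour on this objective. Three safeguards make
the trainers dependable:

* the first trial step on a fresh Hessian model is `min(s, 1/||g||)`;
* the network-training route uses a conservative Armijo initial step
  (`s = 0.1`) and small initial weights (`U[-0.2, 0.2]`), keeping the
  units in their responsive range early on;
* multistart keeps the best point of local searches that stop at the
  iteration cap (the `1e-6` gradient norm is rarely reachable on this
  surface), while its *reported distinct minima* remain
  converged-points-only.

The generic weight box is `[-10, 10]` per weight. For the shipped
desk-scale study the search regions are deliberately smaller: uniform
samples over the full box are almost surely deeply saturated (the
pre-activation of a hidden unit is a sum of seven `U[-10,10]`-weighted
z-scored features), so multistart draws its starting points from
`[-0.5, 0.5]` (local searches still roam the full box) and the GA
evolves inside `[-2, 2]`. These are initialization/search-region
choices, not constraints on the representable networks a practitioner
would care about at this scale.

## What the synthetic generator emulates - and what it does not

`synthetic_config()` ships two five-class profiles with the Bonn
geometry (100 recordings per class by default, 23.6 s at 173.61 Hz).
Each class is a sum of four band-limited sinusoids (frequency redrawn
per recording inside its band, so classifiers must separate classes at
the band level rather than keying on one FFT bin), white Gaussian
noise, and Poisson-timed transient spikes shaped as 3-cycle damped
oscillations 3-100 ms wide - wide enough to partially survive the
40 Hz low-pass, as real epileptiform sharp waves do. In both profiles
the ictal class S has at least 5x the variance of every other class.

* The **separable** profile gives each class a dominant rhythm
  (Z alpha, O beta, N theta, F delta) with low noise plus a
  high-amplitude spiking S. It is the parameter-recovery condition:
  classifiers should approach perfect accuracy at long windows, and
  failures indicate pipeline defects rather than hard data.
* The **noisy** profile makes the window length matter. A stationary
  sinusoid-plus-noise class structure turns out *not* to favour long
  windows in these features: the band-mean amplitude's signal term and
  its noise fluctuation both end up window-length independent (the
  coherent gain `n`, the noise magnitude `sqrt(n)` and the band bin
  count `n` cancel), so short windows would simply win through epoch
  abundance. What genuinely requires long windows is estimating the
  *rate* of transient events. The noisy profile therefore pairs
  classes that share a band profile and differ in spike rate (Z/O at
  0 vs 0.8 events/s, N/F at 0.2 vs 1.8): a 1 s epoch contains a spike
  essentially at random, while a 21 s epoch sees a stable count. This
  is the synthetic analogue of short windows failing to capture the
  characteristic waveforms of a condition.

What the generator does **not** emulate: 1/f background spectra,
amplitude nonstationarity beyond spikes, inter-channel structure,
artefacts, or patient-level heterogeneity. Passing the shipped
recovery checks therefore demonstrates that the pipeline measures what
it should under controlled conditions - not that any particular
accuracy level will transfer to clinical EEG.

## Study sizes used by the shipped checks

The acceptance workflow runs the full protocol at desk scale: 10
recordings per class, windows {1, 8, 21} s, 10-fold cross-validation
repeated 3 times (the full 30-repeat protocol is one config value
away), with `study_method_config()` budgets - GA population 50 over 60
generations with local search every 20, 8 multistart launches capped
at 150 BFGS iterations each, single-start BFGS capped at 300. On the
separable profile every classifier reaches at least 0.90 mean accuracy
at the 21 s window, and on the noisy profile K-NN accuracy at 1 s is
strictly below its 21 s value. The direction of that contrast was
verified across eight independent master seeds when the profile was
frozen.

## Degenerate inputs and edge rules

* Windows longer than the recording by more than 2 s yield no epochs
  (warning); the sweep marks such cells unavailable and continues.
* A band with no FFT bins (very short windows at low rates) scores 0
  with a warning rather than NaN.
* Constant feature columns get unit scale in z-scoring.
* `cohen_kappa` returns `NaN` for degenerate marginals (`p_e = 1`).
* Classes with fewer epochs than folds abort evaluation with the
  class named.

## Known limitations

* Epoch-level folding leaks overlapping-epoch similarity; use
  `grouping = "recording"` for a conservative estimate.
* The GA stopping rule compares best and worst fitness; with elitist
  replacement this can keep a converged population iterating until the
  generation cap when a single straggler remains.
* AUPRC uses trapezoidal integration; step-function interpolation
  would give slightly different (lower) values on coarse K = 2 score
  grids.
* Exhaustive K-NN is quadratic in the epoch count; at 1 s windows on
  the full Bonn geometry this is still comfortably fast, but much
  denser sweeps would warrant a neighbour index.
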