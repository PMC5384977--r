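---
title: "Measuring muscle fractionation in StartReact responses: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring muscle fractionation in StartReact responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(startreact)
```

This vignette explains the models and procedures implemented in
**startreact**, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate, and
the numerical and design choices made where more than one reasonable option
existed. It states no empirical result beyond what the package's own tests
and acceptance script compute.

## 1. The question and the measurement

A startling auditory cue shortens voluntary reaction times (StartReact).
Whether the accelerated response is produced by the same descending
pathways as a normal voluntary response can be probed through the
*dimensionality* of muscle recruitment: corticospinal control supports
highly fractionated (selective, high-dimensional) muscle use, whereas more
divergent brainstem pathways would impose low-dimensional, stereotyped
coactivation. The package quantifies dimensionality as the cumulative
percentage of variance explained (CPVE) by the principal components of the
across-trial muscle-activity covariance, and compares CPVE between loud-
and quiet-cued trials with a calibrated exhaustive shuffle test. A
complementary cosine-similarity analysis asks whether the *specific
pattern* of muscles recruited for a given task is preserved across cue
types.

## 2. Onset detection and the earliest reaction time

Per muscle, the EMG is rectified and a threshold set at

> baseline mean + `k_sd` × baseline SD,

with the baseline taken over `[-baseline_ms, 0)` ms before the cue
(half-open, excluding the stimulus sample; SD with the n−1 denominator).
The muscle's reaction time is the first post-stimulus time at which the
processed signal *strictly* exceeds the threshold, searched up to
`search_limit_ms`; the trial's earliest reaction time (eRT) is the minimum
over muscles. Defaults: `baseline_ms = 200`, `k_sd = 3`,
`search_limit_ms = 500` (chosen to cover the plausible eRT range with
margin; the value is not critical because detected eRTs concentrate far
below it).

**Why the pipeline smooths and debounces.** The textbook single-sample rule
is unusable on its own for automated analysis: for a roughly Gaussian
rectified baseline, a single sample exceeds mean + 3 SD of the half-normal
with probability ≈ 0.009, so at 5 kHz a 200 ms pre-onset stretch contains
~9 false crossings in expectation. Historically this was handled by visual
inspection and manual correction of every trace. The package keeps the
plain rule as the default of `detect_rt()` (and provides
`apply_overrides()` as the scripted analogue of manual correction), but the
pipeline applies two documented robustness parameters:

* `smooth_ms = 5` — a centered moving average of the rectified signal
  before thresholding (baseline statistics are computed on the same
  processed signal, so threshold and signal stay on one scale);
* `min_above_ms = 10` — the crossing must stay strictly above threshold
  for 10 ms.

A centered window starts responding about half a window before the true
onset while the ramping burst delays the crossing by a comparable amount,
so the two biases largely cancel; on synthetic ground truth the detected
eRT sits within ~1 ms of the programmed onset (see the onset-detection
tests, which also verify `detect_rt()` against a naive sample-by-sample
oracle across randomized settings).

eRT distributions are compared between cues with a two-sided Wilcoxon
rank-sum test; normality is assessed with the Lilliefors-corrected
Kolmogorov–Smirnov test (`nortest::lillie.test`), since the plain KS test
with estimated mean and SD is anticonservative.

## 3. Windows, exclusions, condition matrices

Mean rectified EMG is extracted per muscle in windows 0–10, 10–20, 20–30
and 50–100 ms after the eRT. All windows (and the baseline) are half-open
`[start, end)` so adjacent windows never share a sample. Trials with no
detected eRT are dropped with a warning.

Loud-cue trials with eRT > `cutoff_ms` (default 100) are excluded — such
late "loud" responses are not candidate StartReact responses — and an equal
number of quiet trials is removed uniformly at random, pooled across tasks
within subject, so both conditions keep identical trial counts and
therefore identical estimator bias in the eigenanalysis. Because the quiet
removal is random, the whole CPVE analysis is repeated `repeats = 100`
times with fresh draws and the curves averaged; the loud curve is
deterministic across repeats and the implementation asserts this. If
missing-eRT drops leave the cue counts unequal, the larger side is randomly
trimmed to equality (equal n is treated as a hard invariant; the choice
matters only for degenerate inputs).

Each subject × cue × window matrix (rows = retained trials in deterministic
(task, trial) order, columns = muscles) is z-scored per column (n−1 SD).
Zero-variance columns are set to zero and flagged *degenerate* rather than
erroring, which keeps the eigendecomposition defined; the flag propagates.

## 4. CPVE and its sampling behaviour

The covariance of the z-scored matrix is eigendecomposed; eigenvalues are
sorted, expressed as percent of their sum, and cumulated. Numerical
safeguards: eigenvalues in `[-1e-10 × trace, 0)` are clipped to zero;
anything more negative raises an error (a non-PSD covariance signals a
bug, not noise). Ties among eigenvalues are irrelevant because CPVE sums
over them. For z-scored input the first CPVE value is at least 100/15.

## 5. The calibrated shuffle test

CPVE values are cumulative, hence strongly dependent across components, so
standard multiple-comparison corrections do not apply. Instead, all
2^S within-subject relabelings of the per-subject (loud, quiet) curve pairs
are enumerated (1,024 for S = 10); for each, the difference of relabeled
condition means is computed. Swapping a subject simply negates its
contribution to the difference of means, so the surrogate set is generated
as a ±1 design matrix product and is exactly symmetric about zero; the
identity relabeling (the observed difference) is included, as "all possible
shuffles" implies.

Per-component thresholds are the rank-n smallest and largest surrogate
values (the ordinal "(M−n)-th" is read as *n-th largest*, preserving
symmetry). A surrogate counts as detected if *any* component lies strictly
outside its thresholds; n is calibrated to the largest value whose detected
count stays at or below `target_count` (default `floor(0.05 × 2^S)`, i.e.
51 of 1,024 for ten subjects, a family-wise *P* ≤ 0.05). The count is
monotone in n because the thresholds are nested, which licenses a binary
search (asserted, and verified against an exhaustive scan in the tests).
Strict inequality makes ties conservative; component 15 can never be
flagged since both curves end at 100. For S > 20, 2^20 random relabelings
(identity forced in) replace exhaustive enumeration — a documented
approximation. Each time window is tested separately, with no correction
across windows.

The achieved level is slightly below the nominal 5% (the count must stay
*at or below* 51); the level check in the test suite reflects this.

## 6. Pattern similarity

Similarity between two trials' 15-dimensional window-mean activation
vectors is their cosine, `x_j · x_k / (|x_j||x_k|)` — 1 for parallel, 0 for
orthogonal, scale-invariant per trial. Because it is scale-invariant and
the vectors are nonnegative raw window means, the similarity analysis uses
the *non*-z-scored features and a single seeded exclusion draw. Four sets
are computed per window, pooled over tasks and subjects but never pairing
across subjects (electrode placement differs): unordered same-task
quiet–quiet and loud–loud pairs (no self-pairs), unordered different-task
quiet–quiet pairs, and all same-task quiet×loud cross pairs. Zero-magnitude
vectors contribute no pairs and are counted. Summaries report means, the
fraction above a report cutoff (default 0.8), Welch t-tests of each set
against the same-task quiet–quiet reference and of loud–loud against
quiet–loud. Overlapping pairs make the values statistically dependent; the
t-tests deliberately ignore this (the conventional treatment for pooled
pairwise measures) and should be read descriptively.

## 7. The synthetic generator

`generate_experiment()` produces a full experiment with known ground truth.
Per subject, `synergy_rank` (K) nonnegative sparse synergy vectors are
drawn; each task mixes a random subset of them (inclusion probability 1/2,
at least one) with nonnegative coefficients, and the pattern is scaled so
its strongest muscle has weight 1. Muscle–synergy membership probability is
`min(1, 2(1 − sparsity^(1/K)))`, so the expected fraction of silent muscles
per task matches `pattern_sparsity` while *which* muscles are silent varies
across tasks; for small K the rank constraint binds and realized sparsity
is lower (rank-1 patterns are necessarily proportional across tasks).

Per trial, the earliest onset is drawn from the cue's reaction-time
distribution — Gaussian, truncated below at 30 ms to avoid nonphysical
values — with a `loud_slow_fraction` (default 0.15) of loud trials drawing
from the quiet distribution so the >100 ms exclusion path is exercised.
Active muscles start at the earliest onset plus a uniform lag in
`[0, muscle_lag_max_ms]`; the task's strongest muscle (the "prime mover")
always has lag 0, so the programmed earliest onset is the minimum over
muscle onsets and belongs to the highest-amplitude muscle. Each burst ramps
linearly over `onset_ramp_ms` to amplitude weight × (1 + trial jitter).

The signal is amplitude-modulated Gaussian noise — the standard surrogate
for interference-pattern EMG: baseline N(0, `noise_sd`²) plus a zero-mean
carrier whose SD follows the activation envelope. Mean rectified amplitude
is then `sqrt(2/π) × sqrt(noise_sd² + envelope²)`, essentially proportional
to the envelope at the default signal-to-noise ratio (envelope up to 1,
`noise_sd = 0.05`), which makes window means linear in the pattern weights.
All randomness flows from one seed through a documented splitting scheme;
identical seeds give byte-identical trial sets on disk. Defaults mirror the
reference study conditions: 10 subjects × 32 tasks × 5 trials per cue, 15
muscles at 5 kHz, quiet reaction times 204 ± 79 ms and loud 144 ± 75 ms.

Two consequences of this model are worth stating precisely:

* **Truncation bias.** The realized mean of N(μ, σ) truncated at 30 ms is
  μ + σ·φ(a)/(1−Φ(a)) with a = (30−μ)/σ: ≈ 206.8 ms for the quiet default
  and ≈ 154.1 ms for the loud default. Generator-recovery tests therefore
  compare detected eRT means against these truncated means (with a ~2 ms
  detection allowance), and against the nominal 204/144 values only at
  sampling scale.
* **Carrier sampling noise.** A window mean of |N(0, e²)| over n samples
  has relative SD ≈ 0.603/(0.798·√n) ≈ 4.8% for the 250-sample 50–100 ms
  window, *independent of* `noise_sd`. Column z-scoring surfaces this
  floor, so even noiseless rank-K patterns yield CPVE_K slightly below 100
  (and a rank-1 experiment concentrates CPVE₁ only insofar as trial
  amplitude variability dominates this floor: the inter-column correlation
  is jitter²/(jitter² + 0.048²)). The tests assert exact rank recovery
  (CPVE_K = 100) on directly constructed rank-K feature vectors, and an
  elbow criterion (CPVE_K ≥ 95, flat beyond K) for the full
  generation→detection→window→PCA chain.

What the generator does **not** emulate: the temporal autocorrelation of
band-passed real EMG (hardware notch and band-pass filters are treated as
design parameters, not simulated DSP), electrode cross-talk, motor-unit
physiology, task-specific biomechanics (tasks are distinct random patterns,
not the actual movement repertoire), and any systematic startle-specific
early burst. Passing tests therefore validate the *analysis machinery* and
its statistical calibration, not claims about real muscle physiology.

`generate_cpve_samples()` sidesteps the signal level entirely: it draws
per-subject CPVE curve pairs around a supplied mean/SD curve, injecting a
difference `delta` at a chosen component and all later ones (capped at 100,
monotonicity enforced), because a CPVE difference propagates cumulatively.
`power_analysis()` wraps it to estimate the shuffle test's power as a
function of `delta`. The mean/SD inputs are user-supplied: the reference
study's own experimental curves are not published, so its printed power
figure is not a reproduction target; the machinery is validated instead by
its type-I level at `delta = 0` and by monotonicity in `delta`.

## 8. Parameters at a glance

| parameter | default | units | role |
|---|---|---|---|
| `baseline_ms` | 200 | ms | baseline window before cue |
| `k_sd` | 3 | – | threshold multiplier |
| `search_limit_ms` | 500 | ms | latest accepted crossing |
| `smooth_ms` (pipeline) | 5 | ms | centered rectified-EMG smoothing |
| `min_above_ms` (pipeline) | 10 | ms | minimum supra-threshold duration |
| `cutoff_ms` | 100 | ms | loud-eRT exclusion cutoff |
| windows | 0–10, 10–20, 20–30, 50–100 | ms | eRT-referenced feature windows |
| `repeats` | 100 | – | random-exclusion repeats averaged |
| `target_count` | floor(0.05·2^S) | surrogates | family-wise calibration target |
| `similarity_cutoff` | 0.8 | – | report fraction cutoff |
| `rt_quiet_*`, `rt_loud_*` | 204±79, 144±75 | ms | cue RT distributions (truncated ≥30) |
| `noise_sd` | 0.05 | amp | baseline EMG noise (weights scaled to max 1) |
| `amp_jitter_sd` | 0.1 | – | per-trial amplitude variability |
| `onset_ramp_ms` | 10 | ms | burst rise time |
| `muscle_lag_max_ms` | 20 | ms | max per-muscle onset lag |
| `synergy_rank` | 8 | – | true pattern dimensionality |
| `pattern_sparsity` | 0.4 | – | expected silent-muscle fraction per task |

## 9. Problem sizes used by the test suite

The suite exercises the full chain at sizes chosen to keep the default run
comfortably fast while preserving the statistical structure: end-to-end
runs use 10 subjects (so the shuffle test has its full 1,024-surrogate
calibration) with 6 tasks × 3 trials per cue; generator-recovery statistics
use 5,000 trials per cue in seeded chunks; the test-level and power checks
use several hundred replicate curve-level experiments; the acceptance
script scales the recovery run to 50,000 trials per cue. Note that with
*fewer* than about 5 subjects the calibrated test becomes structurally
unable to reject (the union of per-column extremes already exceeds
`floor(0.05·2^S)` at rank 2), which is why scaled-down end-to-end checks
keep S = 10 rather than shrinking the subject count.

## 10. Known limitations

* The similarity t-tests ignore pair dependence (by design, see §6).
* The equal-n balance trim after asymmetric missing-eRT losses is a
  pragmatic rule for degenerate inputs, not a modelled procedure.
* For S > 20 subjects the surrogate set is sampled, not exhaustive.
* The generator's amplitude-modulated white-noise carrier lacks the
  autocorrelation of band-passed EMG; detection latencies on real
  recordings may differ slightly from the synthetic ~1 ms figure.
* CPVE-based fractionation is a linear, second-order summary; nonlinear
  muscle couplings are outside its reach.
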