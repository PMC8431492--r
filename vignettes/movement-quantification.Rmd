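---
title: "Quantifying seated movement from pose keypoint series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying seated movement from pose keypoint series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skelquant)
```

## The problem and the model

A child seated on a clinic chair is filmed by a fixed camera; a pose
estimator reports 25 body joints per frame as `(x, y, confidence)` in image
pixels, with undetected joints encoded `(0, 0, 0)`. The question is whether
the child's movement — fidgeting, swaying back and forth, swiveling on the
chair — measurably changes between two recordings (typically before and
after a month of medication).

`skelquant` reduces each recording to eleven per-frame **skeleton
parameters**: angle and length of the left/right shoulder (joints 5–1 and
2–1), left/right hip (12–8, 9–8) and right thigh (10–9) segments, and the
trunk angle (1–8). Angles are the absolute arctangent of the segment slope
in degrees, `[0°, 90°]`, except the trunk angle, which keeps orientation
over `[0°, 180°)` by adding 180° to negative arctangents. Only the right
thigh is defined; the asymmetry in the parameter set is deliberate and
preserved. Lengths are 2D image distances — there is no pixel-to-metric
calibration, so length features are comparable within a subject/camera
setup but not across them (a within-subject paired design is exactly the
setting where this is harmless).

Each parameter traced over `T` frames is a time series `s`. Three summaries
are computed per series, 33 features per recording:

* `acf(s)`: the lag-1 autocorrelation, the Pearson correlation over the
  `T − 1` overlapping pairs `(s(t), s(t+1))`, each sub-series centred by
  its own mean. A stable posture has `acf` near 1.
* `acf′(s′)`: the same statistic on the first difference
  `s′(t) = s(t+1) − s(t)`. If the parameter behaves like a stationary AR(1)
  process with persistence `φ`, the differenced series has lag-1
  autocorrelation `−(1 − φ)/2`; restless, weakly persistent motion pushes
  this toward −0.5, so a *decrease* means *more* frame-to-frame jitter.
* `var̄(s)`: the mean of per-window population variances over
  `I = ⌊T/W⌋` consecutive non-overlapping windows (remainder frames
  dropped) — a movement-amplitude measure that discounts drifts slower
  than the window.

Paired cohorts are then compared feature by feature with a classical
two-tailed paired t-test on the within-subject differences.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `window_size` (W) | 30 frames | averaged-variance window; ≈1 s at 25 fps. The source method leaves W unstated, so it is an explicit, recorded parameter here (every feature CSV gets a sidecar noting the W used). Longer windows fold slow sway into the variance; shorter ones isolate jitter. |
| `lag` (τ) | 1 | autocorrelation lag; the features use τ = 1 by definition. |
| `conf_threshold` | 0.1 | pose confidence below which a joint is treated as missing, in addition to the `(0,0,0)` convention. Low-confidence detections are noisy rather than informative. |
| `jump_threshold` | 150 px | person-tracking guard: if the nearest candidate skeleton's centroid jumps farther than this between frames, selection falls back to maximal summed confidence. |
| `acf_method` | `"pairwise"` | literal overlapping-pairs Pearson. `"stationary"` switches to the classical common-mean estimator for sensitivity analysis; the two differ at `O(1/T)` and are indistinguishable at clinical recording lengths. |

### Numerical choices

* **Vertical segments** (`Δx = 0`) return exactly 90° — the arctangent
  limit — rather than an error; seated subjects produce near-vertical
  trunks and thighs constantly. Exactly coincident joints are a
  degenerate-segment error naming the parameter.
* **Variance denominator** is the population form (divide by `W`). Inside
  the autocorrelation the normalisation cancels; in `var̄` it only rescales
  by `W/(W−1)` uniformly, which the paired test is invariant to.
* **Undefined autocorrelation** (a constant series, e.g. a perfectly
  frozen parameter) is surfaced as a missing feature with a warning, and
  cohort comparisons drop incomplete pairs per column, reporting the
  effective `n`. One frozen parameter must not abort a cohort run.
* **Missing joints**: leading/trailing frames missing a required joint are
  trimmed; internal gaps are linearly interpolated per coordinate
  (confidence set to 0 but marked valid). Interpolating rather than
  segmenting preserves the temporal adjacency that differencing and lag-1
  autocorrelation require; the cost is that long gaps are bridged by
  straight lines, which *reduces* apparent movement — worth auditing via
  the logged interpolation counts when dropout is heavy.
* **No multiple-testing correction** on the primary p-values, matching the
  reporting convention the package mirrors; a Holm-adjusted column is
  included, clearly labelled as an extension, for users who want it.

## What the synthetic generator does and does not emulate

Patient videos cannot be shared, so the package carries its own stated
world: `generate_sequence()` jitters every joint around a hard-coded seated
posture (640 × 480 image, y down) with independent stationary AR(1)
displacements `u(t) = φ·u(t−1) + ε`. The innovation SD is
`σ·sqrt(1 − φ²)`, so `jitter_sd` is the *marginal* SD regardless of `φ` and
ground truth is directly comparable across persistence levels. Two
correlated modes add body-plausible structure: a sinusoidal horizontal sway
of the head/shoulder girdle (0.2 Hz) and a sinusoidal rotation of the lower
body about the mid hip (0.35 Hz) — the swaying and swiveling that dominate
seated restlessness. Frequencies are fixed, plausible postural-oscillation
values chosen once; phases are drawn per recording. Optional dropout
replaces joints with `(0, 0, 0)`; it defaults to 0 so motion ground truth
stays exact, and is switched on explicitly where the cleaner is under test.

The default cohort (`cohort_config()`) is the package's stated treatment
scenario: 25 subjects, 3000 frames, pre-treatment `φ = 0.95, σ = 3 px,
sway 4 px, swivel 3°` against post-treatment `φ = 0.7, σ = 1.5 px,
sway 1 px, swivel 1°`, with per-subject body proportions and positions
drawn once and shared across sessions.

What a green test on this world establishes: the geometry, feature and
testing code recover built-in amplitude and persistence changes of the
stated size, with correctly calibrated type-I error under the null. What it
does not establish: anything about real pose-estimator noise (which is
heteroscedastic and occlusion-driven, not i.i.d. Gaussian), about
biomechanical coupling between joints, or about clinical effect sizes —
the synthetic effect was chosen for test power, not clinical realism.

## Design decisions that were genuinely open

* **Person selection** in multi-person frames: maximal summed confidence
  over the required joints initially, then nearest-centroid tracking with a
  max-confidence fallback past the jump threshold. A clinic scene may
  contain a parent; confidence alone would flip identities whenever the
  parent is detected more cleanly.
* **Autocorrelation estimator**: the overlapping-pairs Pearson form is the
  literal reading of the defining ratio `Cov(s, s_τ)/sqrt(Var(s)Var(s_τ))`
  with each sub-series carrying its own mean and variance, and is what the
  package computes; the classical estimator is the config alternative.
* **Seed discipline**: every random draw in the generator flows from the
  config seed through a private RNG stream (the caller's `.Random.seed` is
  restored), so cohorts are reproducible bit for bit and a master seed
  derives per-subject, per-session seeds deterministically.
* **JSON rather than YAML** for CLI config files: the deployment
  environment guarantees a JSON parser but not a YAML one, and the config
  schema is flat enough that nothing is lost.

## Known limitations

* Angles compress toward the ends of their range (`|atan|` folds left/right
  leaning onto the same value); the trunk angle is the only
  orientation-preserving angle.
* Features are treated as duration-invariant estimators; recordings of
  unequal length are compared as-is, which is only exact asymptotically.
* Linear gap interpolation biases movement features downward under heavy
  dropout (see above).
* The paired t-test assumes approximately normal within-subject
  differences; with n = 25 it is reasonably robust, but no non-parametric
  fallback is currently emitted.
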