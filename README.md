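# skelquant

Objective movement quantification from 2D pose keypoint time series, for
clinical before/after comparisons — e.g. evaluating how a stimulant
medication changes the fidgeting of a child with ADHD seated in a consulting
room. Rating scales (SNAP-IV and friends) are parent- or teacher-rated and
subjective; a webcam plus a pose estimator yields an objective alternative.
`skelquant` consumes the pose estimator's output (OpenPose BODY_25: 25
joints × (x, y, confidence) per frame) and turns each recording into 33
interpretable movement features, then tests paired before/after cohorts
feature by feature.

## The method

For each frame, eleven **skeleton parameters** are computed from seven
joints (neck 1, shoulders 2/5, mid hip 8, hips 9/12, right knee 10) in raw
image coordinates:

- segment angles `θ(a,b) = |atan((y_a − y_b)/(x_a − x_b))| · 180/π ∈ [0°, 90°]`
  and lengths `l(a,b) = ‖(x_a, y_a) − (x_b, y_b)‖` (pixels) for the left and
  right shoulder, left and right hip, and the right thigh;
- the **trunk angle** from neck to mid hip, mapped to `[0°, 180°)` via
  `φ` if `φ ≥ 0`, else `φ + 180`, so an upright trunk reads 90°.

Across a `T`-frame recording each parameter forms a series `s`. Three
summaries are taken per parameter (33 features per recording):

- `acf(s) = ρ(s, s₁)` — lag-1 autocorrelation of the original series (near
  +1 for a calm, slowly varying posture);
- `acf′(s′) = ρ(s′, s′₁)` with `s′(t) = s(t+1) − s(t)` — lag-1
  autocorrelation of the differenced series (for AR(1)-like motion with
  persistence φ this tends to `−(1 − φ)/2`: jittery motion drives it toward
  −0.5);
- `var̄(s)` — the mean of per-window population variances over
  `I = ⌊T/W⌋` non-overlapping windows of `W` frames (default `W = 30`), a
  movement-amplitude measure.

Cohorts are compared per feature with a two-tailed paired t-test
(`*` p < 0.05, `**` p < 0.01, `***` p < 0.001, uncorrected; a Holm column is
emitted alongside).

Because clinical recordings are not publicly available, the package ships a
seeded synthetic seated-motion generator (stationary AR(1) joint jitter plus
sinusoidal sway and swivel, optional detection dropout) that stands in for
patient videos in all tests.

## Worked example

Simulate a 25-subject paired cohort whose post-treatment motion has reduced
amplitude and persistence, run the full pipeline, and compare the
averaged-variance features:

```r
library(skelquant)
coh <- generate_paired_cohort(cohort_config(n_subjects = 25, seed = 1))
pc  <- cohort_features(coh, analysis_config(window_size = 30))
cmp <- compare_cohort(pc, paste0("avgvar_", parameter_names()))
format_comparison_table(cmp)
```

```
                     Parameters Before Treatment After Treatment p Value Significance
1    avgvar_left_shoulder_angle      7.05 ± 1.29     4.90 ± 0.75  0.0000          ***
2   avgvar_left_shoulder_length      6.48 ± 0.49     3.74 ± 0.14  0.0000          ***
3   avgvar_right_shoulder_angle      7.09 ± 1.26     4.92 ± 0.78  0.0000          ***
4  avgvar_right_shoulder_length      6.68 ± 0.61     3.72 ± 0.19  0.0000          ***
5         avgvar_left_hip_angle     11.80 ± 2.83     4.42 ± 0.82  0.0000          ***
6        avgvar_left_hip_length      6.59 ± 0.54     3.79 ± 0.14  0.0000          ***
7        avgvar_right_hip_angle     11.81 ± 2.51     4.45 ± 0.94  0.0000          ***
8       avgvar_right_hip_length      6.50 ± 0.47     3.71 ± 0.17  0.0000          ***
9      avgvar_right_thigh_angle      6.38 ± 0.89     2.83 ± 0.46  0.0000          ***
10    avgvar_right_thigh_length      6.45 ± 0.44     3.73 ± 0.17  0.0000          ***
11           avgvar_trunk_angle      1.94 ± 0.38     0.92 ± 0.17  0.0000          ***
```

Every averaged-variance feature drops after "treatment" — the movement
amplitude was built into the simulation (`jitter 3 → 1.5 px, sway 4 → 1 px,
swivel 3° → 1°`), and the pipeline recovers the decrease with p < 0.0001 in
each row. The analogous comparison of the differenced-series
autocorrelations (`acf_diff_*`) shows all 11 features becoming significantly
more negative, the signature of reduced temporal persistence
(`φ: 0.95 → 0.7`).

## Command line

```sh
exec/skelquant simulate --out-dir sim --n-subjects 25 --frames 3000 --seed 1
exec/skelquant extract  --input sim/S01/before/keypoints.csv --format csv --out S01_before.csv
exec/skelquant features --input S01_before.csv --out S01_before_feat.csv --window 30
exec/skelquant compare  --before before.csv --after after.csv --out-dir report --plots
```

`compare` writes three tables (`comparison_acf_orig.csv`,
`comparison_acf_diff.csv`, `comparison_avgvar.csv`) in the mean ± SD /
p-value layout plus optional annotated boxplot PNGs.

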