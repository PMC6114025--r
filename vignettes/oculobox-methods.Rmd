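---
title: "Oculomotor disconjugacy biomarkers: models, assumptions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oculomotor disconjugacy biomarkers: models, assumptions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem and the measurement

Concussion has no structural imaging correlate: a patient can be
substantially impaired with a normal head CT. One candidate physiological
signature is *disconjugate gaze* — the failure of the two eyes to rotate
together — because the brainstem circuits coordinating cranial nerves III
and VI are vulnerable to diffuse injury. The measurement protocol this
package models is deliberately passive: the subject watches a video playing
inside a small aperture that circles the edge of a 4:3 monitor, 10 s per
side, five full 40 s cycles, 220 s in all, while both pupil positions are
sampled at 500 Hz. No spatial calibration is performed; all analysis happens
in the time domain, each eye relative to itself. Plotted as x against y, a
recording traces a rectangular "box trajectory", and a subject's mean
trajectory over the repeated cycles serves as their own calibration.

The package covers the full analysis chain:

1. **`synth`** — simulate cohorts of binocular recordings with a
   controllable disconjugacy effect, so that every downstream stage is
   testable without access to any clinical data;
2. **`preprocess`** — trim, blink-mask, per-eye center, segment into
   cycles/sides, and compute the trial-triggered average trajectory;
3. **`metrics`** — 89 named oculomotor measures per recording;
4. **`cohort`** — case definition and age/sex balancing;
5. **`screen`** — univariate biomarker screening with multiplicity control;
6. **`models`/`evaluate`** — best-subset logistic, lasso, and bagged-tree
   classifiers with repeated cross-validation and external validation.

# The stimulus model

`stimulus_protocol()` fixes the timing grid. The invariants are structural:
`n_cycles * 4 * side_duration + 2 * trim_margin == total_duration`
(5·4·10 + 20 = 220 at defaults), and the retained window holds
`sampling_rate * 200 = 100000` samples. The path is piecewise linear around
the rectangle, clockwise from the top-left corner
(top → right → bottom → left); any fixed corner/order convention yields the
same metric semantics, so this one is simply documented and configurable.
The cycle clock is referenced to the end of the lead-in (`t = trim_margin`),
which makes the retained window exactly five whole cycles.

The traverse extents are 34° horizontally and 23° vertically per side. The
source protocol description gives a half-span figure of "17° horizontally"
(consistent: 2·17 = 34) but "13° vertically", which contradicts the 23°
per-side traverse statement; we adopt the traverse figures (34/23) because
every downstream worked value (pursuit velocity 3.4°/s, aspect ratio
23/34 ≈ 0.68) follows from them.

# The synthetic subject

`simulate_recording()` builds each eye's trace as

```
eye(t) = pursuit_gain · stimulus(t) + ε(t) + [left eye only] d(t)
```

with `ε` white Gaussian tracking noise (`tracking_noise_sd`, default 0.5°
per coordinate — a realistic magnitude for video-based pupil tracking
without calibration) and `d` the disconjugacy process: a Gaussian random
walk low-pass filtered to about 0.5 Hz, then standardized so its empirical
SD over the recording equals `disconjugacy_sd` *exactly*. The
standardization is the design decision that makes the effect size a
recoverable parameter: the conjugate variance metric estimates
`disconjugacy_sd² + 2·tracking_noise_sd²` up to masking effects, and the
monotonicity of variance in `disconjugacy_sd` is a property test. Blinks
are Poisson events (default 12/min, ~150 ms mean duration — typical adult
rates during video viewing) that flag validity false and blank the
coordinates, mirroring tracker dropout without emulating any vendor format.

Cohorts (`simulate_cohort()`) draw ages uniformly on [18, 60], sex by a
configurable fraction, SCAT3 scores consistent with the case definition
(cases: symptom severity > 40, cognitive subscore ≤ 24), and CT status
positive for 13/34 of cases by default, matching the reported composition
of the balanced clinical sample. Per-subject effect sizes are jittered by a
lognormal factor with CV 0.3 — a single, fixed choice representing
biological heterogeneity; without it all cases would share one effect size
and group separation would be unrealistically clean. The default case
profile (`disconjugacy_sd = 1.5°`) is *not* derived from published effect
sizes (none are quantified); it is a "strong effect" world chosen once so
that screening and classification have signal to find.

**What a green test does not establish.** The generator reproduces the
protocol's temporal structure, blink censoring, and a conjugacy deficit
with tunable magnitude. It does not emulate saccade main-sequence dynamics,
pupil-size changes, camera asymmetries, age/sex dependence of real
oculomotor function, or the correlation structure of real metric panels.
Passing tests therefore establish that the pipeline is *correct* (it
recovers what the simulator injects, at the stated thresholds), not that
the biomarker is clinically valid.

# Preprocessing decisions

- **Trimming**: first and last 10 s discarded; at defaults 110,000 →
  100,000 samples.
- **Blinks**: maximal runs where either eye's validity flag is false,
  stored as 0-based half-open `[start, end)` intervals (one convention
  everywhere). Each blink is widened by 200 samples on both sides at
  500 Hz; the margin is specified in time (0.4 s) so reduced-rate
  simulations used in tests mask the same protocol fraction.
- **Joint masking**: either-eye invalidity excludes the sample for both
  eyes, because conjugate metrics need simultaneously valid pairs. Per-eye
  masking remains available for single-eye work.
- **Per-eye transform**: the source analysis transforms "each eye
  respectively", without stating the transformation. We center each eye on
  its own median (x, y) over included samples — robust to residual blink
  artifacts, scale-preserving, and strictly single-eye. The mean variant is
  selectable. This is a documented stand-in, not a recovered definition.
- **Segmentation** is computed from sample indices, never from
  floating-point timestamps, so cycle and side boundaries are exact:
  20,000 samples per cycle at defaults.

The **trial-triggered average** (`trial_triggered_average()`) averages
(x, y) across cycles on a phase-bin grid: 2000 bins/cycle by default (10 ms
bins at 500 Hz, ~10 contributing samples per bin per cycle), capped at one
bin per grid sample for coarser rates. Bins with no valid contributions are
flagged missing, never zero-filled. Averaging is linear and masked samples
cannot influence any output — both property-tested.

# The 89-metric registry

Naming grammar: `{left|right|conj}_{measure}{Side?}_value`, side suffixes
`Top/Bot/Lef/Rit` (lowercase for the variance family, matching the printed
names) and no suffix for totals. Only the significant subset of names is
printed in the source tables; the registry fills the remaining slots by the
grammar, and the published arithmetic (32 + 32 + 25 = 89) forces two
reconstructions beyond the obvious roster:

- per eye (32): height/width/area/aspect-ratio in mean and median variants
  (8), distance and velocity per side + total (10), residual variance of
  x and y per side + total (10), blink count and rate (2), plus **totVar**
  and **varAspect** (2) — per-eye analogues of the conjugate composites;
- conjugate (25): varX/varY per side + total (10), totVar, varAspect, four
  BOX scores, plus left-minus-right differences of distance (per side and
  total), velocity, height, width, and aspect ratio (9).

Definitions worth stating precisely:

- geometry: `width = central x(right side) − central x(left side)`,
  analogously height from top/bottom; area = height·width; aspect ratio =
  height/width, missing when width is zero;
- distance: Euclidean path length over consecutive valid pairs within a
  side and cycle; velocity = distance / valid time in the side;
- per-eye variance: variance of the deviation from the trial-triggered mean
  at the same phase (so pursuit structure is not counted as noise); the raw
  within-side variance is selectable by `per_eye_mode = "raw"` — which of
  the two the original analysis used is unstated;
- conjugate variance: variance of `left − right` over valid pairs;
  `conj_totVar = conj_varX + conj_varY`; `conj_varAspect` = variance across
  cycles of the left-minus-right per-cycle aspect ratio;
- **BOX scores** (never defined at the source; reconstructed): each is the
  mean of z-scores of a constituent set, z-referenced to the control group
  of the current dataset — `boxscore` {varX, varY, varAspect}, `boxscore2`
  {varX, varY}, `boxscore3` the eight per-side variances, `boxscore5`
  {totVar, varAspect}. The construction reproduces the one property stated
  about them: the four are highly mutually correlated, so deduplication
  retains exactly one.

Variance uses the unbiased (n−1) estimator throughout. Entries with fewer
than two contributing values are missing, and missingness propagates
explicitly — it is never silently zero.

# Screening

Group contrasts use a two-sided Wilcoxon rank-sum test with midranks; for
`min(n) ≤ 8` the null distribution is obtained by complete enumeration of
rank assignments (exact under ties), otherwise the normal approximation
with tie and continuity correction. The family threshold is Bonferroni:
0.05/89 ≈ 0.00056.

Covariate exclusion runs on the full control sample: sex via rank-sum
(excluded at p ≤ 0.01), age via Spearman rank correlation with the
t-approximation (excluded at p ≤ 0.05) — the correlation statistic is not
named at the source; Spearman matches the nonparametric spirit of the rest
of the analysis. Thresholds are inclusive.

Per-metric AUC is the Mann–Whitney identity `U/(n₁·n₂)` with ties counted
half. Deduplication joins metrics with |Spearman r| above the cut into
blocks and keeps, per block, the metric with the smallest group-contrast
p-value (ties broken lexicographically) — deterministic, and reproduces
retaining a single BOX score.

# Classifiers and validation

- **Best subset**: exhaustive logistic search over subsets up to 5
  predictors (published winners had 2–4), ranked by AIC with the
  intercept-only model in the running. Complete separation triggers a
  weak-ridge (λ = 10⁻³, intercept unpenalized) IRLS refit with a warning.
  Both missing-data policies are implemented — `drop_rows` (complete
  cases) and `drop_columns` — mirroring the two published best-subset
  variants.
- **Lasso**: glmnet binomial path with internal standardization; penalty by
  internal cross-validated deviance under seed (`min` rule; `1se`
  selectable). A single-candidate call degenerates to the unpenalized fit.
- **Random forest**: implemented in-package as a bagged CART ensemble
  (Gini, `mtry = ⌊√p⌋`, 500 trees) with out-of-bag misclassification,
  because no tree package is available in the offline toolchain. OOB votes
  stabilize above ~50 trees. Majority-vote output yields class labels only,
  so external validation reports no AUC for it (an optional probability
  mode, clearly an extension, does).
- **Repeated CV**: stratified 4-fold assignment per repeat, full selection
  re-run inside every training fold, out-of-fold scores pooled into one
  AUC and misclassification rate per repeat, means over repeats (reference
  count 1000; tests scale to 25–50 repeats and say so). A `leak_selection`
  mode exists solely to demonstrate, in a test, that selecting on the full
  data first inflates null CV AUC.

Evaluation reports store full-precision values; the published tables'
rounding (percent to 1 decimal, proportions to 2–3) is applied only at
presentation. ROC curves come from a threshold sweep with ties grouped, so
the trapezoidal area equals the rank AUC exactly. External validation
enforces subject-id disjointness from training and is label-blind by
construction (scores are computed before labels are consulted).

# Numerical and degenerate-input conventions

- All stochastic operations take explicit seeds; cohort and CV seeds derive
  from one master seed by pre-drawn integer streams.
- Rank-sum on two identical samples returns p = 1 (vacuous test).
- Aspect ratio at zero width, sensitivity with no positives, variance with
  fewer than two values: flagged missing/undefined, never coerced.
- Blink intervals are clipped at recording bounds when widened.
- "Not labelable" subjects (missing CT/SCAT3 fields) are a third state,
  never silently counted as controls.

# Known limitations

- The per-eye transformation, BOX-score formulas, best-subset criterion,
  and lasso penalty rule are reconstructions of unstated procedures; they
  satisfy every property stated about the originals but need not equal
  them.
- Published dataset-dependent numbers (screening p-values, training AUC
  0.878, validation AUC 0.831, …) are functions of undeposited raw data
  and are not reproduction targets; the test suite instead verifies all
  derived arithmetic (confusion-table recomputation, thresholds, worked
  averaging example) and parameter recovery on the synthetic world.
- The age-balancing procedure is nearest-neighbor matching without
  replacement under a seed; the original matching algorithm is unstated.
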