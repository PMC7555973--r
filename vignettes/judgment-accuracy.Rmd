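---
title: "Scoring personality judgment accuracy: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring personality judgment accuracy: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profacc)
```

## The measurement problem

A judge looks at a stranger — a photo, a short muted video, or a video
with sound — and rates them on a handful of trait adjectives. How
accurate is that first impression, and do some judges do it reliably
better than others? `profacc` scores this design. The data are a
judges × targets × traits cube of Likert ratings, a targets × traits
criterion matrix (self-report scale scores, or an objective reasoning
test for intelligence, all rescaled to the rating scale), and judge
metadata including external ability-test scores.

Accuracy is operationalised as correlation-based agreement, in three
complementary ways:

1. **Trait accuracy** asks, separately for each trait within each
   presentation modality, whether the judge *ranks the targets*
   correctly (inter-target discrimination). Each judge yields
   8 × 3 = 24 cell correlations over 10 targets each.
2. **Overall profile accuracy** asks, for each target, whether the
   judge gets the *shape of the trait profile* right (intra-target
   discrimination), yielding 30 profile correlations over 8 traits.
3. **Distinctive profile accuracy** is profile accuracy after the
   normative (average-person) profile has been subtracted from both
   sides, so a judge cannot score well merely by attributing a typical
   profile to everyone.

All three are aggregated per judge by Fisher-*z* transforming the
component correlations, averaging, and back-transforming. Averaging on
the *z* scale stabilises variance; both the mean *z* and the
back-transformed *r* are retained in the fitted object, and reported
totals use the *r* metric.

## Missingness and degeneracy rules

These rules are load-bearing — small-sample correlations over 8 or 10
points degenerate easily:

- A correlation needs at least 3 complete pairs and non-zero variance
  on both sides. Anything else is **undefined**, represented as `NA`,
  never as 0. A judge who rates a whole modality with one constant
  value produces an undefined cell; a judge who assigns the normative
  profile to a target has a zero-variance distinctive profile and an
  undefined distinctive correlation.
- An aggregate (total or subscore) is computed only if at least a
  proportion `min_prop = 0.8` of its components are defined: 20 of 24
  cells, 24 of 30 profiles. Undefined components count against
  availability. The same proportional rule is applied to subscores;
  the threshold is stated in the literature only for totals, so
  extending it proportionally is this package's choice.
- Correlations of exactly ±1 (a real possibility with 3-point
  profiles) are clipped to ±`clip` (default 0.999, i.e. |z| ≤ 3.80)
  before the transform; an infinite *z* would otherwise dominate the
  average. `clip` is configurable.
- Ratings of targets the judge reported knowing are excluded wholesale
  (all of that judge–target pair's cells), and excluded cells are
  ordinary missing values downstream.
- Criterion instruments are rescaled to the 1–5 rating scale by the
  affine map from the instrument's *theoretical* range,
  `1 + 4 (x − min)/(max − min)`. Scaling by the observed sample range
  would make the criteria — and hence every accuracy score — depend on
  which targets happen to be in the study.

The normative rating profile is the grand mean over *all* judges and
all targets, including the judge being scored; this follows the
standard procedure. An `exclude_self` variant is available (it removes
a small self-contamination at the cost of judge-specific normative
profiles) but defaults off. The normative criterion profile is always
computed over the full target set, including for modality and
gender-pairing subscores.

## Reliability and attenuation

Trait accuracy reliability is Cronbach's α over the judge × 24-cell
matrix of Fisher-*z* cells (complete-case judges). For the profile
indices, internal consistency over targets is estimated by repeated
random split-half: targets are split into halves, each judge's mean
*z* is formed per half, the half-scores are correlated across judges,
stepped up with Spearman–Brown 2r/(1+r), and averaged over `n_splits =
200` seeded splits. The split-half definition is this package's
concrete re-specification of the "replicability" idea for profile
correlations; the seed is mandatory, making the estimate exactly
reproducible.

Correlations between accuracy indices and external ability tests are
Spearman rank correlations (accuracy scores are typically skewed), and
correction for attenuation divides by the square root of the product
of the two reliabilities. External test reliabilities are user inputs
(published alphas), never recomputed — item-level data are out of
scope. Corrected values can exceed 1 when reliabilities are low; they
are reported as-is with a flag rather than truncated. A reliability
estimated as non-positive (possible in small samples) leaves the
corrected value explicitly missing.

## The synthetic-data generator

No rating data ship with the package; `simulate_study()` generates
datasets with the statistical structure the indices assume, so every
pipeline stage — and the package's own validation suite — runs on
synthetic data.

The generative model is deliberately the *minimal* one that makes all
three indices identifiable and the null exactly attainable:

- **Targets.** criterion(t, a) = clip(normative(a) + δ(t, a), 1, 5),
  with δ ~ N(0, σ²_distinctive). Modalities are assigned in balanced
  blocks, genders balanced within block (5 + 5 per block of 10).
- **Judges.** Latent ability θ ~ N(θ_mean + gap·female, θ_sd²) clipped
  to [0, 1] (clipping, not resampling, is used for the truncation; the
  resulting point mass at 0 represents judges with no distinctive
  sensitivity). The ERA-style test score is a noisy linear image of θ,
  centred on 50 via the realized mean of θ so that truncation does not
  shift the test's centre. The other two external scores are drawn
  independently of θ, emulating discriminant validity.
- **Ratings.** rating(j, t, a) = normative(a) + w_j · m(t) · δ(t, a) +
  ε, with w_j = nbw + (1 − nbw)·θ_j, m(t) the modality's signal
  multiplier, ε ~ N(0, noise²); clipped to [1, 5] *after* noise and
  then rounded to the Likert grid. Each judge–target pair is flagged
  acquainted with probability 34/3630.

One global seed drives named substreams for targets, judges and
ratings, so enlarging the judge sample never perturbs the target
draws.

### Calibrated defaults

The defaults are fixed once to emulate the reference design's observed
score régime — index means in the .05–.15 band, low reliabilities, a
small female advantage, photo as the weakest modality — while keeping
judge ability recoverable:

| parameter | default | role |
|---|---|---|
| `n_judges`, `n_targets`, `n_traits` | 121, 30, 8 | design sizes |
| `sigma_distinctive` | 0.8 | spread of target deviations (scale units); large because targets are preselected for high/low trait scorers |
| `theta_mean`, `theta_sd` | 0.06, 0.12 | judge ability level and spread on [0, 1] |
| `gender_gap` | 0.05 | ability shift for female judges |
| `modality_multipliers` | 0.5 / 1.0 / 1.1 | photo carries about half the usable signal of the video modalities |
| `normative_bias_weight` | 0 | w = θ: a zero-ability judge emits pure normative ratings |
| `noise_sd` | 0.9 | idiosyncratic rating noise (scale units) |
| `p_known` | 34/3630 | acquaintance missingness rate |

These values were chosen by a coarse grid over (normative spread,
θ_mean, θ_sd, noise) evaluated on a handful of seeds and then frozen.
Under them, 20 replicate studies with 100 judges give grand index
means of about .08 (trait), .14 (overall) and .08 (distinctive), a
Spearman correlation of about .68 between latent ability and trait
accuracy, and a trait-accuracy α near .5 — the qualitative
low-reliability régime of real accuracy tasks, though the generator is
not tuned to hit any particular published reliability.

### The null configuration

`null_config()` sets θ ≡ 0, nbw = 0, no gender gap **and a flat
normative criterion profile**. The last point is easy to miss: with a
non-constant normative profile, ratings and criteria agree across
traits through the average person alone, so *overall* profile accuracy
has a strictly positive expectation even for judges carrying zero
signal. Overall accuracy's chance level is only zero in a
zero-normative-component world; trait and distinctive accuracy are
nulled by the ability settings alone. This is also why, in the
shuffled-criterion check, trait and distinctive accuracy fall to zero
while overall accuracy merely drops toward its normative floor.

### What the generator does not emulate

Real criteria are self-reports with their own biases (social
desirability, limited self-knowledge); the generator's criteria are
the truth by construction. Judge ability is unidimensional, whereas
real interpersonal accuracy is a bundle of loosely related facets;
rating noise is homoscedastic and response styles (extreme/central
tendency, acquiescence) are absent; targets do not vary in
judgeability beyond their random δ. Passing the simulation-based
checks therefore validates the *scoring machinery and its statistical
calibration*, not any substantive claim about human judges.

## Validation suite and problem sizes

The test suite validates every aggregate against independent
brute-force loop implementations (≥ 1000 random small instances for
the correlation primitives and α, 150 random cubes for both profile
modes, tolerance 1e−10), checks the availability thresholds at exactly
19/20-of-24 and 23/24-of-30, calibrates the null configuration with
500 simulated judges and 1000 one-sample-*t* null replicates at
*n* = 115, and measures ability recovery over 20 seeds at 100 judges.
These sizes keep each property estimate's Monte-Carlo error well below
the margins being asserted. `scripts/acceptance.R` re-runs the same
computations from scratch under a caller-supplied seed.

## Known limitations

- Gender analyses assume binary judge/target gender labels; judges
  with other or missing labels are retained in all non-gender scores
  and omitted from gender blocks.
- The split-half replicability estimator is one reasonable choice
  among several (odd–even, single fixed split, generalizability
  models); estimates from different choices are not interchangeable,
  which is why the method label travels with every value.
- With `exclude_self = TRUE`, distinctive scoring recomputes the
  normative profile per judge, which is O(judges²·targets·traits) in
  the current implementation — fine at study sizes, slow for very
  large simulations.
- The scoring functions treat the criterion as fixed and error-free;
  criterion unreliability is only addressed downstream via the
  attenuation correction.
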