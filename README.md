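# profacc

Scoring tools for interpersonal-accuracy studies in which a sample of
**judges** rates a set of **target** persons on several traits, and each
rating is scored against a **criterion** (the target's self-report scale
score or an objective test score). The motivating design is a
first-impression study: 121 judges each rate 30 unacquainted targets —
shown as a photo, a muted video, or a video with sound (10 targets per
modality) — on 8 trait adjectives using a 1–5 Likert scale.

## The three accuracy indices

For judge *j* with ratings *R<sub>jta</sub>* (target *t*, trait *a*) and
criteria *C<sub>ta</sub>*:

- **Trait accuracy** — for each of the trait × modality combinations
  (8 × 3 = 24), correlate the judge's ratings across that modality's 10
  targets with the targets' criteria on that trait:
  *r<sub>jam</sub>* = cor<sub>t∈m</sub>(*R<sub>jta</sub>*, *C<sub>ta</sub>*).
  The 24 correlations are Fisher *z* transformed, averaged (only if at
  least 20, i.e. > 80 %, are defined), and back-transformed.
- **Overall profile accuracy** — for each of the 30 targets, correlate
  the judge's 8-trait rating profile with the target's 8-trait criterion
  profile: *r<sub>jt</sub>* = cor<sub>a</sub>(*R<sub>jta</sub>*, *C<sub>ta</sub>*);
  Fisher-*z* average over targets (≥ 24 of 30 required).
- **Distinctive profile accuracy** — the same after subtracting the
  *normative* profiles: the mean rating per trait over all judges and
  targets from the ratings, and the mean criterion per trait over all
  targets from the criteria. It isolates how well a judge perceives a
  target's deviation from the average person.

A correlation over fewer than 3 pairs, or involving a constant vector
(e.g. a judge rating a whole modality with the same value), is
*undefined* — it counts against the 80 % availability rule and is never
coerced to zero. Degenerate correlations of ±1 are clipped to ±0.999
before the *z* transform.

Around the indices the package provides trait/modality/gender-pairing
subscores, one-sample *t* tests against chance, pooled-variance gender
comparisons, reliability (Cronbach's α over the 24 cells for trait
accuracy; seeded split-half replicability with Spearman–Brown step-up
for the profile indices), Spearman correlations with external ability
tests, and correction for attenuation
*r*<sub>c</sub> = *r* / √(rel<sub>x</sub> · rel<sub>y</sub>).

A calibrated generator (`simulate_study()`) produces synthetic studies
with this structure — shared normative profile, target-specific
distinctive deviations, latent judge ability driving distinctive signal
pickup, modality multipliers, Likert discretization and rare
acquaintance-driven missingness — so every stage is testable without
any real data.

## Worked example

```r
library(profacc)
study <- simulate_study(sim_config(n_judges = 40, seed = 11))
fit <- judgment_accuracy(study$cube, study$crit, study$judges)
fit
#> Personality judgment accuracy fit
#>   40 judges, 8 traits, 3 modalities (min_prop = 0.8)
#>   trait_accuracy                 M = 0.06, SD = 0.09, N = 40
#>   overall_profile_accuracy       M = 0.12, SD = 0.10, N = 40
#>   distinctive_profile_accuracy   M = 0.08, SD = 0.10, N = 40

round(coef(fit)[1:3, ], 3)
#>      trait_accuracy overall_profile_accuracy distinctive_profile_accuracy
#> J001          0.223                    0.220                        0.179
#> J002          0.072                    0.092                        0.085
#> J003          0.133                    0.169                        0.128

accuracy_reliability(fit, seed = 1)
#>                          index                    method     value n_components n_units
#> 1               trait_accuracy     alpha_over_components 0.3553914           24      40
#> 2     overall_profile_accuracy split_half_spearman_brown 0.3103300           30      40
#> 3 distinctive_profile_accuracy split_half_spearman_brown 0.3535774           30      40
```

The index means (.06/.12/.08) are small positive values of the size
typical for first-impression accuracy, and the reliabilities are low
(.31–.36) — accuracy scores aggregate many weakly related cells, which
is exactly why attenuation correction matters when they are correlated
with ability tests. `summary(fit)` adds chance-level *t* tests, subscore
tables and gender comparisons; `score_study()` assembles the full
report (descriptives, Spearman intercorrelations, corrected
correlations) and `write_study_report()` writes it as JSON, CSV and
text tables.

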