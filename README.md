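# ordsustain

Ordinal subtype-and-stage inference for regional neuropathology ratings,
with the downstream classification, heuristic-staging comparison and cohort
statistics of a TDP-43 proteinopathy staging study, exercised end-to-end on
synthetic cohorts.

## The problem

Post-mortem studies grade protein pathology (here TDP-43 inclusions) in
each sampled brain region on a semi-quantitative scale — 0 non-detectable,
0.5 sparse, 1 mild, 2 moderate, 3 severe — across cohorts such as ALS,
FTLD-TDP and LATE-NC. Classical staging schemes order regions by expert
consensus and assume one homogeneous progression per disease. This package
instead *learns* the progression from cross-sectional data with an ordinal
event-based subtype-and-stage model (the SuStaIn family of models):

- An **event** is a region reaching a new score level; with R regions and
  levels {1, 2, 3} there are M = 3R events, and a subject's **stage**
  k ∈ {0, …, M} is the number of events accrued.
- A **sequence** S is a permutation of the events in which level s of a
  region always precedes level s + 1. Given a subject's data x, the model
  evaluates P(x | k, S) = ∏ᵣ P(true score of r = level implied by the first
  k events), where each ordinal rating is translated into P(true score)
  by a normal kernel of standard deviation 0.5 centred on the rating
  (a sparse 0.5 therefore splits its mass evenly between scores 0 and 1,
  and a missing rating is uniform over the four scores).
- Fitting maximises ∑ᵢ log ∑ₖ P(k) P(xᵢ | k, S) over valid sequences by
  greedy multi-start ascent; uncertainty in S is sampled by
  Metropolis–Hastings (positional variance diagrams); **subtypes** are
  mixtures of sequences fitted by split-and-refit EM, and the number of
  subtypes is chosen by the cross-validation information criterion
  CVIC(C) = −2 × held-out log-likelihood summed over 10 folds.

On top of the model: maximum-likelihood subtype/stage assignment,
crossover-event detection (subtype probability crossing the 1/k chance
level after stage 1), three-way diagnosis classification (winner-takes-all
over joint (group, stage) probabilities, and an L2 multinomial logistic
regression adding stage and age at death), declarative composite-ROI
staging schemes with the ≥ 1 rule and an Unclassifiable category, and
region-wise GLMs with Benjamini–Hochberg FDR control.

Raw neuropathology data of this kind are available only on request, so the
package ships a first-class synthetic-cohort generator (`generate_cohort()`,
`cohort_preset()`) emulating the structure of such cohorts: ground-truth
sequences per subtype, truncated-geometric stage distributions,
adjacent-level ordinal observation noise, region-wise missingness and
configurable stage–age coupling.

## Worked example

```r
library(ordsustain)

# a LATE-like synthetic cohort: amygdala-first progression, n = 304
coh <- generate_cohort(cohort_preset("LATE-like", seed = 1))
flt <- filter_regions_by_missingness(coh$table)   # drop regions >25% missing
pr  <- ratings_to_probabilities(flt$table)         # sigma = 0.5 kernel
es  <- build_event_set(regions(flt$table))         # 19 regions -> 57 stages

model <- fit_subtypes(pr, es, 1, fit_config(n_starts = 5, seed = 2))
model
#> <subtype_model> 1 subtype(s), M = 57 events, loglik -3220.96
#>   subtype 1 (f = 1.00): amygdala:1 -> ca_subiculum:1 -> entorhinal_cortex:1
#>     -> dentate_gyrus:1 -> orbitofrontal_cortex:1 ...

a <- assign_subtype_and_stage(pr, model)
head(a, 3)
#>      subject_id subtype ml_stage fit_probability
#> 1 LATE-like_001       1        9       0.7601031
#> 2 LATE-like_002       1       56       0.7476181
#> 3 LATE-like_003       1        4       0.8491134
```

The fitted sequence begins in the amygdala and medial temporal lobe — the
ground truth planted by the preset — and each subject receives a stage (0 =
no pathology) with the probability of that maximum-likelihood stage as a
model-fit measure. `stage_association(a, coh$metadata, "age_at_death")`
recovers the preset's positive stage–age coupling
(r = 0.71, p ≈ 5e-48).

The `analysis/` directory holds the full numbered workflow (simulate →
fit → subtypes/CVIC → classification → staging comparison → statistics);
each script prints what it found and writes its tables under `results/`.

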