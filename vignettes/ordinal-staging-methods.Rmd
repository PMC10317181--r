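---
title: "Ordinal subtype-and-stage modelling of regional neuropathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordinal subtype-and-stage modelling of regional neuropathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordsustain)
```

## The model

The package models cross-sectional, semi-quantitatively scored regional
pathology — ratings 0 (non-detectable), 0.5 (sparse), 1 (mild), 2
(moderate), 3 (severe) per brain region — as snapshots of a common event
sequence. An *event* is a region reaching a new score level (levels 1, 2, 3
are modelled; 0 is the implicit baseline), so R regions give M = 3R events.
A subject at *stage* k has accrued the first k events of the sequence; for
each region the implied level is the highest level among those k events.

Ratings enter the likelihood as probabilities over the true score
$z \in \{0,1,2,3\}$. A rating $r$ yields
$P(z) \propto \exp\{-(z-r)^2 / 2\sigma^2\}$ with $\sigma = 0.5$, normalised
over the four levels — so a sparse 0.5 splits its mass equally between
scores 0 and 1 — and a missing rating is uniform. This density-kernel
translation (rather than CDF binning) makes the sparse category an honest
"either 0 or 1" statement while keeping every probability strictly
positive, which in turn keeps all log-likelihoods finite. A rating of 0 is
kernel-converted like any other rating by default; `hard_zero = TRUE`
instead pins it to score 0, for pipelines that treat 0 as certain absence.

The subject likelihood at stage k under sequence S is
$P(x \mid k, S) = \prod_r P_r(\text{implied level})$, and the fitting
objective marginalises the stage with a uniform prior over $\{0,\dots,M\}$:
stage 0 is inside the support because subjects without enough pathology to
place are a real category ("Unclassified" downstream). The prior is
configurable; uniform was chosen because nothing in the data model favours
any stage a priori, at the cost of mildly over-weighting late stages in
cohorts that undersample them.

Subtypes are mixtures of sequences: the dataset objective is
$\sum_i \log \sum_c f_c P(x_i \mid S_c)$ with mixture fractions $f_c$.

## Fitting

**Greedy multi-start ascent.** From a uniformly random valid sequence,
every event is repeatedly relocated to its best admissible position (one
that keeps level s after level s − 1 of the same region); the sweep repeats
until no relocation improves the objective, and the best of `n_starts`
(default 25) starts wins. Ties in a relocation keep the earliest position,
and only strict improvements (> 1e-9) are accepted so the ascent
terminates. On event sets small enough to enumerate (M ≤ 8), the greedy
optimum matches the exhaustive maximum-likelihood sequence in ≥ 95% of
random instances (this is a standing acceptance test).

**MCMC.** Sequence uncertainty is sampled by Metropolis–Hastings: a
uniformly chosen event is proposed at a uniformly chosen admissible slot
(the slot count for an event does not depend on its current position, so
the proposal is symmetric) and accepted with probability
min(1, L'/L). Default chain length 10,000 with 20% burn-in, thinned to at
most 1,000 stored samples; the chain settings are desk-scale defaults, not
sacred numbers, and every recovery experiment states the settings it used.
The event-by-position frequency matrix of the samples is the positional
variance diagram.

**Subtype fitting.** C subtypes are grown hierarchically from the fitted
(C − 1)-subtype model: each cluster is tentatively split by random
bipartition, a sequence fitted to each half, and the full model refined by
alternating maximum-probability reassignment, per-cluster sequence refits
and fraction updates until the log-likelihood gain falls below `em_tol`.
The best split wins; subtypes are reported by descending fraction. A
cluster that empties during the alternation is re-seeded with the subject
whose reassignment costs least; on data that genuinely support fewer
clusters this converges to a near-degenerate mixture rather than aborting,
which keeps the C-subtype model well-defined for model selection.

**Model selection.** CVIC(C) = −2 × held-out log-likelihood summed over
10 folds, minimised over C. Folds are stratified by stage tertile of a
preliminary single-sequence fit so no fold is empty of a disease epoch.
The held-out likelihood integrates over the MCMC samples of each subtype's
sequence. A known limitation: held-out likelihood carries no explicit
complexity penalty, so under a single-sequence truth the margin between
CVIC(1) and CVIC(2) is small (a vestigial second subtype costs little);
the package's recovery experiments nevertheless select the true count in
at least 8 of 10 replicates in both directions.

## Assignment, classification and fit probabilities

Subjects are assigned to the subtype maximising $f_c$ × marginal
likelihood, then to the stage maximising the stage posterior under that
subtype averaged over MCMC samples (ties to the lowest stage/index). The
*fit probability* reported per model is the probability of the
maximum-likelihood stage.

Two normalisations of that probability serve different purposes, and the
distinction matters:

- `model_fit_probability()` normalises within the model (the maximum of the
  stage posterior). It is bounded, comparable across subjects, and equals
  1/(M+1) for an entirely uninformative subject — but a *badly* fitting
  model can still produce a sharply peaked stage posterior, because
  normalisation hides the absolute likelihood level.
- `group_fit_probabilities()` evaluates the prior-weighted stage
  likelihoods jointly across competing group models and normalises over all
  (group, stage) combinations. This is the quantity the winner-takes-all
  classifier uses: the group-and-stage combination with the highest joint
  probability wins, and a subject whose winning model places it at stage 0
  is Unclassified and excluded from accuracy metrics.

When a model is evaluated on subjects of its own training group, fit
probabilities are computed out-of-sample through a 10-fold map (each
subject scored by the model fitted without their fold); the functions
refuse to compute within-group probabilities without one. Models built on
different retained-region sets are compared on their own regions; the
differing number of likelihood factors introduces a small constant offset
per model, which is negligible against the orders-of-magnitude likelihood
differences that drive classification but is worth knowing about.

The logistic classifier follows the published recipe: L2-penalised
multinomial regression (glmnet ridge; the sklearn-style `C` maps to
`lambda = 1/(n·C)`) on the per-group fit probabilities, the
maximum-likelihood stage and age at death; stratified 80/20 splits repeated
100 times; inner 10-fold CV over 10 *linearly* spaced C values between 1e-4
and 1e4, exactly as printed in the source recipe (a log-spaced option
exists because linear spacing concentrates 9 of 10 grid points above 1e3).
Two numerical accommodations for the coordinate-descent solver: features
are standardised internally (coefficients are reported on the original
scale), and the effective lambda is floored at 1e-6 because ridge solutions
diverge as lambda → 0 on separable data. Both are
prediction-indistinguishable in the weakly-penalised regime the upper C
grid occupies.

## Heuristic staging schemes

Literature schemes are declarative YAML configs: ordered stages, each a
list of member regions. Staging averages the subject's non-missing member
ratings per stage (missing members are excluded rather than zeroed, to
avoid artificial under-staging); a subject sits at the highest stage m with
composite ≥ 1 for stages 1..m, is Unclassifiable if a later stage reaches
threshold while an earlier one does not, and is stage 0 if nothing does.
The ≥ 1 rule is the default; a strict > variant is a switch. The five
shipped configs (Brettschneider ALS and FTLD/bvFTD, Nelson, Josephs, Rush)
carry *provisional* region memberships — plausible reconstructions, clearly
marked in the files — because the authoritative memberships live in
supplementary material not redistributed here; users should edit the YAML
before applying them to real data.

## The synthetic-cohort generator

`generate_cohort()` draws, per subject: a subtype from the mixture
fractions; a stage from a truncated geometric distribution (default decay
0.05 with P(stage 0) = 0.01 — most cohorts oversample early stages and
nearly every included subject has *some* pathology; a uniform option exists
for recovery experiments that need the whole stage axis populated); true
regional scores implied by the subtype's sequence; an observed rating that
deviates to an *adjacent* ladder value (0, 0.5, 1, 2, 3) with probability
epsilon (default 0.1), the sparse 0.5 reachable from both 0 and 1;
region-wise missingness (default 5%); and metadata with age at death =
intercept + slope × stage + noise.

Adjacent-level flipping was chosen over sampling from the model's own
Gaussian kernel deliberately: it keeps ratings on the legal scale and is a
slight model mismatch, so recovery tests do not grade the model against
data drawn from itself.

The three presets encode the cohort archetypes: ALS-like (n = 141,
spinal-cord-first progression, no stage–age coupling, high missingness in
occipital cortex, locus coeruleus and orbitofrontal cortex so the default
25% filter retains 18 of 21 regions), FTLD-like (n = 126, cortical-first,
negative age slope −0.25 yr/stage, orbitofrontal under-sampled, 20 regions
retained), and LATE-like (n = 304, amygdala-first, positive age slope
+0.35 yr/stage, motor cortex and spinal cord under-sampled, 19 retained).
Sequences are built by `staggered_sequence()`: regions reach level 1 in the
preset order and higher levels trail by a fixed lag, so early regions grow
severe while later ones are recruited.

What passing tests on these cohorts do **not** show: real cohorts have
rater effects, correlated regional noise, co-pathology, non-monotone
missingness and between-subject sequence heterogeneity beyond a finite
subtype mixture. Synthetic recovery demonstrates the estimator is correct
and well-conditioned, not that any particular biological claim transfers.

## Numerical choices and degenerate inputs

All likelihoods are computed in log space in compiled code; with the
kernel translation the smallest per-region probability is ~2e-8, so no
intermediate underflow occurs for cohorts up to ~25 regions. Cross-model
scoring accumulates stage likelihoods relative to the consensus sequence's
log-likelihoods, protecting deeply mismatched subjects. `hard_zero` floors
the zero-probability levels at 1e-12 before renormalising. Region filtering
uses a strict "more than 25% missing" rule, so a region missing in exactly
a quarter of subjects is retained. Problem sizes in the recovery
experiments (8 regions × 3 levels, n = 200, epsilon = 0.1; oracle instances
at M = 6 with 12 subjects) were chosen as the smallest instances that
exercise every code path while leaving the statistical questions
non-trivial; the analysis scripts run the full 21-region presets.

## Known limitations

- Single-chain Metropolis–Hastings only; no tempering. Multimodal sequence
  posteriors (e.g. two near-equally-likely orderings) will mix slowly.
- CVIC's weak complexity penalty, discussed above.
- The subtype EM uses hard assignments; soft-responsibility EM would give
  smoother likelihood ascent at the cost of a different fraction estimator.
- Stage-0 subjects carry no subtype information; recovery metrics exclude
  them, and classification labels them Unclassified.
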