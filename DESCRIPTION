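Package: ordsustain
Title: Ordinal Subtype and Stage Inference for Regional Neuropathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-based subtype-and-stage progression modelling for
    semi-quantitative regional neuropathology ratings, such as TDP-43
    inclusion scores graded 0/0.5/1/2/3 across brain regions. Ordinal
    ratings are translated into per-score probabilities, a sequence in
    which regions reach successive severity levels is fitted by greedy
    multi-start optimisation, sequence uncertainty is quantified by
    Markov chain Monte Carlo sampling, and the number of progression
    subtypes is selected with a cross-validation information criterion.
    Includes maximum-likelihood subtype and stage assignment, model-fit
    probabilities for cross-diagnosis classification (winner-takes-all
    and L2 multinomial logistic regression), declarative heuristic
    staging schemes with a composite region-of-interest rule, a
    synthetic-cohort generator for end-to-end validation, and the
    downstream cohort statistics (stage correlations, group t-tests, and
    region-wise general linear models with false-discovery-rate control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
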