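#!/usr/bin/env Rscript
# Compare data-driven stages with heuristic staging schemes.
#
# Each cohort is staged with its literature-style scheme(s) by the composite
# region-of-interest rule (stage reached when the mean rating of its member
# regions is >= 1, all earlier stages also reached; out-of-order pathology
# is Unclassifiable). Heuristic stages are cross-tabulated against the
# data-driven stage, and classifiable vs unclassifiable subjects are
# compared on their (cross-validated) fit probability to the dominant
# progression pattern.
#
# The shipped scheme configs carry provisional region memberships.
#
# Outputs: results/staging/<group>_<scheme>_table.csv, summary.csv.

library(ordsustain)

dir.create("results/staging", recursive = TRUE, showWarnings = FALSE)
CFG <- fit_config(n_starts = 3, mcmc_iterations = 1500, max_samples = 150,
                  seed = 19)

schemes <- list(als = c("brettschneider_als"),
                ftld = c("brettschneider_ftld"),
                late = c("nelson_late", "josephs_late", "rush_late"))

rows <- list()
for (grp in names(schemes)) {
  fit <- readRDS(sprintf("scratch/%s_fit.rds", grp))
  tab <- read_score_table(sprintf("results/cohorts/%s_scores.csv", grp))
  # out-of-sample fit probability to the group's own progression pattern
  cv <- cross_validate_cvic(fit$probs, fit$model$event_set, 1, CFG)
  p_fit <- model_fit_probability(fit$probs, fit$model,
                                 cv = list(folds = cv$folds,
                                           models = lapply(cv$fold_models,
                                                           `[[`, 1)))
  for (sch_name in schemes[[grp]]) {
    sch <- example_staging_scheme(sch_name)
    comp <- composite_stage_scores(tab, sch)
    h <- assign_heuristic_stage(comp)
    cmp <- compare_to_sustain(h, fit$assignments, scheme = sch)
    tt <- tryCatch(classifiable_vs_unclassifiable_test(h, p_fit),
                   error = function(e) list(t = NA, p_value = NA))
    cat(sprintf("%s / %s: rank cor %.2f, %d unclassifiable, t = %.2f (p = %.3g)\n",
                grp, sch_name, cmp$rank_correlation, cmp$n_unclassifiable,
                tt$t, tt$p_value))
    write.csv(as.data.frame(cmp$table),
              sprintf("results/staging/%s_%s_table.csv", grp, sch_name),
              row.names = FALSE)
    rows[[paste(grp, sch_name)]] <- data.frame(
      group = grp, scheme = sch_name,
      rank_correlation = cmp$rank_correlation,
      n_classifiable = cmp$n_classifiable,
      n_unclassifiable = cmp$n_unclassifiable,
      t_classifiable_vs_not = tt$t, p_value = tt$p_value)
  }
}
write.csv(do.call(rbind, rows), "results/staging/summary.csv",
          row.names = FALSE)
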