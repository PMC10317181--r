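#!/usr/bin/env Rscript
# Cohort statistics on the pipeline outputs.
#
# Per cohort: correlations between the data-driven stage and age at onset,
# age at death, disease duration and total pathology (the LATE-like cohort
# is built with a positive stage-age coupling, the FTLD-like cohort with a
# negative one, the ALS-like cohort with none). On the two-subtype cohort:
# region-wise general linear models rating ~ subtype + stage with
# Benjamini-Hochberg correction across regions (positive t = more severe
# in subtype 1).
#
# Outputs: results/stats/stage_associations.csv, regionwise_glm.csv.

library(ordsustain)

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)

rows <- list()
for (grp in c("als", "ftld", "late")) {
  fit <- readRDS(sprintf("scratch/%s_fit.rds", grp))
  md <- read.csv(sprintf("results/cohorts/%s_metadata.csv", grp))
  tab <- read_score_table(sprintf("results/cohorts/%s_scores.csv", grp))
  md$total_pathology <- unname(total_pathology(tab)[md$subject_id])
  for (v in c("age_at_onset", "age_at_death", "disease_duration",
              "total_pathology")) {
    res <- stage_association(fit$assignments, md, v)
    rows[[paste(grp, v)]] <- data.frame(group = grp, variable = v,
                                        r = res$estimate, p = res$p_value,
                                        n = res$n)
    cat(sprintf("%-5s stage ~ %-17s r = %+.2f (p = %.3g)\n", grp, v,
                res$estimate, res$p_value))
  }
}
write.csv(do.call(rbind, rows), "results/stats/stage_associations.csv",
          row.names = FALSE)

# regional subtype contrasts on the two-subtype cohort
sub <- readRDS("scratch/als_two_subtype_subtypes.rds")
tab2 <- read_score_table("results/cohorts/als_two_subtype_scores.csv")
if (sub$cv$selected >= 2) {
  glm_res <- regionwise_subtype_glm(tab2, sub$assignments)
  write.csv(glm_res, "results/stats/regionwise_glm.csv", row.names = FALSE)
  sig <- glm_res[glm_res$q < 0.05, ]
  cat(sprintf("regions differing between subtypes (q < 0.05): %d of %d\n",
              nrow(sig), nrow(glm_res)))
  cat(sprintf("  more severe in subtype 1: %s\n",
              paste(sig$region[sig$t > 0], collapse = ", ")))
  cat(sprintf("  more severe in subtype 2: %s\n",
              paste(sig$region[sig$t < 0], collapse = ", ")))
} else {
  cat("two-subtype model not selected; regional contrasts skipped\n")
}
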