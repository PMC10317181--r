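#!/usr/bin/env Rscript
# Simulate the study cohorts.
#
# Three synthetic cohorts mirror the modelled proteinopathies: an ALS-like
# cohort (n = 141, progression from the spinal cord; occipital cortex,
# locus coeruleus and orbitofrontal cortex under-sampled), an FTLD-like
# cohort (n = 126, cortical-first progression, later stages die younger) and
# a LATE-like cohort (n = 304, amygdala-first progression, later stages die
# older). A fourth cohort plants two ALS-like progression subtypes — one
# subcortical-predominant, one corticolimbic-predominant — to exercise the
# subtype machinery downstream.
#
# Outputs: results/cohorts/*.csv (scores + metadata + ground truth).

library(ordsustain)

out_dir <- "results/cohorts"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
SEED <- 42

presets <- c("ALS-like", "FTLD-like", "LATE-like")
for (i in seq_along(presets)) {
  coh <- generate_cohort(cohort_preset(presets[i], seed = SEED + i))
  stem <- file.path(out_dir, gsub("-like", "", tolower(presets[i])))
  write_score_table(coh$table, paste0(stem, "_scores.csv"))
  write.csv(coh$metadata, paste0(stem, "_metadata.csv"), row.names = FALSE)
  write.csv(coh$truth, paste0(stem, "_truth.csv"), row.names = FALSE)
  cat(sprintf("%s: %d subjects, %.1f%% missing cells, stages %d-%d\n",
              presets[i], nrow(coh$table$ratings),
              100 * mean(is.na(coh$table$ratings)),
              min(coh$truth$stage), max(coh$truth$stage)))
}

# two planted ALS-like subtypes: subcortical-first vs corticolimbic-first
es <- build_event_set(cohort_preset("ALS-like")$regions, 3)
subcortical <- c("spinal_cord", "medulla", "motor_cortex", "upper_pons",
                 "midbrain", "substantia_nigra", "caudate_putamen",
                 "globus_pallidus", "thalamus", "locus_coeruleus",
                 "anterior_cingulate", "middle_frontal", "angular_gyrus",
                 "amygdala", "entorhinal_cortex", "ca_subiculum",
                 "dentate_gyrus", "sup_mid_temporal", "occipital_cortex",
                 "orbitofrontal_cortex", "cerebellum")
corticolimbic <- c("spinal_cord", "motor_cortex", "amygdala",
                   "ca_subiculum", "entorhinal_cortex", "sup_mid_temporal",
                   "dentate_gyrus", "middle_frontal", "anterior_cingulate",
                   "angular_gyrus", "occipital_cortex", "medulla",
                   "caudate_putamen", "thalamus", "globus_pallidus",
                   "midbrain", "substantia_nigra", "upper_pons",
                   "locus_coeruleus", "orbitofrontal_cortex", "cerebellum")
cfg2 <- cohort_preset("ALS-like", seed = SEED + 10)
cfg2$sequences <- list(staggered_sequence(es, subcortical),
                       staggered_sequence(es, corticolimbic))
cfg2$fractions <- c(0.5, 0.5)
cfg2$group_label <- "ALS2-like"
coh2 <- generate_cohort(cfg2)
write_score_table(coh2$table, file.path(out_dir, "als_two_subtype_scores.csv"))
write.csv(coh2$metadata, file.path(out_dir, "als_two_subtype_metadata.csv"),
          row.names = FALSE)
write.csv(coh2$truth, file.path(out_dir, "als_two_subtype_truth.csv"),
          row.names = FALSE)
cat(sprintf("ALS two-subtype: %d subjects, fractions %.2f/%.2f\n",
            nrow(coh2$table$ratings),
            mean(coh2$truth$subtype == 1), mean(coh2$truth$subtype == 2)))
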