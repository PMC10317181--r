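#!/usr/bin/env Rscript
# Three-way diagnosis classification.
#
# Every subject is scored under all three group models. Within-diagnosis
# probabilities are computed out-of-sample via 10-fold cross-validation
# (each subject scored by the model fitted without their fold); cross-
# diagnosis probabilities come from the full group models. Two classifiers
# are compared: winner-takes-all over the joint (group, stage) probability,
# with most-probable-stage-0 subjects labelled Unclassified, and an L2
# multinomial logistic regression on the three probabilities plus
# maximum-likelihood stage and age at death (100 stratified 80/20 splits,
# inner 10-fold CV over 10 linearly spaced C values in [1e-4, 1e4]).
#
# Outputs: results/classification/fit_probabilities.csv, wta_confusion.csv,
# wta_metrics.csv, logistic_metrics.csv, logistic_summary.csv.

library(ordsustain)

dir.create("results/classification", recursive = TRUE, showWarnings = FALSE)
CFG <- fit_config(n_starts = 3, mcmc_iterations = 1500, max_samples = 150,
                  seed = 13)
groups <- c("als", "ftld", "late")

fits <- lapply(groups, function(g) readRDS(sprintf("scratch/%s_fit.rds", g)))
names(fits) <- groups

# within-group fold models (fitted on the group's own retained regions)
cv_maps <- lapply(groups, function(g) {
  es <- fits[[g]]$model$event_set
  cv <- cross_validate_cvic(fits[[g]]$probs, es, 1, CFG)
  list(folds = cv$folds, models = lapply(cv$fold_models, `[[`, 1))
})
names(cv_maps) <- groups

# score every subject under every group model; each model is evaluated on
# its own retained region set, and the joint probability over (group, stage)
# combinations is assembled from the per-model log scores
all_ids <- c(); all_groups <- c()
fp <- NULL; st <- NULL
for (g in groups) {
  tab <- read_score_table(sprintf("results/cohorts/%s_scores.csv", g))
  lb <- matrix(NA_real_, nrow(tab$ratings), length(groups),
               dimnames = list(rownames(tab$ratings), groups))
  lt <- lb; row_st <- lb
  for (h in groups) {
    keep_regions <- attr(fits[[h]]$model$event_set, "regions")
    pr_h <- ratings_to_probabilities(
      score_table(tab$ratings[, keep_regions, drop = FALSE],
                  group = tab$group))
    cv <- if (h == g) cv_maps[[g]] else NULL
    jp <- group_fit_probabilities(pr_h, setNames(list(fits[[h]]$model), h),
                                  cv = if (is.null(cv)) NULL
                                       else setNames(list(cv), h))
    lb[, h] <- jp$log_best[, h]
    lt[, h] <- jp$log_total[, h]
    row_st[, h] <- jp$ml_stages[, h]
  }
  mx <- apply(lt, 1, max)
  norm <- mx + log(rowSums(exp(lt - mx)))
  fp <- rbind(fp, exp(lb - norm)); st <- rbind(st, row_st)
  all_ids <- c(all_ids, rownames(tab$ratings))
  all_groups <- c(all_groups, rep(g, nrow(tab$ratings)))
}

write.csv(data.frame(subject_id = all_ids, true_group = all_groups,
                     fp, ml_stage = st[cbind(seq_along(all_ids),
                                             max.col(fp))]),
          "results/classification/fit_probabilities.csv", row.names = FALSE)

cls <- suppressWarnings(classify_max_likelihood(fp, st))
keep <- !cls$unclassified
met <- classification_metrics(all_groups[keep], cls$predicted[keep])
cat(sprintf("winner-takes-all: accuracy %.1f%% (balanced %.1f%%), %d unclassified\n",
            100 * met$accuracy, 100 * met$balanced_accuracy, sum(!keep)))
write.csv(as.data.frame(met$confusion),
          "results/classification/wta_confusion.csv", row.names = FALSE)
write.csv(data.frame(metric = c("accuracy", "balanced_accuracy"),
                     value = c(met$accuracy, met$balanced_accuracy)),
          "results/classification/wta_metrics.csv", row.names = FALSE)

# logistic model on probabilities + stage + age at death
age <- unlist(lapply(groups, function(g)
  read.csv(sprintf("results/cohorts/%s_metadata.csv", g))$age_at_death))
feats <- data.frame(fp, ml_stage = st[cbind(seq_along(all_ids), max.col(fp))],
                    age_at_death = age)[keep, ]
lg <- classify_logistic(feats, all_groups[keep], n_repeats = 100, seed = 17)
cat(sprintf("logistic (probabilities + stage + age): accuracy %.1f%% (balanced %.1f%%)\n",
            100 * mean(lg$metrics$accuracy),
            100 * mean(lg$metrics$balanced_accuracy)))
write.csv(lg$metrics, "results/classification/logistic_metrics.csv",
          row.names = FALSE)
write.csv(lg$summary, "results/classification/logistic_summary.csv",
          row.names = FALSE)
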