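#' Correlation between assigned stage and a subject variable
#'
#' Univariate association between the data-driven stage and age at onset,
#' age at death, disease duration or total pathology (Pearson by default,
#' Spearman available).
#'
#' @param assignments a [assign_subtype_and_stage()] result.
#' @param metadata cohort metadata data.frame keyed by `subject_id`; may
#'   contain a precomputed `total_pathology` column.
#' @param variable metadata column to correlate with stage.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `estimate`, `p_value`, `n`, `method`.
#' @export
stage_association <- function(assignments, metadata, variable,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!variable %in% names(metadata))
    stop("metadata has no column '", variable, "'")
  idx <- match(assignments$subject_id, metadata$subject_id)
  if (anyNA(idx)) stop("metadata missing for some assigned subjects")
  x <- assignments$ml_stage
  y <- metadata[[variable]][idx]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 3) stop("need at least 3 complete pairs")
  if (sd(x[keep]) == 0 || sd(y[keep]) == 0)
    stop("zero variance in stage or '", variable, "'")
  ct <- suppressWarnings(cor.test(x[keep], y[keep], method = method))
  list(estimate = unname(ct$estimate), p_value = ct$p.value,
       n = sum(keep), method = method)
}

#' Fit-probability difference between classifiable and unclassifiable subjects
#'
#' Two-sided independent-samples t-test (Welch by default) of the model-fit
#' probability between subjects the heuristic staging scheme could stage and
#' those it marked `"Unclassifiable"`. A positive t means classifiable
#' subjects fit the dominant progression pattern better.
#'
#' @param heuristic_stages character stage labels (with
#'   `"Unclassifiable"` entries), aligned with `fit_probabilities`.
#' @param fit_probabilities numeric model-fit probabilities.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @return list with `t`, `p_value`, `df`, group means and sizes.
#' @export
classifiable_vs_unclassifiable_test <- function(heuristic_stages,
                                                fit_probabilities,
                                                var_equal = FALSE) {
  stopifnot(length(heuristic_stages) == length(fit_probabilities))
  uncl <- heuristic_stages == "Unclassifiable"
  if (sum(uncl) < 2 || sum(!uncl) < 2)
    stop("need at least 2 subjects in each of the classifiable and ",
         "unclassifiable groups")
  tt <- t.test(fit_probabilities[!uncl], fit_probabilities[uncl],
               var.equal = var_equal)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_classifiable = mean(fit_probabilities[!uncl]),
       mean_unclassifiable = mean(fit_probabilities[uncl]),
       n_classifiable = sum(!uncl), n_unclassifiable = sum(uncl))
}

#' Region-wise subtype contrasts with FDR control
#'
#' Per region, an ordinary least squares model
#' `rating ~ subtype + stage` is fitted, with stage as a nuisance covariate
#' so that subtype contrasts are not driven by overall progression. The
#' subtype coefficient's t-value is reported with the sign convention that
#' positive t means more severe pathology in subtype 1. p-values are
#' Benjamini-Hochberg adjusted across regions.
#'
#' @param table a [score_table].
#' @param assignments a [assign_subtype_and_stage()] result with (at least)
#'   two subtypes present.
#' @return data.frame with columns `region`, `t`, `p`, `q`, `n`; regions
#'   with a rank-deficient design are skipped with a warning.
#' @export
regionwise_subtype_glm <- function(table, assignments) {
  idx <- match(assignments$subject_id, rownames(table$ratings))
  if (anyNA(idx)) stop("assignments refer to subjects absent from the table")
  if (length(unique(assignments$subtype)) < 2)
    stop("need two subtypes present")
  is_s1 <- as.numeric(assignments$subtype == 1)
  stage <- assignments$ml_stage
  rows <- lapply(colnames(table$ratings), function(rg) {
    y <- table$ratings[idx, rg]
    keep <- !is.na(y)
    if (sum(keep) < 4) return(NULL)
    fit <- lm(y[keep] ~ is_s1[keep] + stage[keep])
    sm <- summary(fit)$coefficients
    if (!"is_s1[keep]" %in% rownames(sm)) return(NULL)
    data.frame(region = rg, t = sm["is_s1[keep]", "t value"],
               p = sm["is_s1[keep]", "Pr(>|t|)"], n = sum(keep),
               stringsAsFactors = FALSE)
  })
  skipped <- colnames(table$ratings)[vapply(rows, is.null, logical(1))]
  if (length(skipped))
    warning("rank-deficient or under-sampled region(s) skipped: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no region could be fitted")
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("region", "t", "p", "q", "n")]
}
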