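#' Assign subjects to subtype and stage
#'
#' Each subject is first assigned to the subtype maximising
#' \eqn{f_c \times} the stage-marginal likelihood under that subtype's
#' maximum-likelihood sequence, then to the stage maximising the stage
#' posterior under the assigned subtype, averaged over the MCMC sequence
#' samples. Stage ties resolve to the lowest stage, subtype ties to the
#' lowest subtype index. The model-fit probability is the maximum of that
#' averaged stage posterior.
#'
#' @param probs a [ratings_to_probabilities()] result.
#' @param model a fitted `subtype_model`.
#' @return a `subject_assignment` data.frame with columns `subject_id`,
#'   `subtype`, `ml_stage`, `fit_probability`; the averaged per-subject
#'   stage posterior and the subtype posterior are attached as attributes
#'   `stage_posterior` and `subtype_posterior`.
#' @export
assign_subtype_and_stage <- function(probs, model) {
  n <- dim(probs$probs)[1]
  C <- model$n_subtypes
  lmat <- vapply(model$sequences, function(s)
    subject_marginal_likelihood(probs, model$event_set, s,
                                model$stage_prior, log = TRUE),
    numeric(n))
  lw <- sweep(matrix(lmat, nrow = n), 2, log(model$fractions), "+")
  post <- exp(lw - .row_logsumexp(lw))
  subtype <- max.col(post, ties.method = "first")

  stage_post <- matrix(NA_real_, n, n_events(model$event_set) + 1)
  for (c in seq_len(C)) {
    members <- which(subtype == c)
    if (!length(members)) next
    avg <- .avg_stage_posterior(subset_probs(probs, members), model, c)
    stage_post[members, ] <- avg
  }
  ml_stage <- max.col(stage_post, ties.method = "first") - 1L
  out <- data.frame(subject_id = dimnames(probs$probs)[[1]],
                    subtype = subtype, ml_stage = ml_stage,
                    fit_probability = stage_post[cbind(seq_len(n),
                                                       ml_stage + 1L)],
                    stringsAsFactors = FALSE)
  rownames(stage_post) <- out$subject_id
  colnames(stage_post) <- paste0("stage", seq_len(ncol(stage_post)) - 1)
  attr(out, "stage_posterior") <- stage_post
  attr(out, "subtype_posterior") <-
    matrix(post, nrow = n,
           dimnames = list(out$subject_id, paste0("subtype", seq_len(C))))
  class(out) <- c("subject_assignment", "data.frame")
  out
}

# stage posterior under one subtype, averaged over its MCMC samples
.avg_stage_posterior <- function(probs, model, subtype) {
  ev <- .ev_cpp(model$event_set)
  avg_stage_posterior_cpp(.logp(probs), dim(probs$probs), ev$region,
                          ev$level, model$mcmc[[subtype]]$samples - 1L,
                          log(model$stage_prior))
}

#' Model-fit probability of each subject under a group model
#'
#' The probability of the maximum-likelihood stage: the maximum of the
#' subject's stage posterior under their best-fitting subtype, averaged over
#' the MCMC sequence samples. Bounded in \[0, 1\] and comparable across models
#' built on different region sets.
#'
#' When the subjects being evaluated belong to the same diagnostic group the
#' model was fitted on, probabilities must be computed out-of-sample: supply
#' `cv` (per-subject fold indices plus one model per fold, each fitted
#' without its fold) as produced by [cross_validate_cvic()].
#'
#' @param probs score probabilities of the subjects to evaluate.
#' @param model a fitted `subtype_model`.
#' @param cv optional list with `folds` (fold index per subject) and
#'   `models` (list of `subtype_model`s, one per fold).
#' @param within_group override the automatic same-group check (logical).
#' @return named numeric vector of fit probabilities in \[0, 1\].
#' @export
model_fit_probability <- function(probs, model, cv = NULL,
                                  within_group = NULL) {
  if (is.null(within_group))
    within_group <- !is.null(probs$group) && !is.null(model$group_label) &&
      any(probs$group == model$group_label)
  if (within_group && is.null(cv))
    stop("within-group evaluation requires a cross-validation fold map ",
         "('cv'); probabilities must be out-of-sample")
  n <- dim(probs$probs)[1]
  if (is.null(cv)) {
    a <- assign_subtype_and_stage(probs, model)
    return(setNames(a$fit_probability, a$subject_id))
  }
  stopifnot(length(cv$folds) == n)
  out <- setNames(rep(NA_real_, n), dimnames(probs$probs)[[1]])
  for (f in unique(cv$folds)) {
    idx <- which(cv$folds == f)
    a <- assign_subtype_and_stage(subset_probs(probs, idx), cv$models[[f]])
    out[idx] <- a$fit_probability
  }
  out
}

#' Most probable stage under a model, per subject
#'
#' Companion to [model_fit_probability()]: the stage achieving the averaged
#' stage-posterior maximum, optionally out-of-sample via a fold map.
#'
#' @inheritParams model_fit_probability
#' @return named integer vector of stages 0..M.
#' @export
model_ml_stage <- function(probs, model, cv = NULL, within_group = NULL) {
  if (is.null(within_group))
    within_group <- !is.null(probs$group) && !is.null(model$group_label) &&
      any(probs$group == model$group_label)
  if (within_group && is.null(cv))
    stop("within-group evaluation requires a cross-validation fold map")
  n <- dim(probs$probs)[1]
  if (is.null(cv)) {
    a <- assign_subtype_and_stage(probs, model)
    return(setNames(a$ml_stage, a$subject_id))
  }
  out <- setNames(rep(NA_integer_, n), dimnames(probs$probs)[[1]])
  for (f in unique(cv$folds)) {
    idx <- which(cv$folds == f)
    a <- assign_subtype_and_stage(subset_probs(probs, idx), cv$models[[f]])
    out[idx] <- a$ml_stage
  }
  out
}

#' Joint fit probabilities under competing group models
#'
#' For cross-diagnosis classification the stage posterior within one model is
#' not the right yardstick: a badly fitting model can still have a sharply
#' peaked stage posterior. Instead, the probability of each (group, stage)
#' combination is evaluated jointly: per model g and stage k, the
#' stage-prior-weighted likelihood averaged over the model's MCMC sequence
#' samples, normalised over all (g, k) pairs. The reported probability of
#' group g is that of its maximum-likelihood stage.
#'
#' Within-group columns (a model evaluated on subjects of its own training
#' group) must be computed out-of-sample: supply an entry in `cv` for that
#' group, as produced by [cross_validate_cvic()] on that group's subjects.
#'
#' @param probs score probabilities of the subjects to evaluate.
#' @param models named list of fitted `subtype_model`s (one per group).
#' @param cv optional named list (by group) of fold maps
#'   (`list(folds=, models=)`) for out-of-sample within-group columns.
#' @return list with `fit_probs` (subjects x groups matrix of joint
#'   probabilities of the per-group maximum-likelihood stage) and
#'   `ml_stages` (subjects x groups matrix of those stages).
#' @export
group_fit_probabilities <- function(probs, models, cv = NULL) {
  stopifnot(!is.null(names(models)))
  n <- dim(probs$probs)[1]
  groups <- names(models)
  log_best <- matrix(NA_real_, n, length(groups),
                     dimnames = list(dimnames(probs$probs)[[1]], groups))
  log_total <- log_best
  ml_stages <- matrix(NA_integer_, n, length(groups),
                      dimnames = dimnames(log_best))
  for (g in groups) {
    fold_map <- if (!is.null(cv)) cv[[g]] else NULL
    if (is.null(fold_map)) {
      sc <- .stage_scores(probs, models[[g]])
      log_best[, g] <- sc$log_best
      log_total[, g] <- sc$log_total
      ml_stages[, g] <- sc$ml_stage
    } else {
      for (f in unique(fold_map$folds)) {
        idx <- which(fold_map$folds == f)
        sc <- .stage_scores(subset_probs(probs, idx), fold_map$models[[f]])
        log_best[idx, g] <- sc$log_best
        log_total[idx, g] <- sc$log_total
        ml_stages[idx, g] <- sc$ml_stage
      }
    }
  }
  norm <- .row_logsumexp(log_total)
  list(fit_probs = exp(log_best - norm), ml_stages = ml_stages,
       log_best = log_best, log_total = log_total)
}

# per-subject log of max_k and sum_k of prior_k * mean_s L(x | k, seq_s),
# under the subject's best subtype; sequence uncertainty integrated out
.stage_scores <- function(probs, model) {
  n <- dim(probs$probs)[1]
  ev <- .ev_cpp(model$event_set)
  logp <- .logp(probs)
  m <- n_events(model$event_set)
  best <- matrix(-Inf, n, model$n_subtypes)
  total <- matrix(-Inf, n, model$n_subtypes)
  stage <- matrix(NA_integer_, n, model$n_subtypes)
  lp0 <- log(model$stage_prior)
  for (c in seq_len(model$n_subtypes)) {
    samples <- model$mcmc[[c]]$samples
    # mean over samples of the stage-conditional likelihood, per stage,
    # accumulated relative to the ML sequence's log-likelihoods so that
    # deeply mismatched subjects do not underflow
    off <- stage_logliks_cpp(logp, dim(probs$probs), ev$region, ev$level,
                             model$sequences[[c]] - 1L)
    acc <- matrix(0, n, m + 1)
    for (i in seq_len(nrow(samples))) {
      ll <- stage_logliks_cpp(logp, dim(probs$probs), ev$region, ev$level,
                              samples[i, ] - 1L)
      acc <- acc + exp(ll - off)
    }
    lw <- off + log(acc / nrow(samples)) + rep(lp0, each = n)
    stage[, c] <- max.col(lw, ties.method = "first") - 1L
    best[, c] <- lw[cbind(seq_len(n), stage[, c] + 1L)]
    total[, c] <- .row_logsumexp(lw)
  }
  pick <- max.col(best, ties.method = "first")
  list(log_best = best[cbind(seq_len(n), pick)],
       log_total = .row_logsumexp(total +
                                    rep(log(model$fractions), each = n)),
       ml_stage = stage[cbind(seq_len(n), pick)])
}

#' Detect subtype crossover events
#'
#' Plots (numerically) the mean subtype-1 posterior probability against
#' assigned stage and flags a crossover wherever the curve crosses the
#' chance level 1/k after stage 1. A crossover suggests a discontinuity
#' between the variation observed before and after that stage.
#'
#' @param assignments a [assign_subtype_and_stage()] result.
#' @param n_subtypes number of subtypes k (>= 2); chance level is 1/k.
#' @return list with `curve` (data.frame stage, mean subtype-1 probability,
#'   n), `chance_level`, `crossover` flag, `crossover_stages` and
#'   `empty_stages` (stages skipped for lack of subjects).
#' @export
detect_crossover <- function(assignments, n_subtypes) {
  stopifnot(n_subtypes >= 2)
  post <- attr(assignments, "subtype_posterior")
  if (is.null(post)) stop("assignments lack a subtype posterior")
  chance <- 1 / n_subtypes
  stages <- sort(unique(assignments$ml_stage))
  curve <- data.frame(
    stage = stages,
    p_subtype1 = vapply(stages, function(k)
      mean(post[assignments$ml_stage == k, 1]), numeric(1)),
    n = vapply(stages, function(k)
      sum(assignments$ml_stage == k), integer(1)))
  all_stages <- 0:max(assignments$ml_stage)
  empty <- setdiff(all_stages, stages)

  above <- curve$p_subtype1 > chance
  cross_at <- integer(0)
  for (i in seq_len(nrow(curve))[-1]) {
    if (above[i] != above[i - 1] && curve$stage[i] > 1)
      cross_at <- c(cross_at, curve$stage[i])
  }
  list(curve = curve, chance_level = chance,
       crossover = length(cross_at) > 0, crossover_stages = cross_at,
       empty_stages = empty)
}

#' Stage histogram of an assignment
#' @param assignments a [assign_subtype_and_stage()] result.
#' @param m number of events (stages run 0..M); default inferred.
#' @return integer vector of counts per stage 0..M.
#' @export
stage_histogram <- function(assignments, m = max(assignments$ml_stage)) {
  counts <- tabulate(assignments$ml_stage + 1L, m + 1L)
  setNames(counts, 0:m)
}
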