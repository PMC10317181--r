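# Thin R wrappers over the compiled likelihood core. All computation is in
# log space; no intermediate underflow occurs for cohorts of up to ~25
# regions because per-stage terms are accumulated additively in logs.

.check_prior <- function(stage_prior, m) {
  if (is.null(stage_prior)) return(rep(1 / (m + 1), m + 1))
  if (length(stage_prior) != m + 1)
    stop("stage_prior must have length M + 1 (stages 0..M)")
  if (abs(sum(stage_prior) - 1) > 1e-8) stop("stage_prior must sum to 1")
  stage_prior
}

.check_sequence <- function(event_set, order) {
  if (!is_valid_sequence(event_set, order))
    stop("invalid event sequence (per-region level order violated)")
  as.integer(order)
}

#' Stage-conditional log-likelihood matrix
#'
#' Row n, column k + 1 holds the log-likelihood of subject n's score
#' probabilities given that the first k events of `order` have occurred:
#' the product over regions of the probability of the implied level.
#'
#' @param probs a [ratings_to_probabilities()] result.
#' @param event_set the event set.
#' @param order integer event-id sequence.
#' @return subjects x (M + 1) matrix of log-likelihoods.
#' @export
stage_loglik_matrix <- function(probs, event_set, order) {
  order <- .check_sequence(event_set, order)
  ev <- .ev_cpp(event_set)
  out <- stage_logliks_cpp(.logp(probs), dim(probs$probs), ev$region,
                           ev$level, order - 1L)
  dimnames(out) <- list(dimnames(probs$probs)[[1]],
                        paste0("stage", 0:length(order)))
  out
}

#' Stage-conditional likelihood of one subject
#'
#' @inheritParams stage_loglik_matrix
#' @param subject subject id or index.
#' @param k stage in 0..M.
#' @return non-negative likelihood.
#' @export
stage_conditional_likelihood <- function(probs, event_set, order, subject, k) {
  m <- length(order)
  if (k < 0 || k > m) stop("stage k must be in 0..M")
  ll <- stage_loglik_matrix(probs, event_set, order)
  idx <- if (is.character(subject)) match(subject, rownames(ll)) else subject
  if (anyNA(idx)) stop("unknown subject: ", subject)
  exp(ll[idx, k + 1])
}

#' Stage-marginal subject likelihood
#'
#' Likelihood of each subject under a sequence, marginalised over stages
#' with a stage prior (default uniform over 0..M, stage 0 included).
#'
#' @inheritParams stage_loglik_matrix
#' @param stage_prior optional prior over stages 0..M; must sum to 1.
#' @param log return log-likelihoods instead (default `FALSE`).
#' @return named numeric vector, one entry per subject.
#' @export
subject_marginal_likelihood <- function(probs, event_set, order,
                                        stage_prior = NULL, log = FALSE) {
  order <- .check_sequence(event_set, order)
  prior <- .check_prior(stage_prior, length(order))
  ev <- .ev_cpp(event_set)
  ll <- marginal_logliks_cpp(.logp(probs), dim(probs$probs), ev$region,
                             ev$level, order - 1L, base::log(prior))
  names(ll) <- dimnames(probs$probs)[[1]]
  if (log) ll else exp(ll)
}

#' Stage posterior matrix
#'
#' P(stage = k | subject) under one sequence:
#' prior_k x stage-conditional likelihood, normalised over k.
#'
#' @inheritParams subject_marginal_likelihood
#' @return subjects x (M + 1) matrix; rows sum to 1.
#' @export
stage_posterior <- function(probs, event_set, order, stage_prior = NULL) {
  prior <- .check_prior(stage_prior, length(order))
  ll <- stage_loglik_matrix(probs, event_set, order)
  lp <- sweep(ll, 2, base::log(prior), "+")
  mx <- apply(lp, 1, max)
  w <- exp(lp - mx)
  w / rowSums(w)
}

#' Dataset log-likelihood of a subtype model
#'
#' Sum over subjects of the log mixture likelihood
#' \eqn{\log \sum_c f_c L(x | seq_c)}, stages marginalised with the model's
#' stage prior. A subject with zero likelihood yields `-Inf`, with the
#' offending subject ids attached as attribute `zero_subjects`.
#'
#' @param probs a [ratings_to_probabilities()] result.
#' @param model a [fit_subtypes()] result.
#' @return scalar log-likelihood.
#' @export
dataset_log_likelihood <- function(probs, model) {
  ll <- mixture_logliks(probs, model$event_set, model$sequences,
                        model$fractions)
  out <- sum(ll)
  if (!is.finite(out) && any(!is.finite(ll)))
    attr(out, "zero_subjects") <- names(ll)[!is.finite(ll)]
  out
}

# per-subject log mixture likelihood over a list of sequences + fractions
mixture_logliks <- function(probs, event_set, sequences, fractions,
                            stage_prior = NULL) {
  stopifnot(length(sequences) == length(fractions))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  mat <- vapply(sequences, function(s)
    subject_marginal_likelihood(probs, event_set, s, stage_prior, log = TRUE),
    numeric(dim(probs$probs)[1]))
  mat <- matrix(mat, nrow = dim(probs$probs)[1])
  lw <- sweep(mat, 2, log(fractions), "+")
  out <- .row_logsumexp(lw)
  names(out) <- dimnames(probs$probs)[[1]]
  out
}

.row_logsumexp <- function(x) {
  mx <- apply(x, 1, max)
  fin <- is.finite(mx)
  out <- mx
  out[fin] <- mx[fin] + log(rowSums(exp(x[fin, , drop = FALSE] - mx[fin])))
  out
}
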