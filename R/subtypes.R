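#' Fit a subtype-and-stage model
#'
#' For one subtype this is a single-sequence fit plus MCMC. For C > 1 the
#' model is grown hierarchically: starting from the fitted (C - 1)-subtype
#' model, each cluster is tentatively split by random bipartition of its
#' members, a sequence is fitted to each side, and the full C-cluster model
#' is refined by alternating (a) maximum-probability subject reassignment,
#' (b) per-cluster sequence refits and (c) mixture-fraction updates until the
#' log-likelihood change falls below `config$em_tol`. The best-likelihood
#' split wins. Subtypes are reported sorted by descending mixture fraction,
#' and an MCMC chain is run per final subtype sequence.
#'
#' @param probs a [ratings_to_probabilities()] result.
#' @param event_set the event set.
#' @param n_subtypes number of subtypes C (>= 1).
#' @param config a [fit_config()].
#' @param stage_prior optional stage prior (default uniform over 0..M).
#' @param group_label optional label stored on the model.
#' @return a `subtype_model`: list with `sequences` (list of event-id
#'   orders), `fractions`, `mcmc` (per-subtype samples and positional
#'   density), `loglik`, `assignments` (ML subtype index per subject),
#'   `event_set`, `group_label`.
#' @export
fit_subtypes <- function(probs, event_set, n_subtypes, config = fit_config(),
                         stage_prior = NULL, group_label = NULL) {
  path <- fit_subtype_path(probs, event_set, n_subtypes, config, stage_prior,
                           group_label)
  path[[n_subtypes]]
}

#' Fit the whole hierarchical path of subtype models
#'
#' As [fit_subtypes()], but returns the list of fitted models for
#' C = 1..`max_subtypes` (each C initialised from the previous one).
#'
#' @inheritParams fit_subtypes
#' @param max_subtypes largest number of subtypes fitted.
#' @return list of `subtype_model`s indexed by C.
#' @export
fit_subtype_path <- function(probs, event_set, max_subtypes,
                             config = fit_config(), stage_prior = NULL,
                             group_label = NULL) {
  stopifnot(max_subtypes >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- dim(probs$probs)[1]
  prior <- .check_prior(stage_prior, n_events(event_set))
  cfg1 <- config; cfg1$seed <- NULL  # seed set once above
  f1 <- fit_single_sequence(probs, event_set, cfg1, prior)
  models <- vector("list", max_subtypes)
  models[[1]] <- .finalize_model(probs, event_set, list(f1$order), 1, prior,
                                 cfg1, group_label)
  for (C in seq_len(max_subtypes)[-1]) {
    prev <- models[[C - 1]]
    best <- NULL
    for (c_split in seq_len(C - 1)) {
      members <- which(prev$assignments == c_split)
      if (length(members) < 4) next
      for (try in seq_len(config$n_split_tries)) {
        half <- sample(members, floor(length(members) / 2))
        seqs <- prev$sequences
        seqs[[c_split]] <- .quick_refit(probs, event_set, half, cfg1, prior,
                                        prev$sequences[[c_split]])
        seqs[[C]] <- .quick_refit(probs, event_set, setdiff(members, half),
                                  cfg1, prior, prev$sequences[[c_split]])
        em <- .em_refine(probs, event_set, seqs, cfg1, prior)
        if (!is.null(em) && (is.null(best) || em$loglik > best$loglik))
          best <- em
      }
    }
    if (is.null(best))
      stop("no cluster could be split into ", C, " subtypes ",
           "(clusters too small or every split collapsed)")
    models[[C]] <- .finalize_model(probs, event_set, best$sequences,
                                   C, prior, cfg1, group_label,
                                   em = best)
  }
  models
}

# greedy refit of one cluster's sequence on a subject subset
.quick_refit <- function(probs, event_set, members, config, prior, init_seq) {
  if (!length(members)) return(init_seq)
  sub <- subset_probs(probs, members)
  cfg <- config
  cfg$n_starts <- 1
  fit_single_sequence(sub, event_set, cfg, prior,
                      init = list(init_seq))$order
}

# EM-style alternation: assignment / per-cluster refit / fraction update.
# An emptied cluster is re-seeded with the subject it loses least by; data
# that genuinely support fewer clusters converge to a near-degenerate
# mixture with a vanishing fraction rather than aborting the fit.
.em_refine <- function(probs, event_set, sequences, config, prior) {
  n <- dim(probs$probs)[1]
  C <- length(sequences)
  if (n < C) return(NULL)
  fractions <- rep(1 / C, C)
  prev_ll <- -Inf
  for (iter in seq_len(config$em_max_iter)) {
    lmat <- vapply(sequences, function(s)
      subject_marginal_likelihood(probs, event_set, s, prior, log = TRUE),
      numeric(n))
    lw <- sweep(matrix(lmat, nrow = n), 2, log(pmax(fractions, 1e-12)), "+")
    assign <- max.col(lw, ties.method = "first")
    for (c in which(tabulate(assign, C) == 0)) {
      cost <- lw[cbind(seq_len(n), assign)] - lw[, c]
      movable <- which(tabulate(assign, C)[assign] > 1)
      if (!length(movable)) return(NULL)
      assign[movable[which.min(cost[movable])]] <- c
    }
    fractions <- tabulate(assign, C) / n
    for (c in seq_len(C))
      sequences[[c]] <- .quick_refit(probs, event_set, which(assign == c),
                                     config, prior, sequences[[c]])
    ll <- sum(mixture_logliks(probs, event_set, sequences, fractions, prior))
    if (is.finite(prev_ll) && ll - prev_ll < config$em_tol) break
    prev_ll <- ll
  }
  list(sequences = sequences, fractions = fractions, assign = assign,
       loglik = ll)
}

# order subtypes by fraction, attach assignments, fractions and MCMC
.finalize_model <- function(probs, event_set, sequences, C, prior, config,
                            group_label, em = NULL) {
  n <- dim(probs$probs)[1]
  if (is.null(em)) {
    fractions <- 1
    assign <- rep(1L, n)
  } else {
    ord <- order(em$fractions, decreasing = TRUE)
    sequences <- em$sequences[ord]
    fractions <- em$fractions[ord]
    assign <- match(em$assign, ord)
  }
  mcmc <- lapply(seq_len(C), function(c) {
    members <- which(assign == c)
    sub <- if (length(members)) subset_probs(probs, members) else probs
    mcmc_sample_sequences(sub, event_set, sequences[[c]], config, prior)
  })
  ll <- sum(mixture_logliks(probs, event_set, sequences, fractions, prior))
  structure(list(sequences = sequences, fractions = fractions,
                 mcmc = mcmc, loglik = ll, assignments = assign,
                 n_subtypes = C, stage_prior = prior,
                 event_set = event_set, group_label = group_label),
            class = "subtype_model")
}

#' @exportS3Method base::print
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model>%s %d subtype(s), M = %d events, loglik %.2f\n",
              if (!is.null(x$group_label)) paste0(" [", x$group_label, "]")
              else "", x$n_subtypes, n_events(x$event_set), x$loglik))
  for (c in seq_len(x$n_subtypes))
    cat(sprintf("  subtype %d (f = %.2f): %s ...\n", c, x$fractions[c],
                paste(head(sequence_labels(x$event_set, x$sequences[[c]]), 5),
                      collapse = " -> ")))
  invisible(x)
}

#' Select the number of subtypes by cross-validation
#'
#' 10-fold cross-validation (stratified by stage tertile of a preliminary
#' single-sequence fit so that no fold is empty of any disease epoch): for
#' each fold and each C, a model is fitted on the training subjects and the
#' held-out log-likelihood is computed integrating over the MCMC sequence
#' samples. CVIC(C) = -2 x the summed held-out log-likelihood; the C
#' minimising CVIC is selected (ties go to the smaller C).
#'
#' @inheritParams fit_subtype_path
#' @return list with `cvic` (named vector over C), `selected` C,
#'   `heldout_loglik` (fold x C matrix), `folds` (fold index per subject)
#'   and `fold_models` (per fold, the fitted model path).
#' @export
cross_validate_cvic <- function(probs, event_set, max_subtypes,
                                config = fit_config(), stage_prior = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- dim(probs$probs)[1]
  if (config$n_folds > n) stop("more folds than subjects")
  cfg <- config; cfg$seed <- NULL
  prior <- .check_prior(stage_prior, n_events(event_set))

  # stratify folds by stage tertile of a cheap preliminary fit
  pre_cfg <- cfg; pre_cfg$n_starts <- min(cfg$n_starts, 5)
  pre <- fit_single_sequence(probs, event_set, pre_cfg, prior)
  stages <- max.col(stage_posterior(probs, event_set, pre$order, prior),
                    ties.method = "first") - 1L
  tert <- cut(rank(stages, ties.method = "first"), 3, labels = FALSE)
  folds <- integer(n)
  for (t in 1:3) {
    idx <- sample(which(tert == t))
    folds[idx] <- rep_len(seq_len(config$n_folds), length(idx))
  }
  if (any(tabulate(folds, config$n_folds) == 0))
    stop("a fold has zero test subjects; reduce n_folds")

  heldout <- matrix(NA_real_, config$n_folds, max_subtypes,
                    dimnames = list(paste0("fold", seq_len(config$n_folds)),
                                    paste0("C", seq_len(max_subtypes))))
  fold_models <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    train <- which(folds != f)
    test <- which(folds == f)
    path <- fit_subtype_path(subset_probs(probs, train), event_set,
                             max_subtypes, cfg, prior)
    fold_models[[f]] <- path
    test_probs <- subset_probs(probs, test)
    for (C in seq_len(max_subtypes))
      heldout[f, C] <- sum(heldout_loglik(test_probs, path[[C]]))
  }
  cvic <- -2 * colSums(heldout)
  list(cvic = cvic, selected = as.integer(which.min(cvic)),
       heldout_loglik = heldout, folds = folds, fold_models = fold_models)
}

#' Held-out log-likelihood under a fitted model
#'
#' Per-subject log mixture likelihood with the progression-pattern
#' uncertainty integrated out: the subtype likelihood is the average of the
#' stage-marginal likelihood over the model's MCMC sequence samples.
#'
#' @param probs score probabilities of the held-out subjects.
#' @param model a fitted `subtype_model`.
#' @return numeric vector of per-subject log-likelihoods.
#' @export
heldout_loglik <- function(probs, model) {
  n <- dim(probs$probs)[1]
  ev <- .ev_cpp(model$event_set)
  logp <- .logp(probs)
  per_subtype <- vapply(seq_len(model$n_subtypes), function(c) {
    samples <- model$mcmc[[c]]$samples
    lmat <- marginal_logliks_batch_cpp(logp, dim(probs$probs), ev$region,
                                       ev$level, samples - 1L,
                                       log(model$stage_prior))
    .row_logsumexp(lmat) - log(ncol(lmat))
  }, numeric(n))
  lw <- sweep(matrix(per_subtype, nrow = n), 2, log(model$fractions), "+")
  out <- .row_logsumexp(lw)
  names(out) <- dimnames(probs$probs)[[1]]
  out
}
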