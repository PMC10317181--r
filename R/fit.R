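#' Fitting configuration
#'
#' Bundles the tuning knobs of sequence fitting, MCMC and cross-validation.
#' Defaults are sized for desk-scale cohorts; every count is configurable.
#'
#' @param n_starts greedy multi-start count (default 25).
#' @param mcmc_iterations Metropolis-Hastings chain length (default 10000).
#' @param burn_frac fraction of the chain discarded as burn-in (default 0.2).
#' @param max_samples at most this many thinned samples are stored
#'   (default 1000).
#' @param em_max_iter assignment/refit alternation cap for subtype fitting
#'   (default 100).
#' @param em_tol log-likelihood convergence tolerance (default 1e-6).
#' @param n_folds cross-validation folds (default 10).
#' @param n_split_tries random bipartitions tried per cluster split
#'   (default 4).
#' @param seed optional integer seed; when given, fits are fully
#'   deterministic.
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_starts = 25, mcmc_iterations = 10000,
                       burn_frac = 0.2, max_samples = 1000,
                       em_max_iter = 100, em_tol = 1e-6, n_folds = 10,
                       n_split_tries = 4, seed = NULL) {
  stopifnot(n_starts >= 1, mcmc_iterations >= 1, em_max_iter >= 1,
            em_tol > 0, n_folds >= 2, n_split_tries >= 1,
            burn_frac >= 0, burn_frac < 1, max_samples >= 1)
  structure(list(n_starts = n_starts, mcmc_iterations = mcmc_iterations,
                 burn_frac = burn_frac, max_samples = max_samples,
                 em_max_iter = em_max_iter, em_tol = em_tol,
                 n_folds = n_folds, n_split_tries = n_split_tries,
                 seed = seed),
            class = "fit_config")
}

#' Fit a single progression sequence
#'
#' Greedy coordinate ascent on the stage-marginalised dataset log-likelihood:
#' from each of `n_starts` random valid sequences, every event is repeatedly
#' relocated to its best admissible position until no relocation improves the
#' objective; the best start wins. Deterministic given `config$seed`.
#'
#' @param probs a [ratings_to_probabilities()] result.
#' @param event_set the event set.
#' @param config a [fit_config()].
#' @param stage_prior optional prior over stages 0..M (default uniform).
#' @param init optional list of starting sequences to use instead of random
#'   starts.
#' @return list with `order` (event-id sequence), `loglik`, `event_set`.
#' @export
fit_single_sequence <- function(probs, event_set, config = fit_config(),
                                stage_prior = NULL, init = NULL) {
  if (dim(probs$probs)[1] < 1) stop("need at least one subject")
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- n_events(event_set)
  prior <- .check_prior(stage_prior, m)
  ev <- .ev_cpp(event_set)
  logp <- .logp(probs)
  dims <- dim(probs$probs)
  starts <- if (is.null(init)) {
    lapply(seq_len(config$n_starts), function(i) random_valid_sequence(event_set))
  } else init
  best <- NULL
  for (s in starts) {
    fit <- greedy_fit_cpp(logp, dims, ev$region, ev$level,
                          as.integer(s) - 1L, log(prior))
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  list(order = as.integer(best$order) + 1L, loglik = best$loglik,
       event_set = event_set)
}

#' Sample sequence uncertainty by MCMC
#'
#' Metropolis-Hastings over valid sequences: each proposal relocates one
#' uniformly chosen event to a uniformly chosen admissible position, accepted
#' with probability min(1, L_new / L_old). Returns thinned post-burn-in
#' samples and the event x position frequency matrix that underlies
#' positional variance diagrams.
#'
#' @inheritParams fit_single_sequence
#' @param start_order starting sequence (typically the greedy fit).
#' @return list with `samples` (rows = sampled sequences of event ids),
#'   `logliks`, `acceptance_rate` and `positional_density`
#'   (M x M matrix; row e gives the frequency of event e at each position;
#'   rows sum to 1).
#' @export
mcmc_sample_sequences <- function(probs, event_set, start_order,
                                  config = fit_config(), stage_prior = NULL) {
  start_order <- .check_sequence(event_set, start_order)
  if (!is.null(config$seed)) set.seed(config$seed)
  m <- n_events(event_set)
  prior <- .check_prior(stage_prior, m)
  ev <- .ev_cpp(event_set)
  n_iter <- config$mcmc_iterations
  burn <- floor(config$burn_frac * n_iter)
  thin <- max(1L, ceiling((n_iter - burn) / config$max_samples))
  res <- mcmc_cpp(.logp(probs), dim(probs$probs), ev$region, ev$level,
                  start_order - 1L, log(prior), n_iter, burn, thin)
  samples <- res$samples + 1L
  list(samples = samples, logliks = res$logliks,
       acceptance_rate = res$acceptance_rate,
       positional_density = positional_density(samples, m))
}

#' Positional density of MCMC sequence samples
#'
#' @param samples matrix of sampled sequences (rows), entries event ids.
#' @param m number of events.
#' @return M x M matrix: entry (e, k) is the fraction of samples placing
#'   event e at position k; rows sum to 1.
#' @export
positional_density <- function(samples, m = ncol(samples)) {
  dens <- matrix(0, m, m,
                 dimnames = list(paste0("event", seq_len(m)),
                                 paste0("pos", seq_len(m))))
  for (i in seq_len(nrow(samples)))
    dens[cbind(samples[i, ], seq_len(m))] <-
      dens[cbind(samples[i, ], seq_len(m))] + 1
  dens / nrow(samples)
}
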