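# Small in-code fixtures shared across tests.

# tiny score table with known ratings and missingness
tiny_table <- function() {
  m <- matrix(c(0, 0.5, 1,
                2, 3, NA,
                0, 0, 0.5), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("rA", "rB", "rC")))
  score_table(m, group = c("g1", "g1", "g2"))
}

# score_probs object built directly from a per-subject/region probability
# list: probs_list[[subject]][[region]] = numeric(4). Bypasses the kernel so
# tests can plant exact probabilities.
manual_probs <- function(probs_list, region_names = NULL) {
  n <- length(probs_list)
  r <- length(probs_list[[1]])
  if (is.null(region_names)) region_names <- paste0("r", seq_len(r))
  arr <- array(NA_real_, c(n, r, 4),
               dimnames = list(paste0("s", seq_len(n)), region_names,
                               paste0("score", 0:3)))
  for (i in seq_len(n))
    for (j in seq_len(r))
      arr[i, j, ] <- probs_list[[i]][[j]]
  structure(list(probs = arr, sigma = 0.5, max_score = 3, group = NULL),
            class = "score_probs")
}

# two-region one-level probability object: P over {baseline, level1} given
# as c(p0, p1) per region; padded to 4 levels with ~zero mass so the shared
# 4-level tensor layout applies (max_score = 1 event sets ignore the rest)
two_region_probs <- function(p_r1, p_r2) {
  pad <- function(p) c(p, 1e-300, 1e-300) / sum(c(p, 1e-300, 1e-300))
  manual_probs(list(list(pad(p_r1), pad(p_r2))))
}

quick_config <- function(seed = 1, ...) {
  args <- list(n_starts = 3, mcmc_iterations = 500, max_samples = 100,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(fit_config, args)
}

# kendall rank correlation between two event orders
order_tau <- function(es, a, b) {
  cor(match(es$event, a), match(es$event, b), method = "kendall")
}
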