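test_that("event sets enumerate region x level events", {
  expect_equal(n_events(build_event_set(paste0("r", 1:20), 3)), 60)
  expect_equal(n_events(build_event_set(paste0("r", 1:18), 3)), 54)
  expect_equal(n_events(build_event_set(paste0("r", 1:19), 3)), 57)
  expect_equal(n_events(build_event_set("r1", 1)), 1)
  es <- build_event_set(c("a", "b"), 3)
  expect_false(anyDuplicated(paste(es$region, es$level)) > 0)
  expect_error(build_event_set(character(0)), "empty")
})

test_that("stage-conditional likelihoods multiply implied-level probabilities", {
  # 1 region / 1 level, P = (0.9, 0.1)
  pr1 <- manual_probs(list(list(c(0.9, 0.1, 1e-300, 1e-300))))
  es1 <- build_event_set("r1", 1)
  expect_equal(stage_conditional_likelihood(pr1, es1, 1L, 1, 0), 0.9,
               tolerance = 1e-12)
  expect_equal(stage_conditional_likelihood(pr1, es1, 1L, 1, 1), 0.1,
               tolerance = 1e-12)
  # 2 regions / 1 level, order (r1, r2): stage likelihoods 0.14, 0.56, 0.24
  pr2 <- two_region_probs(c(0.2, 0.8), c(0.7, 0.3))
  es2 <- build_event_set(c("r1", "r2"), 1)
  ll <- exp(stage_loglik_matrix(pr2, es2, c(1L, 2L)))
  expect_equal(as.numeric(ll), c(0.14, 0.56, 0.24), tolerance = 1e-9)
  # subject with all mass on the baseline has likelihood 1 at stage 0
  pr0 <- manual_probs(list(list(c(1, 1e-300, 1e-300, 1e-300),
                                c(1, 1e-300, 1e-300, 1e-300))))
  expect_equal(stage_conditional_likelihood(pr0, es2, c(1L, 2L), 1, 0), 1,
               tolerance = 1e-9)
})

test_that("stage-marginal likelihood averages over the stage prior", {
  pr1 <- manual_probs(list(list(c(0.9, 0.1, 1e-300, 1e-300))))
  es1 <- build_event_set("r1", 1)
  expect_equal(unname(subject_marginal_likelihood(pr1, es1, 1L)), 0.5,
               tolerance = 1e-9)
  # prior concentrated at k* returns the stage-conditional value
  expect_equal(unname(subject_marginal_likelihood(pr1, es1, 1L,
                                                  stage_prior = c(0, 1))),
               0.1, tolerance = 1e-9)
  pr2 <- two_region_probs(c(0.2, 0.8), c(0.7, 0.3))
  es2 <- build_event_set(c("r1", "r2"), 1)
  expect_equal(unname(subject_marginal_likelihood(pr2, es2, c(1L, 2L))),
               (0.14 + 0.56 + 0.24) / 3, tolerance = 1e-9)
  expect_error(subject_marginal_likelihood(pr2, es2, c(1L, 2L),
                                           stage_prior = c(0.5, 0.5, 0.5)),
               "sum to 1")
})

test_that("dataset log-likelihood is an additive mixture objective", {
  set.seed(3)
  tab <- score_table(matrix(sample(c(0, 1, 2, 3), 12, TRUE), 4, 3))
  pr <- ratings_to_probabilities(tab)
  es <- build_event_set(regions(tab), 3)
  model <- fit_subtypes(pr, es, 1, quick_config(seed = 5))
  # C = 1 reduces to the sum of log marginal likelihoods
  expect_equal(dataset_log_likelihood(pr, model),
               sum(subject_marginal_likelihood(pr, es, model$sequences[[1]],
                                               log = TRUE)),
               tolerance = 1e-9)
  # duplicating every subject doubles the log-likelihood
  tab2 <- score_table(rbind(tab$ratings,
                            `rownames<-`(tab$ratings,
                                         paste0(rownames(tab$ratings), "b"))))
  pr_dup <- ratings_to_probabilities(tab2)
  expect_equal(dataset_log_likelihood(pr_dup, model),
               2 * dataset_log_likelihood(pr, model), tolerance = 1e-9)
  # tiny two-subject instance against a hand computation
  pr2 <- manual_probs(list(list(c(0.2, 0.8, 1e-300, 1e-300),
                                c(0.7, 0.3, 1e-300, 1e-300)),
                           list(c(0.6, 0.4, 1e-300, 1e-300),
                                c(0.5, 0.5, 1e-300, 1e-300))))
  es2 <- build_event_set(c("r1", "r2"), 1)
  hand1 <- (0.2 * 0.7 + 0.8 * 0.7 + 0.8 * 0.3) / 3
  hand2 <- (0.6 * 0.5 + 0.4 * 0.5 + 0.4 * 0.5) / 3
  got <- subject_marginal_likelihood(pr2, es2, c(1L, 2L))
  expect_equal(unname(got), c(hand1, hand2), tolerance = 1e-9)
})

test_that("valid-sequence enumeration counts lattice interleavings", {
  expect_length(enumerate_valid_sequences(build_event_set(c("a", "b"), 1)), 2)
  expect_length(enumerate_valid_sequences(build_event_set("a", 3)), 1)
  seqs <- enumerate_valid_sequences(build_event_set(c("a", "b"), 2))
  expect_length(seqs, 6)
  es <- build_event_set(c("a", "b"), 2)
  expect_true(all(vapply(seqs, function(s) is_valid_sequence(es, s),
                         logical(1))))
  expect_error(enumerate_valid_sequences(build_event_set(paste0("r", 1:6), 2)),
               "too large")
})

test_that("likelihoods are invariant to region input order", {
  set.seed(11)
  tab <- score_table(matrix(sample(c(0, 0.5, 1, 2, 3, NA), 20, TRUE), 4, 5,
                            dimnames = list(paste0("s", 1:4),
                                            paste0("r", 1:5))))
  perm <- c(4, 2, 5, 1, 3)
  tab_perm <- score_table(tab$ratings[, perm])
  es <- build_event_set(regions(tab), 2)
  es_perm <- build_event_set(regions(tab_perm), 2)
  ord <- random_valid_sequence(es)
  # express the same event order relative to the permuted event set
  ord_perm <- sequence_from_labels(es_perm, sequence_labels(es, ord))
  l1 <- subject_marginal_likelihood(ratings_to_probabilities(tab), es, ord,
                                    log = TRUE)
  l2 <- subject_marginal_likelihood(ratings_to_probabilities(tab_perm),
                                    es_perm, ord_perm, log = TRUE)
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("stage posterior rows normalise to one", {
  set.seed(13)
  tab <- score_table(matrix(sample(c(0, 1, 2, 3), 15, TRUE), 5, 3))
  pr <- ratings_to_probabilities(tab)
  es <- build_event_set(regions(tab), 3)
  post <- stage_posterior(pr, es, random_valid_sequence(es))
  expect_equal(unname(rowSums(post)), rep(1, 5), tolerance = 1e-12)
  expect_true(all(post >= 0))
})
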