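test_that("greedy fit recovers a noiseless staged cohort exactly", {
  regs <- paste0("r", 1:5)
  es <- build_event_set(regs, 3)
  truth <- staggered_sequence(es, regs)
  cfg <- generator_config(regs, list(truth), n_subjects = n_events(es) + 1,
                          stage_dist = "uniform", epsilon = 0, missingness = 0,
                          seed = 21)
  coh <- generate_cohort(cfg)
  # one subject per stage: overwrite sampled stages deterministically
  coh$truth$stage <- 0:n_events(es)
  true_tab <- attr(coh$truth, "true_table")
  ratings <- true_tab$ratings
  for (i in seq_len(nrow(ratings))) {
    k <- coh$truth$stage[i]
    lev <- rep(0, length(regs)); names(lev) <- regs
    if (k > 0) {
      head_events <- truth[seq_len(k)]
      got <- tapply(es$level[head_events], es$region[head_events], max)
      lev[names(got)] <- got
    }
    ratings[i, ] <- lev[colnames(ratings)]
  }
  pr <- ratings_to_probabilities(score_table(ratings))
  fit <- fit_single_sequence(pr, es, quick_config(seed = 2, n_starts = 5))
  expect_identical(fit$order, truth)
})

test_that("greedy fit matches the brute-force oracle on small instances", {
  # 3 regions x 2 levels: M = 6, 90 valid sequences; 25 seeded instances
  regs <- c("a", "b", "c")
  es <- build_event_set(regs, 2)
  all_seqs <- enumerate_valid_sequences(es)
  expect_length(all_seqs, 90)
  hits <- 0
  for (i in 1:25) {
    set.seed(1000 + i)
    tab <- score_table(matrix(sample(c(0, 0.5, 1, 2), 10 * 3, TRUE), 10, 3,
                              dimnames = list(NULL, regs)))
    pr <- ratings_to_probabilities(tab, max_score = 3)
    obj <- vapply(all_seqs, function(s)
      sum(subject_marginal_likelihood(pr, es, s, log = TRUE)), numeric(1))
    best <- max(obj)
    fit <- fit_single_sequence(pr, es, quick_config(seed = i, n_starts = 5))
    hits <- hits + (fit$loglik >= best - 1e-9)
  }
  expect_gte(hits, 24)  # >= 95% oracle agreement
})

test_that("single-region event sets admit only the forced sequence", {
  pr <- manual_probs(list(list(c(0.25, 0.25, 0.25, 0.25))))
  es <- build_event_set("r1", 3)
  fit <- fit_single_sequence(pr, es, quick_config())
  expect_identical(fit$order, 1:3)
})

test_that("sequence fitting is deterministic given the seed", {
  coh <- generate_cohort(cohort_preset("LATE-like", n_subjects = 40, seed = 9))
  pr <- ratings_to_probabilities(coh$table)
  es <- build_event_set(regions(coh$table), 3)
  f1 <- fit_single_sequence(pr, es, quick_config(seed = 4))
  f2 <- fit_single_sequence(pr, es, quick_config(seed = 4))
  expect_identical(f1$order, f2$order)
  m1 <- mcmc_sample_sequences(pr, es, f1$order, quick_config(seed = 5))
  m2 <- mcmc_sample_sequences(pr, es, f1$order, quick_config(seed = 5))
  expect_identical(m1$samples, m2$samples)
})

test_that("MCMC samples stay valid and their positional density normalises", {
  regs <- paste0("r", 1:4)
  es <- build_event_set(regs, 2)
  coh <- generate_cohort(generator_config(regs, list(staggered_sequence(es, regs)),
                                          n_subjects = 50, max_score = 2,
                                          epsilon = 0.1, seed = 31))
  pr <- ratings_to_probabilities(coh$table)
  fit <- fit_single_sequence(pr, es, quick_config(seed = 1))
  mc <- mcmc_sample_sequences(pr, es, fit$order, quick_config(seed = 2))
  expect_true(all(apply(mc$samples, 1, function(s) is_valid_sequence(es, s))))
  expect_equal(unname(rowSums(mc$positional_density)),
               rep(1, n_events(es)), tolerance = 1e-12)
  expect_gt(mc$acceptance_rate, 0)
})

test_that("MCMC modal positions recover a well-sampled noiseless sequence", {
  regs <- paste0("r", 1:4)
  es <- build_event_set(regs, 2)
  truth <- staggered_sequence(es, regs)
  coh <- generate_cohort(generator_config(regs, list(truth), n_subjects = 300,
                                          stage_dist = "uniform", max_score = 2,
                                          epsilon = 0, missingness = 0,
                                          seed = 41))
  pr <- ratings_to_probabilities(coh$table)
  fit <- fit_single_sequence(pr, es, quick_config(seed = 1))
  mc <- mcmc_sample_sequences(pr, es, fit$order,
                              quick_config(seed = 2, mcmc_iterations = 4000))
  modal <- apply(mc$positional_density, 1, which.max)
  expect_equal(unname(modal[truth]), seq_len(n_events(es)))
})

test_that("subtype fitting delegates for C = 1 and recovers planted subtypes", {
  regs <- paste0("r", 1:6)
  es <- build_event_set(regs, 3)
  s1 <- staggered_sequence(es, regs)
  s2 <- staggered_sequence(es, rev(regs))
  coh <- generate_cohort(generator_config(regs, list(s1, s2),
                                          fractions = c(0.5, 0.5),
                                          n_subjects = 150, epsilon = 0.05,
                                          seed = 51))
  pr <- ratings_to_probabilities(coh$table)
  m1 <- fit_subtypes(pr, es, 1, quick_config(seed = 6))
  f1 <- fit_single_sequence(pr, es, quick_config(seed = 6))
  expect_identical(m1$sequences[[1]], f1$order)
  m2 <- fit_subtypes(pr, es, 2, quick_config(seed = 6))
  expect_equal(sum(m2$fractions), 1, tolerance = 1e-12)
  expect_true(all(vapply(m2$sequences, function(s) is_valid_sequence(es, s),
                         logical(1))))
  a <- assign_subtype_and_stage(pr, m2)
  keep <- coh$truth$stage > 0  # subtype unidentifiable at stage 0
  acc <- max(mean(a$subtype[keep] == coh$truth$subtype[keep]),
             mean(a$subtype[keep] == 3 - coh$truth$subtype[keep]))
  expect_gte(acc, 0.9)
})

test_that("cross-validation folds partition the cohort exactly once", {
  regs <- paste0("r", 1:5)
  es <- build_event_set(regs, 2)
  coh <- generate_cohort(generator_config(regs, list(staggered_sequence(es, regs)),
                                          n_subjects = 60, max_score = 2,
                                          epsilon = 0.1, seed = 61))
  pr <- ratings_to_probabilities(coh$table)
  cv <- cross_validate_cvic(pr, es, 1,
                            quick_config(seed = 7, n_folds = 5, n_starts = 2))
  expect_length(cv$folds, 60)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(sum(tabulate(cv$folds, 5)), 60)
  expect_length(cv$cvic, 1)
  expect_true(is.finite(cv$cvic))
})
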