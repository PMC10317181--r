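# small fitted model shared by the assignment tests
fit_demo_model <- function(n = 60, seed = 71, regs = paste0("r", 1:5)) {
  es <- build_event_set(regs, 3)
  coh <- generate_cohort(generator_config(
    regs, list(staggered_sequence(es, regs)), n_subjects = n,
    epsilon = 0.05, seed = seed))
  pr <- ratings_to_probabilities(coh$table)
  model <- fit_subtypes(pr, es, 1, quick_config(seed = 3),
                        group_label = "demo")
  list(coh = coh, pr = pr, es = es, model = model)
}

test_that("extreme subjects land on the extreme stages", {
  d <- fit_demo_model()
  m <- n_events(d$es)
  ones <- function() c(1, 1e-300, 1e-300, 1e-300)
  threes <- function() c(1e-300, 1e-300, 1e-300, 1)
  pr_lo <- manual_probs(lapply(1:2, function(i) lapply(1:5, function(j) ones())),
                        region_names = regions(d$coh$table))
  pr_hi <- manual_probs(lapply(1:2, function(i) lapply(1:5, function(j) threes())),
                        region_names = regions(d$coh$table))
  a_lo <- assign_subtype_and_stage(pr_lo, d$model)
  a_hi <- assign_subtype_and_stage(pr_hi, d$model)
  expect_equal(a_lo$ml_stage, c(0L, 0L))
  expect_equal(a_hi$ml_stage, c(m, m))
})

test_that("assignment posteriors normalise and stages track the truth", {
  d <- fit_demo_model(n = 200, seed = 72)
  a <- assign_subtype_and_stage(d$pr, d$model)
  sp <- attr(a, "stage_posterior")
  expect_equal(unname(rowSums(sp)), rep(1, nrow(sp)), tolerance = 1e-9)
  expect_equal(unname(rowSums(attr(a, "subtype_posterior"))),
               rep(1, nrow(sp)), tolerance = 1e-9)
  expect_equal(a$ml_stage, max.col(sp, ties.method = "first") - 1L)
  # low-noise staging error within two events on average
  expect_lte(mean(abs(a$ml_stage - d$coh$truth$stage)), 2)
  # histogram sums to the cohort size
  expect_equal(sum(stage_histogram(a, n_events(d$es))), nrow(a))
})

test_that("an all-missing subject has a uniform stage posterior", {
  d <- fit_demo_model()
  m <- n_events(d$es)
  unif <- function() rep(0.25, 4)
  pr_na <- manual_probs(list(lapply(1:5, function(j) unif())),
                        region_names = regions(d$coh$table))
  a <- assign_subtype_and_stage(pr_na, d$model)
  expect_equal(as.numeric(attr(a, "stage_posterior")),
               rep(1 / (m + 1), m + 1), tolerance = 1e-9)
  expect_equal(a$fit_probability, 1 / (m + 1), tolerance = 1e-9)
  expect_equal(a$ml_stage, 0L)  # tie resolves to the lowest stage
})

test_that("fit probabilities discriminate matched from mismatched models", {
  regs <- paste0("r", 1:5)
  es <- build_event_set(regs, 3)
  fwd <- staggered_sequence(es, regs)
  coh <- generate_cohort(generator_config(regs, list(fwd), n_subjects = 100,
                                          epsilon = 0.1, seed = 81,
                                          group_label = "fwd"))
  pr <- ratings_to_probabilities(coh$table)
  m_fwd <- fit_subtypes(pr, es, 1, quick_config(seed = 1))
  coh_rev <- generate_cohort(generator_config(regs,
                                              list(staggered_sequence(es, rev(regs))),
                                              n_subjects = 100, epsilon = 0.1,
                                              seed = 82, group_label = "rev"))
  pr_rev <- ratings_to_probabilities(coh_rev$table)
  m_rev <- fit_subtypes(pr_rev, es, 1, quick_config(seed = 2))
  jp <- group_fit_probabilities(pr, list(fwd = m_fwd, rev = m_rev))
  expect_true(all(jp$fit_probs >= 0 & jp$fit_probs <= 1))
  expect_gt(mean(jp$fit_probs[, "fwd"]), mean(jp$fit_probs[, "rev"]))
  # and the within-model posterior maximum stays a bounded probability
  p_match <- model_fit_probability(pr, m_fwd, within_group = FALSE)
  expect_true(all(p_match >= 0 & p_match <= 1))
})

test_that("within-group fit probabilities demand a fold map", {
  d <- fit_demo_model()
  d$pr$group <- rep("demo", dim(d$pr$probs)[1])
  expect_error(model_fit_probability(d$pr, d$model), "out-of-sample")
  expect_silent(model_fit_probability(d$pr, d$model, within_group = FALSE))
})

test_that("crossover detection applies the 1/k chance-level rule", {
  fake_assign <- function(stages, p1) {
    a <- data.frame(subject_id = paste0("s", seq_along(stages)),
                    subtype = 1L, ml_stage = stages,
                    fit_probability = 0.5)
    attr(a, "subtype_posterior") <- cbind(p1, 1 - p1)
    a
  }
  # k = 2: chance level is 50%
  a1 <- fake_assign(2:6, rep(0.9, 5))
  r1 <- detect_crossover(a1, 2)
  expect_equal(r1$chance_level, 0.5)
  expect_false(r1$crossover)
  # drop below chance at stage 5 -> crossover flagged there
  a2 <- fake_assign(2:6, c(0.8, 0.8, 0.8, 0.3, 0.3))
  r2 <- detect_crossover(a2, 2)
  expect_true(r2$crossover)
  expect_equal(r2$crossover_stages, 5)
  # unpopulated stages are reported
  a3 <- fake_assign(c(0, 1, 4), c(0.9, 0.9, 0.9))
  expect_equal(detect_crossover(a3, 2)$empty_stages, c(2, 3))
})
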