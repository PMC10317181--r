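fake_assignments <- function(stages, ids = paste0("s", seq_along(stages)),
                             subtype = 1L) {
  data.frame(subject_id = ids, subtype = subtype, ml_stage = stages,
             fit_probability = 0.5, stringsAsFactors = FALSE)
}

test_that("stage associations recover the planted correlation signs", {
  set.seed(31)
  stages <- sample(0:20, 60, replace = TRUE)
  md <- data.frame(subject_id = paste0("s", 1:60),
                   age_at_death = 70 + 0.5 * stages + rnorm(60, 0, 2),
                   flat = rnorm(60),
                   self = stages)
  a <- fake_assignments(stages)
  # correlating the stage with itself gives r = 1
  expect_equal(stage_association(a, md, "self")$estimate, 1)
  pos <- stage_association(a, md, "age_at_death")
  expect_gt(pos$estimate, 0.5)
  expect_lt(pos$p_value, 1e-6)
  expect_error(stage_association(a, md, "nope"), "no column")
  md0 <- md; md0$age_at_death <- 70
  expect_error(stage_association(a, md0, "age_at_death"), "zero variance")
})

test_that("LATE-like cohorts show positive stage-age coupling end to end", {
  coh <- generate_cohort(cohort_preset("LATE-like", n_subjects = 200, seed = 33))
  pr <- ratings_to_probabilities(filter_regions_by_missingness(coh$table)$table)
  es <- build_event_set(regions(filter_regions_by_missingness(coh$table)$table))
  model <- fit_subtypes(pr, es, 1, quick_config(seed = 4))
  a <- assign_subtype_and_stage(pr, model)
  res <- stage_association(a, coh$metadata, "age_at_death")
  expect_gt(res$estimate, 0)
  expect_lt(res$p_value, 0.05)
  # stage is a proxy for total pathology
  md <- coh$metadata
  md$total_pathology <- unname(total_pathology(coh$table))
  expect_gt(stage_association(a, md, "total_pathology")$estimate, 0.8)
})

test_that("the classifiable/unclassifiable t-test matches the Welch formula", {
  h <- c(rep("I", 4), rep("Unclassifiable", 3))
  p <- c(0.9, 0.8, 0.85, 0.95, 0.5, 0.4, 0.45)
  res <- classifiable_vs_unclassifiable_test(h, p)
  x <- p[1:4]; y <- p[5:7]
  tw <- (mean(x) - mean(y)) / sqrt(var(x) / 4 + var(y) / 3)
  expect_equal(res$t, tw, tolerance = 1e-12)
  expect_gt(res$t, 0)
  # identical groups give t = 0
  same <- classifiable_vs_unclassifiable_test(
    c("I", "I", "Unclassifiable", "Unclassifiable"), c(0.6, 0.4, 0.6, 0.4))
  expect_equal(same$t, 0)
  expect_error(classifiable_vs_unclassifiable_test(c("I", "I"), c(0.5, 0.5)),
               "at least 2")
})

test_that("region-wise GLM detects a planted subtype effect and only that", {
  set.seed(35)
  n <- 200
  stages <- sample(1:15, n, replace = TRUE)
  subtype <- rep(1:2, each = n / 2)
  regs <- paste0("r", 1:6)
  base <- sapply(regs, function(r) pmin(3, pmax(0, round(stages / 5))))
  base[subtype == 1, "r3"] <- pmin(3, base[subtype == 1, "r3"] + 1)  # planted
  tab <- score_table(base)
  a <- fake_assignments(stages, ids = rownames(tab$ratings),
                        subtype = subtype)
  res <- regionwise_subtype_glm(tab, a)
  expect_lt(res$q[res$region == "r3"], 0.05)
  expect_gt(res$t[res$region == "r3"], 0)  # more severe in subtype 1
  expect_true(all(res$q >= res$p))
  # antisymmetric under subtype relabelling
  a2 <- a; a2$subtype <- 3L - a$subtype
  res2 <- regionwise_subtype_glm(tab, a2)
  expect_equal(res2$t, -res$t, tolerance = 1e-9)
})

test_that("reported q-values equal the BH step-up transform of the p-values", {
  # independent step-up implementation as oracle
  bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- rev(cummin(rev(p[o] * m / seq_len(m))))
    out <- numeric(m); out[o] <- pmin(q, 1); out
  }
  expect_equal(bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(36)
  n <- 120
  stages <- sample(1:12, n, replace = TRUE)
  subtype <- sample(1:2, n, replace = TRUE)
  tab <- score_table(matrix(sample(c(0, 1, 2, 3), n * 8, TRUE), n, 8))
  a <- fake_assignments(stages, ids = rownames(tab$ratings),
                        subtype = subtype)
  res <- regionwise_subtype_glm(tab, a)
  expect_equal(res$q, bh(res$p), tolerance = 1e-12)
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-15))
  expect_true(all(res$q >= res$p))
})
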