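# The 21 sampled regions (short machine-safe names).
REGIONS_21 <- c(
  "amygdala", "dentate_gyrus", "ca_subiculum", "entorhinal_cortex",
  "anterior_cingulate", "sup_mid_temporal", "middle_frontal",
  "angular_gyrus", "occipital_cortex", "thalamus", "globus_pallidus",
  "caudate_putamen", "substantia_nigra", "midbrain", "locus_coeruleus",
  "upper_pons", "cerebellum", "medulla", "orbitofrontal_cortex",
  "motor_cortex", "spinal_cord")

#' Build a staggered event sequence from a region order
#'
#' Produces a valid event sequence in which regions reach level 1 in the
#' given order, and each region's level-2 and level-3 events trail by a fixed
#' lag, so that early regions accumulate severe pathology while later regions
#' are still being recruited — the shape seen in real staging data.
#'
#' @param event_set an event set.
#' @param region_order character vector: the regions in recruitment order.
#' @param lag positions between a region's successive level events
#'   (default two-thirds of the region count).
#' @return integer event-id sequence.
#' @export
staggered_sequence <- function(event_set, region_order,
                               lag = ceiling(2 * length(region_order) / 3)) {
  if (!setequal(region_order, attr(event_set, "regions")))
    stop("region_order must be a permutation of the event set's regions")
  rank <- match(event_set$region, region_order)
  key <- rank + (event_set$level - 1) * max(1, lag)
  ord <- event_set$event[order(key, event_set$event)]
  stopifnot(is_valid_sequence(event_set, ord))
  ord
}

#' Synthetic-cohort generator configuration
#'
#' Defines the ground truth a synthetic cohort is drawn from: per-subtype
#' event sequences, mixture fractions, a stage distribution, an ordinal
#' observation-noise model (adjacent-level flips, the sparse 0.5 rating
#' reachable from both 0 and 1), region-wise missingness, and a linear
#' stage-age coupling whose sign is configurable.
#'
#' @param regions character vector of region names.
#' @param sequences list of event-id sequences, one per subtype (relative to
#'   `build_event_set(regions, max_score)`).
#' @param fractions subtype mixture fractions (sum to 1).
#' @param n_subjects cohort size.
#' @param stage_dist `"geometric"` (many early-stage, few late-stage
#'   subjects; default) or `"uniform"` over stages 0..M.
#' @param stage_geom_p decay parameter of the truncated geometric stage
#'   distribution (default 0.05).
#' @param p_stage0 probability of stage 0, i.e. no pathology at all
#'   (default 0.01; geometric distribution only).
#' @param epsilon probability that an observed rating deviates one ladder
#'   step from the true score (default 0.1; must be < 0.5).
#' @param missingness per-region missing-cell rate: scalar or named vector
#'   (default 0.05).
#' @param age_intercept,age_slope,age_sd age-at-death model:
#'   age = intercept + slope x stage + N(0, sd).
#' @param duration_mean,duration_sd disease duration (years), truncated
#'   below at 0.5.
#' @param group_label label written on the generated table.
#' @param max_score highest modelled level (default 3).
#' @param seed RNG seed (reproducible cohorts).
#' @return a `generator_config` list.
#' @export
generator_config <- function(regions, sequences, fractions = NULL,
                             n_subjects = 100,
                             stage_dist = c("geometric", "uniform"),
                             stage_geom_p = 0.05, p_stage0 = 0.01,
                             epsilon = 0.1, missingness = 0.05,
                             age_intercept = 70, age_slope = 0, age_sd = 6,
                             duration_mean = 8, duration_sd = 3,
                             group_label = "synthetic", max_score = 3,
                             seed = NULL) {
  stage_dist <- match.arg(stage_dist)
  if (is.null(fractions)) fractions <- rep(1 / length(sequences),
                                           length(sequences))
  stopifnot(length(fractions) == length(sequences),
            abs(sum(fractions) - 1) < 1e-8,
            epsilon >= 0, epsilon < 0.5,
            all(missingness >= 0), all(missingness < 1))
  es <- build_event_set(regions, max_score)
  for (s in sequences)
    if (!is_valid_sequence(es, s)) stop("invalid ground-truth sequence")
  structure(list(regions = regions, sequences = sequences,
                 fractions = fractions, n_subjects = n_subjects,
                 stage_dist = stage_dist, stage_geom_p = stage_geom_p,
                 p_stage0 = p_stage0, epsilon = epsilon,
                 missingness = missingness, age_intercept = age_intercept,
                 age_slope = age_slope, age_sd = age_sd,
                 duration_mean = duration_mean, duration_sd = duration_sd,
                 group_label = group_label, max_score = max_score,
                 seed = seed),
            class = "generator_config")
}

# rating ladder neighbours for the adjacent-flip noise model
.LADDER <- c(0, 0.5, 1, 2, 3)

#' Generate a synthetic cohort
#'
#' Per subject: a subtype is drawn from the mixture fractions, a stage from
#' the stage distribution, true regional scores are those implied by the
#' subtype's sequence at that stage, each score is perturbed to an adjacent
#' rating with probability `epsilon` (0.5 sits between 0 and 1 on the
#' ladder), missingness is applied region-wise, and ages follow the linear
#' stage-age model. Fully reproducible given the config seed.
#'
#' @param config a [generator_config()] or [cohort_preset()].
#' @return list with `table` ([score_table]), `metadata`
#'   (cohort_metadata data.frame), `truth` (subject_id, subtype, stage,
#'   true noiseless ratings as attribute `true_table`), `event_set`,
#'   `config`.
#' @export
generate_cohort <- function(config) {
  if (!is.null(config$seed)) set.seed(config$seed)
  es <- build_event_set(config$regions, config$max_score)
  m <- n_events(es)
  n <- config$n_subjects
  subtype <- sample.int(length(config$fractions), n, replace = TRUE,
                        prob = config$fractions)
  stage <- if (config$stage_dist == "uniform") {
    sample(0:m, n, replace = TRUE)
  } else {
    w <- (1 - config$stage_geom_p)^(0:(m - 1))
    p <- c(config$p_stage0, (1 - config$p_stage0) * w / sum(w))
    sample(0:m, n, replace = TRUE, prob = p)
  }
  ids <- sprintf("%s_%03d", config$group_label, seq_len(n))

  # implied level per region at each subject's stage
  true <- matrix(0, n, length(config$regions),
                 dimnames = list(ids, config$regions))
  for (i in seq_len(n)) {
    k <- stage[i]
    if (k == 0) next
    head_events <- config$sequences[[subtype[i]]][seq_len(k)]
    lev <- tapply(es$level[head_events], es$region[head_events], max)
    true[i, names(lev)] <- lev
  }

  # adjacent-level observation noise on the 0/0.5/1/2/3 ladder
  obs <- true
  idx <- match(true, .LADDER)
  flip <- runif(length(idx)) < config$epsilon
  up <- runif(length(idx)) < 0.5
  new_idx <- idx + ifelse(up, 1L, -1L)
  new_idx[new_idx < 1] <- 2L                  # 0 can only move up to 0.5
  new_idx[new_idx > length(.LADDER)] <- length(.LADDER) - 1L  # 3 down to 2
  obs[flip] <- .LADDER[new_idx[flip]]

  miss_rate <- if (length(config$missingness) == 1)
    rep(config$missingness, length(config$regions))
  else config$missingness[config$regions]
  for (j in seq_along(config$regions))
    obs[runif(n) < miss_rate[j], j] <- NA_real_

  duration <- pmax(0.5, rnorm(n, config$duration_mean, config$duration_sd))
  age_death <- config$age_intercept + config$age_slope * stage +
    rnorm(n, 0, config$age_sd)
  metadata <- cohort_metadata(data.frame(
    subject_id = ids,
    age_at_onset = age_death - duration,
    age_at_death = age_death,
    disease_duration = duration,
    sex = sample(c("F", "M"), n, replace = TRUE),
    post_mortem_interval = pmax(2, rnorm(n, 12, 5)),
    braak_stage = sample(0:6, n, replace = TRUE),
    apoe_e2_carrier = runif(n) < 0.1,
    apoe_e4_carrier = runif(n) < 0.3,
    tdp_type = sample(c("A", "B", "C", "E", NA), n, replace = TRUE),
    stringsAsFactors = FALSE))
  truth <- data.frame(subject_id = ids, subtype = subtype, stage = stage,
                      stringsAsFactors = FALSE)
  attr(truth, "true_table") <- score_table(true,
                                           group = rep(config$group_label, n))
  list(table = score_table(obs, group = rep(config$group_label, n)),
       metadata = metadata, truth = truth, event_set = es, config = config)
}

#' Preset cohort configurations
#'
#' Three cohort archetypes matching the modelled proteinopathies:
#' \describe{
#'   \item{`ALS-like`}{progression beginning in the spinal cord, then
#'     medulla and motor cortex; n = 141; no stage-age coupling; high
#'     missingness in occipital cortex, locus coeruleus and orbitofrontal
#'     cortex (so the default 25% filter retains 18 of 21 regions).}
#'   \item{`FTLD-like`}{cortical-first progression; n = 126; negative
#'     stage-age coupling (later stages die younger); high missingness in
#'     orbitofrontal cortex (20 regions retained).}
#'   \item{`LATE-like`}{progression initially confined to the amygdala,
#'     then hippocampal and entorhinal regions; n = 304; positive stage-age
#'     coupling; high missingness in motor cortex and spinal cord
#'     (19 regions retained).}
#' }
#'
#' @param name preset name.
#' @param ... overrides passed on to [generator_config()]
#'   (e.g. `n_subjects`, `epsilon`, `seed`).
#' @return a [generator_config()].
#' @export
cohort_preset <- function(name = c("ALS-like", "FTLD-like", "LATE-like"),
                          ...) {
  name <- match.arg(name)
  es <- build_event_set(REGIONS_21, 3)
  base_miss <- setNames(rep(0.05, length(REGIONS_21)), REGIONS_21)
  p <- switch(
    name,
    "ALS-like" = {
      ord <- c("spinal_cord", "medulla", "motor_cortex", "caudate_putamen",
               "thalamus", "globus_pallidus", "midbrain", "substantia_nigra",
               "upper_pons", "anterior_cingulate", "middle_frontal",
               "angular_gyrus", "amygdala", "entorhinal_cortex",
               "ca_subiculum", "dentate_gyrus", "sup_mid_temporal",
               "occipital_cortex", "locus_coeruleus", "orbitofrontal_cortex",
               "cerebellum")
      miss <- base_miss
      miss[c("occipital_cortex", "locus_coeruleus",
             "orbitofrontal_cortex")] <- 0.3
      list(order = ord, n = 141, slope = 0, intercept = 63, miss = miss,
           label = "ALS-like", duration = 4, duration_sd = 2)
    },
    "FTLD-like" = {
      ord <- c("middle_frontal", "sup_mid_temporal", "anterior_cingulate",
               "orbitofrontal_cortex", "entorhinal_cortex", "amygdala",
               "angular_gyrus", "dentate_gyrus", "ca_subiculum",
               "caudate_putamen", "thalamus", "globus_pallidus",
               "occipital_cortex", "substantia_nigra", "midbrain",
               "upper_pons", "medulla", "motor_cortex", "spinal_cord",
               "locus_coeruleus", "cerebellum")
      miss <- base_miss
      miss["orbitofrontal_cortex"] <- 0.3
      list(order = ord, n = 126, slope = -0.25, intercept = 76, miss = miss,
           label = "FTLD-like", duration = 7, duration_sd = 3)
    },
    "LATE-like" = {
      ord <- c("amygdala", "ca_subiculum", "entorhinal_cortex",
               "dentate_gyrus", "orbitofrontal_cortex", "anterior_cingulate",
               "sup_mid_temporal", "middle_frontal", "angular_gyrus",
               "thalamus", "caudate_putamen", "globus_pallidus",
               "occipital_cortex", "midbrain", "substantia_nigra",
               "upper_pons", "locus_coeruleus", "medulla", "cerebellum",
               "motor_cortex", "spinal_cord")
      miss <- base_miss
      miss[c("motor_cortex", "spinal_cord")] <- 0.3
      list(order = ord, n = 304, slope = 0.35, intercept = 75, miss = miss,
           label = "LATE-like", duration = 6, duration_sd = 3)
    })
  args <- list(regions = REGIONS_21,
               sequences = list(staggered_sequence(es, p$order)),
               n_subjects = p$n, missingness = p$miss,
               age_intercept = p$intercept, age_slope = p$slope,
               duration_mean = p$duration, duration_sd = p$duration_sd,
               group_label = p$label)
  over <- list(...)
  args[names(over)] <- over
  do.call(generator_config, args)
}
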