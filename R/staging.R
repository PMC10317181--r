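#' Declarative heuristic staging scheme
#'
#' A literature staging system expressed as an ordered list of stages, each
#' owning a set of member regions. Staging works on composite regions of
#' interest: the per-stage mean of the subject's member-region ratings.
#'
#' @param name scheme name.
#' @param stages named list, in stage order (e.g. `I`, `II`, ...), each a
#'   character vector of member region names.
#' @return a `staging_scheme`.
#' @export
staging_scheme <- function(name, stages) {
  if (!length(stages)) stop("a scheme needs at least one stage")
  if (any(!lengths(stages))) stop("every stage needs at least one region")
  if (is.null(names(stages)))
    names(stages) <- as.character(utils::as.roman(seq_along(stages)))
  structure(list(name = name, stages = stages), class = "staging_scheme")
}

#' Read a staging scheme from YAML
#'
#' Expected layout: `name:` plus `stages:` as an ordered mapping from stage
#' label to a list of region names.
#'
#' @param path YAML file.
#' @return a [staging_scheme()].
#' @export
read_staging_scheme <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$name) || is.null(y$stages)) stop("scheme YAML needs 'name' and 'stages'")
  staging_scheme(y$name, lapply(y$stages, as.character))
}

#' Bundled example staging schemes
#'
#' Loads one of the staging-scheme configs shipped with the package
#' (`brettschneider_als`, `brettschneider_ftld`, `nelson_late`,
#' `josephs_late`, `rush_late`). The region memberships in these files are
#' provisional, plausible placeholders — the published schemes' exact
#' memberships should be supplied by editing the YAML.
#'
#' @param name scheme file stem.
#' @return a [staging_scheme()].
#' @export
example_staging_scheme <- function(name = c("brettschneider_als",
                                            "brettschneider_ftld",
                                            "nelson_late", "josephs_late",
                                            "rush_late")) {
  name <- match.arg(name)
  read_staging_scheme(system.file("extdata", "staging_schemes",
                                  paste0(name, ".yaml"),
                                  package = "ordsustain", mustWork = TRUE))
}

#' Composite region-of-interest scores under a staging scheme
#'
#' Per stage, the mean of the subject's non-missing member-region ratings;
#' a stage whose members are all missing yields `NA` and the subject is
#' flagged.
#'
#' @param table a [score_table].
#' @param scheme a [staging_scheme()].
#' @param subject optional subject id(s); default all.
#' @return subjects x stages matrix of composite scores, with attribute
#'   `flagged` naming subjects having an undefined stage composite.
#' @export
composite_stage_scores <- function(table, scheme, subject = NULL) {
  missing_regions <- setdiff(unique(unlist(scheme$stages)),
                             colnames(table$ratings))
  if (length(missing_regions))
    stop("scheme '", scheme$name, "' references unknown region(s): ",
         paste(missing_regions, collapse = ", "))
  mat <- table$ratings
  if (!is.null(subject)) mat <- mat[subject, , drop = FALSE]
  out <- vapply(scheme$stages, function(members)
    rowMeans(mat[, members, drop = FALSE], na.rm = TRUE),
    numeric(nrow(mat)))
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), names(scheme$stages)))
  out[is.nan(out)] <- NA_real_
  attr(out, "flagged") <- rownames(out)[apply(is.na(out), 1, any)]
  out
}

#' Assign a heuristic stage from composite scores
#'
#' A subject sits at the highest stage m such that the composite score is at
#' least `threshold` (default 1) for stage m and every earlier stage. A
#' subject showing out-of-order pathology — a composite at or above threshold
#' in a later stage but not in some earlier stage — is `"Unclassifiable"`;
#' a subject below threshold everywhere is stage `"0"`. An undefined
#' (all-missing) composite counts as below threshold.
#'
#' @param composites numeric vector of composite scores in stage order, or a
#'   subjects x stages matrix.
#' @param threshold rating needed to count a stage as reached (default 1).
#' @param strict use a strict `>` comparison instead of `>=`.
#' @return character stage labels (`"0"`, stage names, `"Unclassifiable"`).
#' @export
assign_heuristic_stage <- function(composites, threshold = 1,
                                   strict = FALSE) {
  if (is.matrix(composites)) {
    return(setNames(apply(composites, 1, assign_heuristic_stage,
                          threshold = threshold, strict = strict),
                    rownames(composites)))
  }
  labels <- names(composites) %||%
    as.character(utils::as.roman(seq_along(composites)))
  reached <- if (strict) composites > threshold else composites >= threshold
  reached[is.na(reached)] <- FALSE
  if (!any(reached)) return("0")
  run <- which(!reached)
  highest_contiguous <- if (!length(run)) length(reached) else run[1] - 1
  if (any(reached[seq_along(reached) > highest_contiguous]))
    return("Unclassifiable")
  labels[highest_contiguous]
}

#' Cross-tabulate heuristic against data-driven stages
#'
#' @param heuristic_stages character vector of heuristic stage labels, named
#'   by subject (as from [assign_heuristic_stage()] on a matrix).
#' @param assignments a [assign_subtype_and_stage()] result for the same
#'   subjects.
#' @param scheme optional [staging_scheme()] fixing the stage-label order.
#' @return list with `table` (heuristic x data-driven stage counts),
#'   `rank_correlation` (Spearman, classifiable subjects only, ordered
#'   0 < I < II < ...), `n_classifiable`, `n_unclassifiable`.
#' @export
compare_to_sustain <- function(heuristic_stages, assignments, scheme = NULL) {
  ids <- assignments$subject_id
  if (is.null(names(heuristic_stages))) {
    if (length(heuristic_stages) != length(ids))
      stop("subject mismatch between heuristic stages and assignments")
    names(heuristic_stages) <- ids
  }
  if (!setequal(names(heuristic_stages), ids))
    stop("subject mismatch between heuristic stages and assignments")
  h <- heuristic_stages[ids]
  stage_levels <- if (!is.null(scheme)) names(scheme$stages) else
    setdiff(sort(unique(h)), c("0", "Unclassifiable"))
  h <- factor(h, levels = c("0", stage_levels, "Unclassifiable"))
  tab <- table(heuristic = h, data_driven = assignments$ml_stage)
  classifiable <- h != "Unclassifiable"
  rank_cor <- NA_real_
  if (sum(classifiable) >= 3) {
    hnum <- as.integer(h[classifiable]) - 1L  # 0, I=1, II=2, ...
    dd <- assignments$ml_stage[classifiable]
    if (length(unique(hnum)) > 1 && length(unique(dd)) > 1)
      rank_cor <- stats::cor(hnum, dd, method = "spearman")
  }
  list(table = tab, rank_correlation = rank_cor,
       n_classifiable = sum(classifiable),
       n_unclassifiable = sum(!classifiable))
}
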