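#' @useDynLib ordsustain, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom cor.test t.test lm p.adjust
#'   coef quantile sd complete.cases setNames predict
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics axis image
#' @importFrom grDevices png dev.off hcl.colors
NULL

# Legal semi-quantitative ratings: 0 non-detectable, 0.5 sparse, 1 mild,
# 2 moderate, 3 severe.
RATING_SCALE <- c(0, 0.5, 1, 2, 3)

#' Regional score table
#'
#' Container for a subjects x regions matrix of semi-quantitative
#' neuropathology ratings on the scale 0 = non-detectable, 0.5 = sparse,
#' 1 = mild, 2 = moderate, 3 = severe, with `NA` marking missing cells,
#' plus an optional diagnostic group label per subject.
#'
#' @param ratings numeric matrix, subjects in rows (rownames = subject ids),
#'   regions in columns (colnames = region names). Entries must be in
#'   \{0, 0.5, 1, 2, 3\} or `NA`.
#' @param group optional character vector of group labels, one per subject.
#' @return an object of class `score_table`.
#' @export
score_table <- function(ratings, group = NULL) {
  ratings <- as.matrix(ratings)
  storage.mode(ratings) <- "double"
  if (is.null(rownames(ratings)))
    rownames(ratings) <- paste0("subj", seq_len(nrow(ratings)))
  if (is.null(colnames(ratings)))
    colnames(ratings) <- paste0("region", seq_len(ncol(ratings)))
  if (anyDuplicated(rownames(ratings)))
    stop("subject ids must be unique")
  if (anyDuplicated(colnames(ratings)))
    stop("region names must be unique")
  bad <- !is.na(ratings) & !(ratings %in% RATING_SCALE)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "rating %s at subject '%s', region '%s' is not on the 0/0.5/1/2/3 scale",
      format(ratings[bad][1]), rownames(ratings)[idx[1]],
      colnames(ratings)[idx[2]]))
  }
  if (!is.null(group)) {
    group <- as.character(group)
    if (length(group) != nrow(ratings))
      stop("'group' must have one label per subject")
  }
  structure(list(ratings = ratings, group = group), class = "score_table")
}

#' @exportS3Method base::print
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d subjects x %d regions\n",
              nrow(x$ratings), ncol(x$ratings)))
  miss <- mean(is.na(x$ratings))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat("  groups:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.score_table <- function(x) dim(x$ratings)

#' Subject ids and region names of a score table
#' @param table a [score_table].
#' @return character vector.
#' @export
subjects <- function(table) rownames(table$ratings)

#' @rdname subjects
#' @export
regions <- function(table) colnames(table$ratings)

#' Read a regional score table from CSV
#'
#' Expects the first column to contain subject identifiers and the remaining
#' columns one region each; a column named by `group_column` (if present) is
#' treated as the diagnostic group label rather than a region. Cells matching
#' any token in `missing_tokens` become missing.
#'
#' @param path CSV file path.
#' @param missing_tokens character tokens marking a missing rating
#'   (default empty cell and `"NA"`).
#' @param group_column name of an optional group-label column
#'   (default `"group"`).
#' @return a [score_table].
#' @export
read_score_table <- function(path, missing_tokens = c("", "NA"),
                             group_column = "group") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character(0))
  if (ncol(raw) < 2)
    stop("malformed CSV: need a subject-id column plus at least one region")
  ids <- raw[[1]]
  raw <- raw[, -1, drop = FALSE]
  group <- NULL
  if (group_column %in% names(raw)) {
    group <- raw[[group_column]]
    raw <- raw[, setdiff(names(raw), group_column), drop = FALSE]
  }
  mat <- matrix(NA_real_, nrow(raw), ncol(raw),
                dimnames = list(ids, names(raw)))
  for (j in seq_len(ncol(raw))) {
    cell <- trimws(raw[[j]])
    is_miss <- cell %in% missing_tokens
    val <- suppressWarnings(as.numeric(cell))
    bad <- !is_miss & (is.na(val) | !(val %in% RATING_SCALE))
    if (any(bad))
      stop(sprintf(
        "invalid rating '%s' at row %d, column '%s' (legal: 0, 0.5, 1, 2, 3)",
        cell[which(bad)[1]], which(bad)[1], names(raw)[j]))
    val[is_miss] <- NA_real_
    mat[, j] <- val
  }
  score_table(mat, group = group)
}

#' Write a regional score table to CSV
#'
#' Inverse of [read_score_table()]: round-trips ratings, the missingness
#' pattern and the group column.
#'
#' @param table a [score_table].
#' @param path output CSV path.
#' @param missing_token token written for missing cells (default `"NA"`).
#' @export
write_score_table <- function(table, path, missing_token = "NA") {
  mat <- table$ratings
  df <- data.frame(subject_id = rownames(mat), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$group)) df$group <- table$group
  for (j in seq_len(ncol(mat))) {
    col <- format(mat[, j], trim = TRUE)
    col[is.na(mat[, j])] <- missing_token
    df[[colnames(mat)[j]]] <- col
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop regions with too much missing data
#'
#' Regions missing in strictly more than `threshold` of subjects are removed
#' before modelling; a region missing in exactly the threshold fraction is
#' retained.
#'
#' @param table a [score_table].
#' @param threshold maximum tolerated missing fraction (default 0.25).
#' @return list with elements `table` (filtered [score_table]) and
#'   `excluded` (character vector of removed region names).
#' @export
filter_regions_by_missingness <- function(table, threshold = 0.25) {
  stopifnot(threshold >= 0, threshold <= 1)
  frac <- colMeans(is.na(table$ratings))
  drop <- frac > threshold
  if (all(drop))
    stop("all regions exceed the missingness threshold; model undefined")
  out <- score_table(table$ratings[, !drop, drop = FALSE], group = table$group)
  list(table = out, excluded = colnames(table$ratings)[drop])
}

#' Total pathology burden per subject
#'
#' Sum of all non-missing regional ratings for each subject; missing cells
#' contribute zero.
#'
#' @param table a [score_table].
#' @param subject optional subject id (or vector of ids); default all.
#' @return named numeric vector of per-subject totals.
#' @export
total_pathology <- function(table, subject = NULL) {
  tot <- rowSums(table$ratings, na.rm = TRUE)
  if (is.null(subject)) return(tot)
  missing <- setdiff(subject, names(tot))
  if (length(missing))
    stop("unknown subject(s): ", paste(missing, collapse = ", "))
  tot[subject]
}

#' Validate per-subject cohort metadata
#'
#' Checks the consistency invariant disease_duration = age_at_death -
#' age_at_onset wherever all three are present.
#'
#' @param df data.frame with a `subject_id` column and any of
#'   `age_at_onset`, `age_at_death`, `disease_duration`, `sex`,
#'   `post_mortem_interval`, `braak_stage`, `apoe_e2_carrier`,
#'   `apoe_e4_carrier`, `tdp_type`.
#' @return the validated data.frame (invisibly classed `cohort_metadata`).
#' @export
cohort_metadata <- function(df) {
  if (!"subject_id" %in% names(df)) stop("metadata needs a subject_id column")
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id in metadata")
  has <- all(c("age_at_onset", "age_at_death", "disease_duration") %in%
               names(df))
  if (has) {
    ok <- is.na(df$age_at_onset) | is.na(df$age_at_death) |
      is.na(df$disease_duration) |
      abs(df$disease_duration - (df$age_at_death - df$age_at_onset)) < 1e-6
    if (!all(ok))
      stop("disease_duration must equal age_at_death - age_at_onset; ",
           "violated for subject(s) ",
           paste(df$subject_id[!ok], collapse = ", "))
  }
  class(df) <- c("cohort_metadata", class(df))
  invisible(df)
}

#' Read cohort metadata from CSV
#' @param path CSV path with a `subject_id` column.
#' @return validated metadata data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cohort_metadata(read.csv(path, check.names = FALSE))
}
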