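#' Translate ordinal ratings into score probabilities
#'
#' Each non-missing rating r is translated into a probability over the
#' modelled score levels \{0, 1, 2, 3\} by evaluating a normal density
#' centred on r with standard deviation `sigma` at each level and
#' normalising over levels. A sparse rating of 0.5 therefore gives equal
#' probability to scores 0 and 1. Missing ratings receive equal probability
#' for every level.
#'
#' By default a rating of 0 is kernel-converted like any other rating
#' (centred on 0); set `hard_zero = TRUE` to instead assign probability one
#' to score 0 (a tiny floor keeps log-likelihoods finite).
#'
#' @param table a [score_table].
#' @param sigma standard deviation of the rating kernel (default 0.5).
#' @param hard_zero if `TRUE`, rating 0 maps to a point mass on score 0.
#' @param max_score highest modelled score level (default 3).
#' @return an object of class `score_probs`: list with `probs`
#'   (subjects x regions x levels array; each subject-region slice sums
#'   to 1), `sigma`, `max_score` and the table's `group`.
#' @export
ratings_to_probabilities <- function(table, sigma = 0.5, hard_zero = FALSE,
                                     max_score = 3) {
  if (sigma <= 0) stop("sigma must be positive")
  levels <- 0:max_score
  ratings <- table$ratings
  n <- nrow(ratings); r <- ncol(ratings)
  probs <- array(NA_real_, dim = c(n, r, length(levels)),
                 dimnames = list(rownames(ratings), colnames(ratings),
                                 paste0("score", levels)))
  # one kernel row per distinct rating value
  kernel <- function(x) {
    w <- exp(-(levels - x)^2 / (2 * sigma^2))
    w / sum(w)
  }
  for (val in RATING_SCALE) {
    hit <- which(!is.na(ratings) & ratings == val, arr.ind = TRUE)
    if (!nrow(hit)) next
    p <- if (hard_zero && val == 0) {
      p0 <- c(1, rep(0, max_score)) + 1e-12
      p0 / sum(p0)
    } else kernel(val)
    for (l in seq_along(levels))
      probs[cbind(hit, l)] <- p[l]
  }
  miss <- which(is.na(ratings), arr.ind = TRUE)
  if (nrow(miss))
    for (l in seq_along(levels))
      probs[cbind(miss, l)] <- 1 / length(levels)
  structure(list(probs = probs, sigma = sigma, max_score = max_score,
                 group = table$group),
            class = "score_probs")
}

#' @exportS3Method base::print
print.score_probs <- function(x, ...) {
  d <- dim(x$probs)
  cat(sprintf("<score_probs> %d subjects x %d regions x %d levels (sigma=%g)\n",
              d[1], d[2], d[3], x$sigma))
  invisible(x)
}

#' @export
dim.score_probs <- function(x) dim(x$probs)

# log-probability array for the C++ core
.logp <- function(probs) log(probs$probs)

#' Restrict a score-probability tensor to a subject subset
#'
#' Used for train/test splits and cross-validation folds.
#'
#' @param probs a [ratings_to_probabilities()] result.
#' @param idx subject indices (or ids) to keep.
#' @return a `score_probs` over the selected subjects.
#' @export
subset_probs <- function(probs, idx) {
  out <- probs
  out$probs <- probs$probs[idx, , , drop = FALSE]
  if (!is.null(probs$group)) out$group <- probs$group[idx]
  out
}
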