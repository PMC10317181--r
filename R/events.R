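#' Build the event set for a region list
#'
#' An event is a (region, score-level) pair for levels 1..`max_score`;
#' score 0 is the implicit baseline and never an event. A model over R
#' regions and 3 levels has M = 3R events and hence M nonzero stages, each
#' stage corresponding to one new region reaching one new score.
#'
#' @param region_names character vector of retained region names.
#' @param max_score highest modelled level (default 3).
#' @return an `event_set`: data.frame with columns `event`, `region`,
#'   `level`, in canonical (region-major) order.
#' @export
build_event_set <- function(region_names, max_score = 3) {
  if (!length(region_names)) stop("empty region list")
  if (max_score < 1) stop("max_score must be >= 1")
  if (anyDuplicated(region_names)) stop("region names must be unique")
  es <- data.frame(
    event = seq_len(length(region_names) * max_score),
    region = rep(region_names, each = max_score),
    level = rep(seq_len(max_score), times = length(region_names)),
    stringsAsFactors = FALSE)
  structure(es, class = c("event_set", "data.frame"),
            regions = region_names, max_score = max_score)
}

#' Number of events (nonzero stages) in an event set
#' @param event_set an [build_event_set()] result.
#' @return integer M.
#' @export
n_events <- function(event_set) nrow(event_set)

#' Human-readable labels for a sequence
#' @param event_set an event set.
#' @param order integer vector of event ids (a sequence).
#' @return character vector of `"region:level"` tokens.
#' @export
sequence_labels <- function(event_set, order) {
  paste0(event_set$region[order], ":", event_set$level[order])
}

#' Parse `"region:level"` tokens back into an event-id sequence
#' @param event_set an event set.
#' @param tokens character vector of `"region:level"` tokens.
#' @return integer vector of event ids.
#' @export
sequence_from_labels <- function(event_set, tokens) {
  key <- paste0(event_set$region, ":", event_set$level)
  idx <- match(tokens, key)
  if (anyNA(idx)) stop("unknown event token(s): ",
                       paste(tokens[is.na(idx)], collapse = ", "))
  order <- event_set$event[idx]
  if (!is_valid_sequence(event_set, order)) stop("sequence violates level order")
  order
}

#' Check the per-region level-ordering constraint
#'
#' A sequence is valid when, for every region, the level-s event precedes the
#' level-(s+1) event.
#'
#' @param event_set an event set.
#' @param order integer vector: permutation of event ids.
#' @return logical.
#' @export
is_valid_sequence <- function(event_set, order) {
  if (length(order) != nrow(event_set) ||
      !setequal(order, event_set$event)) return(FALSE)
  pos <- match(event_set$event, order)
  for (r in unique(event_set$region)) {
    p <- pos[event_set$region == r][order(event_set$level[event_set$region == r])]
    if (is.unsorted(p, strictly = TRUE)) return(FALSE)
  }
  TRUE
}

#' Sample a uniformly random valid sequence
#' @param event_set an event set.
#' @return integer vector of event ids.
#' @export
random_valid_sequence <- function(event_set) {
  # random interleaving of region tracks: permute the multiset of region
  # labels, then levels follow in order of appearance
  lab <- sample(event_set$region)
  counter <- integer(length(attr(event_set, "regions")))
  names(counter) <- attr(event_set, "regions")
  order <- integer(length(lab))
  key <- paste0(event_set$region, ":", event_set$level)
  for (i in seq_along(lab)) {
    counter[lab[i]] <- counter[lab[i]] + 1L
    order[i] <- event_set$event[match(paste0(lab[i], ":", counter[lab[i]]), key)]
  }
  order
}

#' Enumerate all valid sequences (small instances only)
#'
#' Brute-force oracle for testing: every permutation of the event set that
#' respects the per-region level ordering. Guarded to M <= 10.
#'
#' @param event_set an event set.
#' @param max_m guard on the number of events (default 10).
#' @return list of integer event-id vectors.
#' @export
enumerate_valid_sequences <- function(event_set, max_m = 10) {
  m <- nrow(event_set)
  if (m > max_m) stop("event set too large to enumerate (M = ", m, ")")
  regs <- attr(event_set, "regions")
  max_level <- vapply(regs, function(r)
    max(event_set$level[event_set$region == r]), integer(1))
  key <- paste0(event_set$region, ":", event_set$level)
  id_of <- function(r, s) event_set$event[match(paste0(r, ":", s), key)]
  out <- list()
  recurse <- function(prefix, counts) {
    if (length(prefix) == m) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (ri in seq_along(regs)) {
      if (counts[ri] < max_level[ri]) {
        counts2 <- counts
        counts2[ri] <- counts2[ri] + 1L
        recurse(c(prefix, id_of(regs[ri], counts2[ri])), counts2)
      }
    }
  }
  recurse(integer(0), integer(length(regs)))
  out
}

# 0-based event attribute vectors for the C++ core
.ev_cpp <- function(event_set) {
  list(region = match(event_set$region, attr(event_set, "regions")) - 1L,
       level = as.integer(event_set$level))
}
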