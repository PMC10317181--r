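#' Export positional variance diagrams
#'
#' Writes, per subtype, the event x stage positional-frequency matrix of the
#' MCMC samples as CSV, and optionally a heatmap PNG (events on the y-axis
#' in maximum-likelihood order, stages on the x-axis, darker = more certain).
#'
#' @param model a fitted `subtype_model` with MCMC samples.
#' @param path_prefix output path prefix; files are named
#'   `<prefix>_subtype<i>.csv` (and `.png`).
#' @param png also write heatmap images (default `FALSE`).
#' @return character vector of written file paths, invisibly.
#' @export
export_positional_variance <- function(model, path_prefix, png = FALSE) {
  if (is.null(model$mcmc) || !length(model$mcmc))
    stop("model has no MCMC samples")
  written <- character(0)
  for (c in seq_len(model$n_subtypes)) {
    dens <- model$mcmc[[c]]$positional_density
    rownames(dens) <- sequence_labels(model$event_set,
                                      seq_len(nrow(dens)))
    csv <- sprintf("%s_subtype%d.csv", path_prefix, c)
    write.csv(dens, csv)
    written <- c(written, csv)
    if (png) {
      img <- sprintf("%s_subtype%d.png", path_prefix, c)
      grDevices::png(img, width = 900, height = 700)
      plot_positional_variance(model, c)
      grDevices::dev.off()
      written <- c(written, img)
    }
  }
  invisible(written)
}

#' Heatmap of sequence uncertainty
#'
#' Draws the positional variance diagram of one subtype: rows are events
#' ordered by the maximum-likelihood sequence, columns are stages, and cell
#' intensity is the MCMC frequency of the event at that position.
#'
#' @param model a fitted `subtype_model`.
#' @param subtype subtype index (default 1).
#' @export
plot_positional_variance <- function(model, subtype = 1) {
  dens <- model$mcmc[[subtype]]$positional_density
  ord <- model$sequences[[subtype]]
  dens <- dens[ord, , drop = FALSE]
  labels <- sequence_labels(model$event_set, ord)
  m <- nrow(dens)
  graphics::image(seq_len(m), seq_len(m), t(dens[rev(seq_len(m)), ]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  xlab = "stage", ylab = "", axes = FALSE,
                  main = sprintf("Subtype %d positional variance", subtype))
  graphics::axis(1)
  graphics::axis(2, at = seq_len(m), labels = rev(labels), las = 2,
                 cex.axis = 0.6)
  invisible(dens)
}

#' Serialize a fitted model to a list (JSON-ready)
#'
#' Captures the sequences (as `"region:level"` tokens), mixture fractions
#' and a positional-density summary; suitable for
#' `jsonlite::write_json(..., auto_unbox = TRUE)`.
#'
#' @param model a fitted `subtype_model`.
#' @return a plain list.
#' @export
model_to_list <- function(model) {
  list(
    group_label = model$group_label,
    n_subtypes = model$n_subtypes,
    n_events = n_events(model$event_set),
    regions = attr(model$event_set, "regions"),
    fractions = model$fractions,
    loglik = model$loglik,
    sequences = lapply(model$sequences, function(s)
      sequence_labels(model$event_set, s)),
    mcmc_acceptance = vapply(model$mcmc, function(x) x$acceptance_rate,
                             numeric(1)))
}
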