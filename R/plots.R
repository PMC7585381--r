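# Plotting: quick visual checks for spectra and documents.

#' Plot a spectrum as a stick plot
#'
#' @param s A [spectrum()] with inline peaks.
#' @param highlight_mz Optional m/z values (e.g. theoretical fragments from
#'   [fragment_ions()]) drawn in a second colour when within `tol` of a peak.
#' @param tol Matching tolerance in Thomson.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(s, highlight_mz = NULL, tol = 0.01) {
  stopifnot(inherits(s, "dnmso_spectrum"))
  df <- s$peaks
  df$matched <- FALSE
  if (!is.null(highlight_mz)) {
    df$matched <- vapply(df$mz, function(m) any(abs(m - highlight_mz) <= tol),
                         logical(1))
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, xend = .data$mz,
                                   y = 0, yend = .data$intensity,
                                   colour = .data$matched)) +
    ggplot2::geom_segment(show.legend = !is.null(highlight_mz)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                                 name = "fragment match") +
    ggplot2::labs(x = "m/z (Th)", y = "intensity",
                  title = sprintf("%s (precursor %.4f Th, %s+)",
                                  s$id %||% "spectrum", s$precursor_mz,
                                  ifelse(is.na(s$precursor_charge), "?",
                                         s$precursor_charge))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_spectrum
#' @param object,... Autoplot interface.
#' @export
autoplot.dnmso_spectrum <- function(object, ...) plot_spectrum(object, ...)

#' Plot the score distributions of a document
#'
#' One panel per score name across all predictions; useful for choosing
#' filtering thresholds.
#'
#' @param doc A `dnmso_document`.
#' @return A ggplot object.
#' @export
plot_scores <- function(doc) {
  stopifnot(inherits(doc, "dnmso_document"))
  rows <- purrr::map_dfr(doc$predictions, function(p) {
    tibble::tibble(prediction = p$id,
                   score = vapply(p$scores, `[[`, character(1), "name"),
                   value = vapply(p$scores, `[[`, numeric(1), "value"))
  })
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue") +
    ggplot2::facet_wrap(~score, scales = "free") +
    ggplot2::labs(x = "score value", y = "predictions") +
    ggplot2::theme_minimal()
}

#' @rdname plot_scores
#' @param object,... Autoplot interface.
#' @export
autoplot.dnmso_document <- function(object, ...) plot_scores(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
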