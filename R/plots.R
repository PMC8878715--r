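#' Plot a biotype summary
#'
#' Bar chart of the five biotype categories of a differentially expressed
#' transcript set, labeled with percentages.
#'
#' @param object A `biotype_summary` from [classify_biotypes()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biotype_summary <- function(object, ...) {
  d <- object$categories
  d$category <- factor(d$category, levels = d$category[order(-d$count)])
  ggplot2::ggplot(d, ggplot2::aes(x = category, y = count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", percent)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(x = NULL, y = "transcripts",
                  title = sprintf("Biotype composition (n = %d)",
                                  object$n_total)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot p-value distribution of an NB time-course fit
#'
#' Histogram of per-gene p-values; under the null this should be close to
#' uniform, with a spike near zero from truly differential genes.
#'
#' @param object An `nb_timecourse` object.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_timecourse <- function(object, bins = 40, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = p_value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40",
                            boundary = 0, closed = "left") +
    ggplot2::labs(x = "p-value", y = "genes",
                  title = "NB time-course test p-values") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the unmutated-fraction trend across time points
#'
#' Line/point plot of the percent of unmutated (UM) IGHV calls per time
#' point; a decreasing trend indicates preferential expansion of
#' somatically mutated (memory-derived) lineages.
#'
#' @param um_by_timepoint Tibble with `timepoint` and `pct_um` columns
#'   (e.g. [mutation_status()] applied per time point).
#' @return A ggplot object.
#' @export
plot_um_trend <- function(um_by_timepoint) {
  ggplot2::ggplot(um_by_timepoint,
                  ggplot2::aes(x = timepoint, y = pct_um, group = 1)) +
    ggplot2::geom_line(color = "grey50") +
    ggplot2::geom_point(size = 3, color = "firebrick") +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = NULL, y = "% unmutated IGHV calls",
                  title = "UM fraction across differentiation") +
    ggplot2::theme_minimal()
}
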