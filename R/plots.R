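#' Histogram of empirical Bayes frailty estimates
#'
#' @param object A [cmsm_ebayes()] table.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot: one panel per frailty column, with a dashed line at the
#'   prior mean 1.
#' @export
autoplot.cmsm_eb <- function(object, bins = 30, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"id",
                              names_to = "estimate", values_to = "uhat")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$uhat)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35", colour = "white") +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::facet_wrap(~estimate) +
    ggplot2::labs(x = "empirical Bayes frailty estimate", y = "subjects")
}

#' Stacked bar chart of expected occupancy times
#'
#' @param object A [cmsm_occupancy()] table.
#' @param ... Unused.
#' @return A ggplot: expected years per target state, stacked, one bar per
#'   starting state, one panel per process.
#' @export
autoplot.cmsm_occupancy <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$start), y = .data$years,
                               fill = factor(.data$state))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~process) +
    ggplot2::labs(x = "starting state", y = "expected years",
                  fill = "state",
                  title = sprintf("Expected occupancy over %.3g years (%s)",
                                  attr(object, "horizon"), attr(object, "mode")))
}
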