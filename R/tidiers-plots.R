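# Broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.ref_distribution <- function(x, ...) {
  tibble(label = x$labels, value = x$values)
}

#' @export
glance.ref_distribution <- function(x, ...) {
  distribution_summary(x)
}

#' @export
autoplot.ref_distribution <- function(object, n_bins = 20, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = n_bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = mean(df$value), linetype = 2) +
    ggplot2::labs(x = "normalized hydration free energy (kJ/mol/residue)",
                  y = "count")
}

#' @export
autoplot.entropy_sweep <- function(object, ...) {
  df <- object[!object$empty, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$entropy,
                                   colour = .data$segment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "relative solvent-accessibility cutoff",
                  y = "sequence Shannon entropy (nats)")
}

#' Plot per-frame ensemble series
#'
#' @param series Tibble from [run_full_analysis()] (`series` element) or
#'   [timeseries_stats()].
#' @param y Column to plot.
#' @return A ggplot object.
#' @export
plot_series <- function(series, y = "rg") {
  ggplot2::ggplot(series,
                  ggplot2::aes(x = .data$frame, y = .data[[y]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = y)
}
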