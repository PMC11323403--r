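#' Plot a binned metagene profile
#'
#' @param object A `binned_profile` from [bin_profile()] or
#'   [orf_binned_net_gc()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.binned_profile <- function(object, ...) {
  scheme <- attr(object, "scheme") %||% "binned"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "bin", y = "mean value",
                  title = sprintf("Metagene profile (%s)", scheme)) +
    ggplot2::theme_minimal()
}

#' Plot a positional nucleotide/CpG profile around the anchor
#'
#' @param object A `positional_profile`.
#' @param metrics Which columns to draw (default GC and CpG).
#' @param window Optional smoothing window applied before plotting.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.positional_profile <- function(object, metrics = c("gc", "cpg"),
                                        window = 1, ...) {
  df <- object |>
    dplyr::select("offset", dplyr::all_of(metrics)) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(metrics),
                                ~ sliding_mean(.x, window))) |>
    tidyr::pivot_longer(-"offset", names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "position relative to anchor (bp)", y = "fraction") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed window series (net GC change or rates)
#'
#' @param object A `window_series`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.window_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to anchor (bp)",
                  y = "value per source (smoothed)") +
    ggplot2::theme_minimal()
}

#' Plot a permutation-test null distribution with the observed delta
#'
#' @param object A `perm_test`.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.perm_test <- function(object, bins = 40, ...) {
  df <- tibble(delta = object$null_deltas)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey80",
                            colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_delta,
                        colour = "red") +
    ggplot2::labs(x = "null delta",
                  title = sprintf("observed = %.4g, p_emp = %.3g",
                                  object$observed_delta,
                                  object$p_empirical)) +
    ggplot2::theme_minimal()
}
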