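#' Rose plot of displacement angles
#'
#' Circular histogram of track displacement angles (see
#' [displacement_angles()]), drawn with `coord_polar` so 0 degrees points
#' right and angles increase counterclockwise.
#'
#' @param angles Numeric angles in degrees in \[0, 360), or a binned tibble
#'   from [rose_histogram()].
#' @param n_bins Number of bins when `angles` is raw.
#' @return A ggplot object.
#' @export
plot_rose <- function(angles, n_bins = 16) {
  bins <- if (is.data.frame(angles)) angles else rose_histogram(angles, n_bins)
  ggplot2::ggplot(bins, ggplot2::aes(
    x = (.data$start_deg + .data$end_deg) / 2, y = .data$count)) +
    ggplot2::geom_col(width = 360 / nrow(bins), fill = "steelblue",
                      colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar(start = -pi / 2, direction = -1) +
    ggplot2::scale_x_continuous(limits = c(0, 360),
                                breaks = seq(0, 315, by = 45)) +
    ggplot2::labs(x = NULL, y = "count") +
    ggplot2::theme_minimal()
}

#' Raincloud plot of grouped values
#'
#' Half-violin (density), jittered raw points and a boxplot per group.
#'
#' @param data A data frame.
#' @param value,group Column names (strings).
#' @param jitter_alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_raincloud <- function(data, value = "value", group = "group",
                           jitter_alpha = 0.25) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data[[group]], y = .data[[value]], fill = .data[[group]])) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.5, colour = NA,
                         scale = "width") +
    ggplot2::geom_jitter(width = 0.12, size = 0.4, alpha = jitter_alpha) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, alpha = 0.8) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [moderated_ttest()].
#' @param regime A [cutoff_regime()] used to colour significant proteins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_result <- function(object, regime = stringent_regime(), ...) {
  sets <- apply_cutoffs(object, regime)
  df <- tibble::as_tibble(object)
  df$state <- "ns"
  df$state[df$protein %in% sets$up] <- "up"
  df$state[df$protein %in% sets$down] <- "down"
  p_col <- if (regime$p_basis == "raw") "p_value" else "adj_p_value"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2fc,
                                   y = -log10(.data[[p_col]]),
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(ns = "grey70", up = "firebrick",
                                            down = "navy")) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * regime$lfc_cutoff,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(regime$p_cutoff),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::labs(x = "log2 fold change", y = sprintf("-log10(%s)", p_col),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ensemble MSD curve plot
#'
#' @param msd_curve The `msd` tibble from [ensemble_msd()].
#' @return A ggplot object.
#' @export
plot_msd_curve <- function(msd_curve) {
  ggplot2::ggplot(msd_curve, ggplot2::aes(x = .data$tau_s, y = .data$msd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "lag time (s)", y = "MSD (um^2)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
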