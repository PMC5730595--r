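#' Plot a photoconversion trajectory
#'
#' Green and red reporter copy numbers over time, with the conversion
#' instant marked.
#'
#' @param object A `kik_trajectory` from [ssa_two_stage()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kik_trajectory <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("green", "red"),
      names_to = "reporter", values_to = "count"
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$count,
    colour = .data$reporter
  )) +
    ggplot2::geom_step() +
    ggplot2::scale_colour_manual(values = c(green = "#2e7d32", red = "#c62828")) +
    ggplot2::labs(x = "time (h)", y = "copy number") +
    ggplot2::theme_minimal()
  tc <- attr(object, "conversion_time_h")
  if (!is.na(tc)) {
    p <- p + ggplot2::geom_vline(xintercept = tc, linetype = "dashed")
  }
  p
}

#' Box plot of per-image noise by tissue
#'
#' The standard presentation of per-image intrinsic/extrinsic noise values
#' grouped by tissue, with the group mean overplotted.
#'
#' @param results Per-image tibble from [aggregate_noise()] (possibly
#'   covering several tissues).
#' @param components Noise components to show.
#' @return A ggplot.
#' @export
plot_noise_boxplot <- function(results,
                               components = c("eta2_int", "eta2_ext")) {
  df <- results |>
    tidyr::pivot_longer(dplyr::all_of(components),
      names_to = "component", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$tissue, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21, fill = "white") +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "noise (x100 scale)") +
    ggplot2::theme_minimal()
}

#' Dual-reporter scatter of one image
#'
#' Normalized channel-1 vs channel-2 values per nucleus; extrinsic noise
#' spreads cells along the diagonal, intrinsic noise away from it.
#'
#' @param table A mean-normalized [nucleus_table()].
#' @param channels The two channel names.
#' @return A ggplot.
#' @export
plot_dual_reporter <- function(table, channels = c("CFP", "YFP")) {
  wide <- dual_channel_wide(table, channels)
  ggplot2::ggplot(wide, ggplot2::aes(.data$c_value, .data$y_value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = paste("normalized", channels[1]),
      y = paste("normalized", channels[2])
    ) +
    ggplot2::theme_minimal()
}
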