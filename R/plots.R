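#' Horizon-style plot of mood-factor time series
#'
#' Median-centered factor trajectories (one facet per factor), with a shaded
#' band of one median absolute deviation around zero — a small-multiples
#' rendering of the horizon-graph view of a mood panel.
#'
#' @param panel Mood panel tibble.
#' @param metadata Metadata tibble (`sample_id`, `subject_id`, `timepoint`).
#' @param subjects Optional subset of subjects to show.
#' @return A ggplot object.
#' @export
plot_horizon <- function(panel, metadata, subjects = NULL) {
  long <- horizon_panel(panel, metadata)
  if (!is.null(subjects)) {
    long <- dplyr::filter(long, .data$subject_id %in% subjects)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timepoint,
                                     y = .data$centered,
                                     colour = .data$subject_id)) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = -Inf, xmax = Inf,
                   ymin = -.data$band_width, ymax = .data$band_width),
      fill = "grey90", colour = NA, alpha = 0.3
    ) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~factor, scales = "free_y") +
    ggplot2::labs(x = "timepoint", y = "score - median(score)",
                  colour = "subject") +
    ggplot2::theme_minimal()
}

#' ACF panel plot with white-noise confidence bounds
#'
#' @param assessment Output of [assess_stationarity()].
#' @param variable Which variable to plot (one facet per subject).
#' @return A ggplot object.
#' @export
plot_acf <- function(assessment, variable) {
  df <- dplyr::filter(assessment, .data$variable == !!variable,
                      .data$status != "insufficient")
  if (nrow(df) == 0) abort("no assessable series for this variable")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag, y = .data$acf)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$conf_bound),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = -.data$conf_bound),
                        linetype = "dashed", colour = "blue") +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::facet_wrap(~subject_id) +
    ggplot2::labs(title = variable, x = "lag", y = "sample ACF") +
    ggplot2::theme_minimal()
}

#' @method autoplot psy_screen
#' @export
autoplot.psy_screen <- function(object, candidates_only = TRUE, ...) {
  df <- tidy(object)
  if (candidates_only) df <- dplyr::filter(df, .data$candidate)
  if (nrow(df) == 0) abort("nothing to plot: no candidates")
  df <- dplyr::mutate(
    df,
    stars = dplyr::case_when(
      .data$p <= 0.001 ~ "***",
      .data$p <= 0.01 ~ "**",
      .data$p <= 0.05 ~ "*",
      TRUE ~ ""
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$feature_id,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$stars), size = 2.5) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman R") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
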