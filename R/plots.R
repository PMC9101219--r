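#' Line plot of a gender-averaged calendar profile
#'
#' Mirrors the usual presentation of cohort CGM profiles: one line per
#' gender, mean glucose (or SD) against the calendar bucket.
#'
#' @param profile Tibble from [gender_averaged_profile()].
#' @param statistic `"mean"` or `"sd"`.
#' @return A ggplot object.
#' @export
plot_gender_profile <- function(profile, statistic = c("mean", "sd")) {
  statistic <- match.arg(statistic)
  gran <- unique(profile$granularity)[1]
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$bucket, y = .data[[statistic]],
                               colour = .data$gender)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = gran,
                  y = paste0("glucose ", statistic, " (mg/dL)"),
                  colour = "gender") +
    ggplot2::theme_minimal()
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param corr A `cgm_correlation_matrix` from [spearman_matrix()].
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(corr) {
  df <- as.data.frame(as.table(corr$rho))
  names(df) <- c("x", "y", "rho")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
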