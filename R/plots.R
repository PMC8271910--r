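#' Plot methods for study, sweep and track results
#'
#' `autoplot()` methods give quick diagnostic graphics: the LE-DE scatter
#' of a dipole study, the mean-LE-versus-SNR curve of a sweep (error bars
#' are standard deviations across dipoles), and the per-axis raw versus
#' filtered trajectory of a tracked source.
#'
#' @param object A `dipole_study`, `snr_sweep` or `source_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @rdname plots
#' @method autoplot dipole_study
#' @export
autoplot.dipole_study <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$le_mm, y = .data$de_deg)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "localization error (mm)",
                  y = "direction error (deg)",
                  title = sprintf("Test-dipole study (n = %d, SNR = %s dB)",
                                  nrow(object),
                                  format(object$snr_db[1]))) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot snr_sweep
#' @export
autoplot.snr_sweep <- function(object, ...) {
  g <- glance(object)
  g$snr_label <- factor(ifelse(is.infinite(g$snr_db), "Inf",
                               as.character(g$snr_db)),
                        levels = c(sort(unique(g$snr_db[is.finite(g$snr_db)])),
                                   "Inf"))
  ggplot2::ggplot(g, ggplot2::aes(x = .data$snr_label,
                                  y = .data$mean_le_mm)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_le_mm - .data$sd_le_mm,
                                        ymax = .data$mean_le_mm + .data$sd_le_mm),
                           width = 0.2) +
    ggplot2::labs(x = "SNR (dB)", y = "mean localization error (mm)") +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @method autoplot source_track
#' @export
autoplot.source_track <- function(object, ...) {
  df <- tidy(object)
  long <- tidyr::pivot_longer(
    df, cols = dplyr::any_of(c("rx_mm", "ry_mm", "rz_mm",
                               "fx_mm", "fy_mm", "fz_mm",
                               "true_x_mm", "true_y_mm", "true_z_mm")),
    names_to = "series", values_to = "mm")
  long$axis <- dplyr::case_when(
    grepl("x", long$series) ~ "x",
    grepl("y", long$series) ~ "y",
    TRUE ~ "z")
  long$kind <- dplyr::case_when(
    grepl("^r", long$series) ~ "raw OMP",
    grepl("^f", long$series) ~ "Kalman filtered",
    TRUE ~ "truth")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s * 1000, y = .data$mm,
                                     colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~axis, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (ms)", y = "position (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}
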