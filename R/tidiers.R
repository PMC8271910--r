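#' Tidiers for study, sweep, track and estimate objects
#'
#' `tidy()` returns the per-unit (trial/step) table; `glance()` returns a
#' one-row (or one-row-per-level) summary with the headline accuracy
#' numbers: mean and standard deviation of localization error (LE, mm)
#' and direction error (DE, degrees) for studies, per-axis RMSE and mean
#' distance error for tracks.
#'
#' @param x A `dipole_study`, `snr_sweep`, `source_track` or
#'   `source_estimate` object.
#' @param ... Unused, for generic consistency.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy dipole_study
#' @export
tidy.dipole_study <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "dipole_study")
  as_tibble(out)
}

#' @rdname tidiers
#' @method glance dipole_study
#' @export
glance.dipole_study <- function(x, ...) {
  tibble(n = nrow(x),
         mean_le_mm = mean(x$le_mm), sd_le_mm = stats::sd(x$le_mm),
         mean_de_deg = mean(x$de_deg), sd_de_deg = stats::sd(x$de_deg),
         snr_db = x$snr_db[1])
}

#' @rdname tidiers
#' @method tidy snr_sweep
#' @export
tidy.snr_sweep <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "snr_sweep")
  as_tibble(out)
}

#' @rdname tidiers
#' @method glance snr_sweep
#' @export
glance.snr_sweep <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$snr_db) |>
    dplyr::summarise(n_dipoles = dplyr::n(),
                     mean_le_mm = mean(.data$mean_le_mm),
                     sd_le_mm = stats::sd(.data$mean_le_mm),
                     mean_de_deg = mean(.data$mean_de_deg),
                     .groups = "drop")
}

#' @rdname tidiers
#' @method tidy source_track
#' @export
tidy.source_track <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "source_track")
  as_tibble(out)
}

#' @rdname tidiers
#' @method glance source_track
#' @export
glance.source_track <- function(x, ...) {
  if (!all(c("true_x_mm", "true_y_mm", "true_z_mm") %in% names(x))) {
    return(tibble(n = nrow(x), mean_gain = mean(c(x$Kx, x$Ky, x$Kz))))
  }
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  dist <- function(ex, ey, ez) {
    mean(sqrt((ex - x$true_x_mm)^2 + (ey - x$true_y_mm)^2 +
                (ez - x$true_z_mm)^2))
  }
  tibble(n = nrow(x),
         rmse_raw_x_mm = rmse(x$rx_mm, x$true_x_mm),
         rmse_raw_y_mm = rmse(x$ry_mm, x$true_y_mm),
         rmse_raw_z_mm = rmse(x$rz_mm, x$true_z_mm),
         rmse_filt_x_mm = rmse(x$fx_mm, x$true_x_mm),
         rmse_filt_y_mm = rmse(x$fy_mm, x$true_y_mm),
         rmse_filt_z_mm = rmse(x$fz_mm, x$true_z_mm),
         mde_raw_mm = dist(x$rx_mm, x$ry_mm, x$rz_mm),
         mde_filt_mm = dist(x$fx_mm, x$fy_mm, x$fz_mm))
}

#' @rdname tidiers
#' @method tidy source_estimate
#' @export
tidy.source_estimate <- function(x, ...) {
  tibble(grid_index = x$grid_index,
         x_mm = x$location_mm[1], y_mm = x$location_mm[2],
         z_mm = x$location_mm[3],
         jx = x$j_hat[1], jy = x$j_hat[2], jz = x$j_hat[3],
         correlation = x$correlation, residual = x$residual,
         rank_deficient = x$rank_deficient)
}
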