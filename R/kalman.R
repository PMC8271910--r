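#' Tracker configuration for the constant-conduction-velocity model
#'
#' The time series of OMP location estimates is corrected by a Kalman
#' filter built on a constant-speed state-space model: the true source
#' position advances each step by `dt * u(t)`, where the input direction
#' `u(t)` is the estimated current-density direction scaled by the
#' ventricular conduction speed, and the OMP location is the noisy
#' observation of that position. Process and observation noise are
#' zero-mean Gaussian with per-axis variances `Q` and `R`; filtering is
#' per-axis scalar (diagonal covariances), matching the printed scalar
#' gain `K = P / (P + R)`.
#'
#' @param x0_mm Initial state: the AV-node location (mm), the anatomical
#'   origin of ventricular activation.
#' @param v_m_s Conduction speed in m/s (ventricular default 1.9).
#' @param dt_s Time step in seconds (default 1 ms).
#' @param Q Process-noise variance per axis (mm^2); scalar is recycled.
#'   Calibrated in the source protocol as the variance of the
#'   localization error over a 100-dipole study ([estimate_Q()]).
#' @param R Observation-noise variance per axis (mm^2); calibrated from
#'   the spread of localizations across random LFM sub-dictionaries
#'   ([estimate_R()]).
#' @return An object of class `track_config`.
#' @export
track_config <- function(x0_mm, v_m_s = 1.9, dt_s = 0.001, Q = 1, R = 1) {
  if (v_m_s <= 0) abort("`v_m_s` must be positive")
  if (dt_s <= 0) abort("`dt_s` must be positive")
  Q <- rep_len(as.numeric(Q), 3); R <- rep_len(as.numeric(R), 3)
  if (any(Q < 0) || any(R < 0)) abort("`Q` and `R` must be >= 0")
  structure(list(x0_mm = vec3(x0_mm, "x0_mm"), v_m_s = v_m_s, dt_s = dt_s,
                 Q = Q, R = R),
            class = "track_config")
}

#' Predicted displacement from the estimated current direction
#'
#' The state-space input: the unit current-density direction scaled by
#' the conduction speed and the time step, returned as a displacement in
#' mm (`u(t) * dt`). The magnitude of `j_hat` cancels — only its
#' direction matters.
#'
#' @param j_hat Nonzero current-density 3-vector.
#' @param v_m_s Conduction speed (m/s).
#' @param dt_s Time step (s).
#' @return Displacement 3-vector in mm with norm `v * dt`.
#' @export
direction_input <- function(j_hat, v_m_s = 1.9, dt_s = 0.001) {
  j_hat <- vec3(j_hat, "j_hat")
  nj <- sqrt(sum(j_hat^2))
  if (nj == 0) abort("`j_hat` must be nonzero")
  (j_hat / nj) * v_m_s * dt_s * 1000
}

#' One predict/update step of the scalar Kalman recursion
#'
#' Applies, per axis, exactly the textbook scalar recursion of the
#' constant-velocity tracker: predict `x- = x + u_disp`,
#' `P- = P + dt^2 Q`; gain `K = P- / (P- + R)`; update
#' `P = (1 - K) P-`, `x = x- + K (r - x-)`.
#'
#' @param state List with `x_hat_mm` (3-vector) and `P` (per-axis
#'   variance 3-vector, mm^2).
#' @param u_disp_mm Predicted displacement (mm), from
#'   [direction_input()], already including `dt`.
#' @param observation Observed location `r_hat` (mm).
#' @param Q,R Per-axis noise variances (mm^2).
#' @param dt_s Time step (s), entering the process-noise inflation
#'   `dt^2 Q`.
#' @return Updated state list with `x_hat_mm`, `P` and `K` (per-axis
#'   gain in `[0, 1]`).
#' @export
kalman_step <- function(state, u_disp_mm, observation, Q, R, dt_s = 0.001) {
  Q <- rep_len(as.numeric(Q), 3); R <- rep_len(as.numeric(R), 3)
  x_pred <- vec3(state$x_hat_mm, "x_hat_mm") + vec3(u_disp_mm, "u_disp_mm")
  P_pred <- rep_len(as.numeric(state$P), 3) + dt_s^2 * Q
  denom <- P_pred + R
  if (any(denom == 0)) {
    abort("Kalman gain indeterminate: P + R is zero (set Q or R nonzero)")
  }
  K <- ifelse(is.infinite(R), 0, P_pred / denom)
  P <- (1 - K) * P_pred
  x <- x_pred + K * (vec3(observation, "observation") - x_pred)
  list(x_hat_mm = x, P = P, K = K)
}

#' Track a source through an observation series
#'
#' Runs the constant-conduction-velocity Kalman filter over a series of
#' OMP estimates: the state is initialized at the AV-node location with
#' `P(0) = Q`, each step predicts along the estimated current direction
#' and corrects toward the observed location with the per-axis gain.
#'
#' @param series An `observation_series` (from
#'   [synthesize_observations()]) or any data frame with columns `rx_mm`,
#'   `ry_mm`, `rz_mm`, `jx`, `jy`, `jz` (and optionally `t_s`).
#' @param config A [track_config()].
#' @return A `source_track` tibble: per step the raw observation, the
#'   filtered location `fx_mm`..`fz_mm` and the per-axis gains.
#' @export
track_source <- function(series, config) {
  req <- c("rx_mm", "ry_mm", "rz_mm", "jx", "jy", "jz")
  if (nrow(series) == 0) abort("empty observation series")
  if (!all(req %in% names(series))) {
    abort(sprintf("series needs columns %s", paste(req, collapse = ", ")))
  }
  state <- list(x_hat_mm = config$x0_mm, P = config$Q)
  n <- nrow(series)
  fx <- matrix(NA_real_, n, 3)
  gains <- matrix(NA_real_, n, 3)
  for (t in seq_len(n)) {
    j_hat <- c(series$jx[t], series$jy[t], series$jz[t])
    u <- tryCatch(direction_input(j_hat, config$v_m_s, config$dt_s),
                  error = function(e) {
                    abort(sprintf("step %d: %s", t, conditionMessage(e)))
                  })
    obs <- c(series$rx_mm[t], series$ry_mm[t], series$rz_mm[t])
    state <- kalman_step(state, u, obs, config$Q, config$R, config$dt_s)
    fx[t, ] <- state$x_hat_mm
    gains[t, ] <- state$K
  }
  out <- tibble(step = seq_len(n),
                t_s = if ("t_s" %in% names(series)) series$t_s
                      else seq_len(n) * config$dt_s,
                rx_mm = series$rx_mm, ry_mm = series$ry_mm,
                rz_mm = series$rz_mm,
                fx_mm = fx[, 1], fy_mm = fx[, 2], fz_mm = fx[, 3],
                Kx = gains[, 1], Ky = gains[, 2], Kz = gains[, 3])
  if (all(c("true_x_mm", "true_y_mm", "true_z_mm") %in% names(series))) {
    out$true_x_mm <- series$true_x_mm
    out$true_y_mm <- series$true_y_mm
    out$true_z_mm <- series$true_z_mm
  }
  attr(out, "config") <- config
  class(out) <- c("source_track", class(out))
  out
}

#' Calibrate the process-noise variance from a dipole study
#'
#' The process noise of the tracker is taken from the localization
#' performance of the static method itself: the variance of the
#' localization error over a test-dipole study (100 dipoles in the source
#' protocol). Per-axis mode uses the variance of each error component
#' `est - true`; pooled mode the variance of the scalar LE.
#'
#' @param study A [run_dipole_study()] table (>= 2 trials).
#' @param per_axis Per-axis variances (default) or one pooled scalar.
#' @return Numeric vector of length 3 (per-axis) or 1 (pooled), mm^2.
#' @export
estimate_Q <- function(study, per_axis = TRUE) {
  if (nrow(study) < 2) abort("need at least 2 trials to estimate Q")
  if (per_axis) {
    c(var(study$est_x_mm - study$true_x_mm),
      var(study$est_y_mm - study$true_y_mm),
      var(study$est_z_mm - study$true_z_mm))
  } else {
    var(study$le_mm)
  }
}

#' Calibrate the observation-noise variance from LFM sub-dictionaries
#'
#' Measures how much the OMP localization moves when the dictionary
#' itself is subsampled: `n_subsets` random sub-dictionaries of
#' `subset_size` source points are drawn from the LFM (protocol default:
#' ten databases of 500 points), a fixed probe set of noise-free source
#' signals is localized against each, and the per-axis variance of the
#' resulting locations across sub-dictionaries (averaged over probes) is
#' returned.
#'
#' @param lfm A [build_lfm()] lead field.
#' @param n_subsets Number of random sub-dictionaries (default 10).
#' @param subset_size Points per sub-dictionary (default 500, capped at
#'   `N`; error if larger than `N`).
#' @param n_probes Number of probe sources (grid points localized through
#'   their own noise-free columns; default `min(20, N)`).
#' @param seed RNG seed.
#' @return Per-axis variance 3-vector (mm^2).
#' @export
estimate_R <- function(lfm, n_subsets = 10, subset_size = 500,
                       n_probes = NULL, seed = 1L) {
  N <- nrow(lfm$points)
  if (subset_size > N) {
    abort(sprintf("subset_size (%d) exceeds the number of source points (%d)",
                  subset_size, N))
  }
  n_probes <- n_probes %||% min(20L, N)
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  probes <- sample.int(N, n_probes)
  dirs <- runif_sphere(n_probes)
  est <- array(NA_real_, c(n_subsets, n_probes, 3))
  for (s in seq_len(n_subsets)) {
    sub <- sort(sample.int(N, subset_size))
    sub_lfm <- subset_lfm(lfm, sub)
    for (p in seq_len(n_probes)) {
      ip <- probes[p]
      phi <- lfm$L[, c(ip, N + ip, 2 * N + ip), drop = FALSE] %*% dirs[p, ]
      fit <- omp_localize(sub_lfm, as.vector(phi))
      est[s, p, ] <- fit$location_mm
    }
  }
  # variance across sub-dictionaries, averaged over probes, per axis
  apply(est, 3, function(m) mean(apply(m, 2, var)))
}

# restrict a lead field to a subset of source points (all three blocks)
subset_lfm <- function(lfm, sub) {
  N <- nrow(lfm$points)
  cols <- c(sub, N + sub, 2 * N + sub)
  pts <- lfm$points[sub, ]
  pts$point <- seq_along(sub)
  attr(pts, "spacing_mm") <- attr(lfm$points, "spacing_mm")
  class(pts) <- class(lfm$points)
  structure(list(L = lfm$L[, cols, drop = FALSE], points = pts,
                 electrodes = lfm$electrodes, pitch_mm = lfm$pitch_mm,
                 origin_mm = lfm$origin_mm, provenance = lfm$provenance),
            class = "lead_field")
}
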