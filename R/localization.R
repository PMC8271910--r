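#' Add measurement noise at a prescribed SNR
#'
#' Adds zero-mean white Gaussian noise to an electrode potential vector so
#' that the ratio of mean signal power to noise variance equals
#' `10^(snr_db/10)`. `snr_db = Inf` returns the signal unchanged. The
#' study protocol uses the SNR grid `{0, 10, 20, 30, Inf}` dB.
#'
#' @param phi Numeric potential vector.
#' @param snr_db SNR in dB (may be `Inf`).
#' @param seed Optional RNG seed for reproducibility.
#' @return Noisy vector with attributes `snr_db` and `seed`.
#' @export
add_noise <- function(phi, snr_db, seed = NULL) {
  if (!is.numeric(phi) || anyNA(phi)) abort("`phi` must be finite numeric")
  if (is.infinite(snr_db)) {
    out <- phi
  } else {
    p_sig <- mean(phi^2)
    if (p_sig == 0) abort("cannot scale noise to a zero signal")
    if (!is.null(seed)) {
      old <- get0(".Random.seed", globalenv())
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    sd_n <- sqrt(p_sig * 10^(-snr_db / 10))
    out <- phi + rnorm(length(phi), sd = sd_n)
  }
  attr(out, "snr_db") <- snr_db
  attr(out, "seed") <- seed
  out
}

#' Localize a source by orthogonal matching pursuit
#'
#' Single-iteration OMP on the lead-field dictionary: the normalised
#' correlation `|Phi . L_i| / (||Phi|| ||L_i||)` is computed for all `3N`
#' columns, the winning column's grid point is taken as the estimated
#' location, and the current-density vector is recovered by applying the
#' Moore-Penrose pseudoinverse of the three-column support
#' `[L_ix, L_iy, L_iz]` to `Phi`. The absolute value in the correlation
#' makes a source anti-aligned with a basis direction still select its
#' location; the pseudoinverse step recovers the sign. Ties are broken
#' toward the lowest grid-point index.
#'
#' A note on support selection: with a single measurement vector and a
#' highly coherent dictionary (few electrodes, closely spaced source
#' points), the per-column rule can hand an obliquely oriented source to
#' a neighbouring point even in the noise-free case, because the mixture
#' of three columns at the true point may correlate better with one
#' foreign column than with any single column of its own triplet.
#' `selection = "subspace"` scores each point by the projection of `Phi`
#' onto the span of its three columns instead; this variant recovers any
#' noise-free on-grid source exactly (its subspace contains the signal),
#' at the cost of departing from the per-column matching-pursuit rule.
#'
#' @param lfm A [build_lfm()] lead field.
#' @param phi Electrode potential vector (length `M`, nonzero).
#' @param selection `"column"` (default): argmax of the per-column
#'   normalised correlation, the matching-pursuit rule. `"subspace"`:
#'   argmax of the per-point three-column subspace correlation.
#' @return An object of class `source_estimate`: `location_mm`, `j_hat`
#'   (A/m^2), `grid_index`, `correlation`, `residual` (norm of
#'   `L_hat j_hat - Phi`) and `rank_deficient` flag.
#' @export
omp_localize <- function(lfm, phi, selection = c("column", "subspace")) {
  selection <- match.arg(selection)
  phi <- as.numeric(phi)
  if (length(phi) != nrow(lfm$L)) {
    abort("`phi` length must equal the number of electrodes")
  }
  nphi <- sqrt(sum(phi^2))
  if (nphi == 0) abort("`phi` is identically zero")
  N <- nrow(lfm$points)
  loc <- (seq_len(3 * N) - 1L) %% N + 1L   # column -> grid point
  if (selection == "column") {
    cn <- lfm_column_norms(lfm)
    corr <- abs(as.vector(crossprod(lfm$L, phi))) / (cn * nphi)
    corr[cn == 0] <- -Inf
    best <- max(corr)
    i_hat <- min(loc[corr >= best - 1e-15])
  } else {
    corr <- vapply(seq_len(N), function(i) {
      Q <- qr.Q(qr(lfm$L[, c(i, N + i, 2 * N + i), drop = FALSE]))
      sqrt(sum(crossprod(Q, phi)^2)) / nphi
    }, numeric(1))
    best <- max(corr)
    i_hat <- min(which(corr >= best - 1e-15))
  }
  sup <- lfm$L[, c(i_hat, N + i_hat, 2 * N + i_hat), drop = FALSE]
  piv <- pinv(sup)
  j_hat <- as.vector(piv %*% phi)
  rankdef <- qr(sup)$rank < 3
  structure(list(
    location_mm = c(lfm$points$x_mm[i_hat], lfm$points$y_mm[i_hat],
                    lfm$points$z_mm[i_hat]),
    j_hat = j_hat, grid_index = i_hat, correlation = best,
    residual = sqrt(sum((sup %*% j_hat - phi)^2)),
    rank_deficient = rankdef),
    class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> point %d at (%.1f, %.1f, %.1f) mm, corr %.4f\n",
              x$grid_index, x$location_mm[1], x$location_mm[2],
              x$location_mm[3], x$correlation))
  invisible(x)
}

lfm_column_norms <- function(lfm) {
  cn <- attr(lfm, "col_norms")
  if (is.null(cn)) cn <- sqrt(colSums(lfm$L^2))
  cn
}

#' Localization and direction error metrics
#'
#' `localization_error()` is the Euclidean distance (mm) between the
#' estimated and the true source location. `direction_error()` is the
#' angle in degrees between the estimated and the true current-density
#' vectors, in `[0, 180]`, with the cosine argument clamped to `[-1, 1]`
#' against round-off.
#'
#' @param r_hat,r_true Position 3-vectors (mm).
#' @param j_hat,j_true Nonzero current-density 3-vectors.
#' @return Scalar error (mm or degrees).
#' @export
localization_error <- function(r_hat, r_true) {
  sqrt(sum((vec3(r_hat, "r_hat") - vec3(r_true, "r_true"))^2))
}

#' @rdname localization_error
#' @export
direction_error <- function(j_hat, j_true) {
  j_hat <- vec3(j_hat, "j_hat"); j_true <- vec3(j_true, "j_true")
  n1 <- sqrt(sum(j_hat^2)); n2 <- sqrt(sum(j_true^2))
  if (n1 == 0 || n2 == 0) abort("direction error of a zero vector is undefined")
  acos(pmin(1, pmax(-1, sum(j_hat * j_true) / (n1 * n2)))) * 180 / pi
}

#' Run a randomized test-dipole study
#'
#' The standard accuracy protocol: dipoles at random positions in the
#' cardiac tissue with random orientations are forward-solved, measurement
#' noise is added at the requested SNR, each noisy potential vector is
#' localized by OMP, and localization error (LE) and direction error (DE)
#' are scored per trial. A convergence analysis over the trial count shows
#' the mean stabilising from about 100 dipoles, the working default.
#'
#' @param model A [voxel_model()] (forward solves run on it).
#' @param lfm The [build_lfm()] dictionary used for localization.
#' @param n_dipoles Number of trials (default 100).
#' @param snr_db SNR in dB (default `Inf`).
#' @param seed RNG seed; trial `t` draws its noise from `seed + t`
#'   (counter-based, reproducible in any execution order).
#' @param dipoles Optional pre-drawn [make_test_dipoles()] table
#'   (overrides `n_dipoles`).
#' @param on_grid Restrict dipole positions to the LFM source grid
#'   (exact-recovery checks); default `FALSE`, positions anywhere in the
#'   cardiac tissue.
#' @param selection Support-selection rule passed to [omp_localize()].
#' @return An object of class `dipole_study`: tibble of per-trial results
#'   with summary statistics in `glance()`.
#' @export
run_dipole_study <- function(model, lfm, n_dipoles = 100, snr_db = Inf,
                             seed = 1L, dipoles = NULL, on_grid = FALSE,
                             selection = c("column", "subspace")) {
  selection <- match.arg(selection)
  if (is.null(dipoles)) {
    if (on_grid) {
      if (!is.null(seed)) {
        old <- get0(".Random.seed", globalenv())
        on.exit(restore_rng(old), add = TRUE)
        set.seed(seed)
      }
      pick <- sample.int(nrow(lfm$points), n_dipoles, replace = TRUE)
      ori <- runif_sphere(n_dipoles)
      dipoles <- tibble(trial = seq_len(n_dipoles),
                        i = lfm$points$i[pick], j = lfm$points$j[pick],
                        k = lfm$points$k[pick],
                        x_mm = lfm$points$x_mm[pick],
                        y_mm = lfm$points$y_mm[pick],
                        z_mm = lfm$points$z_mm[pick],
                        dx = ori[, 1], dy = ori[, 2], dz = ori[, 3])
    } else {
      dipoles <- make_test_dipoles(model, n_dipoles, seed = seed)
    }
  }
  system <- spfd_system(model)
  factor <- spfd_factor(system)
  n <- nrow(dipoles)
  rows <- vector("list", n)
  for (t in seq_len(n)) {
    node <- c(dipoles$i[t], dipoles$j[t], dipoles$k[t])
    ori <- c(dipoles$dx[t], dipoles$dy[t], dipoles$dz[t])
    fw <- tryCatch(
      forward_oblique(system, factor, node, ori, lfm$electrodes),
      error = function(e) {
        abort(sprintf("forward solve failed at trial %d: %s", t,
                      conditionMessage(e)))
      })
    phi <- add_noise(fw$phi, snr_db,
                     seed = if (!is.null(seed)) seed + t)
    est <- omp_localize(lfm, phi, selection = selection)
    r_true <- c(dipoles$x_mm[t], dipoles$y_mm[t], dipoles$z_mm[t])
    rows[[t]] <- tibble(
      trial = t,
      true_x_mm = r_true[1], true_y_mm = r_true[2], true_z_mm = r_true[3],
      est_x_mm = est$location_mm[1], est_y_mm = est$location_mm[2],
      est_z_mm = est$location_mm[3],
      le_mm = localization_error(est$location_mm, r_true),
      de_deg = direction_error(est$j_hat, fw$j_true),
      corr = est$correlation, snr_db = snr_db)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("dipole_study", class(out))
  out
}

#' Sweep localization accuracy over SNR levels with repeated noise draws
#'
#' For a fixed set of test dipoles, the noise-free forward potentials are
#' computed once; then, for every SNR level, `n_noise` independent noise
#' patterns are drawn per dipole and localized (the correlation step is
#' vectorised over patterns). This is the protocol behind mean-LE versus
#' SNR curves with 1000 noise repetitions.
#'
#' @inheritParams run_dipole_study
#' @param snr_grid SNR levels in dB (default `c(0, 10, 20, 30, Inf)`).
#' @param n_noise Noise patterns per dipole and level (default 1000).
#' @return A `snr_sweep` tibble: one row per (snr_db, dipole) with the
#'   mean LE/DE over noise patterns, plus per-level summaries via
#'   [glance()].
#' @export
run_snr_sweep <- function(model, lfm, n_dipoles = 100,
                          snr_grid = c(0, 10, 20, 30, Inf),
                          n_noise = 1000, seed = 1L) {
  old <- get0(".Random.seed", globalenv())
  on.exit(restore_rng(old), add = TRUE)
  dipoles <- make_test_dipoles(model, n_dipoles, seed = seed)
  system <- spfd_system(model)
  factor <- spfd_factor(system)
  N <- nrow(lfm$points)
  cn <- lfm_column_norms(lfm)
  Ln <- sweep(lfm$L, 2, pmax(cn, .Machine$double.xmin), "/")
  loc <- (seq_len(3 * N) - 1L) %% N + 1L
  sup_pinv <- lapply(seq_len(N), function(i) {
    pinv(lfm$L[, c(i, N + i, 2 * N + i), drop = FALSE])
  })

  rows <- vector("list", length(snr_grid) * nrow(dipoles))
  r <- 0L
  for (t in seq_len(nrow(dipoles))) {
    node <- c(dipoles$i[t], dipoles$j[t], dipoles$k[t])
    ori <- c(dipoles$dx[t], dipoles$dy[t], dipoles$dz[t])
    fw <- forward_oblique(system, factor, node, ori, lfm$electrodes)
    r_true <- c(dipoles$x_mm[t], dipoles$y_mm[t], dipoles$z_mm[t])
    for (s in seq_along(snr_grid)) {
      snr <- snr_grid[s]
      if (is.infinite(snr)) {
        Phi <- matrix(fw$phi, ncol = 1)
      } else {
        set.seed(seed + 7919L * s + t)
        sd_n <- sqrt(mean(fw$phi^2) * 10^(-snr / 10))
        Phi <- matrix(fw$phi, length(fw$phi), n_noise) +
          matrix(rnorm(length(fw$phi) * n_noise, sd = sd_n),
                 length(fw$phi), n_noise)
      }
      picks <- omp_pick_vectorized(Ln, loc, Phi, N)
      le <- de <- numeric(ncol(Phi))
      for (p in seq_len(ncol(Phi))) {
        i_hat <- picks[p]
        j_hat <- as.vector(sup_pinv[[i_hat]] %*% Phi[, p])
        le[p] <- localization_error(
          c(lfm$points$x_mm[i_hat], lfm$points$y_mm[i_hat],
            lfm$points$z_mm[i_hat]), r_true)
        de[p] <- direction_error(j_hat, fw$j_true)
      }
      r <- r + 1L
      rows[[r]] <- tibble(snr_db = snr, trial = t,
                          mean_le_mm = mean(le), sd_le_mm = stats::sd(le),
                          mean_de_deg = mean(de), n_noise = ncol(Phi))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- seed
  class(out) <- c("snr_sweep", class(out))
  out
}

# argmax of |corr| per noisy column, ties toward the lowest grid index
omp_pick_vectorized <- function(Ln, loc, Phi, N) {
  C <- abs(crossprod(Ln, Phi))
  C <- sweep(C, 2, sqrt(colSums(Phi^2)), "/")
  apply(C, 2, function(col) min(loc[col >= max(col) - 1e-15]))
}
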