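#' Specify a synthetic block-torso phantom
#'
#' The phantom emulates the essential conductive structure of a whole-body
#' anatomical voxel model at desk scale: a muscle body inside an air
#' margin, two lung blocks flanking a cardiac block that contains a
#' high-conductivity blood core, and nine surface electrode sites (six
#' precordial on the anterior chest wall spanning the heart projection,
#' plus three distal limb surrogates). All blocks are axis-aligned
#' cuboids, which keeps generation purely deterministic and the geometry
#' auditable; the conductivity contrasts (blood 0.70, heart 0.05, lung
#' 0.20, muscle 0.20 S/m) are the ones that drive localization error in
#' the anatomical case.
#'
#' Unless given explicitly, block positions are derived from `dims`
#' proportionally to the 40-voxel reference design.
#'
#' @param dims Voxel counts per axis (default `c(40, 40, 40)`).
#' @param pitch_mm Voxel pitch in mm (default 2, the working resolution of
#'   the anatomical models this phantom stands in for).
#' @param margin Air margin in voxels around the body.
#' @param heart_center,heart_half Centre voxel index and half-width of the
#'   cardiac block.
#' @param blood_half Half-width of the nested blood core.
#' @param seed Stored for provenance; generation itself is deterministic.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(40, 40, 40), pitch_mm = 2, margin = NULL,
                         heart_center = NULL, heart_half = NULL,
                         blood_half = NULL, seed = 1L) {
  dims <- as.integer(vec3(dims, "dims"))
  if (any(dims < 12)) abort("phantom needs at least 12 voxels per axis")
  margin <- margin %||% max(2L, round(0.05 * min(dims)))
  heart_center <- heart_center %||% round(c(0.53, 0.40, 0.50) * dims)
  heart_half <- heart_half %||% max(3L, round(0.15 * min(dims)))
  blood_half <- blood_half %||% max(1L, round(heart_half / 2))
  spec <- structure(list(dims = dims, pitch_mm = pitch_mm,
                         margin = as.integer(margin),
                         heart_center = as.integer(heart_center),
                         heart_half = as.integer(heart_half),
                         blood_half = as.integer(blood_half),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  d <- spec$dims
  body_lo <- rep(spec$margin + 1L, 3L)
  body_hi <- d - spec$margin
  h_lo <- spec$heart_center - spec$heart_half
  h_hi <- spec$heart_center + spec$heart_half
  if (spec$blood_half >= spec$heart_half) {
    abort("blood core must nest strictly inside the cardiac block")
  }
  if (any(h_lo <= body_lo) || any(h_hi >= body_hi)) {
    abort("cardiac block must nest strictly inside the body")
  }
  spec
}

# packaged whole-body tissue labels used by the phantom
phantom_labels <- function() {
  c(air = 0L, blood = 4L, heart = 25L, lung = 32L, muscle = 33L)
}

#' Generate the block-torso voxel model
#'
#' @param spec A [phantom_spec()].
#' @return A [voxel_model()] using the packaged tissue conductivity table.
#' @examples
#' model <- make_block_torso(phantom_spec(dims = c(24, 24, 24)))
#' table(model$labels)
#' @export
make_block_torso <- function(spec) {
  spec <- validate_phantom_spec(spec)
  d <- spec$dims
  lab <- phantom_labels()
  labs <- array(lab[["air"]], dim = d)

  body_lo <- rep(spec$margin + 1L, 3L)
  body_hi <- d - spec$margin
  labs[body_lo[1]:body_hi[1], body_lo[2]:body_hi[2], body_lo[3]:body_hi[3]] <-
    lab[["muscle"]]

  h_lo <- spec$heart_center - spec$heart_half
  h_hi <- spec$heart_center + spec$heart_half

  # two lung blocks flanking the heart in x, spanning its y/z extent
  pad <- 1L
  lz <- pmax(h_lo[3] - 2L, body_lo[3] + 1L):pmin(h_hi[3] + 2L, body_hi[3] - 1L)
  ly <- pmax(h_lo[2] - 1L, body_lo[2] + 1L):pmin(h_hi[2] + 3L, body_hi[2] - 1L)
  lx_left <- (body_lo[1] + 1L):(h_lo[1] - pad - 1L)
  lx_right <- (h_hi[1] + pad + 1L):(body_hi[1] - 1L)
  if (length(lx_left) > 0) labs[lx_left, ly, lz] <- lab[["lung"]]
  if (length(lx_right) > 0) labs[lx_right, ly, lz] <- lab[["lung"]]

  labs[h_lo[1]:h_hi[1], h_lo[2]:h_hi[2], h_lo[3]:h_hi[3]] <- lab[["heart"]]
  b_lo <- spec$heart_center - spec$blood_half
  b_hi <- spec$heart_center + spec$blood_half
  labs[b_lo[1]:b_hi[1], b_lo[2]:b_hi[2], b_lo[3]:b_hi[3]] <- lab[["blood"]]

  voxel_model(labs, spec$pitch_mm, tissue_table(),
              heart_label = lab[["heart"]], blood_label = lab[["blood"]],
              lung_label = lab[["lung"]])
}

#' Nine-electrode layout for the block torso
#'
#' Places the six precordial surrogates (V1-V6) on the anterior body
#' surface in two rows spanning the heart projection, and the three limb
#' surrogates (RA, LA, LL) at distal surface sites: upper right, upper
#' left and lower left of the body. Coordinates are node positions in mm.
#'
#' @param spec A [phantom_spec()].
#' @return An `electrode_set` tibble (`role`, `x_mm`, `y_mm`, `z_mm`).
#' @export
phantom_electrodes <- function(spec) {
  spec <- validate_phantom_spec(spec)
  d <- spec$dims; p <- spec$pitch_mm
  node_mm <- function(i) (i - 1) * p   # node i sits at (i-1)*pitch
  body_lo <- rep(spec$margin + 1L, 3L)
  body_hi <- d - spec$margin
  y_front <- node_mm(body_lo[2])       # anterior face node plane
  hc <- spec$heart_center; hh <- spec$heart_half

  xs <- round(seq(hc[1] - hh, hc[1] + hh, length.out = 3))
  zs <- c(hc[3] + round(hh / 2), hc[3] - round(hh / 2))
  prec <- expand.grid(x = xs, z = zs)
  df <- tibble(
    role = c("V1", "V2", "V3", "V4", "V5", "V6", "RA", "LA", "LL"),
    x_mm = c(node_mm(prec$x),
             node_mm(body_lo[1]), node_mm(body_hi[1] + 1L),
             node_mm(body_hi[1] + 1L)),
    y_mm = c(rep(y_front, 6),
             node_mm(hc[2]), node_mm(hc[2]), node_mm(hc[2])),
    z_mm = c(node_mm(prec$z),
             node_mm(body_hi[3] + 1L), node_mm(body_hi[3] + 1L),
             node_mm(body_lo[3]))
  )
  electrode_set(df)
}

#' Draw random test dipoles inside the cardiac tissue
#'
#' Positions are uniform over heart-labelled voxels and orientations are
#' uniform on the unit sphere. The anode node of each dipole is the origin
#' corner of the sampled voxel; the reported true location is that node's
#' position in mm.
#'
#' @param model A [voxel_model()] with a heart label.
#' @param n Number of dipoles (study convergence analysis supports 100 as
#'   the working default).
#' @param seed RNG seed for reproducibility (`NULL` to use the current
#'   RNG state).
#' @param replace Sample voxels with replacement (default `TRUE`).
#' @return Tibble: `trial`, anode node indices `i`, `j`, `k`, true
#'   position `x_mm`, `y_mm`, `z_mm`, unit orientation `dx`, `dy`, `dz`.
#' @export
make_test_dipoles <- function(model, n = 100, seed = NULL, replace = TRUE) {
  if (n < 1) abort("`n` must be >= 1")
  hv <- which(heart_mask(model), arr.ind = TRUE)
  if (nrow(hv) == 0) abort("model has no heart voxels")
  if (!replace && n > nrow(hv)) {
    abort("more dipoles requested than heart voxels (no-replacement mode)")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  pick <- sample.int(nrow(hv), n, replace = replace)
  ori <- runif_sphere(n)
  idx <- hv[pick, , drop = FALSE]
  pos <- sweep((idx - 1) * model$pitch_mm, 2, model$origin_mm, "+")
  tibble(trial = seq_len(n),
         i = idx[, 1], j = idx[, 2], k = idx[, 3],
         x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
         dx = ori[, 1], dy = ori[, 2], dz = ori[, 3])
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a constant-speed source trajectory inside the heart
#'
#' Generates the ground-truth motion assumed by the tracking model: the
#' activation source advances at constant conduction speed `v_m_s` along a
#' (possibly curving) direction profile. Each step moves the position by
#' `v * dt` and records the step direction as the ground-truth current
#' direction surrogate.
#'
#' @param model A [voxel_model()]; every position must stay inside the
#'   cardiac tissue.
#' @param start_mm Starting position (mm).
#' @param directions Either a single 3-vector (straight path), an
#'   `n_steps x 3` matrix of per-step directions, or a function
#'   `function(step) -> 3-vector`. Directions are normalised internally.
#' @param v_m_s Conduction speed in m/s (ventricular default 1.9).
#' @param dt_s Time step in seconds (default 1 ms).
#' @param n_steps Number of steps.
#' @return Tibble of class `source_trajectory`: `step`, `t_s`, position
#'   `x_mm`, `y_mm`, `z_mm`, unit direction `dx`, `dy`, `dz`.
#' @export
make_trajectory <- function(model, start_mm, directions, v_m_s = 1.9,
                            dt_s = 0.001, n_steps = 20) {
  start_mm <- vec3(start_mm, "start_mm")
  if (n_steps == 0) {
    out <- tibble(step = integer(0), t_s = numeric(0),
                  x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                  dx = numeric(0), dy = numeric(0), dz = numeric(0))
    class(out) <- c("source_trajectory", class(out))
    return(out)
  }
  dirfun <- if (is.function(directions)) {
    directions
  } else if (is.matrix(directions)) {
    function(s) directions[s, ]
  } else {
    function(s) directions
  }
  step_mm <- v_m_s * dt_s * 1000
  pos <- matrix(NA_real_, n_steps, 3)
  dirs <- matrix(NA_real_, n_steps, 3)
  cur <- start_mm
  if (!position_in_heart(model, cur)) {
    abort("`start_mm` is not inside the cardiac tissue")
  }
  for (s in seq_len(n_steps)) {
    u <- vec3(dirfun(s), "direction")
    nu <- sqrt(sum(u^2))
    if (nu == 0) abort(sprintf("zero direction at step %d", s))
    u <- u / nu
    cur <- cur + step_mm * u
    if (!position_in_heart(model, cur)) {
      abort(sprintf("trajectory exits the cardiac tissue at step %d", s))
    }
    pos[s, ] <- cur
    dirs[s, ] <- u
  }
  out <- tibble(step = seq_len(n_steps), t_s = seq_len(n_steps) * dt_s,
                x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
                dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3])
  class(out) <- c("source_trajectory", class(out))
  out
}

position_in_heart <- function(model, pos_mm) {
  v <- floor((pos_mm - model$origin_mm) / model$pitch_mm) + 1
  d <- dim(model$labels)
  if (any(v < 1) || any(v > d)) return(FALSE)
  model$labels[v[1], v[2], v[3]] == model$heart_label ||
    (!is.na(model$blood_label) &&
       model$labels[v[1], v[2], v[3]] == model$blood_label)
}

#' Simulate the observation series seen by the tracker
#'
#' For every trajectory step: solve the forward problem for the true
#' dipole (superposing the three axis dipoles at the nearest grid node),
#' add measurement noise at the requested SNR, and localize with OMP.
#' The result is the `(r_hat, j_hat)` series the Kalman tracker consumes.
#'
#' @param trajectory A [make_trajectory()] result.
#' @param lfm A [build_lfm()] lead field matrix.
#' @param model The [voxel_model()] the forward solves run on.
#' @param snr_db Signal-to-noise ratio in dB (`Inf` for noise-free).
#' @param seed RNG seed for the noise draws.
#' @param factor Optional [spfd_factor()] to reuse.
#' @return Tibble of class `observation_series`: per step the OMP estimate
#'   (`rx_mm` .. `jz`), the true position, and the electrode potentials'
#'   SNR bookkeeping.
#' @export
synthesize_observations <- function(trajectory, lfm, model, snr_db = Inf,
                                    seed = NULL, factor = NULL) {
  if (nrow(trajectory) == 0) abort("empty trajectory")
  system <- spfd_system(model)
  factor <- factor %||% spfd_factor(system)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", globalenv())
    on.exit(restore_rng(old), add = TRUE)
  }
  rows <- vector("list", nrow(trajectory))
  for (s in seq_len(nrow(trajectory))) {
    pos <- c(trajectory$x_mm[s], trajectory$y_mm[s], trajectory$z_mm[s])
    ori <- c(trajectory$dx[s], trajectory$dy[s], trajectory$dz[s])
    node <- round((pos - model$origin_mm) / model$pitch_mm) + 1
    fw <- forward_oblique(system, factor, node, ori, lfm$electrodes)
    if (!is.null(seed)) set.seed(seed + s)   # counter-based per-step noise
    phi <- add_noise(fw$phi, snr_db)
    est <- omp_localize(lfm, phi)
    rows[[s]] <- tibble(step = trajectory$step[s], t_s = trajectory$t_s[s],
                        rx_mm = est$location_mm[1], ry_mm = est$location_mm[2],
                        rz_mm = est$location_mm[3],
                        jx = est$j_hat[1], jy = est$j_hat[2],
                        jz = est$j_hat[3],
                        true_x_mm = pos[1], true_y_mm = pos[2],
                        true_z_mm = pos[3], snr_db = snr_db)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("observation_series", class(out))
  out
}

# forward-solve an oblique unit dipole at `node` by superposition of the
# three positive-axis dipoles; returns electrode potentials and the true
# anode current-density vector (direction components scaled by each axis
# dipole's anode current density).
forward_oblique <- function(system, factor, node, ori, electrodes,
                            current_A = 1) {
  phis <- numeric(nrow(electrodes))
  j_true <- numeric(3)
  for (a in 1:3) {
    if (ori[a] == 0) next
    src <- dipole_source(node, c("+x", "+y", "+z")[a], current_A)
    fld <- solve_field_direct(system, factor, src)
    phis <- phis + ori[a] * electrode_potentials(fld, electrodes)
    j_true[a] <- ori[a] * anode_current_density(system, fld, src)
  }
  list(phi = phis, j_true = j_true)
}

# direct solve through a prepared factor, returning a potential_field
solve_field_direct <- function(system, factor, source) {
  b <- source_to_rhs(system, source)
  x <- factor_solve(factor, b[factor$idx])
  x <- x - mean(x)
  phi <- numeric(prod(system$nd))
  phi[factor$idx] <- x
  structure(list(phi = array(phi, system$nd), residual = 0,
                 iterations = 1L, method = "direct", nd = system$nd,
                 pitch_mm = system$pitch_mm, origin_mm = system$origin_mm,
                 conducting = system$conducting),
            class = "potential_field")
}
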