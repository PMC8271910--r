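#' Electrode sets
#'
#' An electrode set is a table of body-surface measurement sites with role
#' labels. The standard 12-lead ECG system has nine physical observation
#' points: the six precordial electrodes V1-V6 and the three limb
#' electrodes RA, LA, LL.
#'
#' @param x A data frame with columns `role`, `x_mm`, `y_mm`, `z_mm`, or a
#'   path to a CSV file with those columns.
#' @return An `electrode_set` tibble.
#' @export
electrode_set <- function(x) {
  if (is.character(x)) x <- read.csv(x, stringsAsFactors = FALSE)
  req <- c("role", "x_mm", "y_mm", "z_mm")
  if (!all(req %in% names(x))) {
    abort("electrode set needs columns role, x_mm, y_mm, z_mm")
  }
  if (anyDuplicated(x$role)) abort("electrode roles must be unique")
  out <- as_tibble(x[, req])
  class(out) <- c("electrode_set", class(out))
  out
}

#' Select the myocardial source grid
#'
#' A voxel is eligible as a source point when it and all six of its
#' face-neighbours carry the cardiac label — dipoles are only placed well
#' inside the cardiac tissue, never on its interface. Eligible voxels are
#' then subsampled on a regular lattice at `spacing_mm` (anchored at the
#' minimal eligible coordinate on each axis), in deterministic ascending
#' z, y, x scan order. On a 2 mm whole-body anatomical model a 6 mm
#' lattice yields on the order of 900 points.
#'
#' @param model A [voxel_model()] with a heart label.
#' @param spacing_mm Lattice spacing in mm (default 6); rounded to a
#'   whole number of voxels (minimum 1).
#' @return A `source_grid` tibble: `point`, voxel index `i`, `j`, `k` and
#'   the anode-node position `x_mm`, `y_mm`, `z_mm`; the spacing is kept
#'   in attribute `spacing_mm`.
#' @export
select_source_points <- function(model, spacing_mm = 6) {
  hm <- heart_mask(model)
  d <- dim(hm)
  # pad with FALSE so boundary voxels can never be eligible
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- hm
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  elig <- core &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  if (!any(elig)) abort("no voxel has all six face-neighbours in the heart")
  idx <- which(elig, arr.ind = TRUE)
  step <- max(1L, round(spacing_mm / model$pitch_mm))
  anchor <- apply(idx, 2, min)
  on_lattice <- (idx[, 1] - anchor[1]) %% step == 0 &
    (idx[, 2] - anchor[2]) %% step == 0 &
    (idx[, 3] - anchor[3]) %% step == 0
  idx <- idx[on_lattice, , drop = FALSE]
  ord <- order(idx[, 3], idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  pos <- sweep((idx - 1) * model$pitch_mm, 2, model$origin_mm, "+")
  out <- tibble(point = seq_len(nrow(idx)),
                i = idx[, 1], j = idx[, 2], k = idx[, 3],
                x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3])
  attr(out, "spacing_mm") <- spacing_mm
  class(out) <- c("source_grid", class(out))
  out
}

# current density (A/m^2) at the anode in the source direction: branch
# current through the source edge divided by the voxel cross-section.
anode_current_density <- function(system, field, source) {
  nd <- system$nd
  ia <- node_lin(matrix(source$anode, 1), nd)
  ic <- node_lin(matrix(source$cathode, 1), nd)
  S <- -system$A[ia, ic]
  if (S <= 0) abort("source edge carries no conductance")
  pitch_m <- system$pitch_mm / 1000
  phi <- as.vector(field$phi)
  S * (phi[ia] - phi[ic]) / pitch_m^2
}

#' Build the lead field matrix
#'
#' The lead field matrix `L` (size `M x 3N`) maps the current-density
#' amplitudes of unit-direction dipoles at the `N` source-grid points to
#' the potentials at the `M` electrodes: `L j = Phi`. Each column is
#' obtained from one forward solve: a unit dipole is placed at a grid
#' point along one base direction, the electrode potential vector is
#' extracted, and the column is the potential vector divided by the anode
#' current density of that solve (so the injected current magnitude
#' cancels). Columns are ordered in three direction blocks
#' `[x_1..x_N | y_1..y_N | z_1..z_N]`.
#'
#' @param model A [voxel_model()].
#' @param electrodes An [electrode_set()].
#' @param grid A [select_source_points()] grid (defaults to the model's
#'   6 mm grid).
#' @param solver Named list of solver options passed to the forward
#'   solver: `method` (default `"direct"`, exact and fastest for the many
#'   right-hand sides of an LFM build; `"multigrid"`/`"sor"` available),
#'   `tol`, `levels`, `omega`.
#' @return An object of class `lead_field`: matrix `L`, the grid, the
#'   electrodes and a provenance block (model hash, spacing, solver
#'   config, column layout).
#' @export
build_lfm <- function(model, electrodes, grid = NULL,
                      solver = list(method = "direct")) {
  grid <- grid %||% select_source_points(model)
  system <- spfd_system(model)
  method <- solver$method %||% "direct"
  tol <- solver$tol %||% 1e-6
  levels <- solver$levels %||% 6
  omega <- solver$omega %||% 1.5
  factor <- if (method == "direct") spfd_factor(system)

  N <- nrow(grid)
  M <- nrow(electrodes)
  L <- matrix(NA_real_, M, 3 * N)
  axes <- c("+x", "+y", "+z")
  for (p in seq_len(N)) {
    node <- c(grid$i[p], grid$j[p], grid$k[p])
    for (a in 1:3) {
      src <- dipole_source(node, axes[a])
      fld <- tryCatch(
        if (method == "direct") {
          solve_field_direct(system, factor, src)
        } else {
          solve_spfd(system, src, method = method, tol = tol,
                     levels = levels, omega = omega)
        },
        error = function(e) {
          abort(sprintf("forward solve failed at point %d axis %s: %s",
                        p, axes[a], conditionMessage(e)))
        })
      j_an <- anode_current_density(system, fld, src)
      L[, (a - 1) * N + p] <- electrode_potentials(fld, electrodes) / j_an
    }
  }
  structure(list(L = L, points = grid, electrodes = electrodes,
                 pitch_mm = model$pitch_mm, origin_mm = model$origin_mm,
                 provenance = list(
                   model_hash = model_hash(model),
                   spacing_mm = attr(grid, "spacing_mm"),
                   solver = list(method = method, tol = tol,
                                 levels = levels, omega = omega),
                   column_order = "x-block, y-block, z-block",
                   j_anode = "branch current through source edge / pitch^2")),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d electrodes x %d columns (%d points x 3 directions)\n",
              nrow(x$L), ncol(x$L), nrow(x$points)))
  invisible(x)
}

#' Persist and reload a lead field matrix
#'
#' Writes the matrix to `<path>.csv` (full 17-digit precision, lossless
#' for doubles) and everything else — source grid, electrode set, grid
#' geometry and provenance — to `<path>.json`. Loading against a model
#' whose content hash differs from the recorded one fails unless `force`d.
#'
#' @param lfm A [build_lfm()] result.
#' @param path Path stem (extensions are appended).
#' @param model Optional [voxel_model()] to check the provenance hash
#'   against on load.
#' @param force Load despite a model hash mismatch.
#' @return `load_lfm()` returns the `lead_field`; `save_lfm()` the path
#'   stem, invisibly.
#' @export
save_lfm <- function(lfm, path) {
  mat <- format(lfm$L, digits = 17, scientific = TRUE, trim = TRUE)
  write.table(mat, paste0(path, ".csv"), sep = ",", row.names = FALSE,
              col.names = FALSE, quote = FALSE)
  meta <- list(
    dims = dim(lfm$L),
    pitch_mm = lfm$pitch_mm,
    origin_mm = lfm$origin_mm,
    points = as.data.frame(lfm$points),
    spacing_mm = attr(lfm$points, "spacing_mm"),
    electrodes = as.data.frame(lfm$electrodes),
    provenance = lfm$provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname save_lfm
#' @export
load_lfm <- function(path, model = NULL, force = FALSE) {
  jp <- paste0(path, ".json"); cp <- paste0(path, ".csv")
  if (!file.exists(jp) || !file.exists(cp)) {
    abort(sprintf("no lead field found at stem '%s'", path))
  }
  meta <- jsonlite::read_json(jp, simplifyVector = TRUE)
  L <- as.matrix(read.csv(cp, header = FALSE,
                          colClasses = "numeric"))
  dimnames(L) <- NULL
  if (!all(dim(L) == unlist(meta$dims))) {
    abort("lead field matrix dimensions disagree with metadata")
  }
  if (!is.null(model)) {
    h <- model_hash(model)
    if (!identical(h, meta$provenance$model_hash) && !force) {
      abort("lead field was built for a different model (hash mismatch); use force = TRUE to override")
    }
  }
  points <- as_tibble(meta$points)
  attr(points, "spacing_mm") <- meta$spacing_mm
  class(points) <- c("source_grid", class(points))
  structure(list(L = L, points = points,
                 electrodes = electrode_set(
                   as.data.frame(meta$electrodes,
                                 stringsAsFactors = FALSE)),
                 pitch_mm = meta$pitch_mm,
                 origin_mm = unlist(meta$origin_mm),
                 provenance = meta$provenance),
            class = "lead_field")
}
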