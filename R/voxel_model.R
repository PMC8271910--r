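#' Voxelized volume-conductor models
#'
#' A `voxel_model` is a labelled 3-D integer array on a regular grid of
#' cubic voxels, together with the voxel pitch (mm), a world origin and a
#' [tissue_table()] giving each label's conductivity. It represents the
#' passive volume conductor (the torso or whole body) through which cardiac
#' source currents spread to the surface electrodes. Voxel `(i,j,k)`
#' (1-based) occupies the half-open cube `[i-1,i) x [j-1,j) x [k-1,k)` in
#' pitch units from the origin; grid nodes sit at voxel corners.
#'
#' @param labels 3-D integer array of tissue labels.
#' @param pitch_mm Voxel edge length in mm (`> 0`); anatomical whole-body
#'   models in this resolution class use 2 mm.
#' @param tissues A [tissue_table()].
#' @param origin_mm World position of the corner of voxel `(1,1,1)`.
#' @param heart_label,blood_label,lung_label Labels of the cardiac tissue,
#'   the intracardiac blood and the lung; `NA` when absent (for example
#'   after [homogenize()]).
#' @return An object of class `voxel_model`.
#' @export
voxel_model <- function(labels, pitch_mm, tissues,
                        origin_mm = c(0, 0, 0),
                        heart_label = NA_integer_,
                        blood_label = NA_integer_,
                        lung_label = NA_integer_) {
  if (length(dim(labels)) != 3) {
    abort("`labels` must be a 3-D array")
  }
  storage.mode(labels) <- "integer"
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1 || pitch_mm <= 0) {
    abort("`pitch_mm` must be a positive scalar")
  }
  model <- structure(
    list(labels = labels, pitch_mm = as.numeric(pitch_mm),
         origin_mm = vec3(origin_mm, "origin_mm"),
         tissues = tissues,
         heart_label = as.integer(heart_label),
         blood_label = as.integer(blood_label),
         lung_label = as.integer(lung_label)),
    class = "voxel_model")
  validate_voxel_model(model)
}

validate_voxel_model <- function(model) {
  present <- sort(unique(as.integer(model$labels)))
  missing <- setdiff(present, model$tissues$label)
  if (length(missing) > 0) {
    abort(sprintf("label(s) %s present in the volume but absent from the tissue table",
                  paste(missing, collapse = ", ")))
  }
  model
}

#' @export
print.voxel_model <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<voxel_model> %d x %d x %d voxels @ %g mm (%d tissues present)\n",
              d[1], d[2], d[3], x$pitch_mm,
              length(unique(as.integer(x$labels)))))
  if (!is.na(x$heart_label)) {
    cat(sprintf("  heart label %d (%d voxels)\n", x$heart_label,
                sum(x$labels == x$heart_label)))
  }
  invisible(x)
}

#' @export
dim.voxel_model <- function(x) dim(x$labels)

# logical mask of air voxels (sigma exactly 0)
air_mask <- function(model) {
  array(tissue_sigma(model$tissues, as.integer(model$labels)) == 0,
        dim = dim(model$labels))
}

heart_mask <- function(model, include_blood = FALSE) {
  if (is.na(model$heart_label)) {
    abort("model has no heart label")
  }
  m <- model$labels == model$heart_label
  if (include_blood && !is.na(model$blood_label)) {
    m <- m | model$labels == model$blood_label
  }
  m
}

#' Map each voxel to its tissue conductivity
#'
#' Element-wise lookup of the conductivity (S/m) for every voxel. Skin, if
#' present in the tissue table, is forced to 0.1 S/m: surface-potential
#' modelling uses wet/dry skin values rather than the much lower stratum
#' corneum conductivity.
#'
#' @param model A [voxel_model()].
#' @return A 3-D double array of conductivities, zero exactly at air.
#' @export
assign_conductivity <- function(model) {
  tt <- model$tissues
  skin <- tissue_label(tt, "Skin")
  sig <- tt$sigma_S_per_m
  if (!is.na(skin)) sig[tt$label == skin] <- 0.1
  lut <- setNames(sig, tt$label)
  array(unname(lut[as.character(as.integer(model$labels))]),
        dim = dim(model$labels))
}

#' Homogenize a volume conductor
#'
#' Replaces every non-air voxel by a single uniform tissue whose
#' conductivity is two-thirds that of muscle, keeping the body-surface
#' geometry (the air/non-air mask) identical. Homogenized models isolate
#' the purely geometric part of potential propagation from the effect of
#' tissue inhomogeneity, which is dominated by the high conductivity of
#' intracardiac blood.
#'
#' @param model A [voxel_model()] whose tissue table contains a "Muscle"
#'   entry (needed to derive the uniform conductivity).
#' @return A new `voxel_model` with one conducting tissue; the heart,
#'   blood and lung labels are dropped (`NA`) since the structures no
#'   longer exist. Pair it with the original model's source grid when
#'   building a lead field matrix.
#' @export
homogenize <- function(model) {
  muscle <- tissue_label(model$tissues, "Muscle")
  if (is.na(muscle)) {
    abort("cannot homogenize: tissue table has no Muscle entry")
  }
  sigma_h <- (2 / 3) * tissue_sigma(model$tissues, muscle)
  air <- air_mask(model)
  airs <- model$tissues[model$tissues$sigma_S_per_m == 0, , drop = FALSE]
  newlab <- max(model$tissues$label) + 1L
  tt <- new_tissue_table(c(airs$label, newlab),
                         c(airs$name, "Homogeneous tissue"),
                         c(airs$sigma_S_per_m, sigma_h))
  labs <- array(newlab, dim = dim(model$labels))
  labs[air] <- model$labels[air]
  voxel_model(labs, model$pitch_mm, tt, model$origin_mm)
}

#' Rotate or scale the cardiac tissue inside a model
#'
#' Applies a rigid rotation about the z-axis and/or an isotropic scaling,
#' both centred on the heart-voxel centroid, to the cardiac tissue only,
#' leaving the rest of the conductor untouched. This emulates
#' patient-to-patient and beat-phase variation in cardiac orientation and
#' volume when the lead field matrix was built from the unperturbed
#' anatomy. Voxels are resampled by nearest neighbour (inverse mapping),
#' which preserves integer labels; volume vacated by the transform is
#' filled with lung tissue, and voxels newly claimed by the heart overwrite
#' their previous label.
#'
#' @param model A [voxel_model()] with a heart label (and a lung label for
#'   the vacancy fill).
#' @param rotation_deg_z Rotation angle about z in degrees; the sensitivity
#'   protocol uses -10..10 (a warning is issued outside that range).
#' @param scale_pct Isotropic scale in percent; protocol range 90..110.
#' @param move_blood Also transform intracardiac blood voxels (default
#'   `FALSE`: cardiac muscle only).
#' @return A new `voxel_model` with the perturbed heart.
#' @export
transform_heart <- function(model, rotation_deg_z = 0, scale_pct = 100,
                            move_blood = FALSE) {
  if (abs(rotation_deg_z) > 10) {
    warn(sprintf("rotation %g deg is outside the nominal -10..10 range",
                 rotation_deg_z))
  }
  if (scale_pct < 90 || scale_pct > 110) {
    warn(sprintf("scale %g%% is outside the nominal 90..110 range", scale_pct))
  }
  if (scale_pct <= 0) abort("`scale_pct` must be positive")
  cardiac <- heart_mask(model, include_blood = move_blood)
  if (!any(cardiac)) abort("model has no cardiac voxels")
  if (rotation_deg_z == 0 && scale_pct == 100) {
    return(model)
  }
  if (is.na(model$lung_label)) {
    abort("model needs a lung label to fill vacated cardiac volume")
  }

  d <- dim(model$labels)
  idx <- which(cardiac, arr.ind = TRUE)
  ctr <- colMeans(idx) - 0.5          # centroid in voxel-centre coordinates
  s <- scale_pct / 100
  th <- rotation_deg_z * pi / 180

  # candidate target region: cardiac bounding box grown by the transform
  rad <- max(sqrt(rowSums(sweep(idx - 0.5, 2, ctr)^2)))
  grow <- ceiling(rad * max(s, 1) - rad) + 2
  lo <- pmax(apply(idx, 2, min) - grow, 1)
  hi <- pmin(apply(idx, 2, max) + grow, d)
  tg <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))

  # inverse map target voxel centres into the source frame
  p <- sweep(tg - 0.5, 2, ctr)
  q <- p
  q[, 1] <- (cos(th) * p[, 1] + sin(th) * p[, 2]) / s
  q[, 2] <- (-sin(th) * p[, 1] + cos(th) * p[, 2]) / s
  q[, 3] <- p[, 3] / s
  q <- sweep(q, 2, ctr, "+")
  src <- floor(q) + 1

  inside <- src[, 1] >= 1 & src[, 1] <= d[1] &
    src[, 2] >= 1 & src[, 2] <= d[2] &
    src[, 3] >= 1 & src[, 3] <= d[3]
  tg <- tg[inside, , drop = FALSE]
  src <- src[inside, , drop = FALSE]
  src_lin <- src[, 1] + d[1] * (src[, 2] - 1 + d[2] * (src[, 3] - 1))
  hit <- cardiac[src_lin]
  tg_lin <- tg[, 1] + d[1] * (tg[, 2] - 1 + d[2] * (tg[, 3] - 1))

  air <- air_mask(model)
  if (any(air[tg_lin[hit]])) {
    abort("transform pushes cardiac tissue outside the body surface")
  }

  newlab <- model$labels
  newlab[cardiac] <- model$lung_label
  newlab[tg_lin[hit]] <- model$labels[src_lin[hit]]
  out <- model
  out$labels <- newlab
  validate_voxel_model(out)
}
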