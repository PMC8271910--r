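#' Read and write voxel conductor models
#'
#' Three on-disk representations are supported:
#' \describe{
#'   \item{`"raw"`}{little-endian unsigned integer volume (8- or 16-bit,
#'     chosen by the label range) plus a JSON sidecar `<path>.meta.json`
#'     holding shape, pitch, origin, the tissue table and the structural
#'     labels — the common exchange format for anatomical voxel models.}
#'   \item{`"text"`}{a single self-contained JSON file (labels in
#'     column-major order); convenient for small fixtures and diffing.}
#'   \item{`"nifti"`}{a NIfTI integer volume (pitch taken from / written to
#'     the header) plus the same JSON sidecar for the tissue table;
#'     requires the RNifti package.}
#' }
#'
#' @param model A [voxel_model()].
#' @param path Output/input path. For `"auto"` the format is inferred from
#'   the extension (`.raw`, `.json`, `.nii`/`.nii.gz`).
#' @param format One of `"auto"`, `"raw"`, `"text"`, `"nifti"`.
#' @return `load_model()` returns a [voxel_model()]; `save_model()`
#'   returns `path` invisibly.
#' @export
save_model <- function(model, path, format = "auto") {
  format <- resolve_model_format(path, format)
  meta <- list(
    shape = dim(model$labels),
    pitch_mm = model$pitch_mm,
    origin_mm = model$origin_mm,
    heart_label = model$heart_label,
    blood_label = model$blood_label,
    lung_label = model$lung_label,
    tissue_table = as.data.frame(model$tissues)[,
      c("label", "name", "sigma_S_per_m")]
  )
  if (format == "text") {
    meta$labels <- as.integer(model$labels)
    jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", na = "null")
  } else if (format == "raw") {
    maxlab <- max(model$labels)
    size <- if (maxlab < 256) 1L else 2L
    meta$dtype <- if (size == 1L) "uint8" else "uint16"
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(as.integer(model$labels), con, size = size, endian = "little")
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
  } else if (format == "nifti") {
    require_rnifti()
    img <- RNifti::asNifti(model$labels,
                           reference = list(pixdim = c(1, rep(model$pitch_mm, 3))))
    RNifti::writeNifti(img, path)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns", na = "null")
  }
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, format = "auto") {
  format <- resolve_model_format(path, format)
  if (!file.exists(path)) {
    abort(sprintf("model file not found: %s", path))
  }
  read_meta <- function(p) {
    if (!file.exists(p)) {
      abort(sprintf("missing metadata sidecar: %s", p))
    }
    jsonlite::read_json(p, simplifyVector = TRUE)
  }
  if (format == "text") {
    meta <- read_meta(path)
    labs <- array(as.integer(meta$labels), dim = unlist(meta$shape))
  } else if (format == "raw") {
    meta <- read_meta(paste0(path, ".meta.json"))
    shape <- unlist(meta$shape)
    n <- prod(shape)
    size <- if (identical(meta$dtype, "uint16")) 2L else 1L
    con <- file(path, "rb")
    on.exit(close(con), add = TRUE)
    v <- readBin(con, what = "integer", n = n, size = size, signed = FALSE,
                 endian = "little")
    if (length(v) != n) {
      abort(sprintf("raw volume holds %d voxels but sidecar declares %d",
                    length(v), n))
    }
    labs <- array(v, dim = shape)
  } else if (format == "nifti") {
    require_rnifti()
    meta <- read_meta(paste0(path, ".meta.json"))
    img <- RNifti::readNifti(path)
    labs <- array(as.integer(img), dim = dim(img))
    pix <- RNifti::pixdim(img)
    if (!isTRUE(all.equal(unname(pix[1]), meta$pitch_mm, tolerance = 1e-6))) {
      abort("NIfTI header pitch disagrees with the metadata sidecar")
    }
  }
  tt <- new_tissue_table(meta$tissue_table$label, meta$tissue_table$name,
                         meta$tissue_table$sigma_S_per_m)
  voxel_model(labs, meta$pitch_mm, tt,
              origin_mm = unlist(meta$origin_mm),
              heart_label = meta$heart_label %||% NA_integer_,
              blood_label = meta$blood_label %||% NA_integer_,
              lung_label = meta$lung_label %||% NA_integer_)
}

resolve_model_format <- function(path, format) {
  format <- match.arg(format, c("auto", "raw", "text", "nifti"))
  if (format != "auto") return(format)
  if (grepl("\\.nii(\\.gz)?$", path)) return("nifti")
  if (grepl("\\.json$", path)) return("text")
  if (grepl("\\.raw$", path)) return("raw")
  abort(sprintf("cannot infer model format from '%s'; pass `format`", path))
}

require_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("NIfTI support needs the RNifti package")
  }
}
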