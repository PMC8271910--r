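#' Tissue conductivity tables
#'
#' A tissue table maps integer voxel labels to tissue names and electrical
#' conductivities (S/m) at cardiac frequencies, where the quasi-static
#' approximation holds and a single real conductivity per tissue suffices.
#' The packaged default table covers the 51 tissues of a whole-body
#' anatomical voxel model plus air, with skin fixed at 0.1 S/m (dry-skin
#' values appropriate for surface-potential modelling rather than stratum
#' corneum values).
#'
#' @param path Path to a CSV file with columns `label`, `name`,
#'   `sigma_S_per_m`. Defaults to the packaged whole-body table.
#' @return A tibble of class `tissue_table` with columns `label` (integer),
#'   `name` (character) and `sigma_S_per_m` (double).
#' @examples
#' tt <- tissue_table()
#' tt[tt$name == "Blood", ]
#' @export
tissue_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_conductivity.csv",
                        package = "cardiosource", mustWork = TRUE)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("label", "name", "sigma_S_per_m")
  if (!all(req %in% names(df))) {
    abort(sprintf("tissue table must have columns %s",
                  paste(req, collapse = ", ")))
  }
  new_tissue_table(df$label, df$name, df$sigma_S_per_m)
}

#' Construct a tissue table from vectors
#'
#' @param label Integer labels (unique).
#' @param name Tissue names.
#' @param sigma_S_per_m Conductivities in S/m, all `>= 0`; entries named
#'   "Air" or "Internal air" must be exactly 0.
#' @return A `tissue_table` tibble.
#' @export
new_tissue_table <- function(label, name, sigma_S_per_m) {
  label <- as.integer(label)
  sigma <- as.numeric(sigma_S_per_m)
  if (anyDuplicated(label)) {
    abort("tissue labels must be unique")
  }
  if (any(sigma < 0) || anyNA(sigma)) {
    abort("conductivities must be finite and >= 0")
  }
  is_air <- tolower(name) %in% c("air", "internal air")
  if (any(sigma[is_air] != 0)) {
    abort("air tissues must have conductivity exactly 0 S/m")
  }
  out <- tibble(label = label, name = as.character(name),
                sigma_S_per_m = sigma)
  class(out) <- c("tissue_table", class(out))
  out
}

#' @export
print.tissue_table <- function(x, ...) {
  cat(sprintf("<tissue_table> %d tissues, sigma in [%g, %g] S/m\n",
              nrow(x), min(x$sigma_S_per_m), max(x$sigma_S_per_m)))
  NextMethod()
}

tissue_label <- function(tissues, name) {
  hit <- which(tolower(tissues$name) == tolower(name))
  if (length(hit) == 0) return(NA_integer_)
  tissues$label[hit[1]]
}

tissue_sigma <- function(tissues, label) {
  idx <- match(label, tissues$label)
  tissues$sigma_S_per_m[idx]
}

air_labels <- function(tissues) {
  tissues$label[tolower(tissues$name) %in% c("air", "internal air")]
}
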