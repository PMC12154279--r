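# Serialization: raw and spectral containers are written as versioned
# R serialization files with an explicit schema tag checked on read;
# maps go to NIfTI so standard viewers can overlay them, tables to CSV
# and reports to JSON.

SCHEMA_VERSION <- 1L

write_container <- function(x, path, type) {
  saveRDS(list(schema = SCHEMA_VERSION, type = type, payload = x), path)
  invisible(path)
}

read_container <- function(path, type) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot parse ", path, ": ", conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || is.null(obj$schema) || is.null(obj$type))
    stop("file ", path, " is not a recognized container")
  if (obj$type != type)
    stop("file ", path, " holds a '", obj$type, "', expected '", type, "'")
  if (obj$schema != SCHEMA_VERSION)
    stop("schema version mismatch in ", path, ": file v", obj$schema,
         ", reader v", SCHEMA_VERSION)
  obj$payload
}

#' Read and write raw k-space and spectral-image containers
#'
#' Versioned on-disk containers for [kspace_data()] and
#' [spectral_image()] objects; the schema version is checked on read
#' and a mismatch raises an explicit version error.
#'
#' @param x object to write
#' @param path file path
#' @return the path (write) or the restored object (read)
#' @export
write_kspace <- function(x, path) {
  stopifnot(inherits(x, "kspace_data"))
  write_container(x, path, "kspace_data")
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) read_container(path, "kspace_data")

#' @rdname write_kspace
#' @export
write_spectral_image <- function(x, path) {
  stopifnot(inherits(x, "spectral_image"))
  write_container(x, path, "spectral_image")
}

#' @rdname write_kspace
#' @export
read_spectral_image <- function(path) read_container(path, "spectral_image")

#' Export metabolite or ratio maps as NIfTI volumes
#'
#' Writes one single-slice NIfTI volume per map. The voxel size
#' encodes the field of view (1.875 mm at a 60 mm FOV on a 32 x 32
#' grid), so the maps overlay correctly on anatomical references.
#'
#' @param maps a `metabolite_maps` or `ratio_maps` object
#' @param dir output directory
#' @param prefix file-name prefix
#' @param slice_mm slice thickness (mm)
#' @return named character vector of the files written
#' @export
write_maps_nifti <- function(maps, dir, prefix = "map", slice_mm = 8) {
  stopifnot(inherits(maps, "metabolite_maps"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- maps$fov_mm / nrow(maps$maps[[1]])
  out <- vapply(names(maps$maps), function(nm) {
    path <- file.path(dir, paste0(prefix, "_", nm, ".nii.gz"))
    arr <- array(maps$maps[[nm]], c(dim(maps$maps[[1]]), 1))
    attr(arr, "pixdim") <- c(vox, vox, slice_mm)
    RNifti::writeNifti(RNifti::asNifti(arr), path)
    path
  }, character(1))
  out
}

#' Read or write an ROI quantification table
#'
#' @param quant tibble from [quantify_rois()]
#' @param path CSV path
#' @export
write_quant_csv <- function(quant, path) {
  readr::write_csv(quant, path)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write a statistics report as JSON
#'
#' @param report named list (e.g. of [glance.comparison_result()]
#'   rows and summary tables)
#' @param path JSON path
#' @export
write_stats_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
  invisible(path)
}
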