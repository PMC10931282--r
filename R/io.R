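#' Write / read a volume as NIfTI
#'
#' Voxel size goes into the NIfTI pixdim; grid origin, modality and any extra
#' metadata go into a JSON sidecar next to the file (`<file>.json`).
#'
#' @param volume A [volume_image()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param extra Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, extra = list()) {
  img <- RNifti::asNifti(volume$values, pixdim = volume$voxel_size)
  RNifti::writeNifti(img, path)
  meta <- c(list(origin_mm = volume$origin, voxel_mm = volume$voxel_size,
                 modality = volume$modality), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  volume_image(array(as.numeric(img), dim = dim(img)),
               voxel_size = meta$voxel_mm, origin = meta$origin_mm,
               modality = meta$modality)
}

#' Write / read a detector-plane image as 32-bit float TIFF
#'
#' Pixel values are stored as 32-bit IEEE floats scaled to `[0, 1]` by the
#' image maximum; the scale, pitch, gantry angle, image class and plane
#' origin travel in a JSON sidecar so the round trip is exact to float
#' precision.
#'
#' @param image An [epid_image()], [projection_image()] or [fluence_map()].
#' @param path Output `.tif` path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  scale <- max(image$values, 1e-300)
  tiff::writeTIFF(image$values / scale, path, bits.per.sample = 32L)
  meta <- list(scale = scale, pixel_pitch = image$pixel_pitch,
               origin_uv = image$origin_uv,
               class = class(image)[1],
               gantry_angle = image$gantry_angle %||% NA,
               reference_distance = image$reference_distance %||% NA)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  vals <- tiff::readTIFF(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- vals * meta$scale
  switch(meta$class,
    epid_image = epid_image(vals, meta$pixel_pitch, meta$gantry_angle,
                            meta$origin_uv),
    projection_image = projection_image(vals, meta$pixel_pitch,
                                        meta$gantry_angle, meta$origin_uv),
    fluence_map = fluence_map(vals, meta$pixel_pitch,
                              meta$reference_distance, meta$origin_uv),
    stop("unknown image class in sidecar: ", meta$class)
  )
}

#' Write / read a couch-shift list as CSV
#'
#' Columns `sx_mm`, `sy_mm`, `sz_mm` (plus an optional `group` column).
#'
#' @param shifts Tibble/data frame of shifts.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_shifts <- function(shifts, path) {
  utils::write.csv(shifts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shifts
#' @export
read_shifts <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("sx_mm", "sy_mm", "sz_mm") %in% names(df))) {
    stop("shift CSV needs columns sx_mm, sy_mm, sz_mm")
  }
  tibble::as_tibble(df)
}

#' Write / read a geometry or model configuration as YAML
#'
#' @param object A configuration list (e.g. [acquisition_geometry()]).
#' @param path YAML path.
#' @return `path` (write) or the configuration (read).
#' @export
write_config <- function(object, path) {
  lst <- unclass(object)
  lst$.class <- class(object)[1]
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lst <- yaml::read_yaml(path)
  cls <- lst$.class
  lst$.class <- NULL
  if (!is.null(cls)) {
    if (cls == "acquisition_geometry") {
      return(do.call(acquisition_geometry, lst))
    }
    if (cls == "attenuation_model") return(do.call(attenuation_model, lst))
    if (cls == "reconstruction_config") {
      return(do.call(reconstruction_config, lst))
    }
    class(lst) <- cls
  }
  lst
}

#' Write an experiment report as CSV and JSON
#'
#' Floating-point columns are rounded to 9 significant digits so repeated
#' seeded runs produce byte-identical reports.
#'
#' @param report A tibble (from [run_shift_experiment()] or
#'   [run_fluence_experiment()]).
#' @param base Output path without extension.
#' @return The base path, invisibly.
#' @export
write_report <- function(report, base) {
  dir.create(dirname(base), showWarnings = FALSE, recursive = TRUE)
  rounded <- report
  for (nm in names(rounded)) {
    if (is.double(rounded[[nm]])) rounded[[nm]] <- signif(rounded[[nm]], 9)
  }
  utils::write.csv(rounded, paste0(base, ".csv"), row.names = FALSE)
  jsonlite::write_json(rounded, paste0(base, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(base)
}
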