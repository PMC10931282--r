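#' Linac acquisition geometry
#'
#' Describes the source/detector arrangement used both to simulate EPID images
#' and to trace rays during reconstruction. World coordinates put the
#' isocenter at the origin with x = patient left, y = anterior-to-posterior
#' and z = superior-to-inferior; at gantry angle 0 the source sits on +y and
#' the beam travels along -y. The detector plane is perpendicular to the beam
#' axis at distance `SID` from the source and is spanned by the in-plane
#' lateral axis u and v = +z.
#'
#' Defaults reproduce a Halcyon-class setup: SAD 1000 mm, SID 1540 mm, ten
#' gantry angles evenly spaced over 0-180 degrees at 18 degree intervals, a
#' 1280 x 1280 panel at 0.336 mm pitch (43 cm field of view) and a
#' 200 x 200 mm field at the isocenter.
#'
#' @param SAD Source-to-isocenter distance, mm.
#' @param SID Source-to-detector distance, mm (must exceed `SAD`).
#' @param gantry_angles Gantry angles in degrees, each in `[0, 360)`.
#' @param detector_rows,detector_cols Detector grid size.
#' @param detector_pitch Detector pixel pitch, mm.
#' @param field_size Collimated field size at the isocenter, mm (length 2).
#' @param beam `"cone"` for a diverging point source (the physical setup) or
#'   `"parallel"` for a parallel-beam toggle used by oracle tests.
#' @return An object of class `acquisition_geometry`.
#' @export
acquisition_geometry <- function(SAD = 1000, SID = 1540,
                                 gantry_angles = seq(0, 162, by = 18),
                                 detector_rows = 1280L, detector_cols = 1280L,
                                 detector_pitch = 0.336,
                                 field_size = c(200, 200),
                                 beam = c("cone", "parallel")) {
  beam <- match.arg(beam)
  stopifnot(is.numeric(SAD), is.numeric(SID), length(SAD) == 1, length(SID) == 1)
  if (!(SID > SAD && SAD > 0)) {
    stop("geometry requires SID > SAD > 0 (got SAD = ", SAD, ", SID = ", SID, ")")
  }
  if (any(gantry_angles < 0 | gantry_angles >= 360)) {
    stop("gantry angles must lie in [0, 360)")
  }
  if (detector_pitch <= 0) stop("detector_pitch must be > 0")
  if (length(field_size) == 1) field_size <- rep(field_size, 2)
  structure(
    list(SAD = SAD, SID = SID, gantry_angles = as.numeric(gantry_angles),
         detector_rows = as.integer(detector_rows),
         detector_cols = as.integer(detector_cols),
         detector_pitch = detector_pitch,
         field_size = as.numeric(field_size), beam = beam),
    class = "acquisition_geometry"
  )
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat("Acquisition geometry (", x$beam, " beam)\n", sep = "")
  cat(sprintf("  SAD %g mm, SID %g mm (magnification %.3f)\n",
              x$SAD, x$SID, x$SID / x$SAD))
  cat(sprintf("  detector %d x %d @ %g mm, field %g x %g mm at isocenter\n",
              x$detector_rows, x$detector_cols, x$detector_pitch,
              x$field_size[1], x$field_size[2]))
  cat("  gantry angles:", paste(x$gantry_angles, collapse = ", "), "deg\n")
  invisible(x)
}

#' Projection magnification SID/SAD
#' @param geometry An [acquisition_geometry()].
#' @return The detector-plane magnification factor.
#' @export
magnification <- function(geometry) geometry$SID / geometry$SAD

# (u, v) mm of detector pixel (1,1)'s centre for a centred panel
detector_uv0 <- function(nrow, ncol, pitch) {
  c(u0 = -(ncol - 1) / 2 * pitch, v0 = -(nrow - 1) / 2 * pitch)
}

#' 3D image volume on a regular grid
#'
#' Container for attenuation maps, planning CTs, reconstructed MVCTs and dose
#' grids. Values are stored as a 3D array indexed `[x, y, z]`; the world
#' position of the voxel with 0-based index `(i, j, k)` is
#' `origin + (index + 0.5) * voxel_size` (so `origin` is the corner of the
#' first voxel). When `origin` is omitted the grid is centered on the
#' isocenter.
#'
#' @param values 3D numeric array.
#' @param voxel_size Voxel edge lengths, mm (length 3, all > 0).
#' @param origin World mm of the corner of voxel (0,0,0); `NULL` centers the
#'   grid on the origin.
#' @param modality One of `"attenuation"`, `"planning-CT"`, `"MVCT"`, `"dose"`.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(values, voxel_size, origin = NULL,
                         modality = c("attenuation", "planning-CT", "MVCT",
                                      "dose")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3) stop("values must be a 3D array")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive lengths (mm)")
  }
  if (is.null(origin)) origin <- -dim(values) * voxel_size / 2
  structure(
    list(values = values, voxel_size = voxel_size,
         origin = as.numeric(origin), modality = modality),
    class = "volume_image"
  )
}

#' @export
print.volume_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume_image: %s> %d x %d x %d @ %g x %g x %g mm\n",
              x$modality, d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  origin (%g, %g, %g) mm; value range [%g, %g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.array.volume_image <- function(x, ...) x$values

#' Couch shift
#'
#' A rigid translation of the phantom/patient relative to the planned
#' position, in mm.
#'
#' @param sx,sy,sz Translation components along the world axes, mm.
#' @return An object of class `couch_shift` (named numeric of length 3).
#' @export
couch_shift <- function(sx = 0, sy = 0, sz = 0) {
  s <- c(sx = sx, sy = sy, sz = sz)
  if (any(!is.finite(s))) stop("couch shift components must be finite")
  structure(s, class = "couch_shift")
}

#' Translate a volume by a couch shift
#'
#' Moves the imaged object by `shift` (mm) in world coordinates by resampling
#' the scalar grid trilinearly, so sub-voxel shifts are representable.
#' Samples falling outside the grid take the nearest edge value.
#'
#' @param volume A [volume_image()].
#' @param shift A [couch_shift()] or numeric length-3 vector, mm.
#' @return The translated [volume_image()].
#' @export
shift_volume <- function(volume, shift) {
  s <- as.numeric(shift)
  if (all(s == 0)) return(volume)
  d <- dim(volume$values)
  out <- cpp_translate_trilinear(as.numeric(volume$values), as.integer(d),
                                 s / volume$voxel_size)
  volume$values <- array(out, dim = d)
  volume
}

#' Five reference couch shifts used in the registration study
#'
#' In-plane (x, y) displacements of (0,0), (-10,0), (0,-3), (5,10) and
#' (3,-3) mm with no longitudinal component.
#'
#' @return A tibble with columns `group`, `sx_mm`, `sy_mm`, `sz_mm`.
#' @export
table1_shifts <- function() {
  tibble::tibble(
    group = 1:5,
    sx_mm = c(0, -10, 0, 5, 3),
    sy_mm = c(0, 0, -3, 10, -3),
    sz_mm = 0
  )
}
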