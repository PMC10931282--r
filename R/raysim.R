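#' EPID image
#'
#' A 2D detector-plane grayscale grid. Rows advance along the detector v axis
#' (world +z), columns along the in-plane lateral u axis. `origin_uv` is the
#' detector-plane (u, v) mm of the first pixel's center; it is carried through
#' resampling and cropping so any pixel can be mapped back to the detector
#' plane.
#'
#' @param values Non-negative numeric matrix.
#' @param pixel_pitch Pixel pitch, mm.
#' @param gantry_angle Gantry angle of acquisition, degrees.
#' @param origin_uv `(u, v)` mm of pixel (1,1)'s center; `NULL` centers the
#'   grid on the detector axis.
#' @return An object of class `epid_image`.
#' @export
epid_image <- function(values, pixel_pitch, gantry_angle = 0,
                       origin_uv = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (any(values < 0)) stop("EPID grayscale values must be >= 0")
  if (is.null(origin_uv)) {
    origin_uv <- detector_uv0(nrow(values), ncol(values), pixel_pitch)
  }
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 gantry_angle = gantry_angle,
                 origin_uv = as.numeric(origin_uv)),
            class = "epid_image")
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf("<epid_image> %d x %d @ %g mm, gantry %g deg, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch, x$gantry_angle,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Trace one ray through a volume
#'
#' Exact Siddon-style voxel traversal of the straight line from the (rotated)
#' source to a detector pixel. A ray that misses the volume returns an empty
#' path (ray sum 0).
#'
#' @param geometry An [acquisition_geometry()].
#' @param angle Gantry angle, degrees.
#' @param detector_pixel `(row, col)` of the detector pixel (1-based).
#' @param volume A [volume_image()].
#' @param tau_max Fraction of the source-to-pixel segment to integrate
#'   (1 = the full ray; `d/SID` stops at the plane at distance `d`).
#' @return A `ray_path`: list with 1-based linear voxel `index`, intersection
#'   `length` (mm) and the `raysum` of the volume along the path.
#' @export
trace_ray <- function(geometry, angle, detector_pixel, volume, tau_max = 1) {
  r <- detector_pixel[1]; c <- detector_pixel[2]
  if (r < 1 || r > geometry$detector_rows || c < 1 ||
      c > geometry$detector_cols) {
    stop("detector_pixel outside the detector grid")
  }
  uv0 <- detector_uv0(geometry$detector_rows, geometry$detector_cols,
                      geometry$detector_pitch)
  ends <- ray_endpoints_r(geometry, angle,
                          uv0[1] + (c - 1) * geometry$detector_pitch,
                          uv0[2] + (r - 1) * geometry$detector_pitch)
  path <- cpp_trace_segment(ends$p0, ends$p1, volume$origin,
                            volume$voxel_size, dim(volume$values), tau_max)
  path$raysum <- sum(volume$values[path$index] * path$length)
  class(path) <- "ray_path"
  path
}

# R-side mirror of the C++ gantry frame, used by trace_ray and tests
ray_endpoints_r <- function(geometry, angle, u_mm, v_mm) {
  th <- angle * pi / 180
  s <- sin(th); cth <- cos(th)
  src <- c(geometry$SAD * s, geometry$SAD * cth, 0)
  dc <- -c((geometry$SID - geometry$SAD) * s,
           (geometry$SID - geometry$SAD) * cth, 0)
  u <- c(cth, -s, 0); v <- c(0, 0, 1); beam <- c(-s, -cth, 0)
  if (geometry$beam == "cone") {
    list(p0 = src, p1 = dc + u_mm * u + v_mm * v)
  } else {
    iso <- (u_mm * u + v_mm * v) * geometry$SAD / geometry$SID
    list(p0 = iso - geometry$SAD * beam,
         p1 = iso + (geometry$SID - geometry$SAD) * beam)
  }
}

#' Forward-project a volume onto the detector
#'
#' Line integrals (ray sums) of the volume for every pixel of a detector grid
#' at one gantry angle.
#'
#' @inheritParams trace_ray
#' @param nrow,ncol,pitch Optional detector grid override (defaults to the
#'   geometry's panel).
#' @param plane_d If given, integrate only from the source up to the plane
#'   perpendicular to the beam axis at distance `plane_d` mm from the source.
#' @return Matrix of ray sums (`nrow` x `ncol`).
#' @export
forward_project <- function(volume, geometry, angle, nrow = NULL, ncol = NULL,
                            pitch = NULL, plane_d = NULL) {
  nrow <- nrow %||% geometry$detector_rows
  ncol <- ncol %||% geometry$detector_cols
  pitch <- pitch %||% geometry$detector_pitch
  uv0 <- detector_uv0(nrow, ncol, pitch)
  tau <- if (is.null(plane_d)) 1 else plane_d / geometry$SID
  cpp_forward_project(as.numeric(volume$values), dim(volume$values),
                      volume$origin, volume$voxel_size, angle, geometry$SAD,
                      geometry$SID, as.integer(nrow), as.integer(ncol), pitch,
                      uv0[1], uv0[2], geometry$beam == "parallel", tau)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# collimated-field mask at the detector plane (field edges magnified by
# SID/SAD)
field_mask <- function(geometry, nrow, ncol, pitch) {
  half <- geometry$field_size / 2 * magnification(geometry)
  uv0 <- detector_uv0(nrow, ncol, pitch)
  us <- uv0[1] + (seq_len(ncol) - 1) * pitch
  vs <- uv0[2] + (seq_len(nrow) - 1) * pitch
  outer(abs(vs) <= half[2], abs(us) <= half[1], "&")
}

#' Simulate an EPID open-field / transmission image pair
#'
#' The open-field image is `I0_level` inside the collimated field footprint
#' (scaled by the optional radial profile) and zero outside; the transmission
#' image attenuates it by `exp(-raysum)` through the (optionally shifted)
#' phantom, i.e. the forward model whose logarithm is the projection
#' conversion `P = ln(I0 / I)`. With `noise = "poisson"` each pixel of both
#' images is drawn from a Poisson law with the noiseless value as mean.
#'
#' @param geometry An [acquisition_geometry()].
#' @param angle Gantry angle, degrees.
#' @param phantom Attenuation [volume_image()] (1/mm).
#' @param shift A [couch_shift()] applied to the phantom, mm.
#' @param I0_level Open-field grayscale level (> 0).
#' @param noise `"off"` or `"poisson"`.
#' @param seed Optional integer seed used when `noise = "poisson"`.
#' @param profile `"flat"` or `"radial"` (a gentle cosine falloff with
#'   off-axis distance, as a stand-in for an unflattened beam profile).
#' @param nrow,ncol,pitch Optional detector grid override.
#' @return List with elements `open` and `transmission`, both [epid_image()]s.
#' @export
simulate_epid_pair <- function(geometry, angle, phantom,
                               shift = couch_shift(0, 0, 0), I0_level = 1e4,
                               noise = c("off", "poisson"), seed = NULL,
                               profile = c("flat", "radial"), nrow = NULL,
                               ncol = NULL, pitch = NULL) {
  noise <- match.arg(noise)
  profile <- match.arg(profile)
  if (I0_level <= 0) stop("I0_level must be > 0")
  nrow <- nrow %||% geometry$detector_rows
  ncol <- ncol %||% geometry$detector_cols
  pitch <- pitch %||% geometry$detector_pitch

  moved <- shift_volume(phantom, shift)
  raysum <- forward_project(moved, geometry, angle, nrow, ncol, pitch)
  open <- I0_level * field_mask(geometry, nrow, ncol, pitch)
  if (profile == "radial") {
    uv0 <- detector_uv0(nrow, ncol, pitch)
    us <- uv0[1] + (seq_len(ncol) - 1) * pitch
    vs <- uv0[2] + (seq_len(nrow) - 1) * pitch
    r2 <- outer(vs^2, us^2, "+")
    open <- open * (0.9 + 0.1 * cos(pi * sqrt(r2) / max(sqrt(r2))))
  }
  trans <- open * exp(-raysum)
  if (noise == "poisson") {
    if (!is.null(seed)) set.seed(seed)
    open <- matrix(stats::rpois(length(open), open), base::nrow(open))
    trans <- matrix(stats::rpois(length(trans), trans), base::nrow(trans))
  }
  list(open = epid_image(open, pitch, angle),
       transmission = epid_image(trans, pitch, angle))
}
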