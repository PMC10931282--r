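#' Projection image (line integrals at the detector plane)
#'
#' Same layout as [epid_image()] but the values are dimensionless
#' log-projections `P = ln(I0 / I)`.
#'
#' @inheritParams epid_image
#' @return An object of class `projection_image`.
#' @export
projection_image <- function(values, pixel_pitch, gantry_angle = 0,
                             origin_uv = NULL) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (any(!is.finite(values))) stop("projection values must be finite")
  if (is.null(origin_uv)) {
    origin_uv <- detector_uv0(nrow(values), ncol(values), pixel_pitch)
  }
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 gantry_angle = gantry_angle,
                 origin_uv = as.numeric(origin_uv)),
            class = "projection_image")
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf(
    "<projection_image> %d x %d @ %g mm, gantry %g deg, range [%g, %g]\n",
    nrow(x$values), ncol(x$values), x$pixel_pitch, x$gantry_angle,
    min(x$values), max(x$values)))
  invisible(x)
}

#' Convert an EPID pair to a log-projection image
#'
#' Elementwise `P = ln(I0 / I)` with both intensities clamped at a small
#' positive floor before the logarithm (the conversion is undefined at zero
#' pixels, e.g. outside the collimated field). Negative projections, which can
#' arise from noise making I > I0, are clamped to zero: attenuation line
#' integrals are physically non-negative.
#'
#' @param open,transmission [epid_image()]s of identical shape, pitch and
#'   angle.
#' @param floor Intensity floor; default `1e-6 * max(open)`.
#' @return A [projection_image()].
#' @export
to_projection <- function(open, transmission, floor = NULL) {
  if (!identical(dim(open$values), dim(transmission$values))) {
    stop(sprintf("shape mismatch: open %s vs transmission %s",
                 paste(dim(open$values), collapse = "x"),
                 paste(dim(transmission$values), collapse = "x")))
  }
  if (open$pixel_pitch != transmission$pixel_pitch ||
      open$gantry_angle != transmission$gantry_angle) {
    stop("open and transmission images must share pitch and gantry angle")
  }
  floor <- floor %||% (1e-6 * max(open$values))
  if (floor <= 0) stop("floor must be > 0")
  p <- log(pmax(open$values, floor) / pmax(transmission$values, floor))
  p[p < 0] <- 0
  projection_image(p, open$pixel_pitch, open$gantry_angle, open$origin_uv)
}

#' Resample a detector-plane image to a new pixel pitch
#'
#' Bilinear interpolation on pixel-center coordinates. The output grid has
#' `round(n_in * pitch_in / pitch_out)` pixels per side and shares the input's
#' physical center, so the image's world footprint is preserved (which the
#' downstream registration relies on). Sample points slightly outside the
#' input grid take the nearest edge value. Constant images map to constant
#' images.
#'
#' @param image An [epid_image()] or [projection_image()].
#' @param target_pitch New pixel pitch, mm.
#' @return The resampled image, same class as the input.
#' @export
resample_bilinear <- function(image, target_pitch) {
  if (target_pitch <= 0) stop("target_pitch must be > 0")
  vals <- image$values
  p_in <- image$pixel_pitch
  n_out <- round(dim(vals) * p_in / target_pitch)
  if (any(n_out < 2)) {
    stop("target pitch coarser than the image (output smaller than 2 x 2)")
  }
  # centers: input pixel i at origin + (i-1)*pitch; output grid shares the
  # physical center of the input grid
  ctr <- image$origin_uv + rev(dim(vals) - 1) / 2 * p_in  # (u, v) of center
  u_out <- ctr[1] + (seq_len(n_out[2]) - (n_out[2] + 1) / 2) * target_pitch
  v_out <- ctr[2] + (seq_len(n_out[1]) - (n_out[1] + 1) / 2) * target_pitch
  # continuous input indices (1-based)
  ci <- (v_out - image$origin_uv[2]) / p_in + 1
  cj <- (u_out - image$origin_uv[1]) / p_in + 1
  out <- bilinear_grid(vals, ci, cj)
  make_like(image, out, target_pitch, origin_uv = c(u_out[1], v_out[1]))
}

# bilinear sample of `vals` on the grid rows x cols (continuous 1-based
# indices), clamped to the edge
bilinear_grid <- function(vals, rows, cols) {
  nr <- nrow(vals); nc <- ncol(vals)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1); c0 <- pmin(floor(cols), nc - 1)
  fr <- rows - r0; fc <- cols - c0
  i00 <- outer(r0, c0, function(r, c) vals[cbind(r, c)])
  i10 <- outer(r0 + 1, c0, function(r, c) vals[cbind(r, c)])
  i01 <- outer(r0, c0 + 1, function(r, c) vals[cbind(r, c)])
  i11 <- outer(r0 + 1, c0 + 1, function(r, c) vals[cbind(r, c)])
  FR <- matrix(fr, length(rows), length(cols))
  FC <- matrix(fc, length(rows), length(cols), byrow = TRUE)
  (1 - FR) * ((1 - FC) * i00 + FC * i01) + FR * ((1 - FC) * i10 + FC * i11)
}

make_like <- function(image, values, pitch, origin_uv) {
  if (inherits(image, "projection_image")) {
    projection_image(values, pitch, image$gantry_angle, origin_uv)
  } else {
    epid_image(values, pitch, image$gantry_angle, origin_uv)
  }
}

#' Crop invalid border rows/columns
#'
#' Removes the maximal border rows and columns whose every pixel is at or
#' below `zero_tol` in the validity mask (by default the image itself; the
#' preprocessing chain passes the resampled open-field image so that genuinely
#' zero projections inside the field survive). The crop offset in pixels is
#' recorded in the `crop_offset` attribute and `origin_uv` is advanced so
#' world positions are preserved.
#'
#' @param image An [epid_image()] or [projection_image()].
#' @param zero_tol Validity threshold.
#' @param mask Optional validity matrix (same shape as the image).
#' @return The cropped image with attribute `crop_offset = c(rows, cols)`.
#' @export
crop_invalid <- function(image, zero_tol = 0, mask = NULL) {
  m <- mask %||% image$values
  if (!identical(dim(m), dim(image$values))) {
    stop("mask shape must match the image")
  }
  valid_r <- which(apply(m, 1, function(x) any(x > zero_tol)))
  valid_c <- which(apply(m, 2, function(x) any(x > zero_tol)))
  if (length(valid_r) == 0 || length(valid_c) == 0) {
    stop("image is fully invalid (all pixels at or below zero_tol)")
  }
  r <- range(valid_r); c <- range(valid_c)
  out <- image$values[r[1]:r[2], c[1]:c[2], drop = FALSE]
  res <- make_like(image, out, image$pixel_pitch,
                   image$origin_uv +
                     c(c[1] - 1, r[1] - 1) * image$pixel_pitch)
  attr(res, "crop_offset") <- c(rows = r[1] - 1L, cols = c[1] - 1L)
  res
}

# symmetric center crop (or zero-pad) to a fixed pixel count per side
center_crop_pad <- function(image, size) {
  vals <- image$values
  out <- matrix(0, size[1], size[2])
  r_off <- floor((nrow(vals) - size[1]) / 2)
  c_off <- floor((ncol(vals) - size[2]) / 2)
  src_r <- seq(max(1, r_off + 1), min(nrow(vals), r_off + size[1]))
  src_c <- seq(max(1, c_off + 1), min(ncol(vals), c_off + size[2]))
  out[src_r - r_off, src_c - c_off] <- vals[src_r, src_c]
  make_like(image, out, image$pixel_pitch,
            image$origin_uv + c(c_off, r_off) * image$pixel_pitch)
}

#' Full projection preprocessing chain
#'
#' Converts a native-pitch EPID pair to the reduced projection grid used by
#' the reconstruction: log-projection at native pitch, bilinear resample to
#' `intermediate_pitch` (1 mm), crop of the invalid (unexposed) border using
#' the open-field mask, symmetric center crop/pad to
#' `final_size * final_pitch` mm, then resample to `final_pitch` (3 mm). With
#' the default settings the result is a 100 x 100 grid at 3 mm pitch
#' regardless of the native detector sampling.
#'
#' @param open,transmission Native [epid_image()] pair.
#' @param intermediate_pitch First resampling pitch, mm.
#' @param final_pitch Final pitch, mm.
#' @param final_size Final grid side, pixels.
#' @param floor Intensity floor for [to_projection()].
#' @param zero_tol Relative validity threshold for the open-field mask
#'   (fraction of its maximum).
#' @return A [projection_image()] of `final_size` x `final_size` pixels.
#' @export
preprocess_chain <- function(open, transmission, intermediate_pitch = 1,
                             final_pitch = 3, final_size = 100, floor = NULL,
                             zero_tol = 1e-3) {
  proj <- to_projection(open, transmission, floor)
  proj1 <- resample_bilinear(proj, intermediate_pitch)
  open1 <- resample_bilinear(open, intermediate_pitch)
  proj1 <- crop_invalid(proj1, zero_tol * max(open1$values),
                        mask = open1$values)
  target_px <- round(final_size * final_pitch / intermediate_pitch)
  proj1 <- center_crop_pad(proj1, c(target_px, target_px))
  out <- resample_bilinear(proj1, final_pitch)
  stopifnot(all(dim(out$values) == final_size))
  out
}
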