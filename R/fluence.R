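#' Attenuation/conversion model for primary-fluence inversion
#'
#' Bundles the linear grayscale-to-fluence conversion factor `f`, the
#' off-axis softening correction coefficient `a(r)` and the hardening
#' correction coefficient `b(r)`. Both coefficients are low-order polynomials
#' in the off-axis radius `r` (mm at the EPID plane, rescaled by `d/SID` when
#' evaluated at depth): `a(r) = a0 + a2 * (r / 100)^2`, `b(r) = b0`. The
#' defaults are water-like at 6 MV (`a0 = 0.005`/mm) with no off-axis or
#' hardening terms; site-specific values come from a transit-dosimetry
#' calibration and plug in here.
#'
#' @param f Grayscale-to-fluence conversion factor (> 0).
#' @param a0,a2 Softening-correction polynomial coefficients (1/mm).
#' @param b0 Hardening-correction coefficient (1/mm).
#' @return An object of class `attenuation_model`.
#' @export
attenuation_model <- function(f = 1, a0 = 0.005, a2 = 0, b0 = 0) {
  if (f <= 0) stop("conversion factor f must be > 0")
  structure(list(f = f, a0 = a0, a2 = a2, b0 = b0),
            class = "attenuation_model")
}

eval_a <- function(model, r) model$a0 + model$a2 * (r / 100)^2
eval_b <- function(model, r) model$b0 + 0 * r

# off-axis radius (mm) of each pixel of a detector-plane image
offaxis_radius <- function(image) {
  us <- image$origin_uv[1] + (seq_len(ncol(image$values)) - 1) *
    image$pixel_pitch
  vs <- image$origin_uv[2] + (seq_len(nrow(image$values)) - 1) *
    image$pixel_pitch
  sqrt(outer(vs^2, us^2, "+"))
}

#' Water-equivalent thickness maps for one gantry angle
#'
#' Per detector pixel: `t`, the water-equivalent path length from the source
#' to the EPID plane, and `t_prime`, the part of it beyond the calculation
#' plane at distance `plane_d` from the source (i.e. between the calculation
#' point and the EPID). CT values are converted to relative water density
#' before integration: attenuation maps divide by `mu_water`, Hounsfield-like
#' planning CTs use `HU/1000 + 1` clamped at 0.
#'
#' @param ct_volume A [volume_image()] (attenuation or planning-CT modality).
#' @param geometry An [acquisition_geometry()].
#' @param angle Gantry angle, degrees.
#' @param plane_d Distance of the calculation plane from the source, mm
#'   (defaults to the isocenter plane, `SAD`). Must lie in (0, SID].
#' @param mu_water Water attenuation used for the density conversion, 1/mm.
#' @param nrow,ncol,pitch Optional detector grid override.
#' @return An `equivalent_thickness` object: matrices `t` and `t_prime` (mm),
#'   plus `pixel_pitch`, `plane_d` and `gantry_angle`.
#' @export
compute_equivalent_thickness <- function(ct_volume, geometry, angle,
                                         plane_d = geometry$SAD,
                                         mu_water = 0.005, nrow = NULL,
                                         ncol = NULL, pitch = NULL) {
  if (plane_d <= 0 || plane_d > geometry$SID) {
    stop("plane_d must lie in (0, SID]: the calculation point cannot sit ",
         "beyond the EPID")
  }
  dens <- if (ct_volume$modality == "planning-CT") {
    pmax(ct_volume$values / 1000 + 1, 0)
  } else {
    ct_volume$values / mu_water
  }
  dvol <- volume_image(dens, ct_volume$voxel_size, ct_volume$origin,
                       modality = "attenuation")
  t_full <- forward_project(dvol, geometry, angle, nrow, ncol, pitch)
  t_to_plane <- forward_project(dvol, geometry, angle, nrow, ncol, pitch,
                                plane_d = plane_d)
  structure(list(t = t_full, t_prime = t_full - t_to_plane,
                 pixel_pitch = pitch %||% geometry$detector_pitch,
                 plane_d = plane_d, gantry_angle = angle),
            class = "equivalent_thickness")
}

#' Primary fluence map at a reference plane
#'
#' @param values Non-negative fluence matrix.
#' @param pixel_pitch Pixel pitch at the reference plane, mm.
#' @param reference_distance Distance of the plane from the source, mm.
#' @param origin_uv Plane (u, v) mm of pixel (1,1); `NULL` centers the grid.
#' @return An object of class `fluence_map`.
#' @export
fluence_map <- function(values, pixel_pitch, reference_distance,
                        origin_uv = NULL) {
  if (any(values < 0)) stop("fluence values must be >= 0")
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (is.null(origin_uv)) {
    origin_uv <- detector_uv0(nrow(values), ncol(values), pixel_pitch)
  }
  structure(list(values = values, pixel_pitch = pixel_pitch,
                 reference_distance = reference_distance,
                 origin_uv = as.numeric(origin_uv)),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("<fluence_map> %d x %d @ %g mm at d = %g mm, range [%g, %g]\n",
              nrow(x$values), ncol(x$values), x$pixel_pitch,
              x$reference_distance, min(x$values), max(x$values)))
  invisible(x)
}

attenuation_factor <- function(model, r, t_prime) {
  denom <- 1 + eval_b(model, r) * t_prime
  if (any(denom <= 0)) {
    stop("attenuation model invalid for this thickness: 1 + b(r) t' <= 0")
  }
  exp(-eval_a(model, r) * t_prime / denom)
}

#' Invert EPID grayscale to accelerator primary fluence
#'
#' `psi_p = f * SID^2 / d^2 * psi_EPID / exp(-a(r) t' / (1 + b(r) t'))`:
#' grayscale-to-fluence conversion, inverse-square scaling from the EPID plane
#' back to the calculation plane at distance `d`, and removal of the
#' attenuation between that plane and the EPID. The off-axis radius `r` is
#' measured at the EPID plane.
#'
#' @param epid_primary [epid_image()] holding the primary (scatter-corrected)
#'   EPID signal.
#' @param thickness An `equivalent_thickness` map from
#'   [compute_equivalent_thickness()] on the same grid, with
#'   `plane_d == d`.
#' @param model An [attenuation_model()].
#' @param geometry An [acquisition_geometry()].
#' @param d Distance of the calculation plane from the source, mm (0 < d <=
#'   SID).
#' @return A [fluence_map()] at distance `d`; its pitch is the EPID pitch
#'   scaled by `d / SID`.
#' @export
invert_primary_fluence <- function(epid_primary, thickness, model, geometry,
                                   d = geometry$SAD) {
  if (d <= 0 || d > geometry$SID) stop("d must lie in (0, SID]")
  if (!identical(dim(epid_primary$values), dim(thickness$t_prime))) {
    stop("EPID image and thickness map shapes differ")
  }
  r <- offaxis_radius(epid_primary)
  att <- attenuation_factor(model, r, thickness$t_prime)
  vals <- model$f * (geometry$SID^2 / d^2) * epid_primary$values / att
  scale <- d / geometry$SID
  fluence_map(vals, epid_primary$pixel_pitch * scale, d,
              origin_uv = epid_primary$origin_uv * scale)
}

#' Forward EPID model for a known primary fluence
#'
#' The algebraic inverse of [invert_primary_fluence()]:
#' `psi_EPID = d^2 / SID^2 * psi_p * exp(-a(r) t' / (1 + b(r) t')) / f`. Used
#' to synthesize transmission images from a prescribed accelerator output and
#' as the round-trip oracle for the inversion.
#'
#' @param fluence A [fluence_map()] at plane `d = fluence$reference_distance`.
#' @param thickness Matching `equivalent_thickness` map (detector grid).
#' @param model An [attenuation_model()].
#' @param geometry An [acquisition_geometry()].
#' @param noise `"off"` or `"poisson"`; Poisson draws use the noiseless
#'   grayscale as mean.
#' @param seed Optional seed for the Poisson draw.
#' @return An [epid_image()] at the detector plane.
#' @export
epid_from_fluence <- function(fluence, thickness, model, geometry,
                              noise = c("off", "poisson"), seed = NULL) {
  noise <- match.arg(noise)
  d <- fluence$reference_distance
  scale <- geometry$SID / d
  pitch <- fluence$pixel_pitch * scale
  img <- epid_image(fluence$values * 0, pitch, thickness$gantry_angle,
                    origin_uv = fluence$origin_uv * scale)
  r <- offaxis_radius(img)
  att <- attenuation_factor(model, r, thickness$t_prime)
  vals <- d^2 / geometry$SID^2 * fluence$values * att / model$f
  if (noise == "poisson") {
    if (!is.null(seed)) set.seed(seed)
    vals <- matrix(stats::rpois(length(vals), vals), nrow(vals))
  }
  epid_image(vals, pitch, thickness$gantry_angle,
             origin_uv = img$origin_uv)
}

#' Calibrate the grayscale-to-fluence conversion factor
#'
#' Least-squares scalar `f` minimizing `||f * open - known||^2`, i.e.
#' `f = <open, known> / <open, open>`.
#'
#' @param open_field [epid_image()] of the open-field acquisition.
#' @param known_output [fluence_map()] of the known accelerator output on the
#'   same grid (non-negative).
#' @return A list with `f` and the root-mean-square `residual`.
#' @export
calibrate_conversion <- function(open_field, known_output) {
  o <- as.numeric(open_field$values)
  k <- as.numeric(known_output$values)
  if (length(o) != length(k)) stop("open field and known output sizes differ")
  if (all(o == 0)) stop("open-field image is identically zero")
  if (any(k < 0)) stop("known output must be non-negative")
  f <- sum(o * k) / sum(o * o)
  list(f = f, residual = sqrt(mean((f * o - k)^2)))
}

#' Scatter-correction hook
#'
#' Separates the primary component of an EPID transmission image. `"none"`
#' returns the image unchanged; `"gaussian"` subtracts `amplitude` times the
#' image convolved with a normalized Gaussian of standard deviation
#' `width_px` pixels (a single-kernel scatter estimate), clamping at zero.
#'
#' @param epid_transmission An [epid_image()].
#' @param kernel `"none"` or `"gaussian"`.
#' @param amplitude Scatter fraction subtracted (>= 0).
#' @param width_px Gaussian kernel standard deviation, pixels.
#' @return The corrected [epid_image()].
#' @export
scatter_correct <- function(epid_transmission, kernel = c("none", "gaussian"),
                            amplitude = 0, width_px = 5) {
  kernel <- match.arg(kernel)
  if (kernel == "none" || amplitude == 0) return(epid_transmission)
  v <- epid_transmission$values
  k <- gaussian_kernel_2d(width_px, half_width = ceiling(3 * width_px))
  est <- conv2d_fft(v, k)
  out <- v - amplitude * est
  if (sum(out) < 0) {
    stop("scatter amplitude produces a negative total signal")
  }
  epid_transmission$values <- pmax(out, 0)
  epid_transmission
}

gaussian_kernel_2d <- function(sigma_px, half_width) {
  if (sigma_px <= 0) return(matrix(1, 1, 1))
  g <- stats::dnorm(seq(-half_width, half_width), sd = sigma_px)
  k <- outer(g, g)
  k / sum(k)
}

# zero-padded 2D convolution via FFT, output same size as x (kernel centered)
conv2d_fft <- function(x, k) {
  nr <- nrow(x) + nrow(k) - 1
  nc <- ncol(x) + ncol(k) - 1
  X <- matrix(0, nr, nc); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  K <- matrix(0, nr, nc); K[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(X) * stats::fft(K), inverse = TRUE)) /
    (nr * nc)
  r0 <- (nrow(k) - 1) %/% 2
  c0 <- (ncol(k) - 1) %/% 2
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x))]
}
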