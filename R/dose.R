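#' Three-component pencil-beam dose model
#'
#' Dose at depth `d` is `sum_j D'_j(d) * (Psi (*) W_j)` with one primary and
#' two scatter components. Depth-dose factors are exponentials
#' `D'_j(d) = c_j * exp(-mu_j * d)` and lateral kernels are a discrete delta
#' (primary) plus normalized Gaussians (small- and large-scale scatter) whose
#' widths must strictly increase with the component index. All parameters are
#' configurable; the defaults are generic 6 MV-like values in arbitrary model
#' units (no absolute calibration is attempted).
#'
#' @param weights Component weights `c_j` (length 3).
#' @param mu Depth attenuation of each component, 1/mm (length 3).
#' @param sigma Lateral kernel widths, mm (length 3; first is 0 = delta;
#'   must be strictly increasing).
#' @param depth_range Depths (mm) over which the model is defined.
#' @return An object of class `pencil_beam_model`.
#' @export
pencil_beam_model <- function(weights = c(0.8, 0.15, 0.05),
                              mu = c(0.005, 0.004, 0.003),
                              sigma = c(0, 3, 20), depth_range = c(0, 400)) {
  stopifnot(length(weights) == 3, length(mu) == 3, length(sigma) == 3)
  if (any(weights < 0)) stop("component weights must be >= 0")
  if (any(diff(sigma) <= 0)) {
    stop("kernel widths must strictly increase from primary to large-scale ",
         "scatter")
  }
  structure(list(weights = weights, mu = mu, sigma = sigma,
                 depth_range = depth_range),
            class = "pencil_beam_model")
}

depth_dose <- function(model, depths) {
  m <- vapply(seq_len(3),
              function(j) model$weights[j] * exp(-model$mu[j] * depths),
              numeric(length(depths)))
  matrix(m, nrow = length(depths), ncol = 3)
}

lateral_kernel <- function(model, j, pitch) {
  s_px <- model$sigma[j] / pitch
  gaussian_kernel_2d(s_px, half_width = max(1, ceiling(3 * s_px)))
}

#' Pencil-beam dose from a fluence map
#'
#' For each requested depth, convolves the fluence with each component's
#' lateral kernel (2D discrete convolution, zero-padded borders) and weights
#' by the component depth-dose factor.
#'
#' @param fluence A [fluence_map()].
#' @param model A [pencil_beam_model()].
#' @param depth_grid Depths (mm) at which dose planes are computed; all must
#'   lie inside the model's `depth_range`.
#' @return A `dose_grid`: [volume_image()] with modality `"dose"` (planes
#'   indexed by depth, voxel z-size = depth spacing) plus a `depths`
#'   attribute.
#' @export
pencil_beam_dose <- function(fluence, model, depth_grid) {
  if (any(fluence$values < 0)) stop("fluence must be non-negative")
  if (any(depth_grid < model$depth_range[1] |
            depth_grid > model$depth_range[2])) {
    stop(sprintf("depth outside the model range [%g, %g] mm",
                 model$depth_range[1], model$depth_range[2]))
  }
  dd <- depth_dose(model, depth_grid)   # ndepth x 3
  conv <- lapply(seq_len(3), function(j) {
    k <- lateral_kernel(model, j, fluence$pixel_pitch)
    if (length(k) == 1) fluence$values else conv2d_fft(fluence$values, k)
  })
  out <- array(0, c(dim(fluence$values), length(depth_grid)))
  for (i in seq_along(depth_grid)) {
    plane <- dd[i, 1] * conv[[1]] + dd[i, 2] * conv[[2]] + dd[i, 3] * conv[[3]]
    out[, , i] <- plane
  }
  dz <- if (length(depth_grid) > 1) diff(depth_grid)[1] else 1
  vol <- volume_image(pmax(out, 0),
                      c(fluence$pixel_pitch, fluence$pixel_pitch, dz),
                      modality = "dose")
  attr(vol, "depths") <- depth_grid
  attr(vol, "provenance") <- "treatment"
  class(vol) <- c("dose_grid", class(vol))
  vol
}

#' Correct the planning CT to the measured patient pose
#'
#' Resamples the planning CT at grid points translated by `-t` (trilinear),
#' so the corrected volume shows the anatomy where the registration found it.
#' Integer-voxel shifts reduce to a pure index roll (no interpolation blur);
#' out-of-volume samples take the nearest boundary value.
#'
#' @param planning_ct A [volume_image()].
#' @param shift Recovered couch shift `t`, mm (length 3 or
#'   `registration_result`).
#' @return The corrected [volume_image()].
#' @export
apply_registration_correction <- function(planning_ct, shift) {
  if (inherits(shift, "registration_result")) shift <- shift$shift_mm
  s <- as.numeric(shift)
  if (any(!is.finite(s))) stop("shift must be finite")
  shift_volume(planning_ct, s)
}

#' Accumulate imaging and treatment dose
#'
#' Elementwise sum of all per-field dose grids with provenance bookkeeping.
#' The imaging contribution (the dose spent acquiring the MVCT projections)
#' is reported as a fraction of the total.
#'
#' @param imaging_fields,treatment_fields Lists of `dose_grid`s on identical
#'   grids.
#' @return A `dose_grid` with attributes `imaging_fraction` (fraction of the
#'   total integral dose) and `contributions` (per-field integral dose).
#' @export
accumulate_total_dose <- function(imaging_fields, treatment_fields = list()) {
  fields <- c(imaging_fields, treatment_fields)
  if (length(fields) == 0) stop("no dose fields to accumulate")
  d0 <- dim(fields[[1]]$values)
  for (f in fields) {
    if (!identical(dim(f$values), d0)) {
      stop("dose grids do not share a common grid")
    }
  }
  total <- Reduce(`+`, lapply(fields, function(f) f$values))
  imaging <- if (length(imaging_fields)) {
    Reduce(`+`, lapply(imaging_fields, function(f) f$values))
  } else {
    array(0, d0)
  }
  out <- fields[[1]]
  out$values <- total
  attr(out, "provenance") <- "total"
  attr(out, "imaging_fraction") <-
    if (sum(total) > 0) sum(imaging) / sum(total) else 0
  attr(out, "contributions") <- vapply(fields, function(f) sum(f$values),
                                       numeric(1))
  out
}
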