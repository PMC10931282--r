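#' ART-TV reconstruction configuration
#'
#' Defaults follow the study protocol: 12 iterations, relaxation 0.1, TV
#' weight 1, and a 128 x 128 x 122 output grid at 2 x 2 x 3 mm voxels (a local
#' volume centered on the isocenter). The TV descent step can run after every
#' ray (the literal algorithm, costly), after every view (default) or once per
#' full iteration; `d`, the adaptive step size, is the L2 norm of the
#' ART-induced image change accumulated since the previous TV step.
#'
#' @param max_iterations Number of full sweeps over all rays (>= 1).
#' @param lambda ART relaxation factor, in (0, 2).
#' @param tv_weight TV regularization weight `mu` (0 disables TV).
#' @param epsilon Smoothing constant in the TV gradient denominator.
#' @param stop_tol Early-stop tolerance: iteration stops when the per-sweep
#'   change norm falls below `stop_tol * ||x||`.
#' @param grid_shape Reconstruction grid dimensions.
#' @param voxel_size Reconstruction voxel size, mm.
#' @param tv_cadence `"per_ray"`, `"per_view"` or `"per_iteration"`.
#' @return An object of class `reconstruction_config`.
#' @export
reconstruction_config <- function(max_iterations = 12, lambda = 0.1,
                                  tv_weight = 1, epsilon = 1e-8,
                                  stop_tol = 1e-6,
                                  grid_shape = c(128, 128, 122),
                                  voxel_size = c(2, 2, 3),
                                  tv_cadence = c("per_view", "per_ray",
                                                 "per_iteration")) {
  tv_cadence <- match.arg(tv_cadence)
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (lambda <= 0 || lambda >= 2) stop("lambda must lie in (0, 2)")
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(max_iterations = as.integer(max_iterations), lambda = lambda,
                 tv_weight = tv_weight, epsilon = epsilon,
                 stop_tol = stop_tol, grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 tv_cadence = tv_cadence),
            class = "reconstruction_config")
}

#' Single Kaczmarz (ART) ray update
#'
#' `x <- x + lambda * (p_i - w_i' x) / ||w_i||^2 * w_i`, touching only the
#' voxels on the ray. Zero-norm (empty) rays leave the image unchanged.
#'
#' @param x Numeric array (the current image estimate).
#' @param ray A `ray_path` from [trace_ray()] (fields `index`, `length`).
#' @param p_i Measured projection value for this ray.
#' @param lambda Relaxation factor (> 0).
#' @return The updated array.
#' @export
art_update_ray <- function(x, ray, p_i, lambda) {
  if (lambda <= 0) stop("lambda must be > 0")
  if (length(ray$index) == 0) return(x)
  w <- ray$length
  wnorm2 <- sum(w^2)
  if (wnorm2 == 0) return(x)
  resid <- p_i - sum(x[ray$index] * w)
  x[ray$index] <- x[ray$index] + lambda * resid / wnorm2 * w
  x
}

#' Non-negativity projection
#'
#' Elementwise `max(x, 0)`; idempotent.
#'
#' @param x Numeric array.
#' @return The projected array.
#' @export
nonneg_project <- function(x) {
  x[x < 0] <- 0
  x
}

#' Total-variation norm
#'
#' `sum over i,j of sqrt((x[i,j]-x[i-1,j])^2 + (x[i,j]-x[i,j-1])^2)` over
#' interior indices (both backward neighbours present). 3D arrays are summed
#' slice-by-slice along the third dimension, matching the per-slice TV used in
#' the reconstruction.
#'
#' @param x Numeric matrix or 3D array (each slice at least 2 x 2).
#' @param eps Optional smoothing added under the square root (0 gives the
#'   plain TV norm; the reconstruction's gradient uses a smoothed version).
#' @return Scalar TV norm.
#' @export
tv_norm <- function(x, eps = 0) {
  tv2d <- function(m) {
    di <- m[-1, -1, drop = FALSE] - m[-nrow(m), -1, drop = FALSE]
    dj <- m[-1, -1, drop = FALSE] - m[-1, -ncol(m), drop = FALSE]
    sum(sqrt(eps + di^2 + dj^2))
  }
  if (is.matrix(x)) return(tv2d(x))
  stopifnot(length(dim(x)) == 3)
  sum(apply(x, 3, tv2d))
}

#' Smoothed TV gradient
#'
#' The three-term derivative of the smoothed TV norm with respect to each
#' pixel; terms whose neighbours fall outside the grid are dropped
#' (one-sided), mirroring the valid-index convention of [tv_norm()]. 3D arrays
#' are processed slice-by-slice in the axial plane.
#'
#' @param x Numeric matrix or 3D array.
#' @param eps Smoothing constant (> 0).
#' @return Array of the same shape as `x`.
#' @export
tv_gradient <- function(x, eps = 1e-8) {
  if (eps <= 0) stop("eps must be > 0")
  d <- dim(x)
  out <- cpp_tv_gradient(as.numeric(x), as.integer(d), eps)
  array(out, dim = d)
}

#' Reconstruct a local MVCT with ART-TV
#'
#' Ray-by-ray algebraic reconstruction with non-negativity and adaptive-step
#' TV gradient descent. For every ray: Kaczmarz update, non-negativity
#' projection, accumulation of the change norm `d`; at the configured cadence
#' the image takes a TV descent step `x <- x - mu * d * v / ||v||` with `v`
#' the smoothed TV gradient. Sweeps stop at `max_iterations` or when the
#' per-sweep change norm drops below `stop_tol * ||x||`. The ray sweep order
#' is fixed (views in the order given, row-major within each view), so the
#' reconstruction is deterministic.
#'
#' @param projections List of [projection_image()]s (one per gantry angle).
#' @param geometry An [acquisition_geometry()].
#' @param config A [reconstruction_config()].
#' @return A list with `volume` (the MVCT [volume_image()]), `trace` (tibble
#'   with per-iteration `iteration`, `d`, `rel_change`, `tv_norm`), `support`
#'   (integer array of per-voxel ray counts) and `config`.
#' @export
reconstruct <- function(projections, geometry, config = reconstruction_config()) {
  if (length(projections) < 1) stop("at least one projection is required")
  angles <- vapply(projections, function(p) p$gantry_angle, numeric(1))
  pitches <- vapply(projections, function(p) p$pixel_pitch, numeric(1))
  uv0 <- t(vapply(projections, function(p) p$origin_uv, numeric(2)))
  vol <- volume_image(array(0, config$grid_shape), config$voxel_size,
                      modality = "MVCT")
  cad <- match(config$tv_cadence, c("per_ray", "per_view", "per_iteration")) - 1L
  res <- cpp_art_tv(lapply(projections, function(p) p$values), angles, uv0,
                    pitches, geometry$SAD, geometry$SID, config$grid_shape,
                    config$voxel_size, vol$origin, config$max_iterations,
                    config$lambda, config$tv_weight, config$epsilon,
                    config$stop_tol, cad, geometry$beam == "parallel")
  support <- array(res$support, config$grid_shape)
  if (all(support == 0)) {
    stop("geometry mismatch: no ray intersects the reconstruction volume")
  }
  vol$values <- array(res$x, config$grid_shape)
  n <- res$iterations
  trace <- tibble::tibble(
    iteration = res$trace_iteration[seq_len(n)],
    d = res$trace_d[seq_len(n)],
    rel_change = res$trace_rel_change[seq_len(n)],
    tv_norm = res$trace_tv[seq_len(n)]
  )
  list(volume = vol, trace = trace, support = support, config = config)
}
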