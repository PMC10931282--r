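#' Shannon entropy of binned intensities
#'
#' Entropy in bits of the normalized bin-count distribution of `values` over
#' `bins` equal-width bins spanning the value range. Empty bins contribute
#' nothing.
#'
#' @param values Numeric vector/array (at least one finite sample).
#' @param bins Number of bins (>= 2).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(values, bins = 64) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("at least one sample is required")
  if (bins < 2) stop("bins must be >= 2")
  p <- bin_counts(values, bins, range(values)) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

bin_counts <- function(values, bins, rng) {
  span <- diff(rng)
  if (span <= 0) span <- 1
  idx <- pmin(pmax(floor((values - rng[1]) / span * bins), 0), bins - 1) + 1
  tabulate(idx, nbins = bins)
}

bin_index <- function(values, bins, rng) {
  span <- diff(rng)
  if (span <= 0) span <- 1
  pmin(pmax(floor((values - rng[1]) / span * bins), 0), bins - 1) + 1
}

#' Joint intensity histogram of two images
#'
#' @param a,b Numeric arrays of identical shape.
#' @param bins Number of bins per image.
#' @return A list of class `joint_histogram` with the `bins` x `bins` count
#'   matrix (`a` on rows), the two marginals and the intensity ranges used.
#' @export
joint_histogram <- function(a, b, bins = 64) {
  if (!identical(dim(a) %||% length(a), dim(b) %||% length(b))) {
    stop("shape mismatch between the two images")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  ra <- range(a); rb <- range(b)
  ia <- bin_index(a, bins, ra); ib <- bin_index(b, bins, rb)
  counts <- matrix(tabulate((ib - 1) * bins + ia, nbins = bins * bins), bins)
  structure(list(bins = bins, counts = counts,
                 marginal_a = rowSums(counts), marginal_b = colSums(counts),
                 range_a = ra, range_b = rb),
            class = "joint_histogram")
}

entropy_from_counts <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two same-shaped images
#'
#' `MI(A, B) = H(A) + H(B) - H(A, B)` in bits, with all three entropies taken
#' from one joint histogram (marginals are its row/column sums), which
#' guarantees `MI >= 0` up to rounding.
#'
#' @inheritParams joint_histogram
#' @return Mutual information in bits.
#' @export
mutual_information <- function(a, b, bins = 64) {
  jh <- joint_histogram(a, b, bins)
  entropy_from_counts(jh$marginal_a) + entropy_from_counts(jh$marginal_b) -
    entropy_from_counts(jh$counts)
}

#' Convert matched/planned window centers to a couch shift
#'
#' `t = (c0 - c) * voxel_size`, componentwise, in mm: the translation that the
#' registration attributes to the patient.
#'
#' @param plan_center Planned window center, voxel coordinates.
#' @param matched_center Matched window center, voxel coordinates.
#' @param voxel_size Voxel size, mm (length 3, or recycled).
#' @return Numeric length-3 shift in mm, names `tx`, `ty`, `tz`.
#' @export
shift_from_centers <- function(plan_center, matched_center, voxel_size) {
  t <- (as.numeric(plan_center) - as.numeric(matched_center)) *
    rep(as.numeric(voxel_size), length.out = length(plan_center))
  names(t) <- c("tx", "ty", "tz")[seq_along(t)]
  t
}

#' Locate the MVCT inside the planning CT by exhaustive MI search
#'
#' Slides a window of the MVCT's size over the planning CT in one-voxel steps
#' within `search_radius` of the planned position and evaluates the mutual
#' information at every offset. The maximizing window center is the measured
#' patient position; the couch shift follows from [shift_from_centers()].
#' Ties are broken by the smallest Euclidean offset, then lexicographically in
#' (z, y, x). Window centers use the half-voxel convention for even window
#' sizes (e.g. 128.5), matching how treatment centers are usually quoted.
#'
#' @param mvct Reconstructed [volume_image()] (floating image).
#' @param planning_ct Planning [volume_image()] (reference/search area); must
#'   share the MVCT's voxel size.
#' @param plan_center Planned window center in planning-CT voxel coordinates
#'   (half-voxel convention); `NULL` derives it from the two volumes' world
#'   origins (the window the MVCT would occupy with no shift).
#' @param search_radius Search radius in voxels per axis (scalar or length 3).
#' @param bins Histogram bins.
#' @param mask Logical array (MVCT shape): voxels participating in the MI
#'   (typically the ray-support mask from [reconstruct()]); `NULL` uses all.
#' @return A `registration_result`: `matched_center`, `plan_center`,
#'   `mi_value` (bits), `shift_mm`, `mi_surface` (array over offsets) and
#'   `voxel_size`.
#' @export
sliding_search <- function(mvct, planning_ct, plan_center = NULL,
                           search_radius = 15, bins = 64, mask = NULL) {
  if (!isTRUE(all.equal(mvct$voxel_size, planning_ct$voxel_size))) {
    stop("MVCT and planning CT must share voxel size")
  }
  wdim <- dim(mvct$values)
  cdim <- dim(planning_ct$values)
  if (any(wdim > cdim)) stop("window larger than the search area")
  if (is.null(plan_center)) {
    # window start (1-based) such that the window's world footprint matches
    # the MVCT's, then the half-voxel center convention
    start <- (mvct$origin - planning_ct$origin) / planning_ct$voxel_size + 1
    plan_center <- start + (wdim - 1) / 2
  }
  start0 <- plan_center - (wdim - 1) / 2
  if (any(abs(start0 - round(start0)) > 1e-6)) {
    stop("plan_center must be voxel-aligned for this window size")
  }
  start0 <- as.integer(round(start0))
  radius <- as.integer(rep(search_radius, length.out = 3))
  m <- mask %||% array(TRUE, wdim)
  res <- cpp_mi_search(as.numeric(mvct$values), as.logical(m),
                       as.integer(wdim), as.numeric(planning_ct$values),
                       as.integer(cdim), start0, radius, as.integer(bins))
  matched <- plan_center + res$offset
  structure(list(
    matched_center = matched, plan_center = plan_center,
    mi_value = res$mi,
    shift_mm = shift_from_centers(plan_center, matched,
                                  planning_ct$voxel_size),
    mi_surface = array(res$surface, res$surface_dim),
    offsets = res$offset, voxel_size = planning_ct$voxel_size,
    n_voxels = res$n_masked
  ), class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat("MI registration result\n")
  cat(sprintf("  matched center (%s), plan center (%s)\n",
              paste(x$matched_center, collapse = ", "),
              paste(x$plan_center, collapse = ", ")))
  cat(sprintf("  MI %.4f bits over %d voxels\n", x$mi_value, x$n_voxels))
  cat(sprintf("  recovered couch shift t = (%g, %g, %g) mm\n",
              x$shift_mm[1], x$shift_mm[2], x$shift_mm[3]))
  invisible(x)
}

#' @export
as.data.frame.registration_result <- function(x, ...) {
  data.frame(matched_cx = x$matched_center[1], matched_cy = x$matched_center[2],
             matched_cz = x$matched_center[3], tx_mm = x$shift_mm[1],
             ty_mm = x$shift_mm[2], tz_mm = x$shift_mm[3],
             mi_bits = x$mi_value)
}
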