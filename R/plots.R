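#' Display an axial slice of a volume
#'
#' @param x A [volume_image()].
#' @param slice Axial (z) slice index; defaults to the middle slice.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the slice matrix.
#' @export
plot_volume_slice <- function(x, slice = NULL, ...) {
  slice <- slice %||% ceiling(dim(x$values)[3] / 2)
  m <- x$values[, , slice]
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::gray.colors(256), asp = 1,
                  xlab = "x (voxels)", ylab = "y (voxels)",
                  main = sprintf("%s, slice %d", x$modality, slice), ...)
  invisible(m)
}

#' Display a gamma map
#'
#' Pixels below the evaluation threshold are blank; passing pixels
#' (gamma <= 1) are shown in the lower half of the color scale.
#'
#' @param x A `gamma_map` from [global_gamma()].
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the gamma matrix.
#' @export
plot_gamma_map <- function(x, ...) {
  m <- x$values
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), pmin(m, 2),
                  zlim = c(0, 2), col = grDevices::hcl.colors(64, "Blue-Red"),
                  asp = 1, xlab = "u (pixels)", ylab = "v (pixels)",
                  main = sprintf("gamma map (%.1f%% passing)",
                                 x$passing_rate), ...)
  invisible(m)
}

#' Plot an ART-TV convergence trace
#'
#' @param trace The `trace` tibble from [reconstruct()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `trace`.
#' @export
plot_convergence <- function(trace, ...) {
  graphics::plot(trace$iteration, trace$rel_change, type = "b", log = "y",
                 xlab = "iteration", ylab = "relative image change", ...)
  invisible(trace)
}
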