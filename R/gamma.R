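#' Gamma-index acceptance criteria
#'
#' Standard transit-dosimetry criteria: dose tolerance as a percentage of the
#' global normalization value (the maximum of the reference map),
#' distance-to-agreement in mm, and a low-signal threshold below which
#' reference pixels are not evaluated.
#'
#' @param dose_tol Dose-difference tolerance, % of the normalization value.
#' @param dta Distance to agreement, mm.
#' @param low_threshold Evaluation threshold, % of the normalization value.
#' @param normalization `"global"` (max of the reference map) or `"local"`
#'   (per-pixel reference value).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 3, dta = 2, low_threshold = 10,
                           normalization = c("global", "local")) {
  normalization <- match.arg(normalization)
  if (dose_tol <= 0 || dta <= 0 || low_threshold <= 0) {
    stop("all gamma criteria must be > 0")
  }
  structure(list(dose_tol = dose_tol, dta = dta,
                 low_threshold = low_threshold,
                 normalization = normalization),
            class = "gamma_criteria")
}

#' Global gamma comparison of two maps
#'
#' For each reference pixel at or above the low-signal threshold, the gamma
#' index is the minimum over nearby evaluated positions of
#' `sqrt((dr/dta)^2 + (dD/(tol*norm))^2)`, searched on a disk of radius
#' `search_radius` (default 3 x dta) with sub-pixel bilinear sampling at
#' `step` mm spacing. Boundary pixels use only in-map samples. A pixel with
#' `gamma <= 1` agrees with the reference within the criteria.
#'
#' @param reference,evaluated [fluence_map()]s (or any objects with `values`
#'   and `pixel_pitch`) on the same pitch.
#' @param criteria A [gamma_criteria()].
#' @param search_radius Search radius, mm; `NULL` gives `3 * dta`.
#' @param step Sub-sampling step, mm.
#' @return A `gamma_map`: list with the `values` matrix (NA below threshold),
#'   logical `evaluated` mask, `passing_rate` (%) and the criteria.
#' @export
global_gamma <- function(reference, evaluated, criteria = gamma_criteria(),
                         search_radius = NULL, step = 0.2) {
  if (!isTRUE(all.equal(reference$pixel_pitch, evaluated$pixel_pitch))) {
    stop(sprintf("pixel pitch mismatch: %g vs %g mm", reference$pixel_pitch,
                 evaluated$pixel_pitch))
  }
  if (!identical(dim(reference$values), dim(evaluated$values))) {
    stop("reference and evaluated maps must share a grid")
  }
  search_radius <- search_radius %||% (3 * criteria$dta)
  norm_val <- max(reference$values)
  g <- cpp_gamma(reference$values, evaluated$values, reference$pixel_pitch,
                 criteria$dose_tol / 100, criteria$dta,
                 criteria$low_threshold / 100, norm_val, search_radius, step,
                 criteria$normalization == "local")
  mask <- !is.na(g)
  structure(list(values = g, evaluated = mask,
                 passing_rate = 100 * sum(g[mask] <= 1) / sum(mask),
                 criteria = criteria),
            class = "gamma_map")
}

#' @export
print.gamma_map <- function(x, ...) {
  cat(sprintf(
    "<gamma_map> %d evaluated pixels, passing rate %.2f%% (%g%%/%g mm, %g%% threshold)\n",
    sum(x$evaluated), x$passing_rate, x$criteria$dose_tol, x$criteria$dta,
    x$criteria$low_threshold))
  invisible(x)
}

#' Gamma passing rate
#'
#' Percentage of evaluated pixels with `gamma <= 1` (the boundary case counts
#' as a pass).
#'
#' @param gamma_map A `gamma_map` from [global_gamma()].
#' @return Passing rate in percent.
#' @export
passing_rate <- function(gamma_map) {
  if (sum(gamma_map$evaluated) == 0) {
    stop("all pixels below threshold: empty evaluated mask")
  }
  100 * sum(gamma_map$values[gamma_map$evaluated] <= 1) /
    sum(gamma_map$evaluated)
}
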