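#' End-to-end workflow configuration
#'
#' Bundles every stage configuration for the simulate - preprocess -
#' reconstruct - register - invert - dose chain. The default is the
#' desk-scale study: a 128 x 128 x 40 planning grid at 2 x 2 x 3 mm voxels, a
#' thorax phantom scaled so the whole body fits the 64 x 64 x 32 local
#' reconstruction volume, a 320 x 320 simulation panel at 1.344 mm pitch, the
#' five reference couch shifts and noiseless acquisition for the shift study.
#' All component-level constructors keep their own full-scale defaults; this
#' config exists so a complete experiment runs in minutes on one CPU.
#'
#' @param geometry An [acquisition_geometry()] (defaults to a 320 x 320 panel
#'   at 1.344 mm, full-scale source geometry).
#' @param phantom_grid,phantom_voxel Simulation/planning grid.
#' @param phantom_spec Insert list (defaults to the thorax layout scaled by
#'   `phantom_scale`).
#' @param phantom_scale Scale factor for [default_thorax_spec()].
#' @param recon A [reconstruction_config()].
#' @param search_radius Registration search radius, voxels per axis.
#' @param bins Histogram bins for the MI search.
#' @param shifts Tibble of couch shifts (columns `sx_mm`, `sy_mm`, `sz_mm`);
#'   defaults to [table1_shifts()].
#' @param attenuation An [attenuation_model()].
#' @param pencil_beam A [pencil_beam_model()].
#' @param I0_level Open-field grayscale level.
#' @param fluence_peak Peak reference fluence for the inversion study,
#'   grayscale-equivalent units.
#' @param noise `"off"` or `"poisson"` for the shift study acquisitions.
#' @param fluence_noise Noise mode for the inversion study (default Poisson:
#'   the gamma criterion is meant to absorb measurement noise).
#' @param n_fields Number of synthetic IMRT-like fields.
#' @param mu_water Water attenuation used for grayscale conversions, 1/mm.
#' @param seed Integer seed fixing all stochastic stages.
#' @param out_dir Optional directory for intermediate artifacts and reports.
#' @return An object of class `workflow_config`.
#' @export
workflow_config <- function(geometry = NULL,
                            phantom_grid = c(128, 128, 40),
                            phantom_voxel = c(2, 2, 3),
                            phantom_spec = NULL, phantom_scale = 0.35,
                            recon = NULL, search_radius = c(8, 8, 2),
                            bins = 64, shifts = table1_shifts(),
                            attenuation = attenuation_model(),
                            pencil_beam = pencil_beam_model(),
                            I0_level = 1e4, fluence_peak = 3e4,
                            noise = "off", fluence_noise = "poisson",
                            n_fields = 3, mu_water = 0.005, seed = 1,
                            out_dir = NULL) {
  geometry <- geometry %||% acquisition_geometry(
    detector_rows = 320L, detector_cols = 320L, detector_pitch = 1.344)
  phantom_spec <- phantom_spec %||% default_thorax_spec(scale = phantom_scale)
  recon <- recon %||% reconstruction_config(grid_shape = c(64, 64, 32))
  structure(list(geometry = geometry, phantom_grid = as.integer(phantom_grid),
                 phantom_voxel = as.numeric(phantom_voxel),
                 phantom_spec = phantom_spec, recon = recon,
                 search_radius = search_radius, bins = bins, shifts = shifts,
                 attenuation = attenuation, pencil_beam = pencil_beam,
                 I0_level = I0_level, fluence_peak = fluence_peak,
                 noise = noise, fluence_noise = fluence_noise,
                 n_fields = n_fields, mu_water = mu_water,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "workflow_config")
}

workflow_phantom <- function(config) {
  build_thorax_phantom(config$phantom_grid, config$phantom_voxel,
                       config$phantom_spec)
}

#' Simulate, preprocess and reconstruct one MVCT
#'
#' Runs the acquisition half of the chain for one couch shift: EPID
#' open/transmission pairs at every gantry angle, the projection preprocessing
#' chain, and the ART-TV reconstruction.
#'
#' @param config A [workflow_config()].
#' @param shift A [couch_shift()] (mm).
#' @param seed Seed for the Poisson stage (only used when the config asks for
#'   noise).
#' @return A list with `recon` (output of [reconstruct()]) and `projections`.
#' @export
acquire_mvct <- function(config, shift = couch_shift(0, 0, 0), seed = NULL) {
  phantom <- workflow_phantom(config)
  moved <- shift_volume(phantom, shift)
  projections <- lapply(seq_along(config$geometry$gantry_angles), function(i) {
    ang <- config$geometry$gantry_angles[i]
    pair <- simulate_epid_pair(config$geometry, ang, moved,
                               I0_level = config$I0_level,
                               noise = config$noise,
                               seed = if (!is.null(seed)) seed + i)
    preprocess_chain(pair$open, pair$transmission)
  })
  list(recon = reconstruct(projections, config$geometry, config$recon),
       projections = projections)
}

#' Run the couch-shift recovery experiment
#'
#' For each configured shift: simulate the ten-view EPID acquisition of the
#' shifted phantom, preprocess, reconstruct the local MVCT, and register it
#' against the (unshifted) synthetic planning CT. A failed stage aborts that
#' row (its reason is recorded in `status`); other rows continue.
#'
#' @param config A [workflow_config()].
#' @return A tibble with one row per shift: the matched window center, the
#'   registration-derived positioning error `t`, the gold-standard shift, the
#'   per-axis registration error, the MI value and a `status` column.
#' @export
run_shift_experiment <- function(config = workflow_config()) {
  phantom <- workflow_phantom(config)
  planning_ct <- attenuation_to_ct(phantom, config$mu_water)
  rows <- lapply(seq_len(nrow(config$shifts)), function(g) {
    sh <- config$shifts[g, ]
    res <- tryCatch({
      shift <- couch_shift(sh$sx_mm, sh$sy_mm, sh$sz_mm)
      acq <- acquire_mvct(config, shift, seed = config$seed + 1000L * g)
      reg <- sliding_search(acq$recon$volume, planning_ct,
                            search_radius = config$search_radius,
                            bins = config$bins,
                            mask = acq$recon$support > 0)
      maybe_write_artifacts(config, g, acq, reg)
      tibble::tibble(
        group = sh$group %||% g,
        matched_cx = reg$matched_center[1], matched_cy = reg$matched_center[2],
        matched_cz = reg$matched_center[3],
        tx_mm = reg$shift_mm[["tx"]], ty_mm = reg$shift_mm[["ty"]],
        tz_mm = reg$shift_mm[["tz"]],
        gold_sx_mm = sh$sx_mm, gold_sy_mm = sh$sy_mm, gold_sz_mm = sh$sz_mm,
        err_x_mm = reg$shift_mm[["tx"]] - sh$sx_mm,
        err_y_mm = reg$shift_mm[["ty"]] - sh$sy_mm,
        err_z_mm = reg$shift_mm[["tz"]] - sh$sz_mm,
        mi_bits = reg$mi_value, status = "ok")
    }, error = function(e) {
      message("shift group ", g, " failed: ", conditionMessage(e))
      tibble::tibble(group = sh$group %||% g, matched_cx = NA_real_,
                     matched_cy = NA_real_, matched_cz = NA_real_,
                     tx_mm = NA_real_, ty_mm = NA_real_, tz_mm = NA_real_,
                     gold_sx_mm = sh$sx_mm, gold_sy_mm = sh$sy_mm,
                     gold_sz_mm = sh$sz_mm, err_x_mm = NA_real_,
                     err_y_mm = NA_real_, err_z_mm = NA_real_,
                     mi_bits = NA_real_, status = conditionMessage(e))
    })
    res
  })
  report <- if (length(rows) == 0) {
    tibble::tibble(group = integer(0), matched_cx = numeric(0),
                   matched_cy = numeric(0), matched_cz = numeric(0),
                   tx_mm = numeric(0), ty_mm = numeric(0), tz_mm = numeric(0),
                   gold_sx_mm = numeric(0), gold_sy_mm = numeric(0),
                   gold_sz_mm = numeric(0), err_x_mm = numeric(0),
                   err_y_mm = numeric(0), err_z_mm = numeric(0),
                   mi_bits = numeric(0), status = character(0))
  } else {
    do.call(rbind, rows)
  }
  if (!is.null(config$out_dir)) {
    write_report(report, file.path(config$out_dir, "shift_experiment"))
  }
  report
}

#' Synthetic IMRT-like field specifications
#'
#' Each field is a sum of 2-5 apertures, randomly rectangular or Gaussian,
#' with random in-field positions, sizes and weights. Fixing the seed fixes
#' the library.
#'
#' @param n_fields Number of fields.
#' @param field_size Field extent, mm (apertures are kept inside).
#' @param seed Integer seed.
#' @return A list of field specifications.
#' @export
imrt_field_specs <- function(n_fields = 3, field_size = 200, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_fields), function(i) {
    n_ap <- sample(2:5, 1)
    apertures <- lapply(seq_len(n_ap), function(j) {
      type <- sample(c("rect", "gauss"), 1)
      center <- stats::runif(2, -field_size / 4, field_size / 4)
      if (type == "rect") {
        list(type = "rect", center = center,
             size = stats::runif(2, 30, field_size / 2),
             weight = stats::runif(1, 0.4, 1))
      } else {
        list(type = "gauss", center = center,
             sigma = stats::runif(1, 10, 40),
             weight = stats::runif(1, 0.4, 1))
      }
    })
    list(id = i, apertures = apertures)
  })
}

#' Rasterize a field specification into a fluence map
#'
#' @param spec One element of [imrt_field_specs()].
#' @param n Grid side, pixels.
#' @param pitch Pixel pitch at the reference plane, mm.
#' @param d Reference-plane distance from the source, mm.
#' @param peak Peak fluence value after scaling.
#' @return A [fluence_map()].
#' @export
build_imrt_fluence <- function(spec, n = 100, pitch = 2, d = 1000,
                               peak = 3e4) {
  u <- (seq_len(n) - (n + 1) / 2) * pitch
  v <- u
  vals <- matrix(0, n, n)
  for (ap in spec$apertures) {
    if (ap$type == "rect") {
      m <- outer(abs(v - ap$center[2]) <= ap$size[2] / 2,
                 abs(u - ap$center[1]) <= ap$size[1] / 2, "&")
      vals <- vals + ap$weight * m
    } else {
      r2 <- outer((v - ap$center[2])^2, (u - ap$center[1])^2, "+")
      vals <- vals + ap$weight * exp(-r2 / (2 * ap$sigma^2))
    }
  }
  if (max(vals) > 0) vals <- vals / max(vals) * peak
  fluence_map(vals, pitch, d)
}

#' Run the fluence-inversion gamma experiment
#'
#' For each synthetic field: forward-model the EPID transmission image of the
#' reference fluence through the thorax phantom (inverse-square, softening /
#' hardening attenuation, optional Poisson noise), invert it back to primary
#' fluence, and compute the global gamma passing rate against the reference.
#'
#' @param config A [workflow_config()].
#' @param criteria A [gamma_criteria()].
#' @return A tibble with one row per field: `field`, `passing_rate`,
#'   `mean_gamma`, `n_evaluated`, `status`.
#' @export
run_fluence_experiment <- function(config = workflow_config(),
                                   criteria = gamma_criteria()) {
  phantom <- workflow_phantom(config)
  geometry <- config$geometry
  d <- geometry$SAD
  n <- 100
  pitch_iso <- geometry$field_size[1] / n
  pitch_det <- pitch_iso * magnification(geometry)
  specs <- imrt_field_specs(config$n_fields,
                            field_size = geometry$field_size[1],
                            seed = config$seed)
  rows <- lapply(specs, function(spec) {
    res <- tryCatch({
      ref <- build_imrt_fluence(spec, n = n, pitch = pitch_iso, d = d,
                                peak = config$fluence_peak)
      th <- compute_equivalent_thickness(phantom, geometry, angle = 0,
                                         plane_d = d,
                                         mu_water = config$mu_water,
                                         nrow = n, ncol = n,
                                         pitch = pitch_det)
      epid <- epid_from_fluence(ref, th, config$attenuation, geometry,
                                noise = config$fluence_noise,
                                seed = config$seed + 7000L + spec$id)
      inv <- invert_primary_fluence(epid, th, config$attenuation, geometry,
                                    d = d)
      g <- global_gamma(ref, inv, criteria)
      tibble::tibble(field = spec$id, passing_rate = passing_rate(g),
                     mean_gamma = mean(g$values[g$evaluated]),
                     n_evaluated = sum(g$evaluated), status = "ok")
    }, error = function(e) {
      message("field ", spec$id, " failed: ", conditionMessage(e))
      tibble::tibble(field = spec$id, passing_rate = NA_real_,
                     mean_gamma = NA_real_, n_evaluated = NA_integer_,
                     status = conditionMessage(e))
    })
    res
  })
  report <- do.call(rbind, rows)
  if (!is.null(config$out_dir)) {
    write_report(report, file.path(config$out_dir, "fluence_experiment"))
  }
  report
}

#' Imaging plus treatment dose accumulation for one session
#'
#' Computes the dose of the ten 1 MU imaging fields (one per gantry angle,
#' open-field fluence through the phantom) and one treatment field of
#' `treatment_mu` MU on the registration-corrected planning CT frame, and
#' accumulates them.
#'
#' @param config A [workflow_config()].
#' @param registration Optional `registration_result` used to correct the
#'   planning CT before dose calculation.
#' @param treatment_mu Monitor units of the treatment field (imaging fields
#'   deliver 1 MU each).
#' @param depth_grid Depths (mm) of the dose planes.
#' @return A list with `total` (a `dose_grid` with `imaging_fraction`
#'   attribute), `imaging` and `treatment` field lists and the corrected CT.
#' @export
run_dose_accumulation <- function(config = workflow_config(),
                                  registration = NULL, treatment_mu = 100,
                                  depth_grid = seq(50, 250, by = 10)) {
  phantom <- workflow_phantom(config)
  planning_ct <- attenuation_to_ct(phantom, config$mu_water)
  corrected <- if (!is.null(registration)) {
    apply_registration_correction(planning_ct, registration)
  } else {
    planning_ct
  }
  geometry <- config$geometry
  n <- 50
  pitch_iso <- geometry$field_size[1] / n
  imaging <- lapply(geometry$gantry_angles, function(ang) {
    flu <- fluence_map(matrix(1, n, n), pitch_iso, geometry$SAD)
    pencil_beam_dose(flu, config$pencil_beam, depth_grid)
  })
  treat_flu <- fluence_map(matrix(treatment_mu, n, n), pitch_iso,
                           geometry$SAD)
  treatment <- list(pencil_beam_dose(treat_flu, config$pencil_beam,
                                     depth_grid))
  list(total = accumulate_total_dose(imaging, treatment), imaging = imaging,
       treatment = treatment, corrected_ct = corrected)
}

maybe_write_artifacts <- function(config, group, acq, reg) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir, sprintf("group%02d", group))
  write_volume(acq$recon$volume, paste0(base, "_mvct.nii.gz"),
               extra = list(stage = "reconstruct",
                            iterations = nrow(acq$recon$trace)))
  jsonlite::write_json(
    list(stage = "register",
         matched_center = reg$matched_center,
         shift_mm = unname(signif(reg$shift_mm, 9)),
         mi_bits = signif(reg$mi_value, 9)),
    paste0(base, "_registration.json"), auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
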