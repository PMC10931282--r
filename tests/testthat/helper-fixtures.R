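# Shared fixtures: small geometries and phantoms sized so unit tests run in
# seconds. All randomness is seeded inside each test.

# a thorax-like layout that fits a 32 x 32 x 8 grid at 4 x 4 x 6 mm voxels
tiny_thorax_spec <- function() {
  list(
    phantom_insert("ellipsoid", c(0, 0, 0), semiaxes = c(50, 40, 20),
                   mu = 0.005, name = "body"),
    phantom_insert("ellipsoid", c(-20, 0, 0), semiaxes = c(15, 18, 12),
                   mu = 0.0012, name = "lung"),
    phantom_insert("sphere", c(15, 10, 0), radius = 8, mu = 0.008,
                   name = "bone")
  )
}

tiny_phantom <- function() {
  build_thorax_phantom(c(32, 32, 8), c(4, 4, 6), tiny_thorax_spec())
}

tiny_geometry <- function(...) {
  acquisition_geometry(detector_rows = 24L, detector_cols = 24L,
                       detector_pitch = 14, ...)
}

# noiseless projections of the tiny phantom at the reconstruction's own ray
# sampling (consistent system, no preprocessing)
tiny_projections <- function(geometry = tiny_geometry(),
                             phantom = tiny_phantom(), nrow = 24, ncol = 24,
                             pitch = 14) {
  lapply(geometry$gantry_angles, function(a) {
    projection_image(forward_project(phantom, geometry, a, nrow = nrow,
                                     ncol = ncol, pitch = pitch), pitch, a)
  })
}

tiny_recon_config <- function(...) {
  reconstruction_config(grid_shape = c(32, 32, 8), voxel_size = c(4, 4, 6),
                        ...)
}

# a smooth, strictly positive random volume for registration tests
smooth_volume <- function(dims = c(40, 40, 20), voxel = c(2, 2, 3),
                          seed = 42) {
  set.seed(seed)
  raw <- array(stats::rnorm(prod(dims)), dims)
  sm <- raw
  for (pass in 1:3) {
    sm <- (sm +
             sm[c(1, seq_len(dims[1] - 1)), , ] +
             sm[c(seq_len(dims[1] - 1) + 1, dims[1]), , ] +
             sm[, c(1, seq_len(dims[2] - 1)), ] +
             sm[, c(seq_len(dims[2] - 1) + 1, dims[2]), ] +
             sm[, , c(1, seq_len(dims[3] - 1))] +
             sm[, , c(seq_len(dims[3] - 1) + 1, dims[3])]) / 7
  }
  volume_image(sm - min(sm) + 0.1, voxel, modality = "planning-CT")
}

# fast workflow config for unit tests (coarser grids than the desk study)
fast_workflow_config <- function(...) {
  workflow_config(
    geometry = acquisition_geometry(detector_rows = 160L,
                                    detector_cols = 160L,
                                    detector_pitch = 2.688),
    phantom_grid = c(64, 64, 20), phantom_voxel = c(4, 4, 6),
    phantom_spec = default_thorax_spec(scale = 0.35),
    recon = reconstruction_config(max_iterations = 8,
                                  grid_shape = c(32, 32, 16),
                                  voxel_size = c(4, 4, 6)),
    search_radius = c(4, 4, 1), ...
  )
}
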