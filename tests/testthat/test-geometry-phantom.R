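test_that("phantom painting is piecewise constant, ordered and deterministic", {
  spec <- list(phantom_insert("ellipsoid", c(0, 0, 0),
                              semiaxes = c(40, 30, 20), mu = 0.005,
                              name = "water"))
  vol <- build_thorax_phantom(c(32, 32, 10), c(4, 4, 6), spec)
  # interior voxel centers are exactly mu, exterior exactly 0
  xs <- vol$origin[1] + (1:32 - 0.5) * 4
  ys <- vol$origin[2] + (1:32 - 0.5) * 4
  zs <- vol$origin[3] + (1:10 - 0.5) * 6
  inside <- outer(outer((xs / 40)^2, (ys / 30)^2, "+"), (zs / 20)^2, "+") <= 1
  expect_true(all(vol$values[inside] == 0.005))
  expect_true(all(vol$values[!inside] == 0))

  thorax <- tiny_phantom()
  mu <- thorax$values
  expect_true(0.0012 < 0.005 && 0.005 < 0.008)  # lung < body < bone in spec
  expect_setequal(unique(as.numeric(mu)), c(0, 0.0012, 0.005, 0.008))
  expect_identical(thorax$values, tiny_phantom()$values)
})

test_that("inserts outside the grid are rejected by name", {
  spec <- list(phantom_insert("sphere", c(100, 0, 0), radius = 50, mu = 0.01,
                              name = "stray lesion"))
  expect_error(build_thorax_phantom(c(16, 16, 8), c(4, 4, 6), spec),
               "stray lesion")
})

test_that("ray tracing gives exact lengths on axis-aligned and oblique rays", {
  geo <- acquisition_geometry(detector_rows = 11L, detector_cols = 11L,
                              detector_pitch = 2)
  vol <- volume_image(array(0.01, c(20, 20, 20)), c(5, 5, 5))  # 100 mm cube
  central <- trace_ray(geo, 0, c(6, 6), vol)
  expect_equal(sum(central$length), 100, tolerance = 1e-8)
  expect_equal(central$raysum, 1.0, tolerance = 1e-8)

  # corner-clipping oblique ray vs a dense-sampling line integral
  set.seed(7)
  vol$values[] <- stats::runif(length(vol$values))
  ray <- trace_ray(geo, 33, c(2, 11), vol)
  ends <- epidmvct:::ray_endpoints_r(geo, 33,
                                     (11 - 6) * 2,  # u of col 11
                                     (2 - 6) * 2)   # v of row 2
  n_s <- 1e5
  ts <- (seq_len(n_s) - 0.5) / n_s
  pts <- outer(ts, ends$p1 - ends$p0) +
    matrix(ends$p0, n_s, 3, byrow = TRUE)
  seg <- sqrt(sum((ends$p1 - ends$p0)^2)) / n_s
  idx <- floor(sweep(sweep(pts, 2, vol$origin), 2, vol$voxel_size, "/")) + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= 20 & idx[, 2] >= 1 & idx[, 2] <= 20 &
    idx[, 3] >= 1 & idx[, 3] <= 20
  dense_chord <- sum(ok) * seg
  dense_raysum <- sum(vol$values[idx[ok, , drop = FALSE]]) * seg
  expect_gt(length(ray$index), 0)
  expect_equal(sum(ray$length), dense_chord, tolerance = 1e-3)
  expect_equal(ray$raysum, dense_raysum, tolerance = 1e-3)

  # ray aimed far off-axis misses the volume entirely
  far <- volume_image(array(1, c(4, 4, 4)), c(2, 2, 2),
                      origin = c(400, 400, 400))
  miss <- trace_ray(geo, 0, c(6, 6), far)
  expect_length(miss$index, 0)
  expect_equal(miss$raysum, 0)
})

test_that("ray sums are linear in the volume", {
  geo <- tiny_geometry()
  set.seed(11)
  a <- volume_image(array(stats::runif(32 * 32 * 8, 0, 0.01), c(32, 32, 8)),
                    c(4, 4, 6))
  b <- volume_image(array(stats::runif(32 * 32 * 8, 0, 0.01), c(32, 32, 8)),
                    c(4, 4, 6))
  ab <- volume_image(a$values + b$values, c(4, 4, 6))
  for (ang in c(0, 45, 117)) {
    pa <- forward_project(a, geo, ang)
    pb <- forward_project(b, geo, ang)
    pab <- forward_project(ab, geo, ang)
    expect_lt(max(abs(pab - (pa + pb))), 1e-9)
  }
})

test_that("translating the phantom equals counter-translating the geometry", {
  geo <- tiny_geometry()
  ph <- tiny_phantom()
  delta <- c(8, -4, 6)  # integer multiples of the voxel size
  moved <- shift_volume(ph, delta)
  # translating the sampling grid by delta == moving the volume's origin
  counter <- volume_image(ph$values, ph$voxel_size,
                          origin = ph$origin + delta)
  for (ang in c(0, 72)) {
    p1 <- forward_project(moved, geo, ang)
    p2 <- forward_project(counter, geo, ang)
    expect_lt(max(abs(p1 - p2)), 1e-6)
  }
})

test_that("a point insert at the isocenter plane magnifies by SID/SAD", {
  geo <- acquisition_geometry()
  vol <- volume_image(array(0, c(64, 64, 8)), c(2, 2, 5))
  offset_mm <- 19  # voxel center at x = +19 mm, y = z = 0
  vol$values[32 + 10, 32, 4:5] <- 1
  pr <- forward_project(vol, geo, 0, nrow = 3, ncol = 201, pitch = 1)
  profile <- pr[2, ]
  u <- (seq_len(201) - 101)  # mm, pitch 1
  centroid <- sum(u * profile) / sum(profile)
  expect_equal(centroid, offset_mm * magnification(geo), tolerance = 1)
  expect_equal(magnification(geo), 1.54)
})

test_that("EPID simulation follows Beer-Lambert and detector symmetry", {
  geo <- tiny_geometry()
  empty <- volume_image(array(0, c(16, 16, 8)), c(8, 8, 6))
  pair <- simulate_epid_pair(geo, 0, empty)
  expect_identical(pair$open$values, pair$transmission$values)

  # uniform slab: 16 voxels * 6.25 mm = 100 mm thick along y
  godd <- acquisition_geometry(detector_rows = 25L, detector_cols = 25L,
                               detector_pitch = 14)
  slab <- volume_image(array(0.007, c(40, 16, 12)), c(10, 6.25, 20))
  pair <- simulate_epid_pair(godd, 0, slab, I0_level = 1000)
  r0 <- 13L  # odd grid: central pixel exactly on the beam axis
  expect_equal(pair$transmission$values[r0, r0] / pair$open$values[r0, r0],
               exp(-0.007 * 100), tolerance = 1e-9)

  # left-right symmetric phantom at gantry 0 -> symmetric transmission
  sym <- tiny_phantom()
  sym$values <- (sym$values + sym$values[32:1, , ]) / 2
  tr <- simulate_epid_pair(geo, 0, sym)$transmission$values
  expect_lt(max(abs(tr - tr[, ncol(tr):1])), 1e-9)
})

test_that("Poisson noise is unbiased around the noiseless image", {
  geo <- acquisition_geometry(detector_rows = 100L, detector_cols = 100L,
                              detector_pitch = 4, field_size = 450)
  empty <- volume_image(array(0, c(8, 8, 8)), c(4, 4, 4))
  noisy <- simulate_epid_pair(geo, 0, empty, I0_level = 800,
                              noise = "poisson", seed = 99)
  # every in-field open pixel is an iid Poisson(800) replicate
  m <- 800
  reps <- as.numeric(noisy$open$values)[seq_len(1e4)]
  se <- sqrt(m / 1e4)
  expect_lt(abs(mean(reps) - m), 3 * se)
})

test_that("degenerate geometry and inputs are rejected", {
  expect_error(acquisition_geometry(SAD = 1600), "SID > SAD")
  expect_error(acquisition_geometry(gantry_angles = c(0, 370)), "360")
  expect_error(simulate_epid_pair(tiny_geometry(), 0, tiny_phantom(),
                                  I0_level = 0), "I0_level")
})
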