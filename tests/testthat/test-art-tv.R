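test_that("the Kaczmarz ray update is the hyperplane projection", {
  # hand case: w = (1,1), p = 2, x = (0,0), lambda = 1 -> x = (1,1)
  ray <- list(index = c(1L, 2L), length = c(1, 1))
  x <- c(0, 0)
  x1 <- art_update_ray(x, ray, p_i = 2, lambda = 1)
  expect_equal(x1, c(1, 1))
  # projection characterization: the constraint holds and the step is
  # parallel to w (orthogonal to the hyperplane)
  expect_equal(sum(x1 * ray$length), 2)
  step <- x1 - x
  expect_equal(step / sqrt(sum(step^2)),
               ray$length / sqrt(sum(ray$length^2)))

  # zero residual: no change
  x2 <- art_update_ray(x1, ray, p_i = 2, lambda = 1)
  expect_identical(x2, x1)

  # empty and degenerate rays are no-ops
  expect_identical(art_update_ray(x1, list(index = integer(0),
                                           length = numeric(0)), 5, 1), x1)
  expect_identical(art_update_ray(x1, list(index = 1L, length = 0), 5, 1), x1)
})

test_that("non-negativity projection clamps and is idempotent", {
  expect_identical(nonneg_project(c(2, 3)), c(2, 3))
  expect_identical(nonneg_project(c(-1, 2)), c(0, 2))
  x <- c(-3, 0, 7)
  expect_identical(nonneg_project(nonneg_project(x)), nonneg_project(x))
})

test_that("tv_norm matches a literal double-loop evaluation", {
  m <- matrix(c(0, 0, 0, 1), 2, 2)
  expect_equal(tv_norm(m), sqrt(2))

  brute_tv <- function(x) {
    s <- 0
    for (i in 2:nrow(x)) {
      for (j in 2:ncol(x)) {
        s <- s + sqrt((x[i, j] - x[i - 1, j])^2 + (x[i, j] - x[i, j - 1])^2)
      }
    }
    s
  }
  set.seed(5)
  r <- matrix(stats::rnorm(48), 6, 8)
  expect_equal(tv_norm(r), brute_tv(r), tolerance = 1e-12)
  # positive homogeneity
  expect_equal(tv_norm(-2.5 * r), 2.5 * tv_norm(r), tolerance = 1e-12)
  # constant image has zero TV
  expect_equal(tv_norm(matrix(4, 5, 5)), 0)
})

test_that("tv_gradient matches numerical differentiation of the smoothed TV", {
  eps <- 1e-8
  set.seed(6)
  x <- matrix(stats::rnorm(64), 8, 8)
  g <- tv_gradient(x, eps)
  h <- 1e-6
  num <- matrix(0, 8, 8)
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + h
    xm <- x; xm[k] <- xm[k] - h
    num[k] <- (tv_norm(xp, eps = eps) - tv_norm(xm, eps = eps)) / (2 * h)
  }
  expect_equal(g, num, tolerance = 1e-4)

  # constant image: zero gradient; gradient ignores additive constants
  expect_true(all(tv_gradient(matrix(3, 6, 6), eps) == 0))
  expect_equal(tv_gradient(x + 11.5, eps), g, tolerance = 1e-9)
})

test_that("pure ART converges to the direct linear-algebra solution", {
  # fully determined single-slice system, parallel beam, TV off, lambda = 1
  geo <- acquisition_geometry(SAD = 1000, SID = 1540,
                              gantry_angles = seq(0, 168.75, by = 11.25),
                              detector_rows = 1L, detector_cols = 10L,
                              detector_pitch = 5 * 1.54, beam = "parallel")
  vol <- volume_image(array(0, c(8, 8, 1)), c(4, 4, 60))
  set.seed(8)
  xs <- (1:8 - 4.5) * 4
  blob <- outer(exp(-(xs / 12)^2), exp(-(xs / 14)^2)) + 0.5
  x_true <- array(blob, c(8, 8, 1))
  truth <- volume_image(x_true, c(4, 4, 60))

  rays <- list()
  W <- NULL
  p <- c()
  for (ang in geo$gantry_angles) {
    for (col in 1:10) {
      ray <- trace_ray(geo, ang, c(1, col), truth)
      w <- numeric(64)
      w[ray$index] <- ray$length
      W <- rbind(W, w)
      p <- c(p, ray$raysum)
    }
  }
  expect_gte(qr(W)$rank, 64)  # every voxel determined

  direct <- qr.solve(qr(W), p)
  projs <- lapply(geo$gantry_angles, function(a) {
    projection_image(forward_project(truth, geo, a, nrow = 1, ncol = 10,
                                     pitch = 5 * 1.54), 5 * 1.54, a)
  })
  cfg <- reconstruction_config(max_iterations = 600, lambda = 1,
                               tv_weight = 0, stop_tol = 0,
                               grid_shape = c(8, 8, 1),
                               voxel_size = c(4, 4, 60))
  rec <- reconstruct(projs, geo, cfg)
  rel <- sqrt(sum((as.numeric(rec$volume$values) - direct)^2)) /
    sqrt(sum(direct^2))
  expect_lt(rel, 1e-3)
  expect_equal(direct, as.numeric(x_true), tolerance = 1e-6)
})

test_that("the C++ sweep reproduces the exported R ray update", {
  geo <- tiny_geometry(gantry_angles = c(0, 90))
  ph <- tiny_phantom()
  projs <- tiny_projections(geo, ph)
  cfg <- tiny_recon_config(max_iterations = 2, tv_weight = 0, stop_tol = 0)
  rec <- reconstruct(projs, geo, cfg)

  x <- array(0, c(32, 32, 8))
  vol0 <- volume_image(x, c(4, 4, 6))
  for (t in 1:2) {
    for (v in seq_along(projs)) {
      pm <- projs[[v]]$values
      for (r in seq_len(nrow(pm))) {
        for (cc in seq_len(ncol(pm))) {
          ray <- trace_ray(geo, projs[[v]]$gantry_angle, c(r, cc), vol0)
          x <- nonneg_project(art_update_ray(x, ray, pm[r, cc], cfg$lambda))
        }
      }
    }
  }
  expect_equal(as.numeric(rec$volume$values), as.numeric(x),
               tolerance = 1e-12)
})

test_that("reconstruction improves over iterations and stays non-negative", {
  geo <- tiny_geometry()
  ph <- tiny_phantom()
  projs <- tiny_projections(geo, ph)
  rec1 <- reconstruct(projs, geo, tiny_recon_config(max_iterations = 1))
  rec12 <- reconstruct(projs, geo, tiny_recon_config(max_iterations = 12))
  rmse <- function(v) sqrt(mean((v$values - ph$values)^2))
  expect_lt(rmse(rec12$volume), rmse(rec1$volume))
  expect_gte(min(rec12$volume$values), 0)
  expect_identical(nrow(rec12$trace), 12L)

  # fixed point: all-zero projections stay at the zero image
  zero <- lapply(projs, function(p) {
    p$values[] <- 0
    p
  })
  rec0 <- reconstruct(zero, geo, tiny_recon_config(max_iterations = 3))
  expect_true(all(rec0$volume$values == 0))

  # determinism: bit-identical repeat runs
  rec12b <- reconstruct(projs, geo, tiny_recon_config(max_iterations = 12))
  expect_identical(rec12$volume$values, rec12b$volume$values)
})

test_that("the literal per-ray algorithm settles within twelve iterations", {
  geo <- tiny_geometry()
  projs <- tiny_projections(geo)
  rec <- reconstruct(projs, geo,
                     tiny_recon_config(max_iterations = 12,
                                       tv_cadence = "per_ray"))
  expect_lt(rec$trace$rel_change[12], 0.01)
})

test_that("stronger TV regularization never raises the final TV norm", {
  geo <- tiny_geometry()
  ph <- tiny_phantom()
  for (seed in 1:3) {
    projs <- lapply(geo$gantry_angles, function(a) {
      pair <- simulate_epid_pair(geo, a, ph, I0_level = 5000,
                                 noise = "poisson", seed = seed * 100 + a)
      to_projection(pair$open, pair$transmission)
    })
    # mu = 0 -> 0.25 -> 1; far larger weights overshoot the adaptive step
    # and destabilize the sweep rather than smoothing further
    tv_at <- vapply(c(0, 0.25, 1), function(mu) {
      rec <- reconstruct(projs, geo,
                         tiny_recon_config(max_iterations = 6,
                                           tv_weight = mu))
      tv_norm(rec$volume$values)
    }, numeric(1))
    expect_true(all(diff(tv_at) <= 1e-9))
  }
})

test_that("reconstruction rejects geometry that misses the volume", {
  geo <- tiny_geometry()
  proj <- projection_image(matrix(1, 4, 4), 14, 0,
                           origin_uv = c(5e4, 5e4))
  expect_error(reconstruct(list(proj), geo, tiny_recon_config()),
               "geometry mismatch")
})

test_that("reconstruction defaults follow the study protocol", {
  cfg <- reconstruction_config()
  expect_identical(cfg$max_iterations, 12L)
  expect_equal(cfg$lambda, 0.1)
  expect_equal(cfg$tv_weight, 1)
  expect_identical(cfg$grid_shape, c(128L, 128L, 122L))
  expect_equal(cfg$voxel_size, c(2, 2, 3))
})
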