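test_that("equivalent thickness is the water-equivalent ray sum", {
  geo <- acquisition_geometry(detector_rows = 25L, detector_cols = 25L,
                              detector_pitch = 14)
  empty <- volume_image(array(0, c(8, 8, 8)), c(10, 10, 10))
  th <- compute_equivalent_thickness(empty, geo, 0, nrow = 9, ncol = 9,
                                     pitch = 10)
  expect_true(all(th$t == 0))
  expect_true(all(th$t_prime == 0))

  # 100 mm water slab (mu = mu_water) -> t = 100 mm on the central axis
  slab <- volume_image(array(0.005, c(40, 16, 12)), c(10, 6.25, 20))
  th <- compute_equivalent_thickness(slab, geo, 0, nrow = 25, ncol = 25,
                                     pitch = 14)
  expect_equal(th$t[13, 13], 100, tolerance = 1e-3)

  # calculation plane at the slab exit: everything lies upstream, t' = 0
  # (slab spans y in [-50, 50]; the beam at gantry 0 travels -y, so the exit
  # plane sits at distance SAD + 50 from the source)
  th2 <- compute_equivalent_thickness(slab, geo, 0,
                                      plane_d = geo$SAD + 50 + 1e-6,
                                      nrow = 25, ncol = 25, pitch = 14)
  expect_lt(max(abs(th2$t_prime)), 1e-6)

  # HU-like planning CT maps to relative water density
  hu <- attenuation_to_ct(slab)  # mu_water slab -> 0 HU -> density 1
  th3 <- compute_equivalent_thickness(hu, geo, 0, nrow = 25, ncol = 25,
                                      pitch = 14)
  expect_equal(th3$t, th$t, tolerance = 1e-12)

  expect_error(compute_equivalent_thickness(slab, geo, 0, plane_d = 2000),
               "beyond the EPID")
})

test_that("fluence inversion applies unit, inverse-square and attenuation factors", {
  geo <- acquisition_geometry(detector_rows = 16L, detector_cols = 16L,
                              detector_pitch = 20)
  set.seed(41)
  psi <- matrix(stats::runif(256, 10, 100), 16, 16)
  epid <- epid_image(psi, 20, 0)
  zero_t <- structure(list(t = matrix(0, 16, 16), t_prime = matrix(0, 16, 16),
                           pixel_pitch = 20, plane_d = geo$SID,
                           gantry_angle = 0), class = "equivalent_thickness")
  m0 <- attenuation_model(f = 1, a0 = 0)

  # a = 0, f = 1, d = SID: identity
  out <- invert_primary_fluence(epid, zero_t, m0, geo, d = geo$SID)
  expect_equal(out$values, psi, tolerance = 1e-12)

  # d = SID / 2: inverse square quadruples the fluence
  zero_t$plane_d <- geo$SID / 2
  out2 <- invert_primary_fluence(epid, zero_t, m0, geo, d = geo$SID / 2)
  expect_equal(out2$values, 4 * psi, tolerance = 1e-12)
  expect_equal(out2$pixel_pitch, 20 / 2)

  # inverse-square law across a range of planes
  vals_at <- vapply(c(geo$SID, geo$SID / 2, geo$SID / 4), function(d) {
    zt <- zero_t
    zt$plane_d <- d
    invert_primary_fluence(epid, zt, m0, geo, d = d)$values[8, 8]
  }, numeric(1))
  expect_equal(vals_at / vals_at[1], (geo$SID / c(geo$SID, geo$SID / 2,
                                                  geo$SID / 4))^2,
               tolerance = 1e-12)
})

test_that("the inversion is the exact algebraic inverse of the forward model", {
  geo <- acquisition_geometry(detector_rows = 20L, detector_cols = 20L,
                              detector_pitch = 15)
  set.seed(42)
  d <- geo$SAD
  psi_true <- fluence_map(matrix(stats::runif(400, 50, 500), 20, 20),
                          15 * d / geo$SID, d)
  th <- structure(list(t = matrix(stats::runif(400, 50, 250), 20, 20),
                       t_prime = matrix(stats::runif(400, 0, 150), 20, 20),
                       pixel_pitch = 15, plane_d = d, gantry_angle = 0),
                  class = "equivalent_thickness")
  model <- attenuation_model(f = 1.7, a0 = 0.004, a2 = 0.002, b0 = 0.001)
  epid <- epid_from_fluence(psi_true, th, model, geo)
  back <- invert_primary_fluence(epid, th, model, geo, d = d)
  expect_equal(back$values, psi_true$values, tolerance = 1e-9)

  # a hardening denominator crossing zero is rejected, not propagated
  bad <- attenuation_model(f = 1, a0 = 0.005, b0 = -0.02)
  expect_error(invert_primary_fluence(epid, th, bad, geo, d = d),
               "attenuation model invalid")
})

test_that("grayscale-to-fluence calibration is an unbiased least-squares scalar", {
  set.seed(43)
  open <- epid_image(matrix(stats::runif(400, 100, 1000), 20, 20), 10, 0)
  known <- fluence_map(2 * open$values, 10, 1000)
  cal <- calibrate_conversion(open, known)
  expect_equal(cal$f, 2)
  expect_equal(cal$residual, 0)

  fs <- vapply(1:20, function(s) {
    set.seed(500 + s)
    noisy <- fluence_map(pmax(open$values +
                                stats::rnorm(400, sd = 30), 0), 10, 1000)
    calibrate_conversion(open, noisy)$f
  }, numeric(1))
  expect_lt(abs(mean(fs) - 1), 3 * stats::sd(fs) / sqrt(20))

  expect_error(calibrate_conversion(epid_image(matrix(0, 4, 4), 1, 0),
                                    fluence_map(matrix(1, 4, 4), 1, 1000)),
               "zero")
  neg <- structure(list(values = matrix(-1, 20, 20)), class = "fluence_map")
  expect_error(calibrate_conversion(open, neg), "non-negative")
})

test_that("the scatter-correction hook subtracts the stated kernel", {
  img <- epid_image(matrix(c(rep(0, 84), 100, rep(0, 84)), 13, 13), 1, 0)
  expect_identical(scatter_correct(img, "none"), img)
  expect_identical(scatter_correct(img, "gaussian", amplitude = 0), img)

  width <- 5
  out <- scatter_correct(img, "gaussian", amplitude = 0.1, width_px = width)
  # the delta's center loses amplitude * kernel self-contribution
  g <- stats::dnorm(seq(-15, 15), sd = width)
  k0 <- (g[16]^2) / sum(outer(g, g))
  expect_equal(out$values[7, 7], 100 - 0.1 * 100 * k0, tolerance = 1e-9)

  expect_error(scatter_correct(img, "gaussian", amplitude = 50), "negative")
})
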