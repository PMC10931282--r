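test_that("Shannon entropy of binned intensities is correct in bits", {
  expect_equal(shannon_entropy(rep(7, 100), bins = 8), 0)
  expect_equal(shannon_entropy(rep(1:4, each = 25), bins = 4), 2)
  # counts (50, 25, 25): H = 0.5*1 + 2*0.25*2 = 1.5 bits
  expect_equal(shannon_entropy(rep(c(0.1, 0.5, 0.9), c(50, 25, 25)),
                               bins = 3), 1.5)
  expect_error(shannon_entropy(numeric(0)), "sample")
})

test_that("mutual information matches a brute-force joint histogram", {
  set.seed(31)
  a <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
  b <- matrix(sample(0:3, 16, replace = TRUE), 4, 4)
  bins <- 4

  # independent tabulation and direct evaluation of the entropy sums
  pj <- matrix(0, bins, bins)
  for (k in seq_along(a)) {
    ia <- min(floor((a[k] - min(a)) / (max(a) - min(a)) * bins), bins - 1) + 1
    ib <- min(floor((b[k] - min(b)) / (max(b) - min(b)) * bins), bins - 1) + 1
    pj[ia, ib] <- pj[ia, ib] + 1
  }
  pj <- pj / sum(pj)
  hfun <- function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  mi_brute <- hfun(rowSums(pj)) + hfun(colSums(pj)) - hfun(pj)
  expect_equal(mutual_information(a, b, bins), mi_brute, tolerance = 1e-12)

  # MI(A, A) = H(A); constant image carries no information
  expect_equal(mutual_information(a, a, bins),
               shannon_entropy(a, bins), tolerance = 1e-12)
  expect_equal(mutual_information(matrix(2, 4, 4), b, bins), 0)
  expect_error(mutual_information(a, matrix(0, 2, 8), bins), "shape")
})

test_that("joint histogram marginals are its row/column sums", {
  set.seed(32)
  a <- stats::runif(500)
  b <- stats::runif(500)
  jh <- joint_histogram(a, b, bins = 16)
  expect_equal(sum(jh$counts), 500)
  expect_identical(jh$marginal_a, rowSums(jh$counts))
  expect_identical(jh$marginal_b, colSums(jh$counts))
  expect_true(all(jh$counts >= 0))
})

test_that("integer-voxel shifts of a planning-CT window are recovered exactly", {
  ct <- smooth_volume(c(40, 40, 20), c(2, 2, 3))
  wdim <- c(16, 16, 8)
  plan_start <- c(13, 13, 7)
  plan_center <- plan_start + (wdim - 1) / 2
  for (off in list(c(0, 0, 0), c(3, -2, 1), c(-5, 4, -2), c(5, 5, 2))) {
    s <- plan_start + off
    win <- ct$values[s[1]:(s[1] + 15), s[2]:(s[2] + 15), s[3]:(s[3] + 7)]
    mvct <- volume_image(win, ct$voxel_size, modality = "MVCT")
    reg <- sliding_search(mvct, ct, plan_center = plan_center,
                          search_radius = 5, bins = 32)
    expect_equal(unname(reg$matched_center), plan_center + off)
    expect_equal(unname(reg$shift_mm), -off * c(2, 2, 3))
    # the matching offset is the global maximum of a non-negative surface
    expect_equal(reg$mi_value, max(reg$mi_surface, na.rm = TRUE))
    expect_true(all(reg$mi_surface >= -1e-12, na.rm = TRUE))
  }
})

test_that("sub-voxel shifts are recovered to within grid quantization", {
  ct <- smooth_volume(c(40, 40, 20), c(2, 2, 3), seed = 77)
  wdim <- c(16, 16, 8)
  plan_center <- c(13, 13, 7) + (wdim - 1) / 2
  for (delta in list(c(2.7, -1.2, 0), c(-4.9, 3.1, 0))) {
    moved <- shift_volume(ct, couch_shift(delta[1], delta[2], delta[3]))
    s <- c(13, 13, 7)
    win <- moved$values[s[1]:(s[1] + 15), s[2]:(s[2] + 15), s[3]:(s[3] + 7)]
    mvct <- volume_image(win, ct$voxel_size, modality = "MVCT")
    reg <- sliding_search(mvct, ct, plan_center = plan_center,
                          search_radius = 5, bins = 32)
    err <- abs(unname(reg$shift_mm) - delta)
    expect_true(all(err <= ct$voxel_size / 2 + ct$voxel_size))
  }
})

test_that("search is symmetric for mirrored shifts of a symmetric volume", {
  ct <- smooth_volume(c(40, 40, 20), c(2, 2, 3), seed = 5)
  ct$values <- (ct$values + ct$values[40:1, , ]) / 2  # symmetric in x
  wdim <- c(16, 16, 8)
  plan_start <- c(13, 13, 7)
  plan_center <- plan_start + (wdim - 1) / 2
  rec <- sapply(c(-3, 3), function(ox) {
    s <- plan_start + c(ox, 0, 0)
    win <- ct$values[s[1]:(s[1] + 15), s[2]:(s[2] + 15), s[3]:(s[3] + 7)]
    reg <- sliding_search(volume_image(win, ct$voxel_size,
                                       modality = "MVCT"),
                          ct, plan_center = plan_center, search_radius = 5,
                          bins = 32)
    reg$shift_mm[["tx"]]
  })
  expect_equal(rec[1], -rec[2])
})

test_that("MI ties resolve to the smallest offset", {
  ct <- volume_image(array(1, c(20, 20, 10)), c(2, 2, 3))
  win <- volume_image(array(1, c(8, 8, 4)), c(2, 2, 3), modality = "MVCT")
  reg <- sliding_search(win, ct, plan_center = c(8.5, 8.5, 4.5),
                        search_radius = 2, bins = 16)
  expect_equal(unname(reg$offsets), c(0, 0, 0))
})

test_that("center differences convert to millimetre shifts per convention", {
  expect_equal(unname(shift_from_centers(c(5, 5, 5), c(5, 5, 5), c(2, 2, 3))),
               c(0, 0, 0))
  # lateral: matched 133.5 vs planned 128.5 at 2 mm voxels -> -10 mm
  expect_equal(shift_from_centers(c(128.5, 126.5, 61),
                                  c(133.5, 126.5, 61),
                                  c(2, 2, 3))[["tx"]], -10)
  # vertical: matched 128.5 vs planned 126.5 at 2 mm voxels -> -4 mm
  expect_equal(shift_from_centers(c(128.5, 126.5, 61),
                                  c(128.5, 128.5, 61),
                                  c(2, 2, 3))[["ty"]], -4)
})
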