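test_that("reflectivity is the summed channel power and is swap-invariant", {
  expect_equal(compute_reflectivity(ascan_pair(0, 0)), 0)
  expect_equal(compute_reflectivity(ascan_pair(1, 0)), 1)
  expect_equal(compute_reflectivity(ascan_pair(3, 4)), 25)
  set.seed(42)
  for (k in 1:10) {
    a1 <- runif(16, 0, 5); a2 <- runif(16, 0, 5)
    expect_equal(compute_reflectivity(ascan_pair(a1, a2)),
                 compute_reflectivity(ascan_pair(a2, a1)))
  }
})

test_that("phase retardation handles the limiting channel ratios", {
  expect_equal(compute_phase_retardation(ascan_pair(1, 1)), 45)
  expect_equal(compute_phase_retardation(ascan_pair(1, 0)), 0)
  expect_equal(compute_phase_retardation(ascan_pair(0, 1)), 90)
  # both channels dark: invalid, not zero
  out <- compute_phase_retardation(ascan_pair(c(0, 1), c(0, 1)))
  expect_true(is.na(out[1]))
  expect_equal(out[2], 45)
})

test_that("channel swap maps retardation to its complement", {
  set.seed(7)
  a1 <- runif(32, 0.1, 3); a2 <- runif(32, 0.1, 3)
  pr <- compute_phase_retardation(ascan_pair(a1, a2))
  pr_sw <- compute_phase_retardation(ascan_pair(a2, a1))
  expect_equal(pr_sw, 90 - pr, tolerance = 1e-12)
})

test_that("synthesized pairs encode the requested retardation", {
  p45 <- synthesize_ascan_pair(45, 1, 8, 0, 1)
  expect_equal(p45$a1, p45$a2)
  p0 <- synthesize_ascan_pair(0, 1, 8, 0, 1)
  expect_equal(p0$a2, rep(0, 8))
  # determinism
  expect_identical(synthesize_ascan_pair(30, 2, 16, 0.05, 99),
                   synthesize_ascan_pair(30, 2, 16, 0.05, 99))
  # noiseless round trip across the full angular range
  for (theta in seq(0, 90, by = 15)) {
    pr <- compute_phase_retardation(synthesize_ascan_pair(theta, 2, 4, 0, 1))
    expect_equal(pr, rep(theta, 4), tolerance = 1e-9)
  }
})

test_that("noisy retardation recovery is unbiased at small noise", {
  recovered <- vapply(1:1000, function(s) {
    mean(compute_phase_retardation(synthesize_ascan_pair(30, 2, 16, 0.01, s)))
  }, numeric(1))
  expect_lt(abs(mean(recovered) - 30), 3 * sd(recovered))
})

test_that("en-face extraction samples the posterior surface and masks dark pixels", {
  # constant volume with equal channels
  a1 <- array(1, dim = c(5, 7, 4))
  vol <- ascan_volume(a1, a1, spacing = 0.25)
  m <- extract_enface_pr(vol, 2)
  expect_equal(m$values, matrix(45, 5, 7))
  expect_true(all(m$mask))

  # round trip of a known retardation field through synthesized A-scans
  ny <- 9; nx <- 11; nz <- 3
  pr_field <- matrix(seq(5, 85, length.out = ny * nx), ny, nx)
  a1 <- array(0, dim = c(ny, nx, nz)); a2 <- a1
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    p <- synthesize_ascan_pair(pr_field[i, j], 1.7, nz, 0, 1)
    a1[i, j, ] <- p$a1; a2[i, j, ] <- p$a2
  }
  m <- extract_enface_pr(ascan_volume(a1, a2, 0.5), 3)
  expect_equal(m$values, pr_field, tolerance = 1e-9)

  # one dark A-scan is masked without disturbing neighbours
  a1[4, 5, ] <- 0; a2[4, 5, ] <- 0
  m2 <- extract_enface_pr(ascan_volume(a1, a2, 0.5), 1)
  expect_false(m2$mask[4, 5])
  expect_equal(sum(!m2$mask), 1)
  dark <- (5 - 1) * ny + 4  # column-major index of the dark pixel
  expect_equal(m2$values[-dark], pr_field[-dark], tolerance = 1e-9)

  # out-of-range surface index names the A-scan
  si <- matrix(1, ny, nx); si[2, 3] <- 99
  expect_error(extract_enface_pr(ascan_volume(a1, a2, 0.5), si), "y=2, x=3")
})

test_that("floating-average smoothing matches a brute-force masked mean", {
  # constant map is a fixed point
  cm <- const_map(33)
  expect_equal(smooth_map(cm, c(1, 1))$values, cm$values)

  # unit impulse: covered pixels equal 1/k, k from explicit enumeration
  v <- matrix(0, 15, 15); v[8, 8] <- 1
  imp <- corneal_map(v, spacing = 0.25, units = "um", quantity = "reflectivity")
  sm <- smooth_map(imp, c(1, 1))  # 5 x 5 pixel window
  expect_equal(sm$values[8, 8], 1 / 25)
  expect_equal(sm$values[6, 8], 1 / 25)
  expect_equal(sm$values[5, 8], 0)

  # random masked maps against the independent loop oracle
  set.seed(3)
  for (k in 1:5) {
    v <- matrix(rnorm(13 * 17), 13, 17)
    msk <- matrix(runif(13 * 17) > 0.2, 13, 17)
    v[!msk] <- NA
    mp <- corneal_map(v, spacing = 0.25, units = "um",
                      quantity = "reflectivity", mask = msk)
    got <- smooth_map(mp, c(1, 0.8))
    expect_equal(got$values, smooth_oracle(mp, c(1, 0.8)), tolerance = 1e-12)
    expect_identical(got$mask, msk)
  }

  # repeated smoothing agrees with the oracle applied twice
  mp <- field_map(function(y, x) 50 + x^2 - y, spacing = 0.25)
  twice <- smooth_map(smooth_map(mp, c(1, 1)), c(1, 1))
  o1 <- mp; o1$values <- smooth_oracle(mp, c(1, 1))
  expect_equal(twice$values, smooth_oracle(o1, c(1, 1)), tolerance = 1e-12)

  expect_error(smooth_map(cm, c(0.1, 0.1)), "smaller than one pixel")
})

test_that("smoothing conserves the total when the support is interior", {
  # every interior pixel contributes to exactly k windows with weight 1/k,
  # so a signal supported away from the borders keeps its sum
  set.seed(8)
  v <- matrix(0, 21, 21)
  v[5:17, 5:17] <- rnorm(13 * 13, 40, 3)
  mp <- corneal_map(v, spacing = 0.25, units = "um", quantity = "reflectivity")
  sm <- smooth_map(mp, c(1, 1))
  expect_equal(sum(sm$values), sum(v), tolerance = 1e-10)
})

test_that("centred cropping preserves spacing and composes", {
  g <- field_map(function(y, x) 50 + x + 2 * y, extent = c(10, 8),
                 spacing = 0.25)
  expect_equal(crop_field(g, c(10, 8))$values, g$values)

  c88 <- crop_field(g, c(8, 8))
  expect_equal(unname(map_extent(c88)), c(8, 8))
  # symmetric margins: the retained x axis is centred
  expect_equal(dim(c88$values), c(33, 33))
  expect_equal(c88$values, g$values[, 5:37])

  c44_direct <- crop_field(g, c(4, 4))
  c44_chain <- crop_field(crop_field(g, c(8, 6)), c(4, 4))
  expect_equal(c44_direct$values, c44_chain$values)

  expect_error(crop_field(c88, c(12, 8)), "exceeds")
})
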