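test_that("default phenotypes carry the published class statistics", {
  ph <- default_phenotypes()
  idx <- function(p, f, col) p$index_means_sds[[col]][p$index_means_sds$index == f]
  expect_equal(idx(ph$healthy, "pc_IS", "mean"), 0.3)
  expect_equal(idx(ph$healthy, "pc_IS", "sd"), 0.5)
  expect_equal(idx(ph$healthy, "pc_KISA", "mean"), 8)
  expect_equal(idx(ph$healthy, "pc_BADD", "mean"), 1.0)
  expect_equal(idx(ph$kc, "pc_Kmax", "mean"), 55.0)
  expect_equal(idx(ph$kc, "pc_Kmax", "sd"), 4.9)
  expect_true(ph$healthy$bowman_mean >= 15 && ph$healthy$bowman_mean <= 17)
  expect_true(ph$kc$cone_present)
  expect_false(ph$healthy$cone_present)
  # keratoconus KISA% is lognormal (heavy right skew), others gaussian
  expect_equal(idx(ph$kc, "pc_KISA", "dist"), "lognormal")
  expect_equal(idx(ph$healthy, "pc_KISA", "dist"), "normal")
  # every index table covers the same record fields
  expect_identical(ph$healthy$index_means_sds$index,
                   ph$kc$index_means_sds$index)
})

test_that("eye generation is deterministic given the seed", {
  ph <- default_phenotypes()
  e1 <- generate_eye(ph$kc, rng_seed = 33)
  e2 <- generate_eye(ph$kc, rng_seed = 33)
  expect_identical(e1$pr_map[[1]]$values, e2$pr_map[[1]]$values)
  expect_identical(e1$epi_map[[1]]$values, e2$epi_map[[1]]$values)
  idx_cols <- grep("^(pc|ms)_", names(e1), value = TRUE)
  expect_identical(e1[idx_cols], e2[idx_cols])
  e3 <- generate_eye(ph$kc, rng_seed = 34)
  expect_false(identical(e1$pr_map[[1]]$values, e3$pr_map[[1]]$values))
})

test_that("degenerate parameters give constant maps at their means", {
  ph <- default_phenotypes()$healthy
  ph$pr_central_sd <- 0; ph$epi_sd <- 0; ph$bowman_sd <- 0
  ph$pr_peripheral_rise <- 0; ph$pr_peripheral_rise_sd <- 0
  ph$pr_rhombus_amp <- 0; ph$pr_rhombus_amp_sd <- 0
  ph$pr_noise_sd <- 0; ph$epi_noise_sd <- 0; ph$bowman_noise_sd <- 0
  e <- generate_eye(ph, rng_seed = 5)
  expect_equal(e$pr_map[[1]]$values,
               matrix(ph$pr_central_mean, 33, 41), tolerance = 1e-12)
  expect_equal(e$epi_map[[1]]$values,
               matrix(ph$epi_mean, 33, 33), tolerance = 1e-12)
  expect_equal(e$bowman_map[[1]]$values,
               matrix(ph$bowman_mean, 33, 33), tolerance = 1e-12)
})

test_that("keratoconus eyes exceed healthy eyes in central retardation", {
  ph <- default_phenotypes()
  wins <- 0
  for (s in 1:50) {
    h <- generate_eye(ph$healthy, rng_seed = 10000 + s)
    k <- generate_eye(ph$kc, rng_seed = 20000 + s)
    wins <- wins + (map_central_mean(k$pr_map[[1]]) >
                      map_central_mean(h$pr_map[[1]]))
  }
  # sign test: under no difference wins ~ Binom(50, .5); 40 is p < 1e-4
  expect_gte(wins, 40)
})

test_that("cohorts have the requested composition and respect physical ranges", {
  co <- default_cohort()
  expect_equal(nrow(co), 359)
  expect_equal(sum(co$true_group == "healthy"), 120)
  expect_equal(sum(co$true_group == "skc"), 109)
  expect_equal(sum(co$true_group == "kc"), 130)
  expect_equal(sum(co$skc_subtype == "fellow_eye"), 33)
  expect_equal(sum(co$skc_subtype == "bilateral_suspect"), 76)
  expect_true(all((co$skc_subtype == "none") == (co$true_group != "skc")))
  expect_false(anyDuplicated(co$eye_id) > 0)

  # physical ranges over a subsample of maps
  for (i in seq(1, 359, by = 30)) {
    pr <- co$pr_map[[i]]$values[co$pr_map[[i]]$mask]
    expect_true(all(pr >= 0 & pr <= 90))
    expect_true(all(co$epi_map[[i]]$values[co$epi_map[[i]]$mask] > 0))
    expect_true(all(co$bowman_map[[i]]$values[co$bowman_map[[i]]$mask] > 0))
  }

  expect_equal(nrow(generate_cohort(0, 0, 0, 0, 1)), 0)

  # a different base seed changes the data
  co2 <- generate_cohort(2, 2, 2, 0.5, rng_seed = 7)
  co3 <- generate_cohort(2, 2, 2, 0.5, rng_seed = 8)
  expect_false(identical(co2$pr_map[[1]]$values, co3$pr_map[[1]]$values))
  # and the same seed reproduces it exactly
  co4 <- generate_cohort(2, 2, 2, 0.5, rng_seed = 7)
  expect_identical(co2$pc_KISA, co4$pc_KISA)
  expect_identical(co2$pr_map[[1]]$values, co4$pr_map[[1]]$values)
})

test_that("central retardation is ordered healthy < skc < kc in the mean", {
  co <- default_cohort()
  pr <- vapply(co$pr_map, map_central_mean, numeric(1))
  m <- tapply(pr, co$true_group, mean)
  expect_lt(m[["healthy"]], m[["skc"]])
  expect_lt(m[["skc"]], m[["kc"]])
})

test_that("inconsistent phenotype parameters are rejected, not looped forever", {
  ph <- default_phenotypes()$healthy
  tab <- ph$index_means_sds
  # a BAD-D distribution far above the healthy box cannot be truncated in
  tab$mean[tab$index == "pc_BADD"] <- 50
  tab$sd[tab$index == "pc_BADD"] <- 0.01
  ph$index_means_sds <- tab
  expect_error(generate_eye(ph, rng_seed = 1, max_redraws = 50), "threshold box")
})

test_that("cohort round-trips through the plain-text format", {
  co <- generate_cohort(2, 1, 1, 1, rng_seed = 3)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(nrow(back), 4)
  expect_equal(back$pc_KISA, co$pc_KISA)
  expect_equal(back$true_group, co$true_group)
  for (i in 1:4) {
    expect_equal(back$pr_map[[i]]$values, co$pr_map[[i]]$values,
                 tolerance = 1e-12)
    expect_identical(back$pr_map[[i]]$mask, co$pr_map[[i]]$mask)
  }
})
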