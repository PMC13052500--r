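# shared fixtures, built in code

# cache expensive cohorts across test files (one R process per test run)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# the default-condition cohort used by labeling and pipeline checks
default_cohort <- function(seed = 101) {
  cached(paste0("cohort_", seed), generate_cohort(rng_seed = seed))
}

# phenotypes with negligible within-class spread: classes separated by a
# huge margin in many features
separated_phenotypes <- function() {
  ph <- default_phenotypes()
  for (g in names(ph)) {
    ph[[g]]$pr_central_sd <- 0.05
    ph[[g]]$epi_sd <- 0.05
    ph[[g]]$bowman_sd <- 0.05
    ph[[g]]$pr_peripheral_rise_sd <- 0.05
    ph[[g]]$pr_rhombus_amp_sd <- 0.05
    ph[[g]]$pr_noise_sd <- 0.01
    ph[[g]]$epi_noise_sd <- 0.01
    ph[[g]]$bowman_noise_sd <- 0.01
    tab <- ph[[g]]$index_means_sds
    tab$sd <- pmin(tab$sd, abs(tab$mean) * 0.002 + 1e-4)
    ph[[g]]$index_means_sds <- tab
  }
  # push the class means far apart in the maps and one tomography index so
  # every schema separates with a huge margin
  shift <- function(tab, idx, delta) {
    tab$mean[tab$index == idx] <- tab$mean[tab$index == idx] + delta
    tab
  }
  ph$skc$index_means_sds <- shift(ph$skc$index_means_sds, "pc_Kmax", 2)
  ph$healthy$pr_central_mean <- 15
  ph$skc$pr_central_mean <- 35
  ph$kc$pr_central_mean <- 55
  ph$healthy$epi_mean <- 58
  ph$skc$epi_mean <- 48
  ph$kc$epi_mean <- 38
  ph$healthy$bowman_mean <- 18
  ph$skc$bowman_mean <- 13
  ph$kc$bowman_mean <- 8
  # margin lives in the map levels; the randomly positioned cone would
  # otherwise add high-variance position features to the keratoconus class
  ph$kc$cone_present <- FALSE
  ph
}

separated_cohort <- function(n_per_class = 30, seed = 11) {
  cached(
    paste0("sep_cohort_", n_per_class, "_", seed),
    generate_cohort(n_per_class, n_per_class, n_per_class,
                    fellow_eye_fraction = 0, rng_seed = seed,
                    phenotypes = separated_phenotypes(),
                    healthy_like_prob = c(fellow_eye = 0,
                                          bilateral_suspect = 0))
  )
}

# plain gaussian 3-class feature table (no cohort machinery): class means
# 0, delta, 2*delta on the first two of p features
gaussian_features <- function(n_per_class, delta, p = 4, seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  cls <- rep(kc_groups(), each = n_per_class)
  shift <- rep(c(0, delta, 2 * delta), each = n_per_class)
  x[, 1] <- x[, 1] + shift
  x[, 2] <- x[, 2] + shift
  colnames(x) <- paste0("f", seq_len(p))
  list(
    features = dplyr::bind_cols(
      tibble::tibble(eye_id = sprintf("e%03d", seq_len(n))),
      tibble::as_tibble(x)
    ),
    labels = factor(cls, levels = kc_groups())
  )
}

# small constant corneal map
const_map <- function(value = 45, n = 17, spacing = 0.25,
                      quantity = "phase_retardation",
                      units = "degrees") {
  corneal_map(matrix(value, n, n), spacing = spacing, units = units,
              quantity = quantity)
}

# map whose pixels carry a known smooth field f(x, y)
field_map <- function(f, extent = c(8, 8), spacing = 0.5,
                      quantity = "epithelium_thickness", units = "um") {
  nx <- round(extent[[1]] / spacing) + 1
  ny <- round(extent[[2]] / spacing) + 1
  x <- (seq_len(nx) - (nx + 1) / 2) * spacing
  y <- (seq_len(ny) - (ny + 1) / 2) * spacing
  v <- outer(y, x, f)
  corneal_map(v, spacing = spacing, units = units, quantity = quantity)
}

# independent brute-force masked box smoother (oracle for smooth_map)
smooth_oracle <- function(map, window_mm) {
  kx <- ceiling(window_mm[[1]] / map$spacing[["x"]] - 1e-9)
  kx <- kx + (kx %% 2 == 0)
  ky <- ceiling(window_mm[[2]] / map$spacing[["y"]] - 1e-9)
  ky <- ky + (ky %% 2 == 0)
  hx <- (kx - 1) / 2; hy <- (ky - 1) / 2
  v <- map$values; msk <- map$mask
  out <- matrix(NA_real_, nrow(v), ncol(v))
  for (i in seq_len(nrow(v))) {
    for (j in seq_len(ncol(v))) {
      if (!msk[i, j]) next
      rs <- max(1, i - hy):min(nrow(v), i + hy)
      cs <- max(1, j - hx):min(ncol(v), j + hx)
      vals <- v[rs, cs][msk[rs, cs]]
      out[i, j] <- mean(vals)
    }
  }
  out
}

# independent enumeration oracle for the venn partition
venn_oracle <- function(a, b, c) {
  out <- c(all_three = 0, a_b = 0, b_c = 0, a_c = 0, none = 0)
  for (i in seq_along(a)) {
    if (a[i] == b[i] && b[i] == c[i]) out["all_three"] <- out["all_three"] + 1
    else if (a[i] == b[i]) out["a_b"] <- out["a_b"] + 1
    else if (b[i] == c[i]) out["b_c"] <- out["b_c"] + 1
    else if (a[i] == c[i]) out["a_c"] <- out["a_c"] + 1
    else out["none"] <- out["none"] + 1
  }
  out
}
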