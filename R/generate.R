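#' Synthetic cohort generation
#'
#' Deterministic, seed-splittable simulation of PS-OCT + tomography cohorts
#' with the class-conditional structure the downstream analysis assumes:
#' spatially structured en-face maps (radial retardation rise with a
#' fourfold "rhombus" modulation, near-uniform sublayer thickness, a focal
#' cone in keratoconus) and tomography index records truncated into each
#' group's labeling box so that generated labels always round-trip through
#' [classify_group()].
#'
#' @name synthetic_cohort
NULL

# default grids: 10 x 8 mm retardation field, 8 x 8 mm thickness fields,
# 0.25 mm pixel pitch
kc_grid_defaults <- function() {
  list(spacing = 0.25, pr_extent = c(10, 8), thickness_extent = c(8, 8))
}

grid_coords <- function(extent, spacing) {
  nx <- round(extent[[1]] / spacing) + 1L
  ny <- round(extent[[2]] / spacing) + 1L
  list(x = (seq_len(nx) - (nx + 1) / 2) * spacing,
       y = (seq_len(ny) - (ny + 1) / 2) * spacing, nx = nx, ny = ny)
}

# one truncated draw; rejection with bounded attempts
draw_trunc <- function(n, mean, sd, dist = "normal", lower = -Inf, upper = Inf,
                       max_tries = 1000) {
  draw1 <- function() {
    if (dist == "lognormal") {
      if (sd == 0) return(rep(mean, n))
      s2 <- log(1 + (sd / mean)^2)
      stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
    } else {
      stats::rnorm(n, mean, sd)
    }
  }
  out <- draw1()
  for (t in seq_len(max_tries)) {
    bad <- out < lower | out > upper
    if (!any(bad)) return(out)
    out[bad] <- draw1()[bad]
  }
  stop_kc("truncated draw failed: the truncation region has negligible mass ",
          sprintf("(index mean %.3g, sd %.3g, bounds [%.3g, %.3g])",
                  mean, sd, lower, upper))
}

build_phenotype_map <- function(kind, params, centre_value, cone,
                                noise_sd) {
  g <- kc_grid_defaults()
  ext <- if (kind == "pr") g$pr_extent else g$thickness_extent
  gc <- grid_coords(ext, g$spacing)
  X <- matrix(rep(gc$x, each = gc$ny), nrow = gc$ny)
  Y <- matrix(rep(gc$y, times = gc$nx), nrow = gc$ny)
  r <- sqrt(X^2 + Y^2)
  th <- atan2(Y, X)
  v <- matrix(centre_value, gc$ny, gc$nx)
  if (kind == "pr") {
    s <- (r / 4)^2
    v <- v + params$pr_peripheral_rise * s +
      params$pr_rhombus_amp * s * cos(4 * th)
  }
  if (!is.null(cone)) {
    d2 <- (X - cone$cx)^2 + (Y - cone$cy)^2
    bump <- exp(-d2 / cone$radius^2)
    if (kind == "pr") {
      v <- v + cone$pr_elevation * bump
    } else if (kind == "epi") {
      # doughnut: focal thinning at the cone apex with a compensatory
      # annular thickening around it
      ring <- exp(-(sqrt(d2) - 1.8 * cone$radius)^2 / cone$radius^2)
      v <- v - cone$epi_thinning * bump + 0.35 * cone$epi_thinning * ring
    } else {
      v <- v - cone$bowman_thinning * bump
    }
  }
  if (noise_sd > 0) {
    v <- v + matrix(stats::rnorm(length(v), 0, noise_sd), gc$ny, gc$nx)
  }
  quantity <- switch(kind, pr = "phase_retardation",
                     epi = "epithelium_thickness", bow = "bowman_thickness")
  units <- if (kind == "pr") "degrees" else "um"
  if (kind == "pr") v <- pmin(pmax(v, 0), 90) else v <- pmax(v, 0.5)
  m <- corneal_map(v, spacing = g$spacing, units = units, quantity = quantity)
  smooth_map(m, c(1, 1))
}

#' Generate one synthetic eye
#'
#' Draws one eye from a phenotype: between-eye central levels, the three
#' en-face maps (with per-pixel noise followed by the standard 1 x 1 mm
#' floating-average smoothing), and the two device index records. The three
#' labeling indices (KISA%, IS, BAD-D) are re-drawn jointly (up to
#' `max_redraws`) until the eye satisfies its group's threshold box, so a
#' generated eye always round-trips through [classify_group()]. All draws
#' are deterministic given `rng_seed`.
#'
#' @param params A [kc_phenotype()].
#' @param rng_seed Integer seed for this eye.
#' @param eye_id,subject_id,laterality,skc_subtype Optional metadata.
#' @param max_redraws Bound on labeling-index re-draws before signalling
#'   inconsistent parameters.
#' @return A one-row tibble: metadata, list-columns `pr_map`, `epi_map`,
#'   `bowman_map`, and one column per simulated index (`pc_*`, `ms_*`,
#'   including the map-derived `ms_e*` epithelium Zernike summaries).
#' @export
generate_eye <- function(params, rng_seed, eye_id = sprintf("eye_%d", rng_seed),
                         subject_id = eye_id, laterality = "OD",
                         skc_subtype = if (params$group == "skc")
                           "bilateral_suspect" else "none",
                         max_redraws = 1000) {
  stopifnot(inherits(params, "kc_phenotype"))
  set.seed(as.integer(rng_seed))

  pr_c <- draw_trunc(1, params$pr_central_mean, params$pr_central_sd,
                     lower = 0, upper = 90)
  epi_c <- draw_trunc(1, params$epi_mean, params$epi_sd, lower = 5)
  bow_c <- draw_trunc(1, params$bowman_mean, params$bowman_sd, lower = 2)
  # per-eye spatial-profile draws: real corneas vary in how steeply
  # retardation rises toward the periphery and in the rhombus contrast
  params$pr_peripheral_rise <- draw_trunc(1, params$pr_peripheral_rise,
                                          params$pr_peripheral_rise_sd %||% 0,
                                          lower = 0)
  params$pr_rhombus_amp <- draw_trunc(1, params$pr_rhombus_amp,
                                      params$pr_rhombus_amp_sd %||% 0,
                                      lower = 0)

  cone <- NULL
  if (params$cone_present) {
    jit <- stats::rnorm(2, 0, 0.4)
    cone <- list(cx = params$cone_center[[1]] + jit[1],
                 cy = params$cone_center[[2]] + jit[2],
                 radius = params$cone_radius,
                 pr_elevation = params$cone_pr_elevation,
                 epi_thinning = params$cone_epi_thinning,
                 bowman_thinning = params$cone_bowman_thinning)
  }

  pr_map <- build_phenotype_map("pr", params, pr_c, cone, params$pr_noise_sd)
  epi_map <- build_phenotype_map("epi", params, epi_c, cone, params$epi_noise_sd)
  bow_map <- build_phenotype_map("bow", params, bow_c, cone, params$bowman_noise_sd)

  tab <- params$index_means_sds
  idx <- stats::setNames(numeric(nrow(tab)), tab$index)
  for (i in seq_len(nrow(tab))) {
    idx[[i]] <- draw_trunc(1, tab$mean[i], tab$sd[i], tab$dist[i],
                           tab$lower[i], tab$upper[i])
  }

  # joint re-draw of the labeling triple into the group's threshold box
  suspect <- params$group == "skc"
  triple <- c("pc_KISA", "pc_IS", "pc_BADD")
  ok <- FALSE
  for (t in seq_len(max_redraws)) {
    lab <- classify_group(idx[["pc_KISA"]], idx[["pc_IS"]], idx[["pc_BADD"]],
                          clinical_suspect = suspect)$label
    if (as.character(lab) == params$group) { ok <- TRUE; break }
    for (f in triple) {
      row <- which(tab$index == f)
      idx[[f]] <- draw_trunc(1, tab$mean[row], tab$sd[row], tab$dist[row],
                             tab$lower[row], tab$upper[row])
    }
  }
  if (!ok) {
    stop_kc("could not draw labeling indices inside the `", params$group,
            "` threshold box after ", max_redraws,
            " re-draws; phenotype parameters are inconsistent with the criteria.")
  }

  # derived Pentacam fields
  idx[["pc_Kmean"]] <- (idx[["pc_K1"]] + idx[["pc_K2"]]) / 2
  idx[["pc_Astigmatism"]] <- idx[["pc_K2"]] - idx[["pc_K1"]]

  # MS-39 epithelium-map Zernike summaries come from the map itself
  efit <- fit_zernike(epi_map, order_max = 6, pupil_diameter_mm = 8)
  es <- zernike_rms_summaries(efit, prefix = "ms_e")

  dplyr::bind_cols(
    tibble::tibble(
      eye_id = eye_id, subject_id = subject_id, laterality = laterality,
      true_group = factor(params$group, levels = kc_groups()),
      skc_subtype = if (params$group == "skc") skc_subtype else "none",
      pr_map = list(pr_map), epi_map = list(epi_map), bowman_map = list(bow_map)
    ),
    tibble::as_tibble(as.list(c(idx, es)))
  )
}

#' Generate a three-class synthetic cohort
#'
#' Builds `n_healthy + n_skc + n_kc` eyes with per-eye seeds derived from
#' `rng_seed` via [derive_seed()] (so the cohort is reproducible and any eye
#' can be regenerated in isolation). Subclinical eyes are split into fellow
#' eyes of highly asymmetric keratoconus subjects versus bilateral suspects
#' by `fellow_eye_fraction` (count rounded half up). The default sizes and
#' split mirror the reference cohort: 120 healthy, 109 subclinical (33
#' fellow eyes), 130 keratoconus.
#'
#' The subclinical class is simulated as a two-component mixture: a fraction
#' of subclinical eyes (by default 65% of fellow eyes and 30% of bilateral
#' suspects) carry a near-healthy device phenotype — maps and device indices
#' blended 45% of the way from the healthy parameter set toward the
#' subclinical one, while the three labeling indices still sample the
#' subclinical box. This encodes the clinical heterogeneity of the
#' subclinical group (eyes suspected on contextual grounds whose own imaging
#' is essentially normal) and is what makes subclinical the hardest class
#' for every device model.
#'
#' @param n_healthy,n_skc,n_kc Group sizes.
#' @param fellow_eye_fraction Fraction of subclinical eyes that are fellow
#'   eyes of asymmetric keratoconus subjects.
#' @param rng_seed Integer base seed.
#' @param phenotypes Named list of [kc_phenotype()] (default
#'   [default_phenotypes()]).
#' @param healthy_like_prob Named probabilities that a subclinical eye of
#'   each subtype draws the near-healthy phenotype component.
#' @param healthy_like_blend Blend weight of the near-healthy component
#'   (0 = fully healthy phenotype, 1 = full subclinical phenotype).
#' @return A cohort tibble, one row per eye (see [generate_eye()]).
#' @export
generate_cohort <- function(n_healthy = 120, n_skc = 109, n_kc = 130,
                            fellow_eye_fraction = 33 / 109, rng_seed = 1,
                            phenotypes = default_phenotypes(),
                            healthy_like_prob = c(fellow_eye = 0.65,
                                                  bilateral_suspect = 0.30),
                            healthy_like_blend = 0.45) {
  stopifnot(n_healthy >= 0, n_skc >= 0, n_kc >= 0,
            fellow_eye_fraction >= 0, fellow_eye_fraction <= 1)
  groups <- rep(kc_groups(), times = c(n_healthy, n_skc, n_kc))
  if (length(groups) == 0) return(tibble::tibble())
  n_fellow <- floor(fellow_eye_fraction * n_skc + 0.5)
  subtype_pool <- rep(c("fellow_eye", "bilateral_suspect"),
                      times = c(n_fellow, n_skc - n_fellow))
  skc_healthy_like <- if (n_skc > 0 && !is.null(phenotypes$skc) &&
                          !is.null(phenotypes$healthy)) {
    blend_phenotypes(phenotypes$healthy, phenotypes$skc,
                     weight = healthy_like_blend, group = "skc",
                     keep_labeling_from = phenotypes$skc)
  }
  k <- 0
  rows <- purrr::imap(groups, function(g, i) {
    st <- "none"
    ph <- phenotypes[[g]]
    if (g == "skc") {
      k <<- k + 1
      st <- subtype_pool[[k]]
      set.seed(derive_seed(rng_seed, paste0("mix_", i)))
      if (stats::runif(1) < healthy_like_prob[[st]]) ph <- skc_healthy_like
    }
    generate_eye(ph, rng_seed = derive_seed(rng_seed, i),
                 eye_id = sprintf("eye_%04d", i),
                 subject_id = sprintf("subj_%04d", i),
                 laterality = if (i %% 2 == 1) "OD" else "OS",
                 skc_subtype = st)
  })
  dplyr::bind_rows(rows)
}

#' Write / read a cohort as plain-text files
#'
#' The metadata and index table is written as one CSV (map columns
#' excluded); each eye's three maps go to delimited-grid files with a JSON
#' header (see [write_corneal_map()]) named `<eye_id>_<pr|epi|bowman>.tsv`.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   the cohort tibble.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dplyr::select(cohort, -dplyr::any_of(c("pr_map", "epi_map", "bowman_map")))
  readr::write_csv(meta, file.path(dir, "cohort.csv"))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$eye_id[[i]]
    write_corneal_map(cohort$pr_map[[i]], file.path(dir, paste0(id, "_pr.tsv")))
    write_corneal_map(cohort$epi_map[[i]], file.path(dir, paste0(id, "_epi.tsv")))
    write_corneal_map(cohort$bowman_map[[i]], file.path(dir, paste0(id, "_bowman.tsv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  meta <- readr::read_csv(file.path(dir, "cohort.csv"), show_col_types = FALSE)
  meta$true_group <- factor(meta$true_group, levels = kc_groups())
  maps <- lapply(c(pr = "_pr.tsv", epi = "_epi.tsv", bowman = "_bowman.tsv"),
                 function(suf) {
                   lapply(meta$eye_id, function(id) {
                     read_corneal_map(file.path(dir, paste0(id, suf)))
                   })
                 })
  meta$pr_map <- maps$pr
  meta$epi_map <- maps$epi
  meta$bowman_map <- maps$bowman
  tibble::as_tibble(meta)
}

#' Mean of a corneal map over a central disk
#'
#' Summary used for subgroup contrasts (e.g. central 2 mm phase
#' retardation, central sublayer thickness).
#'
#' @param map A `corneal_map`.
#' @param diameter_mm Disk diameter in mm.
#' @return Mean of valid pixels whose centre lies inside the disk.
#' @export
map_central_mean <- function(map, diameter_mm = 2) {
  stopifnot(inherits(map, "corneal_map"))
  df <- map_to_tibble(map)
  r <- diameter_mm / 2
  sel <- df$valid & (df$x_mm^2 + df$y_mm^2) <= r^2 + 1e-12
  mean(df$value[sel])
}

#' Per-eye central map summaries for a cohort
#'
#' @param cohort A cohort tibble with map list-columns.
#' @param diameter_mm Central disk diameter in mm.
#' @return Tibble: `eye_id`, `PR_central`, `ELT_central`, `BLT_central`.
#' @export
cohort_map_summaries <- function(cohort, diameter_mm = 2) {
  tibble::tibble(
    eye_id = cohort$eye_id,
    PR_central = vapply(cohort$pr_map, map_central_mean, numeric(1),
                        diameter_mm = diameter_mm),
    ELT_central = vapply(cohort$epi_map, map_central_mean, numeric(1),
                         diameter_mm = diameter_mm),
    BLT_central = vapply(cohort$bowman_map, map_central_mean, numeric(1),
                         diameter_mm = diameter_mm)
  )
}
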