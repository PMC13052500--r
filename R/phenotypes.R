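#' Class-conditional phenotype parameters
#'
#' A `kc_phenotype` bundles everything needed to simulate one diagnostic
#' class: the spatial-map model (central phase retardation, its peripheral
#' rise and fourfold "rhombus" modulation, sublayer thickness levels, an
#' optional focal cone) and the class-conditional mean/SD of every simulated
#' tomography index. Index distributions are Gaussian unless marked
#' lognormal (used for the heavily right-skewed KISA% in keratoconus), and
#' are truncated to the stated bounds by rejection sampling.
#'
#' @param group `"healthy"`, `"skc"` or `"kc"`.
#' @param pr_central_mean,pr_central_sd Between-eye distribution of central
#'   (apex) phase retardation, degrees.
#' @param pr_peripheral_rise,pr_peripheral_rise_sd Between-eye mean and SD of
#'   the increase of the radial base profile from apex to 4 mm radius, degrees.
#' @param pr_rhombus_amp,pr_rhombus_amp_sd Between-eye mean and SD of the
#'   fourfold angular modulation amplitude at 4 mm radius, degrees.
#' @param epi_mean,epi_sd Between-eye central epithelium thickness, um.
#' @param bowman_mean,bowman_sd Between-eye Bowman's-layer thickness, um.
#' @param pr_noise_sd,epi_noise_sd,bowman_noise_sd Per-pixel measurement
#'   noise SD before the 1 x 1 mm floating-average smoothing.
#' @param cone_present Whether the class carries a focal cone.
#' @param cone_center `(x, y)` nominal cone centre in mm.
#' @param cone_radius Gaussian cone radius in mm (> 0 when present).
#' @param cone_pr_elevation Peak retardation elevation at the cone, degrees.
#' @param cone_epi_thinning Peak epithelial thinning at the cone apex, um
#'   (with a compensatory annular thickening: the "doughnut" pattern).
#' @param cone_bowman_thinning Peak focal Bowman's-layer thinning, um.
#' @param index_means_sds Tibble with columns `index`, `mean`, `sd`, `dist`
#'   (`"normal"`/`"lognormal"`), `lower`, `upper`, covering every simulated
#'   tomography-record field.
#' @return An object of class `kc_phenotype`.
#' @export
kc_phenotype <- function(group, pr_central_mean, pr_central_sd,
                         pr_peripheral_rise, pr_rhombus_amp,
                         pr_peripheral_rise_sd = 0, pr_rhombus_amp_sd = 0,
                         epi_mean, epi_sd, bowman_mean, bowman_sd,
                         pr_noise_sd = 1.0, epi_noise_sd = 0.8,
                         bowman_noise_sd = 0.4,
                         cone_present = FALSE, cone_center = c(0.9, -0.9),
                         cone_radius = 1.6, cone_pr_elevation = 0,
                         cone_epi_thinning = 0, cone_bowman_thinning = 0,
                         index_means_sds) {
  stopifnot(group %in% kc_groups())
  if (any(c(pr_central_sd, epi_sd, bowman_sd, pr_noise_sd, epi_noise_sd,
            bowman_noise_sd, pr_peripheral_rise_sd, pr_rhombus_amp_sd) < 0)) {
    stop_kc("all standard deviations must be non-negative.")
  }
  if (cone_present && cone_radius <= 0) {
    stop_kc("`cone_radius` must be positive when a cone is present.")
  }
  need <- c("index", "mean", "sd", "dist", "lower", "upper")
  if (!all(need %in% names(index_means_sds))) {
    stop_kc("`index_means_sds` must have columns ", paste(need, collapse = ", "))
  }
  if (any(index_means_sds$sd < 0)) stop_kc("index sds must be non-negative.")
  structure(list(
    group = group,
    pr_central_mean = pr_central_mean, pr_central_sd = pr_central_sd,
    pr_peripheral_rise = pr_peripheral_rise, pr_rhombus_amp = pr_rhombus_amp,
    pr_peripheral_rise_sd = pr_peripheral_rise_sd,
    pr_rhombus_amp_sd = pr_rhombus_amp_sd,
    epi_mean = epi_mean, epi_sd = epi_sd,
    bowman_mean = bowman_mean, bowman_sd = bowman_sd,
    pr_noise_sd = pr_noise_sd, epi_noise_sd = epi_noise_sd,
    bowman_noise_sd = bowman_noise_sd,
    cone_present = cone_present, cone_center = cone_center,
    cone_radius = cone_radius, cone_pr_elevation = cone_pr_elevation,
    cone_epi_thinning = cone_epi_thinning,
    cone_bowman_thinning = cone_bowman_thinning,
    index_means_sds = tibble::as_tibble(index_means_sds)
  ), class = "kc_phenotype")
}

#' @export
print.kc_phenotype <- function(x, ...) {
  cat(sprintf("<kc_phenotype> %s: PR %.1f deg (+%.1f peripheral), epi %.1f um, Bowman %.1f um, cone: %s\n",
              x$group, x$pr_central_mean, x$pr_peripheral_rise, x$epi_mean,
              x$bowman_mean, if (x$cone_present) "yes" else "no"))
  invisible(x)
}

# index parameter table: one row per (index, group); mean/sd for the three
# labeling indices, keratometry, pachymetry and the device aberration fields.
# Values for KISA%, IS, BAD-D, Kmax, TCT, CCT, CET follow the published
# class-conditional cohort statistics; the remaining device fields use
# representative clinical values for each class.
index_param_table <- function() {
  tibble::tribble(
    ~index,        ~h_m,   ~h_s,  ~s_m,   ~s_s,  ~k_m,   ~k_s, ~dist,      ~lower, ~upper,
    "pc_KISA",      8,      11,    8,      10,    912,    1290, "special",  0.01,   Inf,
    "pc_IS",        0.3,    0.5,   0.4,    0.5,   5.8,    2.3,  "normal",  -Inf,    Inf,
    "pc_BADD",      1.0,    0.4,   1.9,    0.5,   8.1,    2.8,  "normal",   0,      Inf,
    "pc_K1",        43.2,   1.2,   43.6,   1.6,   49.5,   4.0,  "normal",   30,     80,
    "pc_K2",        44.3,   1.3,   44.8,   1.7,   52.5,   4.5,  "normal",   30,     80,
    "pc_Kmax",      44.5,   1.2,   46.0,   1.9,   55.0,   4.9,  "normal",   30,     90,
    "pc_AxisFlat",  90,     40,    90,     40,    90,     40,   "normal",   0,      180,
    "pc_TCT",       531,    28,    519,    38,    471,    40,   "normal",   250,    800,
    "pc_CCT",       534,    28,    522,    38,    490,    40,   "normal",   250,    800,
    "pc_ISV",       16,     5,     19,     6,     85,     25,   "normal",   0,      Inf,
    "pc_IVA",       0.10,   0.04,  0.13,   0.06,  0.90,   0.35, "normal",   0,      Inf,
    "pc_KI",        1.02,   0.02,  1.03,   0.025,  1.30,   0.12, "normal",   0.8,    2,
    "pc_CKI",       1.00,   0.01,  1.005,  0.012, 1.09,   0.05, "normal",   0.8,    2,
    "pc_IHA",       5,      3,     6,      4.5,     25,     12,   "normal",   0,      Inf,
    "pc_IHD",       0.006,  0.004, 0.009,  0.006, 0.10,   0.04, "normal",   0,      Inf,
    "pc_F_RMS_HOA", 0.40,   0.10,  0.48,   0.15,  2.6,    1.0,  "normal",   0,      Inf,
    "pc_F_RMS_LOA", 1.8,    0.6,   2.0,    0.7,   4.6,    1.8,  "normal",   0,      Inf,
    "pc_F_Ast0",    -0.5,   0.5,   -0.5,   0.5,   -1.5,   1.2,  "normal",  -Inf,    Inf,
    "pc_F_Defocus", 1.3,    0.8,   1.5,    0.8,   3.0,    2.0,  "normal",  -Inf,    Inf,
    "pc_F_Ast45",   0.0,    0.3,   0.0,    0.35,  0.2,    1.0,  "normal",  -Inf,    Inf,
    "pc_F_Trefoil0", 0.05,  0.08,  0.06,   0.10,  0.15,   0.30, "normal",  -Inf,    Inf,
    "pc_F_Coma0",   0.02,   0.10,  0.00,   0.12,  -0.3,   0.5,  "normal",  -Inf,    Inf,
    "pc_F_Coma90",  0.05,   0.10,  -0.05,  0.15,  -1.6,   0.8,  "normal",  -Inf,    Inf,
    "pc_F_Trefoil30", 0.00, 0.08,  0.00,   0.10,  0.10,   0.25, "normal",  -Inf,    Inf,
    "pc_F_SA",      0.25,   0.08,  0.22,   0.10,  -0.25,  0.40, "normal",  -Inf,    Inf,
    "pc_B_RMS_HOA", 0.10,   0.03,  0.12,   0.05,  0.7,    0.3,  "normal",   0,      Inf,
    "pc_B_RMS_LOA", 0.50,   0.15,  0.55,   0.20,  1.2,    0.5,  "normal",   0,      Inf,
    "pc_B_Ast0",    0.12,   0.12,  0.12,   0.15,  0.4,    0.3,  "normal",  -Inf,    Inf,
    "pc_B_Defocus", -0.35,  0.20,  -0.40,  0.20,  -0.8,   0.5,  "normal",  -Inf,    Inf,
    "pc_B_Ast45",   0.0,    0.08,  0.0,    0.10,  0.05,   0.25, "normal",  -Inf,    Inf,
    "pc_B_Trefoil0", 0.01,  0.03,  0.015,  0.04,  0.04,   0.08, "normal",  -Inf,    Inf,
    "pc_B_Coma0",   0.00,   0.03,  0.00,   0.04,  0.08,   0.12, "normal",  -Inf,    Inf,
    "pc_B_Coma90",  0.01,   0.03,  0.02,   0.05,  0.40,   0.20, "normal",  -Inf,    Inf,
    "pc_B_Trefoil30", 0.00, 0.03,  0.00,   0.04,  0.03,   0.08, "normal",  -Inf,    Inf,
    "pc_B_SA",      -0.06,  0.02,  -0.05,  0.03,  0.08,   0.10, "normal",  -Inf,    Inf,
    "ms_AntK1",     43.4,   1.2,   43.8,   1.6,   49.2,   4.0,  "normal",   30,     80,
    "ms_AntK2",     44.6,   1.3,   45.1,   1.7,   52.2,   4.5,  "normal",   30,     80,
    "ms_AntAxis",   90,     40,    90,     40,    90,     40,   "normal",   0,      180,
    "ms_AntKmax",   44.8,   1.2,   46.4,   1.9,   54.6,   4.7,  "normal",   30,     90,
    "ms_AntLORMS",  1.9,    0.6,   2.1,    0.7,   4.8,    1.9,  "normal",   0,      Inf,
    "ms_AntHORMS",  0.35,   0.10,  0.45,   0.15,  2.4,    1.0,  "normal",   0,      Inf,
    "ms_AntComaRMS", 0.15,  0.07,  0.21,   0.11,  1.7,    0.8,  "normal",   0,      Inf,
    "ms_AntDefocus", 1.4,   0.7,   1.5,    0.8,   3.0,    2.0,  "normal",  -Inf,    Inf,
    "ms_AntSA",     0.22,   0.08,  0.18,   0.09,  -0.25,  0.35, "normal",  -Inf,    Inf,
    "ms_BWK1",      44.0,   1.2,   44.8,   1.6,   50.0,   4.2,  "normal",   30,     80,
    "ms_BWK2",      45.2,   1.3,   46.2,   1.7,   53.0,   4.6,  "normal",   30,     80,
    "ms_BWAxis",    90,     40,    90,     40,    90,     40,   "normal",   0,      180,
    "ms_BWKmax",    45.4,   1.2,   47.0,   1.9,   55.2,   4.8,  "normal",   30,     90,
    "ms_BWLORMS",   1.7,    0.5,   1.9,    0.7,   4.4,    1.8,  "normal",   0,      Inf,
    "ms_BWHORMS",   0.30,   0.10,  0.40,   0.15,  2.2,    1.0,  "normal",   0,      Inf,
    "ms_BWComaRMS", 0.13,   0.06,  0.19,   0.10,  1.6,    0.8,  "normal",   0,      Inf,
    "ms_BWDefocus", 1.3,    0.6,   1.4,    0.7,   2.8,    1.8,  "normal",  -Inf,    Inf,
    "ms_BWSA",      0.20,   0.07,  0.17,   0.09,  -0.20,  0.35, "normal",  -Inf,    Inf,
    "ms_CCT",       536,    28,    524,    39,    490,    40,   "normal",   250,    800,
    "ms_CET",       54.9,   3.0,   54.0,   3.6,   49.9,   6.4,  "normal",   20,     90
  )
}

index_table_for <- function(group) {
  tab <- index_param_table()
  cols <- switch(group, healthy = c("h_m", "h_s"), skc = c("s_m", "s_s"),
                 kc = c("k_m", "k_s"))
  out <- tibble::tibble(
    index = tab$index,
    mean = tab[[cols[1]]], sd = tab[[cols[2]]],
    dist = ifelse(tab$dist == "special",
                  ifelse(group == "kc", "lognormal", "normal"), tab$dist),
    lower = tab$lower, upper = tab$upper
  )
  out
}

#' Default phenotype parameter sets for the three diagnostic classes
#'
#' Returns the simulation parameters the package treats as its study
#' conditions. The three labeling indices (KISA%, IS, BAD-D), Kmax,
#' pachymetry and central epithelial thickness use the published
#' class-conditional means and SDs (e.g. healthy IS 0.3 +/- 0.5, KISA% 8,
#' BAD-D 1.0; keratoconus Kmax 55.0 +/- 4.9 D); keratoconus KISA% is drawn
#' lognormally because its 912 +/- 1290 distribution is heavily
#' right-skewed. Spatial-map levels follow the subclinical contrast table
#' (epithelium about 52 um, Bowman's layer 15-17 um in healthy eyes, central
#' retardation rising from healthy through subclinical to keratoconus) with
#' a focal cone — elevated retardation, doughnut-shaped epithelial
#' remodelling, focal Bowman's thinning — only in the keratoconus class.
#'
#' @return Named list of three [kc_phenotype()] objects
#'   (`healthy`, `skc`, `kc`).
#' @export
default_phenotypes <- function() {
  list(
    healthy = kc_phenotype(
      "healthy",
      pr_central_mean = 25.0, pr_central_sd = 3.0,
      pr_peripheral_rise = 18, pr_rhombus_amp = 6,
      pr_peripheral_rise_sd = 3.0, pr_rhombus_amp_sd = 1.5,
      epi_mean = 52.3, epi_sd = 3.0,
      bowman_mean = 16.0, bowman_sd = 0.8,
      index_means_sds = index_table_for("healthy")
    ),
    skc = kc_phenotype(
      "skc",
      pr_central_mean = 31.0, pr_central_sd = 3.5,
      pr_peripheral_rise = 17, pr_rhombus_amp = 5.5,
      pr_peripheral_rise_sd = 3.5, pr_rhombus_amp_sd = 1.5,
      epi_mean = 52.0, epi_sd = 3.5,
      bowman_mean = 15.7, bowman_sd = 1.7,
      index_means_sds = index_table_for("skc")
    ),
    kc = kc_phenotype(
      "kc",
      pr_central_mean = 38.0, pr_central_sd = 4.0,
      pr_peripheral_rise = 14, pr_rhombus_amp = 4,
      pr_peripheral_rise_sd = 4.0, pr_rhombus_amp_sd = 2.0,
      pr_noise_sd = 1.5, epi_noise_sd = 1.0, bowman_noise_sd = 0.5,
      cone_present = TRUE, cone_center = c(0.9, -0.9), cone_radius = 1.6,
      cone_pr_elevation = 18, cone_epi_thinning = 10,
      cone_bowman_thinning = 6,
      epi_mean = 51.0, epi_sd = 4.0,
      bowman_mean = 14.5, bowman_sd = 1.5,
      index_means_sds = index_table_for("kc")
    )
  )
}

#' Blend two phenotypes
#'
#' Linear interpolation between two phenotype parameter sets: every numeric
#' map parameter and every index mean/SD moves `weight` of the way from `a`
#' to `b`. Used to model phenotype heterogeneity inside a diagnostic class —
#' in particular the near-healthy subpopulation of subclinical eyes — and to
#' construct cohorts with scaled class separation.
#'
#' @param a,b [kc_phenotype()] objects with matching index tables.
#' @param weight Interpolation weight in `[0, 1]` (0 = `a`, 1 = `b`).
#' @param group Group label of the result (default: `a`'s group).
#' @param keep_labeling_from Optional phenotype whose KISA%/IS/BAD-D rows
#'   replace the blended ones, so the result still samples inside that
#'   group's labeling box.
#' @return A [kc_phenotype()].
#' @export
blend_phenotypes <- function(a, b, weight, group = a$group,
                             keep_labeling_from = NULL) {
  stopifnot(inherits(a, "kc_phenotype"), inherits(b, "kc_phenotype"),
            weight >= 0, weight <= 1)
  mix <- function(x, y) (1 - weight) * x + weight * y
  src <- if (weight >= 0.5) b else a
  ta <- a$index_means_sds
  tb <- b$index_means_sds[match(ta$index, b$index_means_sds$index), ]
  if (any(is.na(tb$index))) stop_kc("index tables do not match.")
  tab <- tibble::tibble(index = ta$index,
                        mean = mix(ta$mean, tb$mean), sd = mix(ta$sd, tb$sd),
                        dist = src$index_means_sds$dist[
                          match(ta$index, src$index_means_sds$index)],
                        lower = ta$lower, upper = ta$upper)
  if (!is.null(keep_labeling_from)) {
    lt <- keep_labeling_from$index_means_sds
    for (f in c("pc_KISA", "pc_IS", "pc_BADD")) {
      tab[tab$index == f, c("mean", "sd", "dist")] <-
        lt[lt$index == f, c("mean", "sd", "dist")]
    }
  }
  kc_phenotype(
    group,
    pr_central_mean = mix(a$pr_central_mean, b$pr_central_mean),
    pr_central_sd = mix(a$pr_central_sd, b$pr_central_sd),
    pr_peripheral_rise = mix(a$pr_peripheral_rise, b$pr_peripheral_rise),
    pr_rhombus_amp = mix(a$pr_rhombus_amp, b$pr_rhombus_amp),
    pr_peripheral_rise_sd = mix(a$pr_peripheral_rise_sd, b$pr_peripheral_rise_sd),
    pr_rhombus_amp_sd = mix(a$pr_rhombus_amp_sd, b$pr_rhombus_amp_sd),
    epi_mean = mix(a$epi_mean, b$epi_mean), epi_sd = mix(a$epi_sd, b$epi_sd),
    bowman_mean = mix(a$bowman_mean, b$bowman_mean),
    bowman_sd = mix(a$bowman_sd, b$bowman_sd),
    pr_noise_sd = mix(a$pr_noise_sd, b$pr_noise_sd),
    epi_noise_sd = mix(a$epi_noise_sd, b$epi_noise_sd),
    bowman_noise_sd = mix(a$bowman_noise_sd, b$bowman_noise_sd),
    cone_present = src$cone_present, cone_center = src$cone_center,
    cone_radius = src$cone_radius,
    cone_pr_elevation = weight * b$cone_pr_elevation +
      (1 - weight) * a$cone_pr_elevation,
    cone_epi_thinning = weight * b$cone_epi_thinning +
      (1 - weight) * a$cone_epi_thinning,
    cone_bowman_thinning = weight * b$cone_bowman_thinning +
      (1 - weight) * a$cone_bowman_thinning,
    index_means_sds = tab
  )
}
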