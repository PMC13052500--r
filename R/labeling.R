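#' Threshold criteria for the three diagnostic groups
#'
#' Ground-truth group assignment follows composite index criteria on three
#' Pentacam-derived quantities: the KISA% curvature-asymmetry index, the
#' inferior-superior (IS) dioptric asymmetry, and the Belin/Ambrosio total
#' deviation score (BAD-D):
#'
#' * healthy: KISA% < 60, IS < 1.4, BAD-D < 1.65, and no clinical suspicion;
#' * subclinical (skc): KISA% < 60, IS < 1.6, BAD-D < 2.6, with clinical
#'   suspicion (fellow eye of asymmetric keratoconus, or bilateral suspect);
#' * keratoconus (kc): KISA% > 60, IS > 3.0, BAD-D > 3.0.
#'
#' All printed thresholds are strict inequalities; an index exactly at a
#' cutoff fails that criterion. The numeric healthy box is contained in the
#' subclinical box, so the `clinical_suspect` flag — standing in for
#' slit-lamp and fellow-eye context — is what separates those two groups.
#' Eyes in the gap zones (e.g. IS between 1.6 and 3.0) are `indeterminate`.
#'
#' @return A tibble of the threshold values, one row per (group, index).
#' @export
group_criteria <- function() {
  tibble::tribble(
    ~group,    ~index,  ~comparison, ~threshold,
    "healthy", "kisa",  "<",  60,
    "healthy", "is",    "<",  1.4,
    "healthy", "badd",  "<",  1.65,
    "skc",     "kisa",  "<",  60,
    "skc",     "is",    "<",  1.6,
    "skc",     "badd",  "<",  2.6,
    "kc",      "kisa",  ">",  60,
    "kc",      "is",    ">",  3.0,
    "kc",      "badd",  ">",  3.0
  )
}

#' Assign diagnostic group labels from tomography indices
#'
#' Applies the composite threshold criteria of [group_criteria()].
#' Precedence: an eye meeting all three keratoconus conditions is `kc`;
#' otherwise an eye inside the healthy box without clinical suspicion is
#' `healthy`; otherwise an eye inside the subclinical box with clinical
#' suspicion is `skc`; anything else is `indeterminate`.
#'
#' @param kisa_percent KISA% index (vectorized).
#' @param is_value Inferior-superior value in dioptres.
#' @param badd BAD-D total deviation score.
#' @param clinical_suspect Logical; clinical context flags the eye as a
#'   keratoconus suspect (recycled).
#' @return A tibble with one row per eye: `label` (factor healthy/skc/kc/
#'   indeterminate) and the per-criterion pass/fail trace columns
#'   `healthy_kisa` ... `kc_badd`.
#' @examples
#' classify_group(8, 0.3, 1.0)$label        # healthy
#' classify_group(912, 5.8, 8.1)$label      # kc
#' @export
classify_group <- function(kisa_percent, is_value, badd, clinical_suspect = FALSE) {
  n <- max(length(kisa_percent), length(is_value), length(badd),
           length(clinical_suspect))
  kisa <- rep_len(as.numeric(kisa_percent), n)
  is_v <- rep_len(as.numeric(is_value), n)
  bad <- rep_len(as.numeric(badd), n)
  sus <- rep_len(as.logical(clinical_suspect), n)
  if (any(!is.finite(kisa)) || any(!is.finite(is_v)) || any(!is.finite(bad))) {
    stop_kc("all indices must be finite to classify.")
  }
  tr <- tibble::tibble(
    healthy_kisa = kisa < 60, healthy_is = is_v < 1.4, healthy_badd = bad < 1.65,
    skc_kisa = kisa < 60, skc_is = is_v < 1.6, skc_badd = bad < 2.6,
    kc_kisa = kisa > 60, kc_is = is_v > 3.0, kc_badd = bad > 3.0
  )
  label <- dplyr::case_when(
    tr$kc_kisa & tr$kc_is & tr$kc_badd ~ "kc",
    tr$healthy_kisa & tr$healthy_is & tr$healthy_badd & !sus ~ "healthy",
    tr$skc_kisa & tr$skc_is & tr$skc_badd & sus ~ "skc",
    TRUE ~ "indeterminate"
  )
  dplyr::bind_cols(
    tibble::tibble(label = factor(label, levels = c(kc_groups(), "indeterminate"))),
    tr
  )
}

#' Audit a synthetic cohort's labels against the threshold criteria
#'
#' Re-derives every eye's group from its stored Pentacam labeling indices
#' (`pc_KISA`, `pc_IS`, `pc_BADD`, with clinical suspicion taken from
#' `skc_subtype != "none"`) and reports eyes whose indices violate their
#' intended group's criteria. A valid synthetic cohort yields zero rows.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A tibble of mismatching eyes: `eye_id`, `true_group`,
#'   `assigned_label`.
#' @export
audit_cohort_labels <- function(cohort) {
  if (nrow(cohort) == 0) stop_kc("cohort is empty.")
  lab <- classify_group(cohort$pc_KISA, cohort$pc_IS, cohort$pc_BADD,
                        clinical_suspect = cohort$skc_subtype != "none")
  out <- tibble::tibble(eye_id = cohort$eye_id,
                        true_group = as.character(cohort$true_group),
                        assigned_label = as.character(lab$label))
  dplyr::filter(out, .data$true_group != .data$assigned_label)
}
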