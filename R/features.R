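#' Device feature schemas
#'
#' Each diagnostic device contributes a fixed, ordered feature list:
#'
#' * `psoct84` — 84 features: 28 Zernike coefficients (order 6) for each of
#'   the phase-retardation, epithelium-thickness and Bowman's-layer maps.
#' * `pentacam32` — 32 features: 6 anterior keratometry values, 6 derived
#'   topographic indices, and 10 + 10 corneal wavefront aberration terms
#'   (front and back surface).
#' * `ms39_23` — 23 features: anterior keratometry (4) and wavefront
#'   summaries (5), epithelium-Bowman's interface keratometry (4) and
#'   wavefront summaries (5), and 5 Zernike summaries of the epithelium
#'   thickness map.
#'
#' @param schema Schema name.
#' @return Character vector of ordered feature names.
#' @examples
#' length(feature_schema_names("psoct84"))  # 84
#' @export
feature_schema_names <- function(schema = c("psoct84", "pentacam32", "ms39_23")) {
  schema <- match.arg(schema)
  switch(schema,
    psoct84 = paste0(rep(c("PR", "EPI", "BOW"), each = 28), "_",
                     sprintf("Z%02d", 0:27)),
    pentacam32 = c(
      "K1", "K2", "Kmean", "Kmax", "AxisFlat", "Astigmatism",
      "ISV", "IVA", "KI", "CKI", "IHA", "IHD",
      paste0("F_", c("RMS_HOA", "RMS_LOA", "Ast0", "Defocus", "Ast45",
                     "Trefoil0", "Coma0", "Coma90", "Trefoil30", "SA")),
      paste0("B_", c("RMS_HOA", "RMS_LOA", "Ast0", "Defocus", "Ast45",
                     "Trefoil0", "Coma0", "Coma90", "Trefoil30", "SA"))
    ),
    ms39_23 = c(
      "AntK1", "AntK2", "AntAxis", "AntKmax",
      "AntLORMS", "AntHORMS", "AntComaRMS", "AntDefocus", "AntSA",
      "BWK1", "BWK2", "BWAxis", "BWKmax",
      "BWLORMS", "BWHORMS", "BWComaRMS", "BWDefocus", "BWSA",
      "eLORMS", "eHORMS", "eComaRMS", "eDefocus", "eSA"
    )
  )
}

new_feature_vector <- function(schema, values) {
  nms <- feature_schema_names(schema)
  if (length(values) != length(nms)) {
    stop_kc(sprintf("schema `%s` expects %d features, got %d.",
                    schema, length(nms), length(values)))
  }
  if (any(!is.finite(values))) stop_kc("feature values must be finite.")
  names(values) <- nms
  structure(list(schema = schema, values = values), class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> schema %s, %d features\n",
              x$schema, length(x$values)))
  invisible(x)
}

#' Assemble the PS-OCT 84-feature vector
#'
#' Concatenates the order-6 Zernike coefficient blocks of the three PS-OCT
#' maps in fixed order: phase retardation, epithelium thickness, Bowman's
#' layer thickness (28 coefficients each).
#'
#' @param pr,epi,bowman `zernike_fit` objects of order 6 (or bare numeric
#'   vectors of length 28).
#' @return A `feature_vector` with schema `psoct84`.
#' @export
assemble_psoct_features <- function(pr, epi, bowman) {
  blocks <- lapply(list(pr = pr, epi = epi, bowman = bowman), function(b) {
    if (inherits(b, "zernike_fit")) b <- b$coeffs
    if (length(b) != 28) {
      stop_kc("each map block must carry 28 order-6 Zernike coefficients.")
    }
    unname(b)
  })
  new_feature_vector("psoct84", c(blocks$pr, blocks$epi, blocks$bowman))
}

# pull named fields out of a record (named list / vector / one-row df),
# erroring with the name of the first missing field
record_fields <- function(rec, fields, schema) {
  rec <- as.list(rec)
  missing <- setdiff(fields, names(rec))
  if (length(missing) > 0) {
    stop_kc(sprintf("record is missing field `%s` required by schema %s.",
                    missing[[1]], schema))
  }
  vapply(fields, function(f) as.numeric(rec[[f]]), numeric(1))
}

#' Assemble the Pentacam 32-feature vector
#'
#' Orders a tomography record's Pentacam fields into the fixed 32-feature
#' schema: keratometry, derived indices, front-surface and back-surface
#' wavefront aberrations. Field order in the record is irrelevant; a missing
#' field is an error naming it.
#'
#' @param rec Named list, named vector or one-row data frame supplying all
#'   32 fields of [feature_schema_names]`("pentacam32")`.
#' @return A `feature_vector` with schema `pentacam32`.
#' @export
assemble_pentacam_features <- function(rec) {
  nms <- feature_schema_names("pentacam32")
  new_feature_vector("pentacam32", record_fields(rec, nms, "pentacam32"))
}

#' Assemble the MS-39 23-feature vector
#'
#' @param rec Named list, named vector or one-row data frame supplying all
#'   23 fields of [feature_schema_names]`("ms39_23")`.
#' @return A `feature_vector` with schema `ms39_23`.
#' @export
assemble_ms39_features <- function(rec) {
  nms <- feature_schema_names("ms39_23")
  new_feature_vector("ms39_23", record_fields(rec, nms, "ms39_23"))
}

#' Per-eye feature tables for a synthetic cohort
#'
#' Builds the model-ready feature table for one device schema from a cohort
#' tibble (see [generate_cohort()]). For `psoct84` the three en-face maps of
#' each eye are fitted with order-6 Zernike expansions over the central 8 mm
#' pupil and concatenated; for the tomography devices the stored record
#' columns (prefixed `pc_` / `ms_` in the cohort) are reordered into the
#' schema.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param schema Feature schema name.
#' @param order_max,pupil_diameter_mm Zernike fitting controls (psoct84 only).
#' @return A tibble: `eye_id` plus one column per schema feature, rows in
#'   cohort order.
#' @export
cohort_features <- function(cohort, schema = c("psoct84", "pentacam32", "ms39_23"),
                            order_max = 6, pupil_diameter_mm = 8) {
  schema <- match.arg(schema)
  nms <- feature_schema_names(schema)
  rows <- switch(schema,
    psoct84 = purrr::pmap(
      list(cohort$pr_map, cohort$epi_map, cohort$bowman_map),
      function(pr, epi, bow) {
        fits <- lapply(list(pr, epi, bow), fit_zernike,
                       order_max = order_max,
                       pupil_diameter_mm = pupil_diameter_mm)
        assemble_psoct_features(fits[[1]], fits[[2]], fits[[3]])$values
      }),
    pentacam32 = purrr::pmap(
      list(seq_len(nrow(cohort))),
      function(i) {
        rec <- as.list(cohort[i, ])
        names(rec) <- sub("^pc_", "", names(rec))
        assemble_pentacam_features(rec)$values
      }),
    ms39_23 = purrr::pmap(
      list(seq_len(nrow(cohort))),
      function(i) {
        rec <- as.list(cohort[i, ])
        names(rec) <- sub("^ms_", "", names(rec))
        assemble_ms39_features(rec)$values
      })
  )
  out <- tibble::as_tibble(do.call(rbind, rows))
  names(out) <- nms
  dplyr::bind_cols(tibble::tibble(eye_id = cohort$eye_id), out)
}
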