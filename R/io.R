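# plain-text interchange: feature tables, model runs, agreement summaries

#' Write / read a feature table as CSV with a schema sidecar
#'
#' The CSV carries `eye_id` plus one column per schema feature; the schema
#' name (and Zernike convention, for map-derived schemas) goes to
#' `<path>.schema.json` so a reader can validate column order.
#'
#' @param features Feature tibble from [cohort_features()].
#' @param path CSV file path.
#' @param schema Schema name; inferred from the columns when omitted.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble (validated against the sidecar schema).
#' @export
write_features <- function(features, path, schema = NULL) {
  if (is.null(schema)) {
    for (s in c("psoct84", "pentacam32", "ms39_23")) {
      if (identical(names(features)[-1], feature_schema_names(s))) schema <- s
    }
    if (is.null(schema)) stop_kc("could not infer the feature schema.")
  }
  readr::write_csv(features, path)
  jsonlite::write_json(
    list(schema = schema, n_features = ncol(features) - 1L,
         zernike = if (schema == "psoct84")
           list(indexing = "OSA/ANSI", normalization = "unit-RMS",
                order_max = 6L)),
    paste0(path, ".schema.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".schema.json"))
  out <- readr::read_csv(path, show_col_types = FALSE)
  want <- c("eye_id", feature_schema_names(meta$schema))
  if (!identical(names(out), want)) {
    stop_kc("feature columns do not match schema `", meta$schema, "`.")
  }
  out
}

#' Write a fitted device model run to plain-text files
#'
#' Emits `<name>_predictions.csv` (eye_id, true and predicted label, class
#' probabilities), `<name>_confusion.csv` and `<name>_metrics.json`
#' (per-class and macro metrics).
#'
#' @param run A `kc_model_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_run <- function(run, dir) {
  stopifnot(inherits(run, "kc_model_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pfx <- file.path(dir, run$name)
  readr::write_csv(run$per_eye, paste0(pfx, "_predictions.csv"))
  cm <- tibble::as_tibble(run$confusion, rownames = "truth")
  readr::write_csv(cm, paste0(pfx, "_confusion.csv"))
  jsonlite::write_json(
    list(model = run$name, per_class = run$metrics$per_class,
         averaged = run$metrics$averaged),
    paste0(pfx, "_metrics.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write cross-device agreement summaries
#'
#' Emits `agreement.json` (the Venn partition counts and proportions) and
#' one reclassification CSV per device for the requested source group.
#'
#' @param runs Named list of `kc_model_run` objects (2 or 3).
#' @param dir Output directory.
#' @param source_group True group for the reclassification tables.
#' @return `dir`, invisibly.
#' @export
write_agreement <- function(runs, dir, source_group = "skc") {
  stopifnot(length(runs) %in% 2:3)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(runs) == 3) {
    preds <- lapply(runs, function(r) as.character(r$per_eye$predicted))
    v <- venn_partition(preds[[1]], preds[[2]], preds[[3]],
                        names = names(runs))
    jsonlite::write_json(
      list(n_total = v$n_total, all_three = v$all_three,
           pair_only = as.list(v$pair_only), none = v$none,
           all_three_pct = 100 * v$all_three / v$n_total),
      file.path(dir, "agreement.json"), auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(runs)) {
    rc <- reclassification(runs[[nm]]$per_eye, source_group)
    readr::write_csv(rc, file.path(dir, paste0("reclass_", source_group,
                                               "_", nm, ".csv")))
  }
  invisible(dir)
}
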