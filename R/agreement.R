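#' Venn partition of three models' predictions
#'
#' Classifies every eye's agreement pattern across three prediction vectors:
#' all three models agree; exactly one pair agrees (attributed to that
#' pair); or all three disagree. The four counts are an exact partition of
#' the eye set.
#'
#' @param preds_a,preds_b,preds_c Per-eye predicted labels (same eyes, same
#'   order, equal length).
#' @param names Length-3 character vector naming the models.
#' @return An object of class `kc_venn`: `n_total`, `all_three`,
#'   `pair_only` (named counts `a_b`, `b_c`, `a_c`), `none`.
#' @export
venn_partition <- function(preds_a, preds_b, preds_c,
                           names = c("a", "b", "c")) {
  a <- as.character(preds_a); b <- as.character(preds_b)
  cc <- as.character(preds_c)
  if (length(a) != length(b) || length(b) != length(cc)) {
    stop_kc("the three prediction vectors must have equal length.")
  }
  ab <- a == b; bc <- b == cc; ac <- a == cc
  all3 <- ab & bc
  pair <- c(a_b = sum(ab & !all3), b_c = sum(bc & !all3), a_c = sum(ac & !all3))
  names(pair) <- c(paste(names[1], names[2], sep = "_"),
                   paste(names[2], names[3], sep = "_"),
                   paste(names[1], names[3], sep = "_"))
  structure(list(n_total = length(a), all_three = sum(all3),
                 pair_only = pair,
                 none = length(a) - sum(all3) - sum(pair),
                 model_names = names),
            class = "kc_venn")
}

#' @export
print.kc_venn <- function(x, ...) {
  cat(sprintf("<kc_venn> %d eyes: all three agree %d (%.1f%%), pairs only %s, none %d\n",
              x$n_total, x$all_three, 100 * x$all_three / max(x$n_total, 1),
              paste(sprintf("%s=%d", names(x$pair_only), x$pair_only),
                    collapse = ", "),
              x$none))
  invisible(x)
}

#' @export
tidy.kc_venn <- function(x, ...) {
  tibble::tibble(
    pattern = c("all_three", names(x$pair_only), "none"),
    n = c(x$all_three, unname(x$pair_only), x$none),
    proportion = c(x$all_three, unname(x$pair_only), x$none) / x$n_total
  )
}

#' @export
autoplot.kc_venn <- function(object, ...) {
  df <- tidy(object)
  df$pattern <- factor(df$pattern, levels = df$pattern)
  ggplot2::ggplot(df, ggplot2::aes(.data$pattern, .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = "agreement pattern", y = "eyes")
}

#' Reclassification table for one true group
#'
#' Restricts held-out predictions to the eyes of one true group (optionally
#' one subclinical subtype) and tabulates the model's predicted labels —
#' e.g. what fraction of subclinical eyes a model reclassifies as healthy.
#'
#' @param per_eye Prediction tibble from [loocv_predict()].
#' @param source_group True group to restrict to.
#' @param subtype Optional subclinical subtype filter (`"fellow_eye"` or
#'   `"bilateral_suspect"`); requires `cohort`.
#' @param cohort Cohort tibble supplying `eye_id` and `skc_subtype` (needed
#'   only when `subtype` is given).
#' @return A tibble with one row per predicted class: `predicted`, `n`,
#'   `proportion`; attributes `source_group` and `n_total`.
#' @export
reclassification <- function(per_eye, source_group = "skc", subtype = NULL,
                             cohort = NULL) {
  stopifnot(source_group %in% kc_groups())
  sel <- as.character(per_eye$truth) == source_group
  if (!is.null(subtype)) {
    if (is.null(cohort)) stop_kc("`cohort` is required to filter by subtype.")
    sub <- cohort$skc_subtype[match(per_eye$eye_id, cohort$eye_id)]
    sel <- sel & !is.na(sub) & sub == subtype
  }
  if (!any(sel)) stop_kc("no eyes in the requested subgroup.")
  pred <- factor(as.character(per_eye$predicted[sel]), levels = kc_groups())
  tab <- table(pred)
  out <- tibble::tibble(predicted = names(tab), n = as.integer(tab),
                        proportion = as.integer(tab) / sum(tab))
  attr(out, "source_group") <- source_group
  attr(out, "n_total") <- sum(sel)
  out
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2 x 2 table `[[k1, n1-k1], [k2, n2-k2]]` with
#' one degree of freedom and a two-sided p-value. The continuity correction
#' is off by default (plain Pearson statistic); set `correct = TRUE` for the
#' Yates-corrected variant.
#'
#' @param k1,n1 Successes and size of the first sample.
#' @param k2,n2 Successes and size of the second sample.
#' @param correct Apply Yates continuity correction.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `prop1`, `prop2`.
#' @export
compare_proportions <- function(k1, n1, k2, n2, correct = FALSE) {
  if (n1 <= 0 || n2 <= 0 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2) {
    stop_kc("need 0 <= k <= n and n > 0 for both samples.")
  }
  m <- matrix(c(k1, n1 - k1, k2, n2 - k2), nrow = 2, byrow = TRUE)
  if (any(colSums(m) == 0)) {
    stop_kc("degenerate 2 x 2 table: a column margin is zero.")
  }
  if (k1 / n1 == k2 / n2) {
    # identical proportions: Pearson statistic is exactly 0
    return(tibble::tibble(statistic = 0, df = 1L, p_value = 1,
                          prop1 = k1 / n1, prop2 = k2 / n2))
  }
  tst <- suppressWarnings(stats::chisq.test(m, correct = correct))
  tibble::tibble(statistic = unname(tst$statistic), df = 1L,
                 p_value = tst$p.value, prop1 = k1 / n1, prop2 = k2 / n2)
}

#' Parameter contrast between two predicted subgroups
#'
#' Mirrors the classical reclassification analysis: among the eyes of one
#' true group (default: subclinical), splits by the model's predicted label
#' (default: predicted-healthy versus predicted-subclinical) and summarizes
#' each numeric parameter per subgroup (mean, SD, min, max) with a Welch
#' two-sample t-test. Central map summaries (2 mm phase retardation,
#' epithelium and Bowman's-layer thickness) are appended automatically when
#' the cohort carries maps.
#'
#' @param cohort Cohort tibble.
#' @param per_eye Prediction tibble from [loocv_predict()].
#' @param parameters Character vector of cohort columns to contrast;
#'   defaults to the key tomography indices plus the map summaries.
#' @param source_group True group to restrict to.
#' @param split_levels The two predicted labels to contrast.
#' @return A tibble with one row per parameter: per-subgroup `mean`, `sd`,
#'   `min`, `max` and `n` (suffixed `_1`/`_2`), `p_value` (Welch t-test;
#'   `NA` with `degenerate = TRUE` when a subgroup is smaller than 2 or both
#'   variances vanish).
#' @export
subgroup_contrast <- function(cohort, per_eye,
                              parameters = NULL,
                              source_group = "skc",
                              split_levels = c("healthy", "skc")) {
  stopifnot(length(split_levels) == 2)
  dat <- dplyr::inner_join(cohort, per_eye, by = "eye_id")
  dat <- dplyr::filter(dat, as.character(.data$truth) == source_group,
                       as.character(.data$predicted) %in% split_levels)
  if (is.null(parameters)) {
    parameters <- intersect(
      c("pc_BADD", "pc_IS", "pc_KISA", "pc_Kmax", "pc_TCT", "pc_CCT",
        "pc_ISV", "pc_IVA", "pc_IHA", "pc_IHD",
        "ms_AntKmax", "ms_BWKmax", "ms_CET", "ms_CCT"),
      names(dat)
    )
    if (all(c("pr_map", "epi_map", "bowman_map") %in% names(cohort))) {
      ms <- cohort_map_summaries(cohort)
      dat <- dplyr::inner_join(dat, ms, by = "eye_id")
      parameters <- c("PR_central", "ELT_central", "BLT_central", parameters)
    }
  }
  g <- factor(as.character(dat$predicted), levels = split_levels)
  if (any(table(g) == 0)) {
    stop_kc("both predicted subgroups must be nonempty.")
  }
  purrr::map_dfr(parameters, function(p) {
    v1 <- dat[[p]][g == split_levels[1]]
    v2 <- dat[[p]][g == split_levels[2]]
    degenerate <- length(v1) < 2 || length(v2) < 2 ||
      (stats::var(v1) == 0 && stats::var(v2) == 0)
    pv <- if (degenerate) NA_real_ else
      stats::t.test(v1, v2, var.equal = FALSE)$p.value
    tibble::tibble(
      parameter = p,
      n_1 = length(v1), mean_1 = mean(v1), sd_1 = stats::sd(v1),
      min_1 = min(v1), max_1 = max(v1),
      n_2 = length(v2), mean_2 = mean(v2), sd_2 = stats::sd(v2),
      min_2 = min(v2), max_2 = max(v2),
      p_value = pv, degenerate = degenerate
    )
  })
}
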