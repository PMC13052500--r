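#' Random-forest configuration
#'
#' Hyperparameters for the per-device classifiers. Defaults match the fixed
#' protocol used for all three device models: 100 trees, Gini impurity,
#' unbounded depth, node split at 2 samples, at least 1 sample per leaf.
#' (`randomForest` grows Breiman forests with Gini splitting; `nodesize`
#' maps to the minimum leaf size, and depth is unbounded by default, so the
#' remaining settings are the package's defaults by construction.)
#'
#' @param n_trees Number of trees.
#' @param min_samples_leaf Minimum samples per leaf (`nodesize`).
#' @param base_seed Base seed; each leave-one-out fold derives its own seed
#'   from this and the held-out eye's identifier, making predictions
#'   independent of row order.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(n_trees = 100, min_samples_leaf = 1, base_seed = 1) {
  stopifnot(n_trees >= 1, min_samples_leaf >= 1)
  structure(list(n_trees = n_trees, split_criterion = "gini",
                 max_depth = Inf, min_samples_split = 2,
                 min_samples_leaf = min_samples_leaf,
                 base_seed = base_seed),
            class = "rf_config")
}

feature_matrix <- function(features) {
  if (!is.data.frame(features) || !"eye_id" %in% names(features)) {
    stop_kc("`features` must be a data frame with an `eye_id` column.")
  }
  x <- as.matrix(dplyr::select(features, -"eye_id"))
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_kc("feature columns must be finite numerics.")
  }
  rownames(x) <- features$eye_id
  x
}

#' Leave-one-out cross-validated random-forest predictions
#'
#' Implements the evaluation protocol used for every device model: for each
#' eye, a forest is trained on all other eyes and predicts class
#' probabilities for the held-out eye, so every prediction is out-of-sample.
#' Each fold's forest is seeded from `(base_seed, eye_id)`, which makes the
#' result reproducible and invariant to the ordering of rows. The predicted
#' label is the probability argmax; exact ties resolve to the earliest class
#' in the fixed order (healthy, skc, kc).
#'
#' @param features Tibble: `eye_id` plus numeric feature columns (one
#'   schema; see [cohort_features()]).
#' @param labels Vector of true labels (healthy/skc/kc), aligned with
#'   `features` rows; indeterminate labels are not allowed.
#' @param config An [rf_config()].
#' @return Tibble with one row per eye: `eye_id`, `truth`, `predicted`,
#'   `p_healthy`, `p_skc`, `p_kc`.
#' @export
loocv_predict <- function(features, labels, config = rf_config()) {
  x <- feature_matrix(features)
  y <- as_group_factor(labels)
  if (length(y) != nrow(x)) stop_kc("`labels` must match `features` rows.")
  counts <- table(y)
  if (any(counts == 1)) {
    stop_kc("every class present needs at least 2 eyes for leave-one-out ",
            "training; short: ",
            paste(names(counts)[counts == 1], collapse = ", "))
  }
  n <- nrow(x)
  probs <- matrix(NA_real_, n, 3, dimnames = list(NULL, kc_groups()))
  for (i in seq_len(n)) {
    # training rows sorted by eye identifier: the fold is then a pure
    # function of the eye set, not of row order
    tr <- setdiff(seq_len(n), i)
    tr <- tr[order(features$eye_id[tr])]
    set.seed(derive_seed(config$base_seed, features$eye_id[[i]]))
    fit <- randomForest::randomForest(
      x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
      ntree = config$n_trees, nodesize = config$min_samples_leaf
    )
    p <- stats::predict(fit, x[i, , drop = FALSE], type = "prob")
    probs[i, colnames(p)] <- p[1, ]
    probs[i, setdiff(kc_groups(), colnames(p))] <- 0
  }
  pred <- kc_groups()[max.col(probs, ties.method = "first")]
  tibble::tibble(
    eye_id = features$eye_id,
    truth = y,
    predicted = factor(pred, levels = kc_groups()),
    p_healthy = probs[, "healthy"], p_skc = probs[, "skc"], p_kc = probs[, "kc"]
  )
}

#' Confusion matrix of held-out predictions
#'
#' @param per_eye Prediction tibble from [loocv_predict()].
#' @return 3 x 3 integer matrix, rows = true class, columns = predicted
#'   class, in the fixed order healthy, skc, kc.
#' @export
confusion_matrix <- function(per_eye) {
  if (NROW(per_eye) == 0) stop_kc("no predictions to tabulate.")
  t1 <- as_group_factor(per_eye$truth)
  t2 <- as_group_factor(per_eye$predicted)
  m <- table(truth = t1, predicted = t2)
  matrix(as.integer(m), 3, 3, dimnames = dimnames(m))
}

ovr_auc <- function(truth, prob, cls) {
  resp <- factor(truth == cls, levels = c(FALSE, TRUE))
  as.numeric(pROC::auc(pROC::roc(resp, prob, levels = c(FALSE, TRUE),
                                 direction = "<", quiet = TRUE)))
}

#' Classification metrics from held-out predictions
#'
#' Per-class one-vs-rest AUC (from the held-out class probabilities),
#' precision, recall and F1 (from the confusion matrix), their macro
#' averages, and overall accuracy. A class never predicted has undefined
#' precision; it is reported as 0 with a warning (and its F1 as 0), the
#' usual degenerate-case convention.
#'
#' @param per_eye Prediction tibble from [loocv_predict()].
#' @return An object of class `kc_metrics` with elements `per_class`
#'   (tibble: class, auc, precision, recall, f1, n) and `averaged` (named
#'   list: auc, precision, recall, f1 — macro means — and accuracy).
#' @export
compute_metrics <- function(per_eye) {
  cm <- confusion_matrix(per_eye)
  truth <- as_group_factor(per_eye$truth)
  if (any(table(truth) == 0)) {
    stop_kc("every class must be present in the truth to compute per-class metrics.")
  }
  probs <- cbind(healthy = per_eye$p_healthy, skc = per_eye$p_skc,
                 kc = per_eye$p_kc)
  per_class <- purrr::map_dfr(kc_groups(), function(cls) {
    tp <- cm[cls, cls]
    pred_n <- sum(cm[, cls])
    true_n <- sum(cm[cls, ])
    if (pred_n == 0) {
      rlang::warn(paste0("class `", cls, "` was never predicted; precision set to 0."))
      prec <- 0
    } else {
      prec <- tp / pred_n
    }
    rec <- tp / true_n
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble::tibble(class = cls,
                   auc = ovr_auc(truth, probs[, cls], cls),
                   precision = prec, recall = rec, f1 = f1, n = true_n)
  })
  averaged <- list(
    auc = mean(per_class$auc), precision = mean(per_class$precision),
    recall = mean(per_class$recall), f1 = mean(per_class$f1),
    accuracy = sum(diag(cm)) / sum(cm)
  )
  structure(list(per_class = per_class, averaged = averaged),
            class = "kc_metrics")
}

#' @export
print.kc_metrics <- function(x, ...) {
  a <- x$averaged
  cat(sprintf("<kc_metrics> macro AUC %.3f, precision %.3f, recall %.3f, F1 %.3f, accuracy %.3f\n",
              a$auc, a$precision, a$recall, a$f1, a$accuracy))
  print(x$per_class)
  invisible(x)
}

#' Fit and evaluate one device model
#'
#' Convenience wrapper tying the pieces together: leave-one-out random
#' forest on one device's feature table, confusion matrix and metric set.
#'
#' @param features Feature tibble (`eye_id` + feature columns).
#' @param labels True labels aligned with `features`.
#' @param name Model name (e.g. `"psoct"`).
#' @param config An [rf_config()].
#' @return An object of class `kc_model_run`: `name`, `per_eye`,
#'   `confusion`, `metrics`.
#' @export
run_device_model <- function(features, labels, name = "model",
                             config = rf_config()) {
  per_eye <- loocv_predict(features, labels, config)
  structure(list(name = name, per_eye = per_eye,
                 confusion = confusion_matrix(per_eye),
                 metrics = compute_metrics(per_eye)),
            class = "kc_model_run")
}

#' @export
print.kc_model_run <- function(x, ...) {
  cat(sprintf("<kc_model_run> %s: %d eyes\n", x$name, nrow(x$per_eye)))
  print(x$confusion)
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.kc_model_run <- function(x, ...) {
  dplyr::mutate(x$metrics$per_class, model = x$name, .before = 1)
}

#' @export
glance.kc_model_run <- function(x, ...) {
  a <- x$metrics$averaged
  tibble::tibble(model = x$name, n = nrow(x$per_eye), auc = a$auc,
                 precision = a$precision, recall = a$recall, f1 = a$f1,
                 accuracy = a$accuracy)
}

#' @export
autoplot.kc_model_run <- function(object, ...) {
  df <- tibble::as_tibble(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(kc_groups())) +
    ggplot2::labs(title = object$name, x = "predicted", y = "true")
}

#' Paired comparison of two models' one-vs-rest ROC curves
#'
#' Compares the class-specific discrimination of two models evaluated on the
#' same eyes, using the correlated (paired) nonparametric test on the
#' difference of one-vs-rest AUCs computed from the held-out probability
#' scores (DeLong's method). Identical score rankings give a zero statistic
#' and p = 1.
#'
#' @param run_a,run_b `kc_model_run` objects (or prediction tibbles) over
#'   the same eye set.
#' @param group Class whose one-vs-rest ROC is compared.
#' @return One-row tibble: `group`, `auc_a`, `auc_b`, `statistic`,
#'   `p_value`, `method`.
#' @export
compare_model_rocs <- function(run_a, run_b, group = c("healthy", "skc", "kc")) {
  group <- match.arg(group)
  pa <- if (inherits(run_a, "kc_model_run")) run_a$per_eye else run_a
  pb <- if (inherits(run_b, "kc_model_run")) run_b$per_eye else run_b
  if (!setequal(pa$eye_id, pb$eye_id) || anyDuplicated(pa$eye_id)) {
    stop_kc("the two runs must cover exactly the same eyes.")
  }
  pb <- pb[match(pa$eye_id, pb$eye_id), ]
  pcol <- paste0("p_", group)
  resp <- factor(as_group_factor(pa$truth) == group, levels = c(FALSE, TRUE))
  roc_a <- pROC::roc(resp, pa[[pcol]], levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
  roc_b <- pROC::roc(resp, pb[[pcol]], levels = c(FALSE, TRUE),
                     direction = "<", quiet = TRUE)
  auc_a <- as.numeric(pROC::auc(roc_a))
  auc_b <- as.numeric(pROC::auc(roc_b))
  tst <- tryCatch(
    suppressWarnings(pROC::roc.test(roc_a, roc_b, paired = TRUE,
                                    method = "delong")),
    error = function(e) NULL
  )
  stat <- if (!is.null(tst)) unname(tst$statistic) else NaN
  pval <- if (!is.null(tst)) tst$p.value else NaN
  if (!is.finite(stat) && isTRUE(all.equal(auc_a, auc_b))) {
    # identical placements: zero variance of the AUC difference
    stat <- 0
    pval <- 1
  }
  tibble::tibble(group = group, auc_a = auc_a, auc_b = auc_b,
                 statistic = stat, p_value = pval,
                 method = "paired DeLong one-vs-rest AUC difference")
}
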