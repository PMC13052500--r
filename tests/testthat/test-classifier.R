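test_that("configuration defaults match the fixed training protocol", {
  cfg <- rf_config()
  expect_equal(cfg$n_trees, 100)
  expect_equal(cfg$split_criterion, "gini")
  expect_equal(cfg$max_depth, Inf)
  expect_equal(cfg$min_samples_split, 2)
  expect_equal(cfg$min_samples_leaf, 1)
})

test_that("leave-one-out returns one held-out prediction per eye", {
  d <- gaussian_features(8, delta = 3, seed = 2)
  pe <- loocv_predict(d$features, d$labels)
  expect_equal(nrow(pe), 24)
  expect_identical(pe$eye_id, d$features$eye_id)
  expect_equal(pe$p_healthy + pe$p_skc + pe$p_kc, rep(1, 24),
               tolerance = 1e-9)
  # predicted label is the probability argmax
  probs <- cbind(pe$p_healthy, pe$p_skc, pe$p_kc)
  expect_identical(as.integer(pe$predicted),
                   max.col(probs, ties.method = "first"))
})

test_that("widely separated classes are classified perfectly", {
  # two classes, one decisive feature, n = 40
  set.seed(9)
  x <- tibble::tibble(eye_id = sprintf("e%02d", 1:40),
                      f1 = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)),
                      f2 = rnorm(40))
  y <- rep(c("healthy", "kc"), each = 20)
  pe <- loocv_predict(x, y)
  expect_equal(mean(pe$predicted == pe$truth), 1.0)
})

test_that("label permutation drives accuracy to chance", {
  d <- gaussian_features(10, delta = 4, seed = 3)
  set.seed(31)
  accs <- vapply(1:5, function(r) {
    yp <- sample(as.character(d$labels))
    pe <- loocv_predict(d$features, yp, rf_config(base_seed = r))
    mean(pe$predicted == pe$truth)
  }, numeric(1))
  expect_gt(mean(accs), 1 / 3 - 0.2)
  expect_lt(mean(accs), 1 / 3 + 0.2)
})

test_that("predictions are reproducible and invariant to row order", {
  d <- gaussian_features(8, delta = 1, seed = 4)
  pe1 <- loocv_predict(d$features, d$labels, rf_config(base_seed = 7))
  pe2 <- loocv_predict(d$features, d$labels, rf_config(base_seed = 7))
  expect_identical(pe1, pe2)

  set.seed(5)
  perm <- sample(nrow(d$features))
  pe3 <- loocv_predict(d$features[perm, ], d$labels[perm],
                       rf_config(base_seed = 7))
  pe3 <- pe3[match(pe1$eye_id, pe3$eye_id), ]
  expect_equal(pe1$p_healthy, pe3$p_healthy)
  expect_identical(as.character(pe1$predicted), as.character(pe3$predicted))
})

test_that("singleton classes are refused", {
  d <- gaussian_features(5, delta = 1, seed = 6)
  labs <- as.character(d$labels)
  labs[labs == "kc"] <- "healthy"
  labs[1] <- "kc"
  expect_error(loocv_predict(d$features, labs), "at least 2")
})

test_that("metrics follow the hand-computed confusion arithmetic", {
  # confusion [[8,2,0],[1,9,0],[0,0,10]]
  truth <- rep(c("healthy", "skc", "kc"), each = 10)
  pred <- c(rep("healthy", 8), rep("skc", 2),
            "healthy", rep("skc", 9), rep("kc", 10))
  p <- matrix(0.1, 30, 3, dimnames = list(NULL, c("healthy", "skc", "kc")))
  for (i in 1:30) p[i, pred[i]] <- 0.8
  pe <- tibble::tibble(eye_id = as.character(1:30), truth = truth,
                       predicted = pred, p_healthy = p[, 1], p_skc = p[, 2],
                       p_kc = p[, 3])
  m <- compute_metrics(pe)
  cm <- confusion_matrix(pe)
  expect_equal(unname(cm), rbind(c(8L, 2L, 0L), c(1L, 9L, 0L), c(0L, 0L, 10L)))
  pc <- m$per_class
  expect_equal(pc$recall[pc$class == "healthy"], 0.8)
  expect_equal(pc$precision[pc$class == "healthy"], 8 / 9)
  expect_equal(pc$precision[pc$class == "skc"], 9 / 11)
  expect_equal(pc$recall[pc$class == "skc"], 0.9)
  expect_equal(pc$f1[pc$class == "healthy"],
               2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  expect_equal(m$averaged$accuracy, 27 / 30)
  # macro values are the arithmetic means of the per-class values
  expect_equal(m$averaged$precision, mean(pc$precision))
  expect_equal(m$averaged$f1, mean(pc$f1))
  expect_equal(m$averaged$auc, mean(pc$auc))
})

test_that("perfect confident predictions give saturated metrics", {
  truth <- rep(kc_groups(), each = 4)
  p <- matrix(0.05, 12, 3, dimnames = list(NULL, kc_groups()))
  for (i in 1:12) p[i, truth[i]] <- 0.9
  pe <- tibble::tibble(eye_id = as.character(1:12), truth = truth,
                       predicted = truth, p_healthy = p[, 1],
                       p_skc = p[, 2], p_kc = p[, 3])
  m <- compute_metrics(pe)
  expect_equal(m$averaged$accuracy, 1.0)
  expect_equal(m$averaged$f1, 1.0)
  expect_equal(m$per_class$auc, rep(1.0, 3))
  expect_equal(unname(confusion_matrix(pe)), diag(c(4L, 4L, 4L)))
})

test_that("a never-predicted class gets zero precision with a warning", {
  truth <- rep(kc_groups(), each = 4)
  pred <- rep(c("healthy", "healthy", "kc"), each = 4)
  pe <- tibble::tibble(eye_id = as.character(1:12), truth = truth,
                       predicted = pred,
                       p_healthy = ifelse(pred == "healthy", 0.9, 0.05),
                       p_skc = 0.05,
                       p_kc = ifelse(pred == "kc", 0.9, 0.05))
  expect_warning(m <- compute_metrics(pe), "never predicted")
  expect_equal(m$per_class$precision[m$per_class$class == "skc"], 0)
  expect_equal(m$per_class$f1[m$per_class$class == "skc"], 0)
})

test_that("confusion bookkeeping counts swaps and rejects empty input", {
  truth <- rep(kc_groups(), each = 3)
  pe <- tibble::tibble(eye_id = as.character(1:9), truth = truth,
                       predicted = truth,
                       p_healthy = 1, p_skc = 0, p_kc = 0)
  base <- confusion_matrix(pe)
  pe2 <- pe
  pe2$predicted[c(1, 4)] <- pe$predicted[c(4, 1)]  # swap two eyes
  sw <- confusion_matrix(pe2)
  expect_equal(sum(abs(sw - base)), 4)  # two off-diagonal increments + decrements
  expect_equal(sum(sw), 9)
  expect_error(confusion_matrix(pe[0, ]), "no predictions")
})

test_that("accuracy falls monotonically as class separation shrinks", {
  deltas <- seq(0.2, 3.8, length.out = 10)
  acc <- vapply(seq_along(deltas), function(i) {
    mean(vapply(1:10, function(s) {
      d <- gaussian_features(6, delta = deltas[i], p = 3,
                             seed = 100 * i + s)
      pe <- loocv_predict(d$features, d$labels,
                          rf_config(n_trees = 50, base_seed = s))
      mean(pe$predicted == pe$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_gte(suppressWarnings(cor(deltas, acc, method = "spearman")), 0.8)
})

test_that("paired ROC comparison detects separability differences and honors rank invariance", {
  d <- gaussian_features(8, delta = 2, seed = 8)
  pe <- loocv_predict(d$features, d$labels)
  run <- structure(list(name = "m", per_eye = pe), class = "kc_model_run")

  self <- compare_model_rocs(run, run, "kc")
  expect_equal(self$auc_a, self$auc_b)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  # strictly monotone rescaling of the scores keeps the ROC identical
  pe2 <- pe
  pe2$p_kc <- sqrt(pe2$p_kc)
  r2 <- compare_model_rocs(pe, pe2, "kc")
  expect_equal(r2$auc_a, r2$auc_b)
  expect_equal(r2$p_value, 1)

  # power against a genuinely weaker model (n = 200 eyes)
  hits <- 0
  set.seed(12)
  for (r in 1:100) {
    truth <- rep(c("kc", "healthy"), each = 100)
    sig <- as.numeric(truth == "kc")
    a <- tibble::tibble(eye_id = as.character(1:200), truth = truth,
                        predicted = truth,
                        p_kc = plogis(4 * sig - 2 + rnorm(200, 0, 0.8)),
                        p_healthy = 0, p_skc = 0)
    a$p_healthy <- 1 - a$p_kc
    b <- a
    b$p_kc <- plogis(0.6 * sig - 0.3 + rnorm(200, 0, 1.2))
    b$p_healthy <- 1 - b$p_kc
    out <- compare_model_rocs(a, b, "kc")
    hits <- hits + (out$p_value < 0.05)
  }
  expect_gte(hits, 90)

  # mismatched eye sets are refused
  pe3 <- pe; pe3$eye_id[1] <- "other"
  expect_error(compare_model_rocs(pe, pe3, "kc"), "same eyes")
})

test_that("model runs serialize to prediction, confusion and metric files", {
  d <- gaussian_features(6, delta = 3, seed = 10)
  run <- run_device_model(d$features, d$labels, name = "demo")
  dir <- withr::local_tempdir()
  write_model_run(run, dir)
  pred <- readr::read_csv(file.path(dir, "demo_predictions.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(pred), 18)
  met <- jsonlite::fromJSON(file.path(dir, "demo_metrics.json"))
  expect_equal(met$averaged$accuracy, run$metrics$averaged$accuracy)
  cm <- readr::read_csv(file.path(dir, "demo_confusion.csv"),
                        show_col_types = FALSE)
  expect_equal(sum(cm[, -1]), 18)
  write_agreement(list(a = run, b = run, c = run), dir)
  ag <- jsonlite::fromJSON(file.path(dir, "agreement.json"))
  expect_equal(ag$all_three, 18)
  rc <- readr::read_csv(file.path(dir, "reclass_skc_a.csv"),
                        show_col_types = FALSE)
  expect_equal(sum(rc$n), 6)
})
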