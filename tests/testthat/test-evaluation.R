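test_that("stratified folds preserve class proportions to within one row", {
  labels <- rep(c("abnormal", "healthy"), c(1533, 342))
  cfg <- cv_config(n_folds = 10, seed = 4)
  folds <- stratified_folds(labels, cfg)
  # partition property
  expect_identical(sort(unique(folds)), 1:10)
  expect_identical(length(folds), 1875L)
  tab <- table(folds, labels)
  expect_true(all(tab[, "abnormal"] %in% 153:154))
  expect_true(all(tab[, "healthy"] %in% 34:35))
  expect_identical(folds, stratified_folds(labels, cfg))
  expect_false(identical(folds, stratified_folds(labels, cv_config(n_folds = 10, seed = 5))))
  expect_error(stratified_folds(rep(c("a", "h"), c(100, 5)),
                                cv_config(n_folds = 10)), ">= 10")
})

test_that("metrics reproduce the degenerate and near-perfect reference cases", {
  truth <- rep(c("abnormal", "healthy"), c(170, 38))
  # majority-only predictor with healthy (minority) positive
  m <- compute_metrics(confusion_matrix(truth, rep("abnormal", 208), "healthy"))
  expect_equal(m$accuracy, 100 * 170 / 208, tolerance = 1e-10)
  expect_equal(m$accuracy, 81.7, tolerance = 0.05)
  expect_identical(m$recall, 0)
  expect_identical(m$precision, 0)
  expect_true(all(c("precision", "f_score") %in% m$flags))
  # perfect predictor
  p <- compute_metrics(confusion_matrix(truth, truth, "healthy"))
  expect_equal(unlist(p[c("accuracy", "recall", "precision", "f_score")]),
               c(accuracy = 100, recall = 100, precision = 100, f_score = 100))
  # 98.9% of 170 abnormal and 60.5% of 38 healthy correct
  cm <- structure(list(tn = round(0.989 * 170), fp = 170 - round(0.989 * 170),
                       tp = round(0.605 * 38), fn = 38 - round(0.605 * 38),
                       positive = "healthy"), class = "confusion_matrix")
  acc <- compute_metrics(cm)$accuracy
  expect_gte(acc, 91.8)
  expect_lte(acc, 92.0)
})

test_that("ROC staircase has the right endpoints, symmetry and area", {
  labels <- rep(c("n", "p"), c(50, 50))
  perfect <- c(runif(50, 0, 0.4), runif(50, 0.6, 1))
  pts <- roc_points(perfect, labels, "p")
  expect_identical(pts$fpr[1], 0)
  expect_identical(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(any(pts$fpr == 0 & pts$tpr == 1))  # passes the ideal corner
  expect_identical(attr(pts, "auc"), 1)
  # sign reversal maps the area A to 1 - A
  set.seed(6)
  sc <- rnorm(100)
  a <- attr(roc_points(sc, labels, "p"), "auc")
  expect_equal(attr(roc_points(-sc, labels, "p"), "auc"), 1 - a,
               tolerance = 1e-10)
  # label-independent scores give area ~ 0.5 at large n
  set.seed(7)
  big <- rep(c("n", "p"), each = 2000)
  expect_lt(abs(attr(roc_points(rnorm(4000), big, "p"), "auc") - 0.5), 0.05)
  expect_error(roc_points(c(1, 2), c("p", "p"), "p"), "both classes")
  expect_error(roc_points(c(NA, 1), c("n", "p"), "p"), "finite")
})

test_that("staircase area agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  labels <- sample(rep(c("n", "p"), c(70, 40)))
  scores <- rnorm(110) + 0.8 * (labels == "p")
  a <- attr(roc_points(scores, labels, "p"), "auc")
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(labels, scores,
                                                         levels = c("n", "p"),
                                                         direction = "<"))))
  expect_equal(a, ref, tolerance = 1e-10)
})

test_that("the harness confines SMOTE to training rows in every fold", {
  fm <- toy_feature_matrix(n_min = 25, n_maj = 100, seed = 9, shift = 1)
  cfg <- cv_config(n_folds = 5, seed = 3, apply_smote = TRUE,
                   smote_cfg = smote_config(seed = 8))
  rep <- run_experiment(fm, "cart", cfg)
  folds_df <- rep$results$cart$folds
  # synthetic rows present for training, never in any test fold
  expect_true(all(folds_df$n_train_synthetic > 0))
  expect_true(all(folds_df$n_test_synthetic == 0))
  # every original row is tested exactly once across folds
  expect_identical(sum(folds_df$n_test), nrow(fm$x))
  tot <- rep$results$cart$confusion
  expect_identical(tot$tn + tot$fp + tot$fn + tot$tp, nrow(fm$x))
  # pre-oversampled input is refused outright
  oversampled <- smote_oversample(fm, smote_config(seed = 1))
  expect_error(run_experiment(oversampled, "cart", cfg), "synthetic")
})

test_that("reports carry both positive-class conventions and determinism", {
  fm <- toy_feature_matrix(n_min = 30, n_maj = 80, seed = 2, shift = 1.2)
  cfg <- cv_config(n_folds = 5, seed = 13)
  r1 <- run_experiment(fm, c("cart", "et"), cfg)
  r2 <- run_experiment(fm, c("cart", "et"), cfg)
  expect_identical(r1, r2)
  m <- r1$results$et
  expect_true(all(unlist(m$mean_metrics) >= 0 & unlist(m$mean_metrics) <= 100))
  expect_true(all(c("recall_alt", "precision_alt") %in% names(m$folds)))
  # the two conventions describe the same pooled predictions
  expect_identical(m$confusion$tp, m$confusion_alt$tn)
  expect_identical(m$confusion$fp, m$confusion_alt$fn)
  expect_error(run_experiment(fm, "mystery", cfg), "unknown classifiers")
})

test_that("reports serialise to JSON and CSV", {
  fm <- toy_feature_matrix(n_min = 30, n_maj = 80, seed = 2, shift = 1.2)
  rep <- run_experiment(fm, "cart", cv_config(n_folds = 5, seed = 13))
  dir <- withr::local_tempdir()
  save_report(rep, dir)
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_true("cart" %in% names(js))
  expect_equal(js$cart$auc, rep$results$cart$auc, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "roc_cart.csv")))
  expect_true(file.exists(file.path(dir, "confusion_cart.csv")))
})

test_that("every registered classifier fits and scores a small problem", {
  fm <- toy_feature_matrix(n_min = 25, n_maj = 50, seed = 5, shift = 3)
  cfg <- cv_config(n_folds = 2, seed = 7)
  for (clf in available_classifiers()) {
    rep <- run_experiment(fm, clf, cfg)
    res <- rep$results[[clf]]
    expect_identical(res$failures, character(0), label = clf)
    # well-separated classes: every learner should beat chance easily
    expect_gt(res$auc, 0.9, label = clf)
  }
})
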