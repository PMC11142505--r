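#' Cross-validation configuration
#'
#' @param n_folds number of stratified folds (default 10).
#' @param seed integer seed for fold shuffling and classifier fits.
#' @param apply_smote oversample the training rows of each fold with SMOTE
#'   (never the test rows).
#' @param smote_cfg a [smote_config()].
#' @param positive_class class treated as positive for the headline metric
#'   set (default `"healthy"`, the minority class); metrics under the
#'   opposite convention are always reported alongside.
#' @return list of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, seed = 1, apply_smote = FALSE,
                      smote_cfg = smote_config(),
                      positive_class = c("healthy", "abnormal")) {
  assert_scalar_num(n_folds, "n_folds", lower = 2)
  structure(
    list(n_folds = as.integer(n_folds), seed = as.integer(seed),
         apply_smote = isTRUE(apply_smote), smote_cfg = smote_cfg,
         positive_class = match.arg(positive_class)),
    class = "cv_config"
  )
}

#' Stratified fold assignment
#'
#' Partitions row indices into `n_folds` disjoint test sets such that the
#' per-class counts across folds differ by at most one - every fold keeps
#' the class proportions of the full data. Shuffling is seeded.
#'
#' @param labels per-row class labels.
#' @param cfg a [cv_config()] (or anything with `n_folds` and `seed`).
#' @return integer vector of fold ids (1..n_folds), one per row.
#' @export
stratified_folds <- function(labels, cfg = cv_config()) {
  labels <- as.character(labels)
  k <- cfg$n_folds
  counts <- table(labels)
  if (any(counts < k)) {
    stop(sprintf("every class needs >= %d rows for %d folds", k, k),
         call. = FALSE)
  }
  folds <- integer(length(labels))
  with_seed(cfg$seed, {
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Binary confusion matrix
#'
#' @param truth,predicted per-row class labels.
#' @param positive the positive class.
#' @return list of class `confusion_matrix` with integer counts `tn`,
#'   `fp`, `fn`, `tp`.
#' @export
confusion_matrix <- function(truth, predicted, positive) {
  truth_pos <- as.character(truth) == positive
  pred_pos <- as.character(predicted) == positive
  structure(
    list(tn = sum(!truth_pos & !pred_pos), fp = sum(!truth_pos & pred_pos),
         fn = sum(truth_pos & !pred_pos), tp = sum(truth_pos & pred_pos),
         positive = positive),
    class = "confusion_matrix"
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(c("actual -", "actual +"),
                              c("pred -", "pred +")))
  cat(sprintf("<confusion_matrix> positive = %s\n", x$positive))
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, recall (sensitivity to the positive class), precision and
#' F-score, reported in percent. A zero denominator (e.g. a degenerate
#' classifier that never predicts the positive class) yields 0 for the
#' affected metric and sets the corresponding flag instead of propagating
#' `NaN`.
#'
#' @param cm a [confusion_matrix()].
#' @return list with `accuracy`, `recall`, `precision`, `f_score` (percent)
#'   and a character vector `flags` naming any zero-denominator metrics.
#' @export
#' @examples
#' cm <- confusion_matrix(rep(c("a", "h"), c(170, 38)),
#'                        rep("a", 208), positive = "h")
#' compute_metrics(cm)$accuracy  # 81.7
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tn + cm$fp + cm$fn + cm$tp
  if (n < 1) stop("empty confusion matrix", call. = FALSE)
  flags <- character(0)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      return(0)
    }
    num / den
  }
  recall <- safe_div(cm$tp, cm$tp + cm$fn, "recall")
  precision <- safe_div(cm$tp, cm$tp + cm$fp, "precision")
  f_score <- if (precision + recall == 0) {
    flags <- c(flags, "f_score")
    0
  } else 2 * precision * recall / (precision + recall)
  list(accuracy = 100 * (cm$tp + cm$tn) / n, recall = 100 * recall,
       precision = 100 * precision, f_score = 100 * f_score, flags = flags)
}

#' ROC curve points by threshold sweep
#'
#' Sweeps the decision threshold over the unique scores (ties grouped) and
#' returns the monotone staircase of (false positive rate, true positive
#' rate) points from (0, 0) to (1, 1).
#'
#' @param scores finite numeric positive-class scores.
#' @param labels per-row class labels; both classes must be present.
#' @param positive the positive class.
#' @return data frame with columns `fpr` and `tpr`; attribute `"auc"`
#'   holds the trapezoidal area under the curve.
#' @export
roc_points <- function(scores, labels, positive) {
  labels <- as.character(labels)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- is_pos[ord]
  grp <- cumsum(c(TRUE, diff(s) != 0))  # tie groups share a threshold
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(fpr = c(0, fp[last] / n_neg, 1),
                    tpr = c(0, tp[last] / n_pos, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  attr(pts, "auc") <- auc
  pts
}

# ---- classifier registry ---------------------------------------------------
# Off-the-shelf learners behind a uniform fit/score interface. Defaults
# follow the study grid's hyperparameter table where the R learner exposes
# the equivalent knob; scores are positive-class probabilities (SVM uses
# the decision value mapped through a logistic for ranking purposes).

fit_factor <- function(y, positive) factor(y, levels = c(setdiff(unique(y), positive), positive))

classifier_registry <- function() {
  tree_ctrl <- rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                    xval = 0, maxdepth = 30)
  list(
    id3 = list(
      fit = function(x, y, positive, seed) {
        df <- data.frame(x, .y = fit_factor(y, positive), check.names = FALSE)
        rpart::rpart(.y ~ ., df, method = "class",
                     parms = list(split = "information"), control = tree_ctrl)
      },
      score = function(model, x, positive) {
        stats::predict(model, data.frame(x, check.names = FALSE))[, positive]
      }),
    cart = list(
      fit = function(x, y, positive, seed) {
        df <- data.frame(x, .y = fit_factor(y, positive), check.names = FALSE)
        rpart::rpart(.y ~ ., df, method = "class",
                     parms = list(split = "gini"), control = tree_ctrl)
      },
      score = function(model, x, positive) {
        stats::predict(model, data.frame(x, check.names = FALSE))[, positive]
      }),
    bagging = list(
      fit = function(x, y, positive, seed) {
        with_seed(seed, randomForest::randomForest(
          x, fit_factor(y, positive), ntree = 10, mtry = ncol(x)))
      },
      score = function(model, x, positive) {
        stats::predict(model, x, type = "prob")[, positive]
      }),
    rf = list(
      fit = function(x, y, positive, seed) {
        with_seed(seed, randomForest::randomForest(
          x, fit_factor(y, positive), ntree = 100,
          mtry = max(1, floor(sqrt(ncol(x))))))
      },
      score = function(model, x, positive) {
        stats::predict(model, x, type = "prob")[, positive]
      }),
    et = list(
      fit = function(x, y, positive, seed) {
        df <- data.frame(x, .y = fit_factor(y, positive), check.names = FALSE)
        ranger::ranger(.y ~ ., df, num.trees = 100, splitrule = "extratrees",
                       num.random.splits = 1, replace = FALSE,
                       sample.fraction = 1,
                       mtry = max(1, floor(sqrt(ncol(x)))),
                       probability = TRUE, seed = seed, num.threads = 1)
      },
      score = function(model, x, positive) {
        stats::predict(model, data.frame(x, check.names = FALSE),
                       num.threads = 1)$predictions[, positive]
      }),
    gbc = list(
      fit = function(x, y, positive, seed) {
        lab <- as.integer(as.character(y) == positive)
        dtrain <- xgboost::xgb.DMatrix(as.matrix(x), label = lab)
        with_seed(seed, xgboost::xgb.train(
          params = list(objective = "binary:logistic", eta = 0.1,
                        max_depth = 3, nthread = 1),
          data = dtrain, nrounds = 100, verbose = 0))
      },
      score = function(model, x, positive) {
        stats::predict(model, xgboost::xgb.DMatrix(as.matrix(x)))
      }),
    svm = list(
      fit = function(x, y, positive, seed) {
        with_seed(seed, e1071::svm(x, fit_factor(y, positive),
                                   kernel = "radial", cost = 1, scale = TRUE,
                                   probability = TRUE))
      },
      score = function(model, x, positive) {
        pr <- attr(stats::predict(model, x, probability = TRUE), "probabilities")
        pr[, positive]
      }),
    mlp = list(
      fit = function(x, y, positive, seed) {
        # single hidden layer of 100 units on standardised inputs
        mu <- colMeans(x)
        sds <- apply(x, 2, stats::sd)
        sds[sds == 0] <- 1
        xs <- sweep(sweep(x, 2, mu), 2, sds, "/")
        net <- with_seed(seed, nnet::nnet(
          xs, class.ind2(fit_factor(y, positive)), size = 100, maxit = 200,
          decay = 1e-4, MaxNWts = 50000, trace = FALSE, softmax = TRUE))
        list(net = net, mu = mu, sds = sds,
             levels = levels(fit_factor(y, positive)))
      },
      score = function(model, x, positive) {
        xs <- sweep(sweep(x, 2, model$mu), 2, model$sds, "/")
        stats::predict(model$net, xs)[, positive]
      })
  )
}

# two-column class indicator for nnet's softmax interface
class.ind2 <- function(f) {
  m <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  m[cbind(seq_along(f), as.integer(f))] <- 1
  m
}

#' Names of the available classifiers
#'
#' `"id3"` (entropy decision tree), `"cart"` (Gini tree), `"bagging"`,
#' `"gbc"` (gradient boosting), `"rf"` (random forest), `"svm"` (RBF
#' kernel), `"mlp"` (single-hidden-layer perceptron) and `"et"` (extremely
#' randomised trees).
#'
#' @return character vector.
#' @export
available_classifiers <- function() names(classifier_registry())

#' Run a leakage-safe stratified cross-validation experiment
#'
#' For every fold: the model is fit on the training rows only; when
#' `cfg$apply_smote` is on, SMOTE runs on the training rows *after* the
#' split, so synthetic rows can never reach a test fold. Test-fold scores
#' are pooled across folds for the confusion matrix and ROC curve;
#' per-fold metrics are macro-averaged. Metrics are reported under both
#' positive-class conventions.
#'
#' @param mat an [feature_matrix()] of original (non-synthetic) rows.
#' @param classifiers character vector of names from
#'   [available_classifiers()].
#' @param cfg a [cv_config()].
#' @return object of class `emg_eval_report`: per classifier a list with
#'   `folds` (per-fold metric data frame), `mean_metrics`,
#'   `mean_metrics_alt` (opposite positive class), pooled
#'   `confusion`/`confusion_alt`, `roc` points and `auc`; plus `metadata`
#'   capturing the full configuration and seeds.
#' @export
run_experiment <- function(mat, classifiers = "et", cfg = cv_config()) {
  stopifnot(inherits(mat, "emg_features"), inherits(cfg, "cv_config"))
  if (any(mat$synthetic)) {
    stop("input matrix already contains synthetic rows; SMOTE belongs inside the harness",
         call. = FALSE)
  }
  registry <- classifier_registry()
  unknown <- setdiff(classifiers, names(registry))
  if (length(unknown)) {
    stop(sprintf("unknown classifiers: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  pos <- cfg$positive_class
  neg <- setdiff(unique(mat$label), pos)
  if (length(neg) != 1L) stop("labels must form exactly two classes", call. = FALSE)
  folds <- stratified_folds(mat$label, cfg)
  fit_seeds <- derive_seeds(cfg$seed, cfg$n_folds * length(classifiers))
  results <- list()
  for (ci in seq_along(classifiers)) {
    name <- classifiers[ci]
    spec <- registry[[name]]
    fold_rows <- list()
    pooled_scores <- numeric(0)
    pooled_pred <- character(0)
    pooled_truth <- character(0)
    failures <- character(0)
    for (f in seq_len(cfg$n_folds)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      train <- feature_matrix(mat$x[train_idx, , drop = FALSE],
                              label = mat$label[train_idx],
                              subject_id = mat$subject_id[train_idx])
      if (cfg$apply_smote) {
        sm_cfg <- cfg$smote_cfg
        sm_cfg$seed <- cfg$smote_cfg$seed + f  # per-fold stream
        train <- smote_oversample(train, sm_cfg)
      }
      stopifnot(!any(mat$synthetic[test_idx]))  # leakage contract
      seed_f <- fit_seeds[(ci - 1L) * cfg$n_folds + f]
      res <- tryCatch({
        model <- spec$fit(train$x, train$label, pos, seed_f)
        scores <- spec$score(model, mat$x[test_idx, , drop = FALSE], pos)
        pred <- ifelse(scores >= 0.5, pos, neg)
        list(scores = scores, pred = pred)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("fold %d: %s", f, conditionMessage(res)))
        next
      }
      truth <- mat$label[test_idx]
      cm <- confusion_matrix(truth, res$pred, pos)
      cm_alt <- confusion_matrix(truth, res$pred, neg)
      m <- compute_metrics(cm)
      m_alt <- compute_metrics(cm_alt)
      fold_rows[[length(fold_rows) + 1L]] <- data.frame(
        fold = f, n_test = length(test_idx),
        n_train_synthetic = sum(train$synthetic),
        n_test_synthetic = sum(mat$synthetic[test_idx]),
        accuracy = m$accuracy, recall = m$recall, precision = m$precision,
        f_score = m$f_score, recall_alt = m_alt$recall,
        precision_alt = m_alt$precision, f_score_alt = m_alt$f_score)
      pooled_scores <- c(pooled_scores, res$scores)
      pooled_pred <- c(pooled_pred, res$pred)
      pooled_truth <- c(pooled_truth, truth)
    }
    folds_df <- do.call(rbind, fold_rows)
    pooled_cm <- confusion_matrix(pooled_truth, pooled_pred, pos)
    roc <- roc_points(pooled_scores, pooled_truth, pos)
    results[[name]] <- list(
      classifier = name, folds = folds_df,
      mean_metrics = colMeans(folds_df[, c("accuracy", "recall", "precision",
                                           "f_score")]),
      mean_metrics_alt = colMeans(folds_df[, c("recall_alt", "precision_alt",
                                               "f_score_alt")]),
      confusion = pooled_cm,
      confusion_alt = confusion_matrix(pooled_truth, pooled_pred, neg),
      pooled_metrics = compute_metrics(pooled_cm),
      roc = roc, auc = attr(roc, "auc"), failures = failures)
  }
  structure(
    list(results = results,
         metadata = list(cv = cfg, classifiers = classifiers, folds = folds,
                         positive_class = pos, n_rows = nrow(mat$x),
                         class_counts = as.list(table(mat$label)),
                         smote = cfg$apply_smote,
                         fit_seeds = fit_seeds)),
    class = "emg_eval_report"
  )
}

#' @export
print.emg_eval_report <- function(x, ...) {
  cat(sprintf("<emg_eval_report> %d rows (%s), %d-fold CV, SMOTE %s, positive = %s\n",
              x$metadata$n_rows,
              paste(sprintf("%s: %d", names(x$metadata$class_counts),
                            unlist(x$metadata$class_counts)), collapse = ", "),
              x$metadata$cv$n_folds,
              if (x$metadata$smote) "on" else "off",
              x$metadata$positive_class))
  for (r in x$results) {
    mm <- r$mean_metrics
    cat(sprintf("  %-8s acc %5.1f  recall %5.1f  precision %5.1f  F %5.1f  AUROC %.3f\n",
                r$classifier, mm["accuracy"], mm["recall"], mm["precision"],
                mm["f_score"], r$auc))
  }
  invisible(x)
}

#' Serialise an evaluation report to JSON and CSV
#'
#' Writes `report.json` (metrics, configuration, seeds), one confusion
#' matrix CSV and one ROC point CSV per classifier into `dir`.
#'
#' @param report an `emg_eval_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
save_report <- function(report, dir) {
  stopifnot(inherits(report, "emg_eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(metadata = list(
    n_folds = report$metadata$cv$n_folds, seed = report$metadata$cv$seed,
    smote = report$metadata$smote,
    positive_class = report$metadata$positive_class,
    class_counts = report$metadata$class_counts))
  for (r in report$results) {
    js[[r$classifier]] <- list(
      mean_metrics = as.list(r$mean_metrics),
      mean_metrics_alt = as.list(r$mean_metrics_alt),
      auc = r$auc,
      confusion = r$confusion[c("tn", "fp", "fn", "tp")],
      failures = r$failures)
    data.table::fwrite(r$roc, file.path(dir, sprintf("roc_%s.csv", r$classifier)))
    cmdf <- data.frame(tn = r$confusion$tn, fp = r$confusion$fp,
                       fn = r$confusion$fn, tp = r$confusion$tp)
    data.table::fwrite(cmdf, file.path(dir, sprintf("confusion_%s.csv", r$classifier)))
  }
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}
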