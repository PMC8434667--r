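#' Cross-validation / random-forest configuration
#'
#' Settings for the importance-estimation and evaluation protocol: number of
#' CV folds (default 50), number of trees (default 500, for stable impurity
#' importances), RNG seed, fold strategy, AUC aggregation and importance
#' mode. With ~74 subjects a 50-fold split leaves 1-2 subjects per test
#' fold, so per-fold AUC is undefined for most folds; the default therefore
#' pools out-of-fold predicted probabilities into a single ROC
#' (`"pooled_out_of_fold"`), with `"mean_over_valid_folds"` available as the
#' average of per-fold AUCs over folds whose test split contains both
#' classes.
#'
#' @param n_folds Number of CV folds, `>= 2` (checked against the number of
#'   subjects at fit time).
#' @param n_trees Trees per random forest.
#' @param seed Integer seed governing fold assignment and every forest.
#' @param fold_strategy `"stratified_where_possible"` (default) spreads each
#'   class evenly over folds; `"plain"` ignores classes.
#' @param auc_aggregation `"pooled_out_of_fold"` (default) or
#'   `"mean_over_valid_folds"`.
#' @param importance `"impurity"` (default; Gini mean decrease, normalised to
#'   sum to 1 per fold) or `"permutation"`.
#' @param rf_params Named list of extra arguments passed to
#'   [ranger::ranger()].
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 50L, n_trees = 500L, seed = 1L,
                      fold_strategy = c("stratified_where_possible", "plain"),
                      auc_aggregation = c("pooled_out_of_fold",
                                          "mean_over_valid_folds"),
                      importance = c("impurity", "permutation"),
                      rf_params = list()) {
  stopifnot(n_folds >= 2, n_trees >= 1)
  structure(list(n_folds = as.integer(n_folds), n_trees = as.integer(n_trees),
                 seed = as.integer(seed),
                 fold_strategy = match.arg(fold_strategy),
                 auc_aggregation = match.arg(auc_aggregation),
                 importance = match.arg(importance),
                 rf_params = rf_params),
            class = "cv_config")
}

# normalise labels to factor with levels healthy < fall_risk (positive last)
.as_label_factor <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) labels <- ifelse(labels > 0, "fall_risk", "healthy")
  if (!all(labels %in% c("healthy", "fall_risk"))) {
    stop("labels must be 0/1 or healthy/fall_risk")
  }
  factor(labels, levels = c("healthy", "fall_risk"))
}

# deterministic fold assignment; depends only on (labels, config)
.make_folds <- function(labels, config) {
  n <- length(labels)
  if (config$n_folds > n) {
    stop("n_folds (", config$n_folds, ") exceeds number of subjects (", n, ")")
  }
  set.seed(config$seed)
  fold <- integer(n)
  if (config$fold_strategy == "stratified_where_possible") {
    for (lv in levels(labels)) {
      idx <- sample(which(labels == lv))
      # cycle through folds so each class spreads as evenly as possible
      fold[idx] <- rep_len(sample(config$n_folds), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(config$n_folds), n)
  }
  fold
}

.feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- features[, setdiff(names(features), "subject_id"), drop = FALSE]
  }
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("feature table contains missing/undefined values")
  m
}

.fit_rf <- function(x, y, config, seed, importance = "none") {
  args <- c(list(x = x, y = y, num.trees = config$n_trees,
                 probability = TRUE, importance = importance,
                 num.threads = 1L, seed = seed,
                 respect.unordered.factors = "order", verbose = FALSE),
            config$rf_params)
  do.call(ranger::ranger, args)
}

#' Cross-validated random-forest feature importance
#'
#' For each CV fold, fits a random forest on the training split and records
#' the per-feature importance normalised to sum to 1; reports each feature's
#' mean importance across folds and the descending ranking (ties broken by
#' canonical feature order). Folds whose training split contains a single
#' class are skipped with a warning. Fully reproducible under the config
#' seed.
#'
#' @param features Data frame or matrix of feature columns (a `subject_id`
#'   column is ignored); no missing values.
#' @param labels Binary labels (0/1 or `"healthy"`/`"fall_risk"`), 1 =
#'   fall risk.
#' @param config A [cv_config()].
#' @return An object of class `importance_report`: list with `mean_importance`
#'   (named, descending canonical order preserved), `ranking` (feature names
#'   in descending importance), `fold_importance` (folds x features matrix),
#'   `folds` (assignment vector) and `config`.
#' @export
cross_validated_importance <- function(features, labels, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  x <- .feature_matrix(features)
  y <- .as_label_factor(labels)
  stopifnot(nrow(x) == length(y))
  if (nlevels(droplevels(y)) < 2L) {
    stop("both classes must be present in the labels")
  }
  fold <- .make_folds(y, config)
  imp <- matrix(NA_real_, config$n_folds, ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    if (length(unique(y[tr])) < 2L) {
      warning("fold ", f, " skipped: single class in training split")
      next
    }
    fit <- .fit_rf(x[tr, , drop = FALSE], y[tr], config,
                   seed = config$seed + f, importance = config$importance)
    v <- ranger::importance(fit)[colnames(x)]
    v[v < 0] <- 0  # permutation importance can dip below zero
    imp[f, ] <- if (sum(v) > 0) v / sum(v) else v
  }
  keep <- !is.na(imp[, 1L])
  if (!any(keep)) stop("all folds skipped: cannot estimate importance")
  mean_imp <- colMeans(imp[keep, , drop = FALSE])
  ord <- order(-mean_imp, seq_along(mean_imp))  # ties by canonical order
  structure(list(mean_importance = mean_imp,
                 ranking = colnames(x)[ord],
                 fold_importance = imp[keep, , drop = FALSE],
                 folds = fold, config = config),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, n = 10L, ...) {
  cat(sprintf("importance_report: %d features, %d folds used\n",
              length(x$mean_importance), nrow(x$fold_importance)))
  top <- x$ranking[seq_len(min(n, length(x$ranking)))]
  for (i in seq_along(top)) {
    cat(sprintf("  %2d. %-10s %.4f\n", i, top[i], x$mean_importance[top[i]]))
  }
  invisible(x)
}

#' Select the top-k features of an importance report
#'
#' The `k` features with the highest mean importance, in descending order;
#' ties are broken by canonical feature order.
#'
#' @param report An `importance_report`.
#' @param k Number of features, `1 <= k <=` number of features.
#' @return Character vector of `k` feature names.
#' @export
select_top_k <- function(report, k) {
  stopifnot(inherits(report, "importance_report"),
            k >= 1, k <= length(report$ranking))
  report$ranking[seq_len(k)]
}

#' Evaluate a feature subset by cross-validated random forest
#'
#' Refits the forest per fold using only `subset`, predicts fall-risk
#' probabilities for the held-out subjects, and aggregates: pooled
#' out-of-fold AUC (and/or the mean of per-fold AUCs over folds with both
#' classes present, per the config), plus precision and recall at a 0.5
#' probability threshold on the pooled predictions, macro-averaged over the
#' two classes.
#'
#' @inheritParams cross_validated_importance
#' @param subset Character vector of feature names to use.
#' @param condition Optional label describing the run (carried in the
#'   result).
#' @return An object of class `evaluation_result`: list with `auc` (per the
#'   config aggregation), `pooled_auc`, `fold_auc` (per-fold AUC, `NA` where
#'   undefined), `precision`, `recall`, `oof_prob`, `labels`, `folds`,
#'   `subset`, `condition`, `config`.
#' @export
evaluate_subset <- function(features, labels, subset, config = cv_config(),
                            condition = NULL) {
  stopifnot(inherits(config, "cv_config"), length(subset) >= 1)
  x <- .feature_matrix(features)
  missing_f <- setdiff(subset, colnames(x))
  if (length(missing_f) > 0) {
    stop("unknown features in subset: ", paste(missing_f, collapse = ", "))
  }
  # keep table column order so results depend on the subset as a set,
  # not on its ordering (tree fitting samples candidate columns by index)
  x <- x[, colnames(x)[colnames(x) %in% subset], drop = FALSE]
  y <- .as_label_factor(labels)
  stopifnot(nrow(x) == length(y))
  fold <- .make_folds(y, config)
  prob <- rep(NA_real_, length(y))
  fold_auc <- rep(NA_real_, config$n_folds)
  for (f in seq_len(config$n_folds)) {
    tr <- fold != f
    te <- fold == f
    if (!any(te)) next
    if (length(unique(y[tr])) < 2L) {
      warning("fold ", f, " skipped: single class in training split")
      next
    }
    fit <- .fit_rf(x[tr, , drop = FALSE], y[tr], config,
                   seed = config$seed + f)
    p <- predict(fit, data = x[te, , drop = FALSE],
                 num.threads = 1L)$predictions[, "fall_risk"]
    prob[te] <- p
    if (length(unique(y[te])) == 2L) {
      fold_auc[f] <- .auc(y[te], p)
    }
  }
  ok <- !is.na(prob)
  if (length(unique(y[ok])) < 2L) {
    stop("out-of-fold predictions cover a single class; ",
         "cannot compute pooled AUC")
  }
  pooled_auc <- .auc(y[ok], prob[ok])
  pr <- .precision_recall(y[ok], prob[ok] >= 0.5)
  auc <- switch(config$auc_aggregation,
                pooled_out_of_fold = pooled_auc,
                mean_over_valid_folds = mean(fold_auc, na.rm = TRUE))
  structure(list(auc = auc, pooled_auc = pooled_auc, fold_auc = fold_auc,
                 precision = pr$precision, recall = pr$recall,
                 oof_prob = prob, labels = y, folds = fold,
                 subset = subset, condition = condition, config = config),
            class = "evaluation_result")
}

.auc <- function(y, p) {
  as.numeric(pROC::auc(pROC::roc(response = y, predictor = p,
                                 levels = c("healthy", "fall_risk"),
                                 direction = "<", quiet = TRUE)))
}

# macro-averaged precision/recall over the two classes at a hard threshold;
# a class never predicted contributes precision 0 (documented convention)
.precision_recall <- function(y, pred_pos) {
  per_class <- function(truth_pos, predicted_pos) {
    tp <- sum(truth_pos & predicted_pos)
    prec <- if (sum(predicted_pos) == 0) 0 else tp / sum(predicted_pos)
    rec <- if (sum(truth_pos) == 0) 0 else tp / sum(truth_pos)
    c(prec, rec)
  }
  pos <- per_class(y == "fall_risk", pred_pos)
  neg <- per_class(y == "healthy", !pred_pos)
  list(precision = mean(c(pos[1L], neg[1L])),
       recall = mean(c(pos[2L], neg[2L])))
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result%s: %d features, %d folds\n",
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              length(x$subset), x$config$n_folds))
  cat(sprintf("  AUC (%s): %.3f | precision %.3f | recall %.3f\n",
              x$config$auc_aggregation, x$auc, x$precision, x$recall))
  invisible(x)
}

#' Compare models with and without the MSE features
#'
#' Runs the full protocol twice per `k`: once on the complete 27-feature
#' table and once after removing the nine MSE features (MSEM, MSTD, CI on
#' each axis) *before* importance ranking, so the without-MSE model re-ranks
#' its own 18 features. Fold assignment depends only on labels and seed, so
#' the two arms share folds and their per-fold AUCs pair naturally for the
#' downstream t-test.
#'
#' @inheritParams cross_validated_importance
#' @param k_list Top-k sizes to evaluate (default 15, 10, 5).
#' @param condition Optional label naming the clinical test under evaluation.
#' @return An object of class `mse_comparison`: list with
#'   `importance_with`, `importance_without` and, per k, `with[[k]]` /
#'   `without[[k]]` [evaluate_subset()] results.
#' @export
compare_with_without_mse <- function(features, labels, config = cv_config(),
                                     k_list = c(15L, 10L, 5L),
                                     condition = NULL) {
  x_full <- .feature_matrix(features)
  if (!all(feature_names() %in% colnames(x_full))) {
    stop("feature table must contain all 27 canonical features")
  }
  keep <- setdiff(colnames(x_full), mse_feature_names())
  x_nomse <- x_full[, keep, drop = FALSE]
  imp_with <- cross_validated_importance(x_full, labels, config)
  imp_without <- cross_validated_importance(x_nomse, labels, config)
  run <- function(x, imp, k, tag) {
    evaluate_subset(x, labels, select_top_k(imp, k), config,
                    condition = paste0(condition, if (!is.null(condition)) " ",
                                       tag, " top", k))
  }
  ks <- as.character(k_list)
  res_with <- lapply(k_list, function(k) run(x_full, imp_with, k, "with-MSE"))
  res_without <- lapply(k_list, function(k)
    run(x_nomse, imp_without, k, "without-MSE"))
  names(res_with) <- ks
  names(res_without) <- ks
  structure(list(importance_with = imp_with, importance_without = imp_without,
                 with = res_with, without = res_without,
                 k_list = k_list, condition = condition, config = config),
            class = "mse_comparison")
}

#' Replicated with/without-MSE comparison
#'
#' Repeats [compare_with_without_mse()] over `n_reps` cross-validation
#' replicates (config seeds `seed, seed + 1, ...`, re-randomising fold
#' assignment and forests each time) and collects the pooled out-of-fold AUC
#' of both arms per replicate and k. The replicate-level AUC pairs are the
#' recommended input for [mse_effect_t_test()]: per-fold AUCs from 50-fold
#' splits of small cohorts are too coarse (1-2 test subjects per fold) to
#' carry a meaningful paired test, whereas pooled AUCs over independent CV
#' replicates are well-defined and approximately normal.
#'
#' @inheritParams compare_with_without_mse
#' @param n_reps Number of CV replicates.
#' @return Data frame with columns `rep`, `seed`, `k`, `auc_with`,
#'   `auc_without`.
#' @export
replicated_mse_comparison <- function(features, labels, config = cv_config(),
                                      k_list = c(15L, 10L, 5L), n_reps = 8L,
                                      condition = NULL) {
  stopifnot(n_reps >= 2)
  rows <- lapply(seq_len(n_reps), function(rp) {
    cfg <- config
    cfg$seed <- config$seed + rp - 1L
    cmp <- compare_with_without_mse(features, labels, cfg, k_list = k_list,
                                    condition = condition)
    data.frame(rep = rp, seed = cfg$seed, k = k_list,
               auc_with = vapply(as.character(k_list),
                                 function(k) cmp$with[[k]]$pooled_auc, 0),
               auc_without = vapply(as.character(k_list),
                                    function(k) cmp$without[[k]]$pooled_auc, 0))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mse_comparison <- function(x, ...) {
  cat(sprintf("mse_comparison%s (%s):\n",
              if (is.null(x$condition)) "" else paste0(" [", x$condition, "]"),
              x$config$auc_aggregation))
  for (k in as.character(x$k_list)) {
    cat(sprintf("  top %2s: AUC with MSE %.3f | without %.3f\n",
                k, x$with[[k]]$auc, x$without[[k]]$auc))
  }
  invisible(x)
}
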