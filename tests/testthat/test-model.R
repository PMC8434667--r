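cfg_fast <- function(...) cv_config(n_folds = 10L, n_trees = 150L, seed = 4L, ...)

test_that("cross-validated importance recovers a planted signal and is reproducible", {
  pf <- planted_features(n = 120, informative = c("CI (ML)", "STD (V)"),
                         effect = 2)
  rep1 <- cross_validated_importance(pf$x, pf$y, cfg_fast())
  rep2 <- cross_validated_importance(pf$x, pf$y, cfg_fast())
  expect_identical(rep1$ranking, rep2$ranking)
  expect_identical(rep1$mean_importance, rep2$mean_importance)
  # the two informative features dominate
  expect_true(all(c("CI (ML)", "STD (V)") %in% select_top_k(rep1, 5)))
  # per-fold importances are non-negative and normalised
  expect_true(all(rep1$fold_importance >= 0))
  expect_equal(unname(rowSums(rep1$fold_importance)),
               rep(1, nrow(rep1$fold_importance)), tolerance = 1e-9)
})

test_that("permuted labels leave all importances near the uniform level", {
  set.seed(17)
  n <- 200
  X <- matrix(rnorm(n * 27), n, 27, dimnames = list(NULL, feature_names()))
  y <- sample(rep(c(0, 1), each = n / 2))  # independent of X
  rep0 <- cross_validated_importance(as.data.frame(X, check.names = FALSE),
                                     y, cfg_fast())
  expect_true(all(rep0$mean_importance < 3 / 27))
})

test_that("top-k selection is nested, ordered and tie-stable", {
  pf <- planted_features()
  rep1 <- cross_validated_importance(pf$x, pf$y, cfg_fast())
  expect_identical(select_top_k(rep1, 27), rep1$ranking)
  expect_identical(select_top_k(rep1, 1),
                   names(which.max(rep1$mean_importance)))
  expect_true(all(select_top_k(rep1, 5) %in% select_top_k(rep1, 10)))
  expect_true(all(select_top_k(rep1, 10) %in% select_top_k(rep1, 15)))
  expect_error(select_top_k(rep1, 0))
  expect_error(select_top_k(rep1, 28))
  # exact ties break by canonical feature order
  fake <- rep1
  fake$mean_importance[] <- 1 / 27
  fake$ranking <- names(fake$mean_importance)[
    order(-fake$mean_importance, seq_along(fake$mean_importance))]
  expect_identical(select_top_k(fake, 3), feature_names()[1:3])
})

test_that("evaluation reaches AUC 1 on separable data and chance on permuted labels", {
  pf <- planted_features(n = 200, effect = 6)  # clearly separable
  res <- evaluate_subset(pf$x, pf$y, c("CI (ML)", "STD (V)"), cfg_fast())
  expect_identical(res$pooled_auc, 1)
  expect_gt(res$precision, 0.95)
  expect_gt(res$recall, 0.95)
  # permuted labels: pooled AUC near 0.5
  set.seed(23)
  y_perm <- sample(pf$y)
  res0 <- evaluate_subset(pf$x, y_perm, feature_names(), cfg_fast())
  expect_gt(res0$pooled_auc, 0.4)
  expect_lt(res0$pooled_auc, 0.6)
})

test_that("evaluating all features equals evaluating select_top_k(..., 27)", {
  pf <- planted_features(n = 80)
  rep1 <- cross_validated_importance(pf$x, pf$y, cfg_fast())
  r_all <- evaluate_subset(pf$x, pf$y, feature_names(), cfg_fast())
  r_sel <- evaluate_subset(pf$x, pf$y, select_top_k(rep1, 27), cfg_fast())
  expect_identical(r_all$pooled_auc, r_sel$pooled_auc)
  expect_identical(r_all$oof_prob, r_sel$oof_prob)
})

test_that("AUC is invariant under strictly increasing transforms of the scores", {
  set.seed(29)
  y <- factor(rep(c("healthy", "fall_risk"), each = 30),
              levels = c("healthy", "fall_risk"))
  p <- runif(60)
  a1 <- tugentropy:::.auc(y, p)
  a2 <- tugentropy:::.auc(y, plogis(5 * p - 2))
  expect_identical(a1, a2)
})

test_that("the without-MSE arm re-ranks exactly 18 features", {
  pf <- planted_features(n = 80, informative = c("STD (V)"), effect = 3)
  cmp <- compare_with_without_mse(pf$x, pf$y, cfg_fast(), k_list = c(5L))
  expect_length(cmp$importance_without$mean_importance, 18)
  expect_true(!any(mse_feature_names() %in%
                     names(cmp$importance_without$mean_importance)))
  expect_length(cmp$importance_with$mean_importance, 27)
  expect_identical(names(cmp$with), "5")
  # both arms share the same fold assignment, so per-fold AUCs pair
  expect_identical(cmp$with[["5"]]$folds, cmp$without[["5"]]$folds)
  expect_error(compare_with_without_mse(pf$x[, 1:20], pf$y, cfg_fast()),
               "27 canonical")
})

test_that("amplitude-only group differences leave the MSE arm no advantage", {
  # groups differ in signal amplitude, not complexity: the sd-relative
  # tolerance makes MSE features amplitude-blind, so removing them is cheap
  set.seed(61)
  spec_base <- cohort_spec(n_subjects = 16, faller_fraction = c(TUG = 0.5),
                           duration = 10, seed = 100,
                           beta_faller = 1)  # same exponent both groups
  coh <- simulate_cohort(spec_base)
  tg <- cohort_true_groups(coh)$TUG
  feats <- extract_cohort_features(coh)
  # amplify the faller recordings: amplitude signal only
  for (i in which(tg == "faller")) {
    r <- coh$subjects[[i]]$recording
    coh$subjects[[i]]$recording <-
      tug_recording(2 * r$axes$ML, 2 * r$axes$V, 2 * r$axes$AP,
                    r$sampling_rate)
  }
  feats_amp <- extract_cohort_features(coh)
  scale_free <- c(mse_feature_names(),
                  grep("^(PE|ZCR)", feature_names(), value = TRUE))
  for (f in scale_free) {
    expect_equal(feats_amp[[f]], feats[[f]], tolerance = 1e-8)
  }
  amp <- setdiff(feature_names(), scale_free)
  expect_false(isTRUE(all.equal(feats_amp[tg == "faller", amp],
                                feats[tg == "faller", amp])))
})

test_that("degenerate inputs fail loudly", {
  pf <- planted_features(n = 40)
  expect_error(cross_validated_importance(pf$x, rep(0, 40), cfg_fast()),
               "both classes")
  bad <- pf$x; bad[3, 5] <- NA
  expect_error(cross_validated_importance(bad, pf$y, cfg_fast()), "missing")
  expect_error(evaluate_subset(pf$x, pf$y, "NOPE", cfg_fast()), "unknown")
  expect_error(evaluate_subset(pf$x, pf$y, feature_names(),
                               cv_config(n_folds = 99)), "exceeds")
})
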