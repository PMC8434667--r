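#' Normality check of AUC samples
#'
#' One-sample Kolmogorov-Smirnov test of the AUC values against a normal
#' distribution. Because the normal parameters must be estimated from the
#' same sample, the default uses the Lilliefors-corrected test
#' ([nortest::lillie.test()]); `method = "ks"` runs the naive KS test with
#' plug-in mean and SD (anti-conservative, offered for comparison).
#'
#' @param x Numeric sample of AUC (or other) values; at least 4 observations
#'   for `"lilliefors"`, 3 for `"ks"`; non-zero variance.
#' @param method `"lilliefors"` (default) or `"ks"`.
#' @return List with `statistic` (in `[0, 1]`), `p.value` and `method`.
#' @export
ks_normality <- function(x, method = c("lilliefors", "ks")) {
  method <- match.arg(method)
  stopifnot(is.numeric(x), all(is.finite(x)))
  min_n <- if (method == "lilliefors") 4L else 3L
  if (length(x) < min_n) {
    stop("need at least ", min_n, " observations for the ", method, " test")
  }
  if (sd(x) == 0) stop("degenerate input: sample has zero variance")
  if (method == "lilliefors") {
    ht <- nortest::lillie.test(x)
  } else {
    ht <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  }
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       method = method)
}

#' t-test for the effect of including MSE features
#'
#' Two-sided t-test comparing AUC samples from models with vs without the
#' MSE features. Paired by default (the two arms come from the same folds
#' and conditions); `paired = FALSE` runs Welch's test. Identical paired
#' arms (all differences zero) make the paired t statistic degenerate; by
#' convention the function then returns statistic 0 and p = 1.
#'
#' @param auc_with,auc_without Numeric AUC samples; equal length if paired,
#'   at least 2 observations per arm.
#' @param paired Logical, default `TRUE`.
#' @return List with `statistic`, `p.value`, `paired`, `n`.
#' @export
mse_effect_t_test <- function(auc_with, auc_without, paired = TRUE) {
  stopifnot(is.numeric(auc_with), is.numeric(auc_without),
            all(is.finite(auc_with)), all(is.finite(auc_without)))
  if (length(auc_with) < 2L || length(auc_without) < 2L) {
    stop("need at least 2 observations per arm")
  }
  if (paired && length(auc_with) != length(auc_without)) {
    stop("paired test requires arms of equal length")
  }
  if (paired && all(auc_with == auc_without)) {
    return(list(statistic = 0, p.value = 1, paired = TRUE,
                n = length(auc_with)))
  }
  ht <- t.test(auc_with, auc_without, paired = paired)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       paired = paired, n = c(length(auc_with), length(auc_without)))
}

#' Statistical report for a with/without-MSE comparison
#'
#' Convenience wrapper around [ks_normality()] and [mse_effect_t_test()] for
#' an [compare_with_without_mse()] result: per arm and k, the normality test
#' of the per-fold AUCs; per k, the paired t-test of per-fold AUCs over folds
#' where both arms are defined.
#'
#' @param comparison An `mse_comparison` object.
#' @param ks_method Passed to [ks_normality()].
#' @return Data frame with one row per k: normality statistics/p-values for
#'   both arms and the paired t statistic and p-value.
#' @export
comparison_report <- function(comparison, ks_method = "lilliefors") {
  stopifnot(inherits(comparison, "mse_comparison"))
  rows <- lapply(as.character(comparison$k_list), function(k) {
    aw <- comparison$with[[k]]$fold_auc
    ao <- comparison$without[[k]]$fold_auc
    ok <- !is.na(aw) & !is.na(ao)
    ks_w <- tryCatch(ks_normality(aw[ok], ks_method),
                     error = function(e) list(statistic = NA, p.value = NA))
    ks_o <- tryCatch(ks_normality(ao[ok], ks_method),
                     error = function(e) list(statistic = NA, p.value = NA))
    tt <- mse_effect_t_test(aw[ok], ao[ok], paired = TRUE)
    data.frame(k = as.integer(k), n_folds_paired = sum(ok),
               auc_with = comparison$with[[k]]$auc,
               auc_without = comparison$without[[k]]$auc,
               ks_stat_with = ks_w$statistic, ks_p_with = ks_w$p.value,
               ks_stat_without = ks_o$statistic, ks_p_without = ks_o$p.value,
               t_stat = tt$statistic, t_p = tt$p.value)
  })
  do.call(rbind, rows)
}
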