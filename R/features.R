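#' MSE parameter set
#'
#' Parameters of the multiscale-entropy computation: template length `m`,
#' tolerance `r` (as a fraction of the SD of the original series, held fixed
#' across scales) and maximum scale factor `tau_max`. Defaults m = 2,
#' r = 0.15, tau_max = 10.
#'
#' @param m Embedding (template) length, `>= 1`.
#' @param r Tolerance fraction of the series SD, `> 0`.
#' @param tau_max Maximum coarse-graining scale, `>= 1`.
#' @return An object of class `mse_params`.
#' @export
mse_params <- function(m = 2L, r = 0.15, tau_max = 10L) {
  stopifnot(m >= 1, m == as.integer(m), r > 0,
            tau_max >= 1, tau_max == as.integer(tau_max))
  structure(list(m = as.integer(m), r = r, tau_max = as.integer(tau_max)),
            class = "mse_params")
}

#' Permutation-entropy parameter set
#'
#' Embedding dimension `D` and time delay (in samples) for permutation
#' entropy. Defaults `D = 4`, `delay = 1`.
#'
#' @param D Embedding dimension, `>= 2`.
#' @param delay Embedding time delay in samples, `>= 1`.
#' @return An object of class `pe_params`.
#' @export
pe_params <- function(D = 4L, delay = 1L) {
  stopifnot(D >= 2, D == as.integer(D), delay >= 1, delay == as.integer(delay))
  structure(list(D = as.integer(D), delay = as.integer(delay)),
            class = "pe_params")
}

#' Tri-axial TUG recording
#'
#' Container for one subject's tri-axial acceleration recording: mediolateral
#' (ML), vertical (V) and anterior-posterior (AP) series in g-units, all of
#' the same length, plus the sampling rate in Hz. The series are the raw
#' (unsegmented, unfiltered) dynamic acceleration of the trial.
#'
#' @param ml,v,ap Numeric acceleration series (g), equal length `>= 2`,
#'   finite values only.
#' @param sampling_rate Sampling rate in Hz, `> 0`.
#' @return An object of class `tug_recording` with elements `axes` (named
#'   list `ML`, `V`, `AP`) and `sampling_rate`.
#' @export
tug_recording <- function(ml, v, ap, sampling_rate) {
  stopifnot(is.numeric(ml), is.numeric(v), is.numeric(ap),
            length(sampling_rate) == 1L, sampling_rate > 0)
  n <- length(ml)
  if (n < 2L || length(v) != n || length(ap) != n) {
    stop("all three axes must have the same length >= 2")
  }
  if (!all(is.finite(ml), is.finite(v), is.finite(ap))) {
    stop("recording contains non-finite values")
  }
  structure(list(axes = list(ML = as.numeric(ml), V = as.numeric(v),
                             AP = as.numeric(ap)),
                 sampling_rate = as.numeric(sampling_rate)),
            class = "tug_recording")
}

#' @export
print.tug_recording <- function(x, ...) {
  n <- length(x$axes$ML)
  cat(sprintf("tug_recording: 3 axes (ML, V, AP), %d samples @ %g Hz (%.1f s)\n",
              n, x$sampling_rate, n / x$sampling_rate))
  invisible(x)
}

axis_names <- function() c("ML", "V", "AP")

feature_codes <- function() {
  c("MEAN", "STD", "MAX", "MIN", "ZCR", "MSEM", "MSTD", "CI", "PE")
}

#' Canonical feature names
#'
#' The 27 feature names in canonical order: the nine feature codes MEAN, STD,
#' MAX, MIN, ZCR (statistic), MSEM, MSTD, CI (multiscale entropy), PE
#' (permutation entropy), each over the axes ML, V, AP, written as e.g.
#' `"STD (AP)"` or `"CI (ML)"`.
#'
#' @return Character vector of length 27.
#' @export
feature_names <- function() {
  as.vector(t(outer(feature_codes(), axis_names(),
                    function(f, a) paste0(f, " (", a, ")"))))
}

#' Names of the nine MSE features
#'
#' The multiscale-entropy subset of [feature_names()]: MSEM, MSTD and CI on
#' each of the three axes. These are the features removed in the
#' "without MSE" model comparison.
#'
#' @return Character vector of length 9.
#' @export
mse_feature_names <- function() {
  feature_names()[grepl("^(MSEM|MSTD|CI) ", feature_names())]
}

#' Zero-crossing rate
#'
#' Fraction of consecutive sample pairs with a strict sign change, i.e. the
#' rate at which the signal crosses zero acceleration, in crossings per
#' sample step. An exact zero belongs to the preceding sign (leading zeros
#' to the first nonzero sign), so a touch-and-return to the same sign is
#' not counted and a touch-and-cross is counted exactly once.
#'
#' @param x Numeric series of length `>= 2`.
#' @return Crossing rate in `[0, 1]`.
#' @examples
#' zero_crossing_rate(c(1, -1, 1, -1))  # 1
#' @export
zero_crossing_rate <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  n <- length(x)
  if (n < 2L) stop("series must have at least 2 samples")
  s <- sign(x)
  nz <- s != 0
  if (!any(nz)) return(0)  # identically zero: no crossings
  # zeros inherit the preceding sign (leading zeros the first nonzero sign)
  filled <- s
  last <- s[nz][1L]
  for (i in seq_len(n)) {
    if (filled[i] == 0) filled[i] <- last else last <- filled[i]
  }
  sum(filled[-1L] != filled[-n]) / (n - 1L)
}

#' Extract the 27-feature vector from a recording
#'
#' Computes, for each axis (ML, V, AP) of the raw unsegmented recording:
#' mean (MEAN), standard deviation (STD), maximum (MAX), minimum (MIN),
#' zero-crossing rate (ZCR), the mean (MSEM) and standard deviation (MSTD)
#' of the sample-entropy values over the MSE scales, the complexity index
#' (CI, their sum), and permutation entropy (PE) — 27 named features in
#' total. No filtering, segmentation or gravity removal is applied.
#'
#' STD defaults to the population form (divide by N); set
#' `sd_population = FALSE` for the sample form. MSTD is the sample SD of the
#' `tau_max` profile values. Undefined sample entropy at any scale makes the
#' affected MSEM/MSTD/CI features `NA`; by default extraction then fails
#' loudly, unless `tolerate_undefined = TRUE`, in which case the `NA`s are
#' kept and flagged in the `undefined` attribute.
#'
#' @param recording A [tug_recording()].
#' @param mse An [mse_params()] object.
#' @param pe A [pe_params()] object.
#' @param sd_population Logical; population SD for the STD features
#'   (default `TRUE`).
#' @param tolerate_undefined Logical; keep `NA` entropy features instead of
#'   erroring (default `FALSE`).
#' @return A named numeric vector of class `feature_vector`, length 27, in
#'   canonical [feature_names()] order, with the parameter provenance in
#'   attributes `mse_params` and `pe_params`.
#' @export
extract_features <- function(recording, mse = mse_params(), pe = pe_params(),
                             sd_population = TRUE,
                             tolerate_undefined = FALSE) {
  stopifnot(inherits(recording, "tug_recording"),
            inherits(mse, "mse_params"), inherits(pe, "pe_params"))
  profiles <- lapply(recording$axes, mse_profile, params = mse)
  vals <- numeric(0)
  for (code in feature_codes()) {
    for (ax in axis_names()) {
      x <- recording$axes[[ax]]
      v <- switch(code,
        MEAN = mean(x),
        STD  = if (sd_population) sqrt(mean((x - mean(x))^2)) else sd(x),
        MAX  = max(x),
        MIN  = min(x),
        ZCR  = zero_crossing_rate(x),
        MSEM = mean(profiles[[ax]]),
        MSTD = sd(profiles[[ax]]),
        CI   = complexity_index(profiles[[ax]]),
        PE   = permutation_entropy(x, D = pe$D, delay = pe$delay))
      vals[paste0(code, " (", ax, ")")] <- v
    }
  }
  vals <- vals[feature_names()]
  undefined <- names(vals)[is.na(vals)]
  if (length(undefined) > 0 && !tolerate_undefined) {
    stop("undefined entropy features (no template matches or zero tolerance): ",
         paste(undefined, collapse = ", "),
         ". Set tolerate_undefined = TRUE to keep them as NA.")
  }
  structure(vals, class = "feature_vector",
            mse_params = mse, pe_params = pe,
            undefined = undefined)
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("feature_vector (27 features; MSE m =",
      attr(x, "mse_params")$m, ", r =", attr(x, "mse_params")$r,
      ", tau_max =", attr(x, "mse_params")$tau_max,
      "; PE D =", attr(x, "pe_params")$D,
      ", delay =", attr(x, "pe_params")$delay, ")\n")
  print(round(unclass(x)[seq_along(x)], 4))
  invisible(x)
}

#' Feature table for a whole cohort
#'
#' Applies [extract_features()] to every subject of a synthetic cohort (or
#' any list of subject records with `subject_id` and `recording` elements)
#' and binds the results into a data frame with one row per subject, a
#' `subject_id` column, and the 27 canonical feature columns.
#'
#' @param cohort A `tug_cohort` (see [simulate_cohort()]) or list of subject
#'   records.
#' @inheritParams extract_features
#' @return A data frame (`check.names = FALSE`) with 28 columns.
#' @export
extract_cohort_features <- function(cohort, mse = mse_params(),
                                    pe = pe_params(), sd_population = TRUE,
                                    tolerate_undefined = FALSE) {
  subjects <- if (inherits(cohort, "tug_cohort")) cohort$subjects else cohort
  rows <- lapply(subjects, function(s) {
    fv <- extract_features(s$recording, mse = mse, pe = pe,
                           sd_population = sd_population,
                           tolerate_undefined = tolerate_undefined)
    as.data.frame(as.list(unclass(fv)), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(subject_id = vapply(subjects, `[[`, "", "subject_id"),
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
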