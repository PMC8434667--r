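#' Synthetic cohort specification
#'
#' Parameters of the synthetic TUG-cohort generator. Each subject receives
#' one tri-axial recording — a sum of gait harmonics with random phases plus
#' spectrally shaped (1/f^beta) Gaussian noise — and a set of clinical scores
#' drawn conditionally on the subject's per-test group. Healthy subjects use
#' the more correlated noise (larger `beta_healthy`), fallers the whiter
#' noise (`beta_faller`), so the groups separate through the scale behaviour
#' of multiscale entropy while sharing the same gait harmonics and noise
#' variance.
#'
#' Per-test groups are driven by a latent impairment variable. The *first*
#' test named in `faller_fraction` is the test the recording is coupled to
#' (its group decides the recording's noise exponent; by default TUG, since
#' the recording is the TUG trial itself); the other tests' groups correlate
#' with the latent variable at `latent_correlation`, so multifactor label
#' counts behave like real, non-nested test intersections.
#'
#' Default scales: 74 subjects with faller fractions 17/74 (TUG), 13/74
#' (BBS) and 6/74 (SPMSQ), a 15 s trial at 100 Hz, a 1.9 Hz gait fundamental
#' with 3 harmonics, and group noise exponents 1 (healthy) vs 0 (faller).
#'
#' @param n_subjects Number of subjects, `>= 2`.
#' @param faller_fraction Named vector of per-test faller fractions in (0,1);
#'   names among `"TUG"`, `"BBS"`, `"SPMSQ"`. The first name is the
#'   recording-coupled test.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   gait harmonic frequency.
#' @param duration Trial duration in seconds, `> 0`.
#' @param gait_frequency Fundamental step frequency in Hz.
#' @param n_harmonics Number of gait harmonics (amplitude of harmonic k is
#'   `harmonic_amplitude / k`).
#' @param harmonic_amplitude Fundamental amplitude in g.
#' @param noise_amplitude SD in g of the group-dependent physiological
#'   noise (same SD for both groups; only the spectral shape differs).
#' @param beta_healthy,beta_faller Spectral exponents of the 1/f^beta noise
#'   for the two groups; healthy should be the larger (more correlated).
#' @param sensor_noise_amplitude SD in g of the white measurement-noise
#'   floor added identically to every recording (group-independent). It
#'   dominates the sample-to-sample structure, so single-scale ordinal
#'   features see mostly the floor, while coarse-graining averages it away
#'   and exposes the group-dependent correlated component.
#' @param score_noise_sd Named per-test jitter SD added to the generated
#'   scores (`TUG` seconds, `BBS` points, `SPMSQ` errors); 0 gives scores
#'   perfectly consistent with the true groups.
#' @param latent_correlation Correlation in (0,1] between the latent
#'   impairment and the non-coupled tests' group variables.
#' @param seed Integer RNG seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 74L,
                        faller_fraction = c(TUG = 17 / 74, BBS = 13 / 74,
                                            SPMSQ = 6 / 74),
                        sampling_rate = 100,
                        duration = 15,
                        gait_frequency = 1.9,
                        n_harmonics = 3L,
                        harmonic_amplitude = 0.25,
                        noise_amplitude = 0.08,
                        beta_healthy = 1,
                        beta_faller = 0,
                        sensor_noise_amplitude = 0.15,
                        score_noise_sd = c(TUG = 0.5, BBS = 0.75, SPMSQ = 0.3),
                        latent_correlation = 0.7,
                        seed = 1L) {
  tests <- names(faller_fraction)
  if (is.null(tests) || !all(tests %in% c("TUG", "BBS", "SPMSQ")) ||
      anyDuplicated(tests)) {
    stop("faller_fraction must be named with distinct names among TUG, BBS, SPMSQ")
  }
  if (!(n_subjects >= 2)) stop("invalid spec: n_subjects must be >= 2")
  if (!all(faller_fraction > 0 & faller_fraction < 1)) {
    stop("invalid spec: faller fractions must lie strictly in (0, 1)")
  }
  if (!(duration > 0)) stop("invalid spec: duration must be positive")
  if (!(sampling_rate > 2 * gait_frequency * n_harmonics)) {
    stop("invalid spec: sampling_rate must exceed 2 * gait_frequency * n_harmonics")
  }
  stopifnot(n_harmonics >= 1, harmonic_amplitude >= 0, noise_amplitude >= 0,
            sensor_noise_amplitude >= 0,
            beta_healthy >= 0, beta_faller >= 0,
            latent_correlation > 0, latent_correlation <= 1,
            all(score_noise_sd >= 0), all(tests %in% names(score_noise_sd)))
  structure(list(n_subjects = as.integer(n_subjects),
                 faller_fraction = faller_fraction,
                 sampling_rate = sampling_rate, duration = duration,
                 gait_frequency = gait_frequency,
                 n_harmonics = as.integer(n_harmonics),
                 harmonic_amplitude = harmonic_amplitude,
                 noise_amplitude = noise_amplitude,
                 beta_healthy = beta_healthy, beta_faller = beta_faller,
                 sensor_noise_amplitude = sensor_noise_amplitude,
                 score_noise_sd = score_noise_sd,
                 latent_correlation = latent_correlation,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: %d subjects, %g s @ %g Hz, gait %g Hz x%d harmonics\n",
              x$n_subjects, x$duration, x$sampling_rate, x$gait_frequency,
              x$n_harmonics))
  cat(sprintf("  noise sd %g g, beta healthy %g / faller %g, seed %d\n",
              x$noise_amplitude, x$beta_healthy, x$beta_faller, x$seed))
  cat("  faller fractions:",
      paste(sprintf("%s=%.3f", names(x$faller_fraction), x$faller_fraction),
            collapse = ", "), "\n")
  invisible(x)
}

# 1/f^beta Gaussian noise via frequency-domain shaping, unit SD.
# beta = 0 reduces to white noise (DC removed).
colored_noise <- function(n, beta) {
  w <- rnorm(n)
  if (beta == 0) return(as.numeric(scale(w)))
  W <- fft(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k)            # two-sided frequency index
  shape <- ifelse(f > 0, f^(-beta / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# truncated-normal draws by inverse-CDF (vectorised, deterministic)
rtnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

#' Simulate one tri-axial TUG-like recording
#'
#' One recording = per-axis sum of gait harmonics (fundamental
#' `gait_frequency`, amplitudes `harmonic_amplitude / k`, independent uniform
#' random phases per axis and harmonic, axis scaling V > AP > ML as in trunk
#' accelerometry) plus 1/f^beta noise with SD `noise_amplitude`, the exponent
#' chosen by `group`. Uses the current RNG state; seed it (or use
#' [simulate_cohort()]) for reproducibility.
#'
#' @param spec A [cohort_spec()].
#' @param group `"healthy"` or `"faller"` — selects the noise exponent.
#' @return A [tug_recording()] with `round(sampling_rate * duration)` samples
#'   per axis.
#' @export
simulate_recording <- function(spec, group = c("healthy", "faller")) {
  stopifnot(inherits(spec, "cohort_spec"))
  group <- match.arg(group)
  n <- round(spec$sampling_rate * spec$duration)
  if (n < 2) stop("invalid spec: recording would have fewer than 2 samples")
  t <- (seq_len(n) - 1L) / spec$sampling_rate
  beta <- if (group == "healthy") spec$beta_healthy else spec$beta_faller
  axis_scale <- c(ML = 0.6, V = 1.0, AP = 0.8)
  axes <- lapply(axis_scale, function(sc) {
    sig <- numeric(n)
    for (k in seq_len(spec$n_harmonics)) {
      phase <- runif(1L, 0, 2 * pi)
      sig <- sig + sc * (spec$harmonic_amplitude / k) *
        sin(2 * pi * k * spec$gait_frequency * t + phase)
    }
    if (spec$noise_amplitude > 0) {
      # physiological noise scales with the axis amplitude: movement
      # variability is proportional to movement magnitude
      sig <- sig + sc * spec$noise_amplitude * colored_noise(n, beta)
    }
    if (spec$sensor_noise_amplitude > 0) {
      # measurement-noise floor: same on every axis, group-independent
      sig <- sig + spec$sensor_noise_amplitude * rnorm(n)
    }
    sig
  })
  tug_recording(axes$ML, axes$V, axes$AP, spec$sampling_rate)
}

# group-conditional clinical score distributions, straddling the cut-offs
.draw_scores <- function(test, faller, jitter_sd) {
  n <- length(faller)
  raw <- switch(test,
    TUG = ifelse(faller,
                 rtnorm(n, 16.0, 2.5, 12.47, 40),
                 rtnorm(n, 9.5, 1.8, 4, 12.47)),
    BBS = ifelse(faller,
                 rtnorm(n, 18, 3, 0, 22.49),
                 rtnorm(n, 26, 2, 23, 28.49)),
    SPMSQ = ifelse(faller,
                   rtnorm(n, 5, 1.5, 3, 10.49),
                   rtnorm(n, 1, 1, 0, 2.49)))
  if (jitter_sd > 0) raw <- raw + rnorm(n, 0, jitter_sd)
  switch(test,
    TUG = pmax(raw, 0.5),
    BBS = as.integer(pmin(pmax(round(raw), 0), 28)),
    SPMSQ = as.integer(pmin(pmax(round(raw), 0), 10)))
}

#' Simulate a full synthetic cohort
#'
#' Draws per-test group assignments matching the spec's faller fractions
#' (exact counts by ranking a latent impairment variable), generates one
#' recording per subject whose noise exponent follows the recording-coupled
#' test's group, and draws clinical scores from group-conditional truncated
#' normals straddling the labeling cut-offs (12.47 s, 23 points, 3 errors),
#' plus optional jitter. With zero jitter, applying the labeling rules to
#' the generated scores reproduces the true groups exactly.
#'
#' The whole cohort is a deterministic function of the spec (including its
#' `seed`): identical spec gives a bit-identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `tug_cohort`: list with `subjects` (each with
#'   `subject_id`, `recording`, `scores`, `true_group` — a named
#'   healthy/faller vector per test) and `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  tests <- names(spec$faller_fraction)
  z <- rnorm(n)  # latent impairment
  rho <- spec$latent_correlation
  group <- matrix("healthy", n, length(tests), dimnames = list(NULL, tests))
  for (i in seq_along(tests)) {
    zt <- if (i == 1L) z else rho * z + sqrt(1 - rho^2) * rnorm(n)
    n_fall <- round(n * spec$faller_fraction[i])
    if (n * spec$faller_fraction[i] < 1) {
      warning("expected faller count for ", tests[i],
              " is below 1 subject; group may be empty")
    }
    group[rank(-zt, ties.method = "first") <= n_fall, i] <- "faller"
  }
  scores <- lapply(tests, function(tst) {
    .draw_scores(tst, group[, tst] == "faller", spec$score_noise_sd[[tst]])
  })
  names(scores) <- tests
  coupled <- tests[1L]
  subjects <- lapply(seq_len(n), function(i) {
    rec <- simulate_recording(spec, group = group[i, coupled])
    sc <- list()
    if ("TUG" %in% tests) sc$tug_seconds <- scores$TUG[i]
    if ("BBS" %in% tests) sc$sfbbs_points <- scores$BBS[i]
    if ("SPMSQ" %in% tests) sc$spmsq_errors <- scores$SPMSQ[i]
    list(subject_id = sprintf("S%03d", i), recording = rec, scores = sc,
         true_group = group[i, , drop = TRUE])
  })
  structure(list(subjects = subjects, spec = spec), class = "tug_cohort")
}

#' @export
print.tug_cohort <- function(x, ...) {
  tg <- cohort_true_groups(x)
  cat(sprintf("tug_cohort: %d subjects (seed %d)\n",
              length(x$subjects), x$spec$seed))
  for (tst in setdiff(names(tg), "subject_id")) {
    cat(sprintf("  %s: %d fallers / %d\n", tst,
                sum(tg[[tst]] == "faller"), nrow(tg)))
  }
  invisible(x)
}

#' Score and true-group tables of a cohort
#'
#' `cohort_scores()` collects each subject's clinical scores into a data
#' frame (columns `subject_id` plus the scores present); `cohort_true_groups()`
#' collects the generator's per-test true groups.
#'
#' @param cohort A `tug_cohort`.
#' @return A data frame with one row per subject.
#' @export
cohort_scores <- function(cohort) {
  stopifnot(inherits(cohort, "tug_cohort"))
  out <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    stringsAsFactors = FALSE)
  for (fld in c("tug_seconds", "sfbbs_points", "spmsq_errors")) {
    if (!is.null(cohort$subjects[[1L]]$scores[[fld]])) {
      out[[fld]] <- vapply(cohort$subjects,
                           function(s) as.numeric(s$scores[[fld]]), 0)
    }
  }
  out
}

#' @rdname cohort_scores
#' @export
cohort_true_groups <- function(cohort) {
  stopifnot(inherits(cohort, "tug_cohort"))
  tests <- names(cohort$subjects[[1L]]$true_group)
  out <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    stringsAsFactors = FALSE)
  for (tst in tests) {
    out[[tst]] <- vapply(cohort$subjects,
                         function(s) unname(s$true_group[[tst]]), "")
  }
  out
}
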