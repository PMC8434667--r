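test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(faller_fraction = c(TUG = 0)), "strictly in")
  expect_error(cohort_spec(faller_fraction = c(TUG = 1.2)), "strictly in")
  expect_error(cohort_spec(duration = 0), "duration")
  expect_error(cohort_spec(duration = -5), "duration")
  expect_error(cohort_spec(sampling_rate = 10, gait_frequency = 2,
                           n_harmonics = 3), "sampling_rate")
  expect_error(cohort_spec(faller_fraction = c(XYZ = 0.2)), "named")
})

test_that("noise-free single-harmonic recordings are pure gait-frequency sinusoids", {
  spec <- cohort_spec(n_subjects = 4, faller_fraction = c(TUG = 0.25),
                      noise_amplitude = 0, sensor_noise_amplitude = 0,
                      n_harmonics = 1, gait_frequency = 2, duration = 10,
                      sampling_rate = 100)
  set.seed(3)
  rec <- simulate_recording(spec, "healthy")
  for (ax in c("ML", "V", "AP")) {
    x <- rec$axes[[ax]]
    spec_dens <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * spec$sampling_rate / length(x)
    half <- seq_len(length(x) %/% 2)
    peak <- freqs[half][which.max(spec_dens[half])]
    expect_equal(peak, 2, tolerance = 0.15)
    # a pure sinusoid concentrates essentially all power at the peak
    expect_gt(max(spec_dens[half]) / sum(spec_dens[half]), 0.45)
  }
})

test_that("recordings and cohorts are bit-identical under a fixed seed", {
  spec <- cohort_spec(n_subjects = 8, faller_fraction = c(TUG = 0.25),
                      duration = 3, seed = 77)
  set.seed(5); r1 <- simulate_recording(spec, "faller")
  set.seed(5); r2 <- simulate_recording(spec, "faller")
  expect_identical(r1, r2)
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  # a different seed changes the cohort
  c3 <- simulate_cohort(cohort_spec(n_subjects = 8,
                                    faller_fraction = c(TUG = 0.25),
                                    duration = 3, seed = 78))
  expect_false(identical(c1$subjects[[1]]$recording, c3$subjects[[1]]$recording))
})

test_that("group counts match the requested faller fractions exactly", {
  spec <- cohort_spec(n_subjects = 74,
                      faller_fraction = c(TUG = 17 / 74, BBS = 13 / 74,
                                          SPMSQ = 6 / 74),
                      duration = 2, seed = 12)
  coh <- simulate_cohort(spec)
  tg <- cohort_true_groups(coh)
  expect_identical(sum(tg$TUG == "faller"), 17L)
  expect_identical(sum(tg$BBS == "faller"), 13L)
  expect_identical(sum(tg$SPMSQ == "faller"), 6L)
  # repeated simulation reproduces the same groups
  expect_identical(tg, cohort_true_groups(simulate_cohort(spec)))
  # sub-single-subject expected count warns but does not error
  expect_warning(simulate_cohort(cohort_spec(n_subjects = 10,
                                             faller_fraction = c(TUG = 0.05),
                                             duration = 2, seed = 1)),
                 "below 1")
})

test_that("zero score jitter makes labels reproduce true groups exactly", {
  spec <- cohort_spec(n_subjects = 60,
                      faller_fraction = c(TUG = 0.3, BBS = 0.2, SPMSQ = 0.15),
                      score_noise_sd = c(TUG = 0, BBS = 0, SPMSQ = 0),
                      duration = 2, seed = 9)
  coh <- simulate_cohort(spec)
  lab <- label_cohort(cohort_scores(coh))
  tg <- cohort_true_groups(coh)
  expect_identical(lab$TUG, as.integer(tg$TUG == "faller"))
  expect_identical(lab$BBS, as.integer(tg$BBS == "faller"))
  expect_identical(lab$SPMSQ, as.integer(tg$SPMSQ == "faller"))
})

test_that("default score jitter still lets labeling recover groups for >= 95% of subjects", {
  spec <- cohort_spec(n_subjects = 200,
                      faller_fraction = c(TUG = 0.3, BBS = 0.2, SPMSQ = 0.15),
                      duration = 2, seed = 10)
  coh <- simulate_cohort(spec)
  lab <- label_cohort(cohort_scores(coh))
  tg <- cohort_true_groups(coh)
  for (tst in c("TUG", "BBS", "SPMSQ")) {
    agreement <- mean((lab[[tst]] == 1) == (tg[[tst]] == "faller"))
    expect_gte(agreement, 0.95)
  }
})

test_that("generated scores stay within their clinical ranges", {
  spec <- cohort_spec(n_subjects = 120,
                      faller_fraction = c(TUG = 0.4, BBS = 0.4, SPMSQ = 0.4),
                      duration = 2, seed = 14)
  sc <- cohort_scores(simulate_cohort(spec))
  expect_true(all(sc$tug_seconds > 0))
  expect_true(all(sc$sfbbs_points %in% 0:28))
  expect_true(all(sc$spmsq_errors %in% 0:10))
})

test_that("white-noise recordings are less regular at scale 1 than 1/f recordings at scale 5", {
  # direct simulation of the coarse-graining behaviour the generator relies
  # on: white noise loses sample entropy under coarse-graining, 1/f does not
  set.seed(55)
  n <- 2000
  drop_white <- drop_pink <- numeric(20)
  for (i in 1:20) {
    w <- tugentropy:::colored_noise(n, 0)
    p <- tugentropy:::colored_noise(n, 1)
    rw <- 0.15 * sd(w); rp <- 0.15 * sd(p)
    drop_white[i] <- sample_entropy(w, 2, rw, r_mode = "absolute") -
      sample_entropy(coarse_grain(w, 5), 2, rw, r_mode = "absolute")
    drop_pink[i] <- sample_entropy(p, 2, rp, r_mode = "absolute") -
      sample_entropy(coarse_grain(p, 5), 2, rp, r_mode = "absolute")
  }
  expect_true(all(drop_white > 0))
  expect_gt(mean(drop_white), mean(drop_pink) + 0.2)
})

test_that("complexity index separates the groups on the ML axis", {
  spec <- cohort_spec(n_subjects = 80, faller_fraction = c(TUG = 0.5),
                      seed = 33)
  coh <- simulate_cohort(spec)
  feat <- extract_cohort_features(coh)
  tg <- cohort_true_groups(coh)$TUG
  ci <- feat[["CI (ML)"]]
  d <- abs(mean(ci[tg == "faller"]) - mean(ci[tg == "healthy"])) /
    sqrt(0.5 * (var(ci[tg == "faller"]) + var(ci[tg == "healthy"])))
  expect_gt(d, 0.5)
})
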