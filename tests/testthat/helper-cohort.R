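# Shared planted-signal study cohort: 200 subjects whose groups differ only
# in the spectral exponent of the physiological noise (labels via the TUG
# score). Extraction is the slow part, so the fixture is computed once per
# test run and memoised.
.cohort_cache <- new.env(parent = emptyenv())

planted_cohort <- function() {
  if (!is.null(.cohort_cache$fixture)) return(.cohort_cache$fixture)
  spec <- cohort_spec(n_subjects = 200, faller_fraction = c(TUG = 0.3),
                      seed = 11)
  coh <- simulate_cohort(spec)
  feat <- extract_cohort_features(coh)
  lab <- label_cohort(cohort_scores(coh))
  .cohort_cache$fixture <- list(cohort = coh, features = feat,
                                labels = lab$TUG,
                                true_group = cohort_true_groups(coh)$TUG)
  .cohort_cache$fixture
}
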