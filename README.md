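# tugentropy

Entropy-based fall-risk screening from a single unsegmented timed-up-and-go
(TUG) accelerometer recording.

Community-dwelling elderly adults are screened for fall risk with quick
clinical tests — TUG time, the short-form Berg balance scale (SFBBS) and the
short portable mental status questionnaire (SPMSQ) — each with a published
cut-off (risk if TUG > 12.47 s, SFBBS < 23, SPMSQ errors ≥ 3). A belt-worn
tri-axial accelerometer at the lower back records mediolateral (ML),
vertical (V) and anterior–posterior (AP) acceleration during the TUG trial.
This package implements, as a tested reusable pipeline, the analysis that
asks whether features computed from that raw recording — with no
segmentation, filtering or manual processing — can stand in for the clinical
scores, and which features carry the signal:

* **features** — 27 features (9 per axis): mean, SD, max, min,
  zero-crossing rate; multiscale entropy via coarse-graining
  y⁽τ⁾ⱼ = (1/τ) Σ xᵢ and sample entropy SampEn(m, r) = −log(A/B)
  (m = 2, r = 0.15·SD, scales τ = 1..10), summarised as the profile mean
  (MSEM), SD (MSTD) and complexity index CI = Σ_τ SampEn(τ); and
  permutation entropy PE = −Σ pᵢ log₂ pᵢ over ordinal patterns (D = 4).
  The SampEn kernel is compiled (Rcpp) and tested against a brute-force
  template-counting oracle.
* **labeling** — the three cut-off rules plus multifactor combinations
  (TUG + BBS, TUG + SPMSQ, BBS + SPMSQ) under the intersection rule.
* **model** — 50-fold cross-validated random-forest feature importance
  (Gini, normalised per fold, averaged across folds), top-k re-training
  (k = 15, 10, 5), pooled out-of-fold AUC, macro precision/recall, and the
  with/without-MSE comparison (all 27 features vs the 18 non-MSE features,
  re-ranked).
* **stats** — Lilliefors/KS normality check of AUC samples and the paired
  t-test for the MSE effect, with a replicated-CV sample construction.
* **synthetic_data** — a seeded cohort generator (gait harmonics +
  1/f^β physiological noise whose exponent differs by group + a white
  sensor floor, with clinical scores drawn around the cut-offs), because
  the motivating clinical dataset cannot be redistributed.

See the methods vignette (`vignettes/entropy-fall-screening.Rmd`) for the
model, conventions and design rationale.

## Worked example

```r
library(tugentropy)

# a 200-subject synthetic cohort whose groups differ only in the spectral
# exponent of the physiological noise, labeled by TUG score
spec <- cohort_spec(n_subjects = 200, faller_fraction = c(TUG = 0.3), seed = 11)
cohort   <- simulate_cohort(spec)
features <- extract_cohort_features(cohort)
labels   <- label_cohort(cohort_scores(cohort))$TUG

cmp <- compare_with_without_mse(features, labels, cv_config(seed = 5))
print(cmp)
#> mse_comparison (pooled_out_of_fold):
#>   top 15: AUC with MSE 0.972 | without 0.905
#>   top 10: AUC with MSE 0.964 | without 0.902
#>   top  5: AUC with MSE 0.952 | without 0.903
select_top_k(cmp$importance_with, 5)
#> [1] "CI (V)"    "MSEM (V)"  "MSEM (AP)" "CI (AP)"   "MSTD (AP)"
```

The printed AUCs are pooled out-of-fold areas under the ROC for the top-k
random forest with all 27 features versus with the 9 MSE features removed:
classification is strong when complexity features are available and
consistently weaker without them, and the five most important features are
all multiscale-entropy features — the planted complexity signal is found
where it was hidden. `replicated_mse_comparison()` + `mse_effect_t_test()`
turn that gap into a paired significance test, and `run_pipeline()` runs
the whole battery (6 label conditions × 3 k × 2 arms) from one config.

A thin command-line wrapper over the same functions is installed at
`inst/cli/tugentropy.R` (subcommands `simulate`, `extract`, `label`,
`train`, `run`).

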