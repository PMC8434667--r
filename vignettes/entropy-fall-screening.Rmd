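---
title: "Entropy-based fall-risk screening from TUG accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based fall-risk screening from TUG accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugentropy)
```

## The screening problem

Falls are a leading cause of injury among adults over 65, and poor balance
and mobility are among their strongest intrinsic risk factors. Clinics
screen for them with quick functional tests — the timed-up-and-go test
(TUG: stand, walk 3 m, return, sit; the completion time is the score), the
short-form Berg balance scale (SFBBS: seven tasks scored 0–4, maximum 28)
and the short portable mental status questionnaire (SPMSQ: ten cognition
questions, errors counted). Each test has a published screening cut-off:
more than 12.47 s on the TUG, below 23 SFBBS points, or three or more SPMSQ
errors flags a subject as at risk.

A belt-worn tri-axial accelerometer at the lower back (near the body's
centre of mass, L3–L5) records mediolateral (ML), vertical (V) and
anterior–posterior (AP) acceleration during a single TUG trial. The
question this package operationalises: can features computed from that
*one unsegmented recording* — no step detection, no filtering, no manual
annotation — stand in for the clinical scores, and which features carry
the signal?

## Feature set

Twenty-seven features, nine per axis:

* **Statistic** — mean (MEAN), standard deviation (STD), maximum (MAX),
  minimum (MIN), and zero-crossing rate (ZCR), the fraction of consecutive
  sample pairs whose acceleration changes sign.
* **Multiscale entropy (MSE)** — the series is coarse-grained at scale
  $\tau$ by averaging non-overlapping blocks of $\tau$ samples,
  $y_j^{(\tau)} = \frac{1}{\tau}\sum_{i=(j-1)\tau+1}^{j\tau} x_i$, and
  sample entropy
  $\mathrm{SampEn}(m, r) = -\log (A/B)$
  is computed at each scale $1..\tau_{\max}$, where $B$ counts pairs of
  length-$m$ templates within Chebyshev tolerance $r$ and $A$ the same
  pairs extended to length $m+1$. The profile is summarised by its mean
  (MSEM), its standard deviation (MSTD), and the complexity index
  $\mathrm{CI} = \sum_{\tau} \mathrm{SampEn}(\tau)$.
* **Permutation entropy (PE)** — the Shannon entropy, in bits, of the
  relative frequencies of ordinal patterns among delay-embedded vectors of
  dimension $D$: $\mathrm{PE} = -\sum_i p_i \log_2 p_i$, bounded by
  $\log_2 D!$.

Defaults follow standard practice in the gait-entropy literature:
$m = 2$, $r = 0.15$ (as a fraction of the series SD), $\tau_{\max} = 10$;
$D = 4$, delay 1. The classification protocol is 50-fold cross-validated
random-forest feature importance followed by top-$k$ re-training
($k = 15, 10, 5$), with the headline contrast being the model with all 27
features versus the model restricted to the 18 non-MSE features.

## Numerical conventions

Several details are under-determined in common descriptions of these
estimators; the package fixes them as follows.

* **Tolerance across scales.** $r$ is a fraction of the SD of the
  *original* series and the resulting absolute tolerance is held fixed for
  every coarse-graining scale. This is the convention under which white
  noise (whose coarse-grained SD shrinks as $\tau^{-1/2}$) shows decaying
  SampEn with scale while $1/f$ noise stays approximately flat — the
  property that makes MSE informative about long-range correlation. An
  absolute-tolerance mode exists and is what the brute-force oracle tests
  use.
* **SampEn counting.** Richman–Moorman: strict inequality $d < r$,
  Chebyshev distance, self-matches excluded, both template lengths ranging
  over the same $N - m$ start positions. Natural logarithm.
* **Undefined SampEn.** If no template pair matches at either length the
  conditional probability is undefined; the package returns `NA` and
  *propagates* it (CI of a profile with an `NA` is `NA`; extraction fails
  loudly unless `tolerate_undefined = TRUE`). Substituting 0 would
  silently deflate the complexity index.
* **PE sign and ties.** PE is the non-negative Shannon form
  $-\sum p \log_2 p$ (a more regular series has *lower* PE). Ties inside
  an embedded vector — possible with quantised accelerometer output — rank
  by position, earlier index lower, making the estimator deterministic.
* **ZCR zeros.** An exactly-zero sample inherits the preceding sign, so a
  touch-and-return is no crossing and a touch-and-cross counts once.
* **STD.** Population form (divide by $N$) by default, switchable; for
  1500-sample recordings the distinction is cosmetic, but it is recorded.
* **Labeling boundaries.** Strictly over 12.47 s; strictly below 23
  points (23–27 is healthy by this rule; 28 is explicitly "correct
  balance"); three or more errors inclusive. Multifactor labels (TUG +
  BBS, TUG + SPMSQ, BBS + SPMSQ) use the intersection rule — at risk only
  if both constituent tests flag risk — which is the only rule consistent
  with label counts in which each combination is at most the minimum of
  its constituents. The rule sits behind one function with a union option.
* **AUC aggregation.** With ~74 subjects, 50-fold CV leaves 1–2 subjects
  per held-out fold, so a per-fold AUC is undefined for most folds. The
  default pools out-of-fold predicted probabilities into one ROC; the mean
  over folds with both classes present is available
  (`auc_aggregation = "mean_over_valid_folds"`). Precision and recall are
  macro-averaged over the two classes at a 0.5 probability threshold on
  pooled predictions.
* **Importance.** Gini (impurity) mean decrease, normalised to sum to 1
  within each fold, averaged across folds; permutation importance is an
  option. Forests use 500 trees for importance stability; every forest and
  fold assignment is seeded, so all results are exactly reproducible.
* **Which AUC samples enter the statistics.** Per-fold AUCs from tiny
  folds take values in $\{0, 0.25, 0.5, 0.75, 1\}$ — a normality test on
  them rejects trivially and a paired t-test on them is underpowered.
  `replicated_mse_comparison()` therefore repeats the whole CV with
  incremented seeds and pairs the *pooled* AUCs of the two arms by
  replicate; those replicate-level samples feed `ks_normality()`
  (Lilliefors-corrected by default, since the normal parameters are
  estimated) and `mse_effect_t_test()` (paired by default). Both functions
  accept any sample the analyst prefers, labeled accordingly.

## The synthetic cohort generator

The clinical recordings that motivated this pipeline cannot be
redistributed, so the package ships a seeded generator whose cohorts
exercise every downstream stage. It is first-class, tested code, not a
fixture.

Each recording is

$$x(t) = \sum_{k=1}^{K} \frac{a}{k}\, s_{\text{axis}} \sin(2\pi k f t + \phi_k)
        \;+\; s_{\text{axis}}\,\sigma_p\, \eta_\beta(t) \;+\; \sigma_s\, \varepsilon(t),$$

a gait fundamental with harmonics (random phases per axis), plus
*physiological* noise $\eta_\beta$ with a $1/f^\beta$ spectrum whose
exponent depends on the subject's group, plus a white measurement floor
$\varepsilon$ common to all subjects. Healthy subjects get the more
correlated noise ($\beta = 1$), fallers the whiter noise ($\beta = 0$):
degraded postural control showing up as loss of long-range correlation is
the standard complexity-and-aging interpretation, and it is exactly the
difference MSE was designed to detect.

Default parameters and why:

* **74 subjects**, faller fractions 17/74 (TUG), 13/74 (BBS), 6/74
  (SPMSQ) — an imbalanced elderly screening cohort of the size and mix
  this kind of hospital study enrols.
* **15 s at 100 Hz.** A TUG trial near the 12.47 s cut-off; 100 Hz is
  typical for wearable gait sensors and leaves 150 samples at coarse-grain
  scale 10, enough for SampEn to stay defined at every scale (at 50 Hz,
  scale-10 series of 75 points frequently have no $m+1$ template matches).
* **Gait fundamental 1.9 Hz, 3 harmonics, fundamental amplitude 0.25 g**,
  axis scaling V (1.0) > AP (0.8) > ML (0.6), matching the usual energy
  ordering of trunk acceleration during walking.
* **Physiological noise 0.08 g, sensor floor 0.15 g.** The floor
  deliberately dominates sample-to-sample variation. This choice is what
  makes the generator a fair test of the *multiscale* claim: single-scale
  ordinal features (PE, ZCR) mostly see the floor, which is identical
  across groups, while coarse-graining averages the floor away
  ($\propto \tau^{-1/2}$) and exposes the group-dependent correlated
  component at larger scales. Without a floor, a white-vs-$1/f$ group
  difference is *more* visible to lag-one features than to MSE and the
  feature ranking inverts. In probe cohorts these defaults give
  between-group effect sizes of roughly $d \approx 2$ for the best MSE
  feature against $d \approx 1.2$–$1.6$ for PE and ZCR.
* **Clinical scores** are drawn from truncated normals on either side of
  each cut-off (e.g. TUG healthy $\mathcal{N}(9.5, 1.8^2)$ on
  $(4, 12.47)$; faller $\mathcal{N}(16, 2.5^2)$ on $(12.47, 40)$), then
  jittered (defaults 0.5 s, 0.75 points, 0.3 errors). Zero jitter makes
  labels reproduce the generator's groups exactly; the defaults leave
  roughly 1–3% label noise, so a cohort of 200 still recovers ≥95% of
  groups per test.
* **One recording per subject, coupled to the first-named test.** The
  recording *is* the TUG trial, so its complexity follows the subject's
  TUG group; the other tests' groups are driven by a latent impairment
  variable correlated at 0.7, which produces non-nested multifactor label
  counts like a real battery of partially-redundant tests.

What the generator does **not** emulate: sit-to-stand and turning
segments, asymmetric or non-stationary gait, gravity leakage between
axes, sensor drift and quantisation, or any amplitude difference between
groups (deliberately — amplitude separability would be visible to the
plain statistic features and would not probe the entropy machinery).
Passing tests on synthetic cohorts therefore demonstrate that the
pipeline recovers a planted complexity difference under realistic noise
and label imbalance; they do not certify clinical performance on real
patients.

## Study-scale choices

The test suite and the acceptance script run the full pipeline at
n = 200 subjects with a single (TUG) labeling, 50 CV folds, 500 trees,
k ∈ {15, 10, 5}, and 6 CV replicates for the paired t-test; kernel
oracle checks use 50 random series up to length 200, and the known-limit
checks use 50 noise replicates of length 5000 and a 20 000-point PE
ceiling check. These sizes give stable statistics (replicate-to-replicate
pooled-AUC SD well under 0.01) while keeping a full run in the minutes
range on one CPU.

## Known limitations

* The generator's stationary harmonic-plus-noise model is a deliberate
  minimal model; none of its numeric defaults are estimates of human
  parameters.
* Impurity importance is biased toward features with more split points in
  general; here all 27 features are continuous, so the bias is immaterial,
  but permutation importance remains available.
* With extreme imbalance (4 positives of 74) some CV folds train on a
  single class and are skipped with a warning; results then rest on fewer
  folds.
* Undefined SampEn is propagated, not imputed. Short recordings at large
  scales are the usual cause; the remedy is a higher sampling rate, longer
  recording, or smaller `tau_max`, not silent substitution.
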