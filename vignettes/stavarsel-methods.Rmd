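---
title: "Stable ratio-biomarker selection and conservative error bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable ratio-biomarker selection and conservative error bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stavarsel)
```

## The problem

Classification models built from high-dimensional molecular profiles of
small cohorts — here, serum small-extracellular-vesicle miRNA sequencing
of patients along the Barrett's oesophagus disease spectrum — face two
linked obstacles. First, penalized selection (the Lasso) typically picks a
*different* sparse model in every cross-validation training set, so the
"discovered" biomarker panel is unstable. Second, with a leave-one-out
outer loop (the only affordable outer scheme at these cohort sizes) each
held-out sample yields a single prediction probability, and the standard
ways of attaching uncertainty to the resulting error estimates — a normal
(Wald) interval on the per-class proportions, or a bootstrap over the
held-out probabilities — can severely *understate* the variance precisely
when model selection is unstable.

This package implements two answers:

* **StaVarSel**, a stabilized three-stage nested cross-validation: rank
  expression ratios by how often the per-training-set Lasso selects them,
  keep those selected in at least half of the training sets, choose how
  many of the top-ranked ratios to keep by an extra round of
  cross-validations, then refit that one stable panel in every training
  set and score the held-out samples.
* A **conservative variance estimator** for the held-out prediction
  probabilities: repeated n−2 subsampling without replacement (a
  Monte-Carlo general jackknife). For each held-out sample, the training
  set is reduced by one further sample, the model re-derived, and the
  held-out sample rescored; the spread of these probabilities gives a
  nonparametric 95% interval per sample. Using all per-sample interval
  bounds *simultaneously* yields worst-case specificity and sensitivity.

## Pipeline and model

Input is a samples × miRNAs matrix of TMM-normalized counts per million
(CPM) and a two-group sample annotation. The stages:

1. **QC.** Features with mean CPM < 5 or a zero count in any sample are
   removed (strict inequality: mean exactly 5 is kept). Samples are
   flagged as global outliers when their mean, after rescaling every
   feature to mean 1, lies outside mean ± 3 SD (two-sided; flag direction
   recorded), and as haemolysed when the mean of the rescaled
   red-blood-cell markers miR-451a, miR-16-5p and miR-486-5p exceeds the
   cohort mean by 2 SD (one-sided — haemolysis only elevates them).
   Flagged samples are excluded downstream.
2. **Ratio features.** Every unordered pair of retained miRNAs becomes a
   ratio feature \(x_{ij} = \mathrm{CPM}_i/\mathrm{CPM}_j\); p features
   give p(p−1)/2 strictly positive columns.
3. **Per-training-set prefilter.** Within each outer training set only: a
   ratio is dropped when its coefficient of variation exceeds 300% in
   *both* groups, and a surviving ratio is dropped when its two-sided
   Mann–Whitney p-value exceeds 0.2. Both are strict inequalities; values
   exactly at a threshold are retained.
4. **Penalty optimization.** Within each training set, an L1-penalized
   logistic regression is tuned by repeated (default 100×) stratified
   10-fold cross-validation of binomial deviance over a geometric grid of
   100 penalties spanning four decades below the smallest penalty that
   zeroes every coefficient. Either the deviance-minimizing penalty or
   the one-standard-error rule can be used; the per-training-set
   penalties are then averaged (arithmetic mean by default) into one
   shared penalty.
5. **Selection and relaxed refit.** At the shared penalty, the Lasso is
   refit in each training set; its selected ratios are then refit by
   *unpenalized* logistic regression (the relaxed Lasso with relaxation
   0), and the held-out sample is scored. Classification uses a fixed 0.5
   cut-point, with a tie at exactly 0.5 called positive. This is the
   standard two-stage nested cross-validation.
6. **Stabilization (StaVarSel).** Ratios selected in ≥ 50% of training
   sets are ranked by selection fraction (ties by larger mean absolute
   relaxed coefficient, then lexically). A step-forward search evaluates
   k = 1, 2, … top-ranked ratios: within every training set an inner
   leave-one-out loop fits an unpenalized logistic model on the top-k
   ratios and scores the inner held-out sample; k with the lowest mean
   error wins, smallest k on ties. The top-k panel is refit in every
   training set and the outer held-out samples are scored.
7. **Uncertainty.** Three estimators of the error variance are available:
   naive Wald intervals on the per-class correct-classification
   proportions; a class-stratified bootstrap (default 2000 resamples)
   over the held-out (probability, label) pairs; and the conservative
   jackknife above, summarised by the simultaneous worst-case rule — a
   negative-class sample counts as misclassified whenever the top of its
   interval (or its point probability) reaches 0.5, a positive-class
   sample whenever the bottom falls below it.

## Numerical and design choices

**Order-statistic confidence intervals.** All nonparametric intervals
(jackknife and bootstrap) use inverse-ECDF (nearest-order-statistic)
quantiles, so every bound is an element of the stored probabilities. This
is what makes the Monte-Carlo jackknife *exactly* reproduce the
exhaustive single-deletion enumeration: with the held-out sample already
excluded, deleting one of the n−1 training samples gives at most n−1
distinct refits, and Monte-Carlo draws merely resample that support.
Interpolating quantile conventions would manufacture values off the
support and break this identity. By default the package enumerates all
single deletions when the cohort has ≤ 60 samples (exact and cheaper than
1000 draws) and falls back to Monte-Carlo above that.

**Worst-case rule includes the point estimate.** A sample counts as
misclassified in the worst case if *either* its interval bound or its
point probability lies on the wrong side of the cut-point. Including the
point makes the dominance guarantee (conservative ≤ point, per class) a
theorem rather than an almost-always property: a heavily skewed
Monte-Carlo distribution can place the mean outside the percentile band.

**Separation.** Relaxed refits on tiny training sets frequently separate.
Separation is detected scale-freely (a fitted log-odds beyond ±30) and
flagged; the reported coefficients then come from a weakly
ridge-stabilized fit (penalty 10⁻⁶) so jackknife refits never abort and
predictions stay strictly inside (0, 1). Inside the step-forward search
only the classification side of the prediction matters, so the ridge
substitution is skipped there for speed.

**Penalty averaging couples training sets.** The averaged penalty is part
of the published protocol and is kept: each held-out sample influences
*other* splits' penalty estimates and therefore, through the average, the
selection in its own split. The per-split prefilter and per-split penalty
optimization are fully isolated from the held-out sample, and the test
suite asserts exactly that (plus reproduction of the selection at the
fixed averaged penalty).

**Ratio scale.** The prefilters follow the published thresholds on the
raw quotient scale. For the penalized and relaxed fits the package
offers `log2_ratios` (off by default, matching the published analysis,
which never mentions a log step): since CPM are approximately log-normal,
raw quotients are heavily skewed and a linear logistic model on them is
dominated by the tail samples; on the log2 scale each ratio is roughly
Gaussian and selection is markedly more stable. The recovery experiments
below use `log2_ratios = TRUE`; the Mann–Whitney filter is rank-based and
indifferent to the choice.

**Frequency counting.** Selection frequencies are counted across the
outer training-set Lasso fits, one fit per split at the averaged penalty.
A fully nested variant (an inner cross-validation per training set to
derive per-split frequency tables) would multiply the cost roughly by the
cohort size for an ambiguity the source protocol does not resolve; it is
not implemented.

**Inner-CV loss.** Binomial deviance (the cv.glmnet default), clamped at
10⁻⁵ as in that workflow; misclassification loss is not offered.

## The synthetic cohort generator

`cohort_design()`/`generate_cohort()` emulate the statistical structure
the pipeline assumes: per-feature baseline abundances drawn once from a
log-normal (median 100 CPM, log-sd 1.2, i.e. a few CPM to a few thousand),
per-sample log-normal noise (log-sd 0.6, a per-feature CV of ~66%,
typical of circulating miRNA), optional multiplicative haemolysis spiking
of the three marker miRNAs, and optional whole-profile outlier factors.

A planted informative pair shifts the pair's *ratio* by the declared log2
fold-change, split evenly between numerator (up) and denominator (down),
and gives both members a shared per-sample latent factor (log-sd 1.0,
"co-regulation"). The latent cancels in the pair's ratio but inflates the
variance of every ratio pairing one member with an unrelated feature — so
the *pair*, not its individual members, is the truly informative unit,
and "recovering the planted ratio" is a well-posed question. Without the
latent, any ratio sharing the shifted numerator would be almost as
informative as the planted pair and recovery would be a lottery among
correlated proxies.

What the generator does **not** emulate: count-level sampling noise (the
pipeline consumes already-normalized CPM), library-size artefacts, batch
effects, or correlated miRNA families beyond the planted pairs. Passing
the synthetic experiments therefore demonstrates the machinery and its
statistical direction, not clinical performance on real sera.

The fixed scenarios used by the tests and the acceptance script:

* *Signal cohort*: 20 + 20 samples, 40 features, two planted pairs at
  log2 fold-change 1.5.
* *Unstable cohort* (`unstable_design()`): 8 + 8 samples, 50 features
  (1225 candidate ratios), one weak pair (log2 fold-change 1) under
  elevated noise (log-sd 0.8) — the regime the conservative estimator
  targets.
* *Null cohorts*: the signal cohort with labels randomly permuted.

## Problem sizes and observed behavior

The test suite runs the stochastic experiments at reduced inner settings
(10 repeats × 5 folds) and these sizes: 20 seeds for the recovery,
complexity and conservatism experiments, 15 seeds for the null
calibration. With those sizes the whole suite completes in well under
half an hour on a laptop core; the full published settings (100 × 10-fold
inner loops, 1000 Monte-Carlo subsamples) are available through the
configuration objects and change none of the defaults' logic.

Directions consistently observed on the synthetic scenarios: StaVarSel's
held-out balanced accuracy exceeds the standard nested CV's in ~95% of
signal-cohort seeds; conservative size selection never (or almost never)
chooses a larger panel than point-mode selection; and on unstable cohorts
the conservative balanced-accuracy lower bound sits far below the
bootstrap's (often near zero while the bootstrap reports 20–60%),
mirroring the motivating observation that non-conservative estimators
understate uncertainty exactly when selection is unstable. Recovery of
*both* planted pairs by the final stable panel occurs in roughly
two-thirds of signal-cohort seeds; the step-forward search's inner error
curve is noisy at n = 40, and parsimony (smallest k on ties) sometimes
stops at one of the two pairs. This is a real property of the procedure
at that cohort size, not an implementation artefact — the identical
decision is reproduced by a direct leave-one-out logistic oracle on the
same data.

## Known limitations

* The haemolysis and outlier rules use mean ± k·SD thresholds; when a
  large fraction of samples is contaminated the threshold inflates and
  flags can be masked. The detection-rate experiments spike a single
  sample per cohort for this reason.
* The naive Wald interval degenerates at per-class proportions of 0 or 1
  (zero width at the boundary) — a documented weakness of that estimator,
  reproduced faithfully.
* The bootstrap is uninformative under perfect separation (every
  resample yields the same specificity/sensitivity); the package warns
  in that case.
* Worst-case bounds are intentionally pessimistic and can reach 0% on
  small unstable cohorts; they bound, not estimate, the error.
* With LOOCV and an intercept-only fallback model, the training
  prevalence of the held-out sample's class is always slightly below
  one half, so a null cohort scores a balanced accuracy *below* 0.5 —
  an inherent LOOCV artefact worth knowing when reading null
  calibrations.

## A worked example

```{r example, eval = FALSE}
cohort <- worked_example_cohort()
qc <- run_qc(cohort$expression, cohort$metadata)
ratios <- build_ratios(qc$expression)

fit <- run_stavarsel(ratios, qc$metadata,
                     cv = cv_config(inner_repeats = 10, inner_folds = 5),
                     prefilter = prefilter_params(log2_ratios = TRUE),
                     seed = 1)
fit <- conservative_intervals(fit, uncertainty_config(), seed = 2)

glance(fit)
estimator_report(fit, seed = 2)
plot_prediction_probabilities(fit$records)
autoplot(fit)         # step-forward error curve
```
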