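---
title: "Auditing liver-disease classifiers for sex bias: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing liver-disease classifiers for sex bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liverfair)
```

## The problem

Classifiers trained on liver-function panels (bilirubins, ALP, ALT, AST,
proteins, albumin, A/G ratio) routinely reach >70% accuracy at flagging liver
patients, and the Indian Liver Patient Dataset (ILPD) is the standard
benchmark for them. The ILPD is sex-imbalanced (roughly three males per
female) and clinical evidence suggests liver injury expresses more mildly in
female biochemistry. An overall accuracy number can therefore hide a
clinically serious asymmetry: if a model misses diseased women at a higher
rate than diseased men, the aggregate metric never shows it.

`liverfair` packages the audit that makes this visible: evaluate every model
**stratified by sex**, summarise each metric's male−female gap over many
repeated train/test cycles, and test that gap for significance.

## The audit statistic

For each evaluation metric $m$ (accuracy, F-score, ROC AUC, precision,
recall, FNR, TNR, FPR, TPR) computed per sex on each of $R$ runs,

$$\Delta_m \;=\; \overline{m}_{\text{male}} - \overline{m}_{\text{female}}$$

in percentage points, with a two-sided paired $t$-test on the per-run
differences $d_r = m_{\text{male},r} - m_{\text{female},r}$:
$t = \bar d / (s_d/\sqrt{R})$, $R-1$ degrees of freedom, $\alpha = 0.05$, no
multiple-testing correction (matching the source methodology; a user can
apply one downstream from the reported p-values). Negative $\Delta$ means the
female mean is larger — an advantage on benefit metrics, a burden on error
metrics. Because FNR $= 1 -$ recall and FPR $= 1 -$ TNR identically, the
FNR/recall and FPR/TNR rows of any report table are exact sign mirrors; the
suite asserts this to 1e-12.

Metrics are derived from per-group confusion counts; a ratio with a zero
denominator is *undefined* (`NA`), never zero-filled, and undefined entries
are dropped pairwise from disparity series with the dropped count reported
(zero-filling would bias disparities toward zero in small strata). ROC AUC is
the Mann–Whitney statistic with midrank tie handling, computed from each
model's continuous score (predicted probability where the family has one, the
decision-function value for the SVM — rank-equivalent, which is all AUC
needs).

## The pipeline

1. **Read / generate.** `read_ilpd_csv()` reads the headerless UCI dialect
   (column order configurable, Gender parsed case-insensitively, raw Selector
   codes preserved); `generate_cohort()` draws synthetic cohorts (below).
2. **Prepare.** `recode_target()` (Selector 1 → disease 1), `encode_sex()`
   (female 0 / male 1; the categorical field is retained and is what all
   stratification uses, so the direction is inert), `impute_mean()` (the A/G
   ratio column has sporadic gaps), `minmax_scale()` (age + biomarkers; the
   0/1 sex code and target are left alone). A constant feature scales to 0
   rather than erroring so degenerate cohorts pass through.
3. **Balance.** `balance_classes()` SMOTE-oversamples the minority (healthy)
   class to exact parity; `balance_sexes()` then oversamples females to
   parity (the dataset-2 / dataset-3 construction: 583 → 832 → 1190 records
   on the published counts).
4. **Audit.** `run_experiment()` repeats balance → 70/30 split → optional RFE
   → optional grid-search tuning → fit → sex-stratified evaluation, then
   aggregates the disparity table. `run_grid()` crosses the four experiment
   designs with the four learner families (16 cells).

### The four experiments

| experiment | modelling data | feature selection |
|---|---|---|
| 1 | class-balanced, sex-unbalanced | none |
| 2 | class- and sex-balanced | none |
| 3 | class-balanced, sex-unbalanced | RFE top 5 |
| 4 | class- and sex-balanced | RFE top 5 |

"Unbalanced" throughout means *sex*-unbalanced: class balancing is part of
data preparation for all experiments, mirroring common ILPD practice.

### Faithful versus safe mode

The common ILPD pipeline (and the study this audit reproduces) imputes,
scales and oversamples the **whole** dataset before splitting. That leaks
test information into preprocessing statistics and puts interpolated records
into test sets. `mode = "faithful"` (default) reproduces exactly that, so
results are comparable with the literature; `mode = "safe"` splits first,
fits imputation/scaling on the training fold only, oversamples the training
fold only (sex balance via equal per-sex training subsets), and evaluates on
original records. Every report records the mode.

## SMOTE details

Each synthetic record is $x + u\,(x_{nn} - x)$, $u \sim U(0,1)$, with the
seed record $x$ drawn uniformly with replacement from the group being
oversampled and $x_{nn}$ one of its $k = 5$ nearest neighbours (Euclidean
distance) within that group ($k$ is the conventional default; the source
methodology does not state one). Two deliberate choices:

* **Interpolation covers the continuous features only** (age + 8 biomarkers).
  The categorical sex, its 0/1 code and the disease label are inherited from
  the seed record. A generic SMOTE on the encoded matrix would interpolate
  the sex code to fractional values; inheriting instead keeps every record's
  sex well defined, which the later sex-stratified evaluation of balanced
  data requires.
* **Neighbour scope**: class balancing searches neighbours within the
  minority class (either sex); sex balancing searches within the minority sex
  (either class), label inherited from the seed. Consequently the class mix
  of synthetic females is data-geometry-dependent — the published dataset-3
  female class split is not derivable from counts alone, and is not asserted
  anywhere. A `within_class` option constrains neighbours to sex × class
  cells for users who prefer proportional scaling.

## Learners

No classifier dependencies are assumed; the four families are implemented in
the package behind one interface (`fit_learner()` / `predict()`):

* **Random forest** (compiled): CART/gini trees, bootstrap + per-node feature
  subsampling (`mtry = ⌊√p⌋`), 100 trees, probability = mean of leaf class-1
  fractions; impurity importance accumulated for RFE. All draws use R's RNG,
  so forests are exactly reproducible under a seed.
* **Logistic regression**: ridge-penalised (objective $-\ell + \|w\|^2/2C$,
  intercept unpenalised) by Newton's method — deterministic and immune to
  separation.
* **SVM**: RBF-kernel C-SVC solved as the dual QP (`quadprog`), with the
  "scale" gamma convention $1/(p \cdot \mathrm{var}(X))$ and a $10^{-6}$
  diagonal jitter for positive definiteness.
* **Gaussian naive Bayes**: closed form, variance smoothing $10^{-9}
  \max_j \mathrm{var}(x_j)$.

Tuning (`tune = TRUE`, the default in `experiment_config()`) is a grid search
with 3-fold CV on the training fold only: forest trees {100, 200} × depth
{unbounded, 8}; logistic C {0.1, 1, 10}; SVM cost {0.1, 1, 10}; nothing for
naive Bayes. Grids are overridable; a one-point grid is bit-identical to
tuning off. Whether the source study tuned once or per run is unstated; this
package refits per run. The desk-scale calibration tests run with tuning off
purely for time.

**RFE** drops one lowest-importance feature per refit until five remain.
Importance: |coefficient| for the logistic model, impurity importance for the
forest; the SVM and naive Bayes expose neither, so a ridge-logistic surrogate
performs their elimination (recorded on the result) — mirroring how the
standard elimination utilities are used with such estimators. Ties in
importance (and in Pearson rankings) break by codebook column order, for
determinism.

## The synthetic cohort generator

`generate_cohort()` exists so the full audit is exercisable and testable
without the UCI download. It emulates the *structure* of the real cohort, not
its moments:

* **Right-skewed, non-negative biomarkers**: each is log-normal, with
  magnitudes resembling a liver panel (ALP ~190 IU/L, albumin ~3.3 g/dL, …).
  Disease shifts the log-mean by a per-feature effect (enzymes and bilirubins
  up, albumin/proteins/AG slightly down).
* **Effect sizes** default to ≈0.6 within-class SD per informative feature on
  the log scale. Chosen once so that the standard classifiers land in the
  70–85% accuracy band reported across the ILPD literature — the regime the
  audit is meant for — rather than a near-separable toy; they are *not* fit
  to the real data (no moment matching).
* **Sex-differential expression**: for diseased females every effect is
  multiplied by an attenuation $\gamma \in [0,1]$. $\gamma = 1$ is the
  exchangeable-sexes null; decreasing $\gamma$ weakens the female disease
  signal, which the audit should recover as a negative FNR disparity. The
  suite checks monotonicity over $\gamma \in \{1, 0.7, 0.4\}$.
* **Composition**: `ilpd_like_spec()` fixes the real sex totals (142/441)
  and per-sex prevalences (92/142, 324/441), missing A/G cells at the real
  rate (4/583), $\gamma = 0.7$; `null_spec()` gives equal counts, equal
  prevalences, $\gamma = 1$, no missingness.
* Labels are drawn before features (labels cause features), features are
  conditionally independent given the label by default, and ages carry no
  disease signal — so separability is controlled by the stated effects alone
  and the null is exactly exchangeable.

What the generator does **not** emulate: feature–feature correlation (real
bilirubins and transaminases are strongly correlated), measurement rounding,
heaped ages, or any site effects. A green synthetic test therefore
establishes that the machinery detects the modelled mechanism — attenuated
female biomarker expression — not that the real ILPD disparity has that
mechanism.

## Calibration, and a caveat the tests surface

On null cohorts the audit's mean disparities centre on zero (checked over
replicate audits). But the per-audit **paired t-test rejection rate is far
above** $\alpha$ on null cohorts, and the acceptance suite deliberately
asserts the nominal-calibration expectation and lets it fail. The reason is
structural, not a coding defect: the runs of one audit re-split the *same*
finite cohort, so their male−female differences share that cohort's
idiosyncratic realized disparity, and with enough runs the t-test will detect
it. The same machinery is calibrated when the pairs are independent (the
suite's Monte-Carlo check on iid pairs), and the inflation applies equally to
any published analysis using repeated resampling of one dataset with paired
tests. Practical reading: a significant p-value from `run_experiment()` says
"this cohort shows a systematic disparity across splits", not "cohorts from
this population do".

## Other numerical conventions

* IQR profiles use linear-interpolation quantiles (`type = 7`), stated
  because the published per-sex mean-IQR figures depend on the convention.
* Pearson ranking records a zero-variance feature as $r = 0$ with a warning.
* Splits redraw (bounded, 20 tries) until both sexes and classes appear in
  the test fold; >10% degenerate runs aborts an experiment.
* Seeds: run $r$ uses `base_seed + r`; balancing, splitting, RFE and the
  learner each draw from independent streams derived from the run seed, so
  components are individually reproducible.
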