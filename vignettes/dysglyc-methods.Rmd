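---
title: "Predicting inpatient blood glucose decompensation with an error-correcting ensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting inpatient blood glucose decompensation with an error-correcting ensemble}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Inpatient dysglycemia — blood glucose (BG) falling below 3.9 mmol/L
(hypoglycemia) or rising above 10, 13.9 or 16.7 mmol/L (three grades of
hyperglycemia) — is common, dangerous, and in principle predictable from
data a hospital already has: routine laboratory results, demographics, drug
administrations and diagnosis history. The difficulty is the shape of that
data: every patient has their own set of analytes, measured at their own
irregular times, with most of a 52-analyte panel missing for most
admissions.

`dysglyc` implements a pipeline for this setting:

1. **Event anchoring.** Within each admission ("case"), BG measurements are
   assigned categories 0–4 (`categorize_bg()`; the band \[3.9, 10\] mmol/L
   is category 0). The *first* event per category is the prediction target;
   an event already present at the case's first measurements is voided —
   with no prior data there is nothing to predict from.
2. **Look-back windows.** An event instance uses all data strictly before
   its event; a case without events contributes one control instance using
   the full stay. The time from the last datum to the event is the
   *prediction horizon* — the lead time an alert would have had.
3. **Derived variables.** Each analyte series inside a window is reduced to
   eight statistics (mean, sample SD, IQR, total range, recent trend, most
   extreme value, most recent value, analysis count), joined with
   demographics, antidiabetic drug history (ATC A10), previous
   decompensations, diabetes diagnoses, ICU stay and isolation-forest
   outlier flags. Rows are hashed and deduplicated.
4. **Binary model library.** Gradient-boosted tree classifiers
   (`xgboost`, sparsity-aware splits, so missingness needs no imputation)
   are trained for clinically relevant positive-class combinations
   (A = any decompensation, B = hypoglycemia, …, I = moderate+severe
   hyperglycemia), with inverse-frequency instance weights and a stochastic
   hyperparameter search over a 70/30 case split.
5. **Error-correcting ensemble.** Each class has an ideal bit string
   ("codeword") over the chosen binary models; a case's votes are decoded to
   the class at minimal Hamming distance, ties broken by clinical severity
   (hypoglycemia > severe > moderate hyperglycemia > control > mild
   hyperglycemia — mild ranks last to limit false alarms). At least
   ⌈log₂ 5⌉ = 3 binary models are needed; extra models add error-correcting
   redundancy. The composition is chosen by a genetic algorithm maximizing
   macro-averaged precision of the decoded predictions on the withheld
   split.

```{r, eval = FALSE}
library(dysglyc)
coh <- preprocess_cohort(generate_cohort(cohort_config(n_patients = 600,
                                                       seed = 1)), seed = 1)
lab <- label_cohort(coh)
ft  <- derive_features(coh, lab)
fit <- glyc_ecoc(ft, budget = 10, seed = 1)
summary(fit)
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `category_prevalences` | 12.8 / 42.1 / 16.4 / 13.3 % | per-admission probability of a category 1–4 event |
| `signal_strength` | 1.5 | pre-event shift of the signal analytes, in SD units; 0 gives a null cohort |
| `signal_window_h` | 12 h | length of the linear pre-event shift |
| `missingness` | 0.6 | mean per-(case, analyte) inclusion probability |
| `budget` | 100 | random hyperparameter draws per binary model (the original analysis scale is 2000–4000) |
| `threshold` | 0.5 | per-model vote threshold on predicted probability |
| `ga_control()` | pop 50, 30 generations, uniform crossover 0.5, mutation 1/L, tournament 3, elitism 2 | composition search |
| contamination | 0.01 | fraction of measurements flagged per analyte |

Plausibility limits are fixed to the conventional values: age 18–130 years,
height 100–250 cm, weight 25–400 kg blanked to missing; laboratory rows
removed when negative (except base excess) or outside
chloride 65–138 mmol/L, plasma pH 6.8–7.8, potassium 1.3–9.0 mmol/L,
sodium 100–191 mmol/L.

## What the synthetic cohort emulates — and what it does not

No real hospital extract ships with this package, so `generate_cohort()`
produces one with the statistical structure the pipeline assumes, plus the
ground truth needed to test it:

* **Irregular sampling.** Lab times follow an inhomogeneous Poisson process
  with a daytime-peaked intensity (staffing-driven sampling bias). Sampling
  rates differ by analyte: glucose is monitored most intensively
  (6/day) in this dysglycemia-risk population, acute-phase analytes next;
  specialized tests are rare. Per-analyte presence probabilities (core panel
  ≈ 0.9, specialized tests ≈ 0.25, mean 0.6) emulate sparse panels.
* **BG trajectories.** Background glucose is an Ornstein–Uhlenbeck process
  (relaxation time 6 h, stationary SD 0.8 mmol/L) around a per-case
  set-point, clamped inside the nondecompensated band. Injected events are
  therefore *exactly* the decompensations present in the data, which makes
  ground-truth recovery a sharp test.
* **Episode structure.** All injected events of a case share one episode
  timestamp, and hypoglycemia episodes exclude hyperglycemia. Per-category
  prevalences still match the configured marginals exactly; what is given up
  is co-occurrence structure (the rare case with both hypo- and
  hyperglycemia in one admission is not emulated). The design reason:
  sequential events would leave traces of one event inside another event's
  look-back window and, via the previous-decompensation indicators,
  make even a signal-free cohort learnable. With a single episode per case,
  a window never contains evidence of another event of the same case.
* **Null comparability.** Episode times and control stays are drawn from one
  common truncated log-normal (median 4.5 d); event cases stay on after
  their episode. Under `signal_strength = 0`, event and control windows are
  then identically distributed and no feature carries label information —
  the permutation argument behind the null-AUC check holds by construction.
* **Signal.** Six analytes (glucose, lactate, CRP, WBC, cortisol,
  triglycerides) shift linearly by `signal_strength` SD over the 12 h before
  an episode; glucose drifts toward the band edge, downward for
  hypoglycemia. In addition, monitoring intensifies ahead of an episode
  (glucose ×3, signal analytes ×2 within the window) — emulating the
  clinical reality that staff measure more when they suspect deterioration,
  and giving recency/count features a genuine, clinically interpretable
  share of the signal. Both mechanisms are gated on `signal_strength > 0` so
  the null cohort stays null. Drug, diagnosis and ICU context variables are
  deliberately *not* associated with outcomes: associations are confined to
  the stated signal structure.
* **Inclusion guarantee.** Every synthetic patient satisfies at least one
  cohort inclusion rule (diabetes-related ICD-10 code, ATC A10 drug, or an
  extreme-glycemia laboratory criterion), mirroring a cohort extracted
  after inclusion filtering; patients with neither diagnosis nor drug
  receive a qualifying HbA1c measurement, independent of outcome status.

Analyte reference means and SDs are invented and not clinically calibrated;
pharmacokinetics, insulin dosing and between-analyte correlations beyond the
stated signal are out of scope. Passing tests on this cohort demonstrate
that the *pipeline machinery* is correct and that injected signal of known
size is recovered — they say nothing about performance on real EHR data,
where signal size, sampling bias and label noise are unknown.

## Numerical and design choices

* **Boundaries.** Category boundaries are closed exactly as stated
  (3.9 and 10.0 are category 0; 13.9 is category 2; 16.7 is category 3);
  times are continuous hours since admission with half-open windows
  \[admission, event).
* **"First measurements of a case"** is read as the earliest timestamp of
  *any* laboratory datum (configurable to BG-only via
  `first_measurement = "bg"`): an event at that timestamp voids the
  category for the case, and such cases are not reused as controls.
* **Recent trend** is the OLS slope (units/hour) over the last
  `min(3, n)` points, missing below two points — the most literal
  self-contained reading of a "recent trend". **Most extreme value** is the
  value maximizing |x − window mean|, ties resolved to the later
  measurement; this needs no external reference ranges.
* **Quantiles** are linear-interpolation (type 7) quantiles; SD is the
  sample SD; at a single observation SD, IQR, range and trend are missing
  rather than zero.
* **Control windows for multi-event cases** outside a model's positive set
  use the window of the case's earliest event, keeping look-back semantics
  comparable between positives and controls; never-decompensated cases use
  the full stay.
* **Outlier flags.** The isolation forest (100 trees, subsample 256,
  contamination 0.01 — conservative, as the flagging rate is otherwise
  unconstrained) runs per analyte on (value, time-since-admission) pairs, so
  the sparse wide matrix never needs imputation; flags are aggregated per
  window (count and any-flag) as additional predictors. Per-measurement
  flagging with per-case aggregation is one of several defensible readings;
  it is the default here and configurable in the code path.
* **Retained-metric rule.** The library records precision, sensitivity,
  specificity, AUC ROC and informedness for every candidate; the retained
  model maximizes one configurable selection metric (default AUC ROC), since
  no combination rule over the four metrics is canonical.
* **"Average precision"** for the composition search is read as
  macro-averaged per-class precision of the decoded multiclass predictions
  (classes never predicted score 0, so compositions cannot earn credit by
  refusing a class); the PR-curve-area reading is available as
  `fitness = "pr_auc"`.
* **Model types C–F** are not pinned down by the published ensemble; the
  defaults C = {2}, D = {3}, E = {4}, F = {1, 3, 4} are placeholders and
  configurable.
* **Hashing** uses a 64-bit FNV-1a digest of the canonicalized row string
  (ids, category and all feature values at 10 significant digits).
* **Report rounding** is half-up at display time only; raw values are kept
  internally and exposed via attributes.
* **Tie-breaking in decoding** reorders classes by the clinical priority and
  takes the first minimal distance, which is exactly "minimum distance, ties
  by priority" but vectorizes over instances.

## Problem sizes used by the test-suite and acceptance script

Module tests run on a ~250-case cohort. The learnability checks use the
generator's default conditions at ~2000 cases with a search budget of 50
draws per model, and a ~3000-case null cohort — the null run is the larger
of the two so that the sampling error of a held-out AUC (SE ≈ 0.02) is small
against the ±0.05 band around chance. The composition-search optimality
check compares the genetic algorithm against exhaustive enumeration of all
2⁹ − 1 member masks. Cross-validation defaults to case-level folds
(`by-patient` grouping is the natural extension when repeat admissions are a
leakage concern; case-level matches the 70/30 convention used throughout).

## Known limitations

* Synthetic analyte distributions are Gaussian and uncorrelated except for
  the injected signal; real panels are skewed and strongly correlated.
* The three hyperglycemia grades share one signal direction, so their
  mutual confusion in the synthetic demonstration is structural — as it is,
  for different reasons, in real data, where they form a continuum.
* Vote thresholds default to 0.5 and are not calibrated; probability
  calibration is out of scope.
* The prediction horizon on synthetic data reflects the configured
  sampling intensification before events and should not be quoted as a
  clinical lead-time estimate.
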