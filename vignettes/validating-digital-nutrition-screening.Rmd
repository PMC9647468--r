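---
title: "Methods: screening instruments, intake estimation, and validation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening instruments, intake estimation, and validation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutriscreen)
```

This vignette is the package's own account of its methods: the scoring
rules and where they come from, the intake model, the statistics, the
synthetic-cohort generator and its calibration, and the numerical and
design choices made where the published material leaves the design open.

## The screening instruments

### Adapted NRS-2002

The package scores the *final screening* form of the NRS-2002 only. The
published instrument's four-question initial screen is deliberately not
modelled: in routine hospital practice the final screen is administered
directly, and self-administered adaptations follow that practice. The
total is the sum of three components, and risk is flagged at total ≥ 3:

* **Impaired nutritional status (0–3)** — the worst of three indicators:
  * *weight loss*: 5–15% loss over 3 months scores 1, over 2 months 2,
    over 1 month 3; loss exceeding 15% scores 3 at any timeframe (a ≥15%
    loss within 3 months is already the instrument's worst row);
  * *BMI*: below 18.5 scores 3, 18.5 to below 20.5 scores 2, otherwise 0.
    The published worksheet couples low BMI with an "impaired general
    condition" qualifier; the self-administered questionnaire never asks
    it, and for hospitalized oncology inpatients we treat it as satisfied.
    This is a deliberate design decision, stated here because it is
    consequential: BMI < 18.5 alone flags risk under these rules;
  * *intake reduction*: the questionnaire's roughly-quartile reduction
    bins score 1 (25–50%), 2 (50–75%) and 3 (75–100%), mirroring the
    instrument's intake-as-fraction-of-requirement rows.
* **Disease severity (0–3)** — the maximum severity over the diseases the
  patient selects from a configurable catalogue. The shipped catalogue
  seeds the published instrument's prototype grades (e.g. solid tumor 1,
  hematologic malignancy or major abdominal surgery 2, intensive-care
  level illness 3); real deployments are expected to extend it, which is
  why it is configuration rather than code.
* **Age (0–1)** — one point at age ≥ 70.

The weight-change question is presented to respondents with the 5% and
15% thresholds converted to kilograms of their own current weight
(`weight_loss_thresholds()`), rounded to one decimal. The rule is a strict
percentage; worked examples in circulation that print other values for a
58 kg patient are arithmetically inconsistent with the percentage
definition, and the package follows the definition.

### Reduced PG-SGA-SF

The patient-completed short form is reduced to its first three boxes —
weight history, food intake, symptoms — dropping activities-and-function;
risk is flagged at total ≥ 4. Published versions of the worksheet specify
the *ordering* of severities but deployed adaptations differ in exact
points, so the whole map lives in configuration
(`default_scoring_config()$pgsgasf`), with a shipped default that
preserves the published ordering: weight history 0/3/4 for
stable / 5–15% loss / >15% loss, +1 when the loss occurred within one
month; intake reduction 0/1/2/3; diet texture normal 0, soft 1, liquid 2,
fasting 4; the food-intake box contributes the *greater* of the reduction
and texture points (the worksheet's greatest-box-score convention);
appetite never 0, occasionally 1, frequently 3. No package test or
reported quantity depends on the specific default values beyond their
monotone ordering and the cutoff; this is intentional, since the exact
deployed mapping is not recoverable from published material.

Both engines are pure functions of (profile, responses, configuration):
the test suite checks determinism, boundedness, cutoff consistency and
monotonicity (worsening any single answer never lowers a total) by
exhaustive enumeration of the finite response space against an
independently written lookup oracle, and every scoring run is stamped with
an MD5 hash of its configuration.

Ages outside the usual 18–80 eligibility window and BMI outside (10, 60)
are scored but warned about rather than rejected: a screening engine
should not silently refuse plausible clinical data.

## The three-item dietary assessment

Daily energy intake is estimated as

$$E = b_E + \sum_{i \in \{\text{rice, meat, milk}\}} a_i \,
      \frac{x_i}{100} \, e_i$$

with reported daily amounts $x_i$ (g, or mL for milk), per-100 g energy
densities $e_i$, per-item multiplicative adjustments $a_i$ and an additive
daily intercept $b_E$; protein analogously. The three items are the
dominant energy and protein sources in the target diet; the adjustments
exist because a three-item recall omits foods (cooking oil, vegetables)
that a full recall would capture, and a pilot-survey calibration would
absorb them multiplicatively. The shipped table uses plausible densities
for cooked rice (116 kcal, 2.6 g/100 g), cooked mixed meat (250 kcal,
20 g/100 g) and whole milk (65 kcal, 3.0 g/100 mL), adjustments 1.25 and
zero intercepts. **These are a documented default, not a published
calibration**; the table is versioned and every estimate carries the
version string. Amounts above 2000 g/day per item are flagged as
implausible but not rejected. Amounts are accepted as cooked,
as-consumed weights; raw-to-cook conversion belongs to the
dietitian-administered reference workflow, which enters this package only
as externally supplied intake numbers.

Requirements are weight-proportional with defaults of 25 kcal/kg/day and
1.2 g protein/kg/day — mid-range of standard inpatient guidance, and
per-call overridable since guidelines individualise by clinical state. The
reported gap is intake − requirement, so shortfalls are negative.

## Validation statistics

The validation unit is a paired 2×2 table (`tp` = index positive and
reference positive, `fp` = index positive / reference negative, `fn`, `tn`).

* **Proportions** (accuracy, sensitivity, specificity, PPV, NPV) with
  Clopper–Pearson exact CIs by default and Wilson score CIs by flag. The
  exact interval is the default because it is the conservative standard
  for the modest denominators typical of single-site validation studies.
  Point estimates, not CI endpoints, are the surface other results are
  compared on. A metric with an empty denominator is returned as
  *undefined with an explicit flag* — the package never emits a silent
  `NaN`.
* **Cohen's κ** with the large-sample (Fleiss–Cohen–Everitt) standard
  error. Degenerate margins ($p_e = 1$) leave κ undefined, flagged.
* **McNemar's test** with the continuity correction off by default (a
  flag enables it) and an automatic exact-binomial fallback when the
  discordant count is below 25. Both variants are reported by the test
  suite because published analyses rarely state which they used; for
  well-separated discordant cells the conclusion is variant-invariant.
* **Correlation** by Pearson or Spearman, with `method = "auto"`
  selecting Pearson only when both margins pass a Lilliefors-corrected
  Kolmogorov–Smirnov normality screen at α = .05 (the estimated-parameter
  correction is the statistically right version of the screen; samples of
  fewer than 5 are treated as non-normal). CIs use the Fisher
  z-transform, which is exact-variance for Pearson and a tagged
  approximation for Spearman.
* **Paired agreement** for continuous intakes: mean ± SD of differences,
  median and IQR (type-7 quantiles) of per-pair relative differences
  100·(app − ref)/ref — pairs with ref ≤ 0 are excluded with the count
  logged, since the relative difference is undefined there — and a paired
  t or Wilcoxon signed-rank test chosen by the same normality screen
  applied to the differences.
* **Validity grading** applies the conventional bands per criterion and
  never merges them: sensitivity+specificity good when both exceed 80%,
  poor when either falls below 50%, fair between; CC ≥ 0.75 / ≥ 0.4;
  κ ≥ 0.6 / ≥ 0.4. Undefined inputs grade "undetermined". Note the bands
  can disagree across criteria for the same table — a κ just below 0.4
  grades poor on the κ band while the same table grades fair on
  sensitivity/specificity; the package reports all three.

## The synthetic-cohort generator

`generate_cohort()` emulates the structure a paired validation study
assumes, so the full pipeline can be exercised and calibrated without
patient data. Defaults describe the study conditions the package is
validated under: n = 244; an NRS-2002 arm with reference prevalence 0.172
and index sensitivity/specificity 0.810/0.767; a PG-SGA-SF arm with
0.238 and 0.845/0.645; age lognormal matched to median 59 (IQR 51–68) and
truncated to 18–80; weight normal 58.6 (SD 8.9) truncated above 30 kg;
BMI normal 22.2 (SD 2.9); height *derived* from weight and BMI so the
triplet stays consistent; 63.9% male.

Design choices worth stating:

* **Index errors are non-differential**: misclassification is
  conditionally independent of demographics given the reference flag —
  the simplest structure consistent with a marginal 2×2 summary. Real
  self-screening errors plausibly correlate with age or literacy; passing
  calibration tests here says nothing about such differential effects.
* **Response sampling is uniform over the satisfying set.** For each
  record, questionnaire answers are drawn uniformly from the enumerated
  combinations whose score falls on the index flag's side of the cutoff,
  guaranteeing round-trip consistency (re-scoring reproduces the flag for
  100% of records, which the tests assert). Any non-uniform weighting
  would be unidentifiable from published marginal tables.
* **Profile truncation for flag-0 NRS records.** Under the shipped rules
  a profile with BMI subscore + age point ≥ 3 (BMI < 18.5, or BMI in
  [18.5, 20.5) at age ≥ 70) cannot score below the cutoff, so such
  profiles are redrawn for index-negative records — a mild, clinically
  sensible truncation of the joint demographic distribution among
  index-negatives (underweight elderly patients *should* flag risk).
  `responses_for_flag()` raises an error on an empty satisfying set
  rather than returning inconsistent answers.
* **Paired energy intakes** are bivariate normal, parametrised by both
  marginals and the correlation: reference mean 1434.1 kcal (SD 528.8),
  app mean 1578.3 (SD 468.4), r = 0.59, i.e.
  app = μ_app + r·(σ_app/σ_ref)(ref − μ_ref) + ε with
  σ_ε = σ_app·√(1 − r²). This attenuated-regression form was chosen over
  an additive bias-plus-noise model because the three summaries it
  implies — mean difference 144.2, difference SD
  √(σ_app² + σ_ref² − 2rσ_appσ_ref) ≈ 454.7, and both marginal SDs — are
  mutually consistent, whereas independent additive noise cannot match an
  app SD *smaller* than the reference SD. Pairs are redrawn until both
  values are positive; the configured moments refer to the untruncated
  distribution, and the positivity restriction perturbs the mean
  difference by ≈ (λ − 1)·σ_ref·φ(q)/Φ(q) ≈ −2.6 kcal (λ the regression
  slope, q = μ_ref/σ_ref) — visible only at calibration-test sample
  sizes, and accounted for analytically there.
* **Protein intakes** are lognormal (a Gaussian copula on logs), matched
  to reference median 61.7 g (IQR 43.0–82.8) and app median 79.0 g (IQR
  62.7–95.3), correlation 0.47 applied on the log scale. Matching a
  lognormal to a printed median and IQR is overdetermined — the log-IQR
  midpoint need not equal the log median — so σ comes from the IQR ratio
  and μ from the median. The printed difference SD for protein is not
  exactly consistent with these marginals at r = 0.47; the correlation
  was taken as the calibration target and the difference SD emerges
  (~33 g). The raw-scale rank correlation of a log-scale Gaussian copula
  is slightly below its Pearson parameter (≈ 0.45 at 0.47), which the
  calibration test tolerances anticipate.
* **Item amounts** (rice/meat/milk) are back-calculated from each
  record's app energy with Dirichlet-distributed shares around typical
  contributions, so `estimate_intake()` on the amounts reproduces the
  app's energy exactly and the `assess` stage of the pipeline is
  internally consistent. The app's *protein* column is simulated from its
  own marginal and will generally differ from the table-implied protein —
  validation consumes the recorded columns, not the re-derived ones.
* The two instruments are simulated as **separate arms** because their
  within-patient joint distribution is not identifiable from separate
  marginal tables; no record carries reference flags for both.

Everything is a deterministic function of (config, seed).

## Problem sizes and calibration

The package's own calibration checks (in the test suite and the
acceptance script) use: exhaustive enumeration of the response spaces
(420 NRS-2002 combinations across BMI bands and age points; 336
PG-SGA-SF combinations); 200 independent n = 244 cohorts for
parameter-recovery of sensitivity (±0.7 replicate-SE band) and κ (±0.03);
single cohorts of n = 10⁴–10⁵ for convergence of prevalence (4 binomial
SE), sensitivity/specificity, intake bias, difference SD (2%) and
correlation (±0.05); and 1000 random tables for exact (1e−12) agreement of
all 2×2 metrics with a from-first-principles oracle. These sizes were
chosen so each check's sampling error is several times smaller than the
effect it guards.

## What passing tests do and do not show

The simulator reproduces the *assumed* structure of a validation study:
non-differential misclassification, independence of intake errors from
demographics and from screening errors, and clean categorical responses.
Real data violate all three in ways a synthetic calibration cannot
detect — recall bias that varies with age, intake misreporting correlated
with nutritional status, ambiguous questionnaire answers. Passing
recovery tests shows the statistics and the pipeline are implemented
correctly, not that a particular deployed instrument is valid. The
shipped food-composition coefficients and PG-SGA-SF point values are
documented defaults standing in for deployment-specific calibrations, and
conclusions drawn from them inherit that caveat.

## Known limitations

* No ROC/AUC analysis: the instruments are binarized at their published
  cutoffs before validation, so only 2×2 machinery is provided.
* No multi-rater κ, and no Bland–Altman plotting (the summary numbers are
  computed; rendering is left to the user).
* The κ and Spearman CIs are large-sample approximations; for very small
  validation samples a bootstrap would be preferable.
* Energy and protein only; no micronutrients.
* The CLI is a thin wrapper over the R API and performs no concurrent
  processing; cohorts are assumed to fit comfortably in memory.
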