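---
title: "Methods: the SAS score, its comparators, and the evaluation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SAS score, its comparators, and the evaluation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasscreen)
```

## The screening problem

Obstructive sleep apnea syndrome (OSAS) is diagnosed by polysomnography
through the apnea–hypopnea index (AHI), the mean number of apneas and
hypopneas per hour of sleep; AHI ≥ 30 events/h marks clinically
significant disease. Polysomnography is too expensive for population-wide
screening, so questionnaire-style risk scores are used to decide who to
refer. The widely used STOP-Bang score is very sensitive but so
unspecific that screening a large population floods sleep laboratories
with false positives. `sasscreen` implements a simple continuous score
built for higher specificity, the *SAS score*, alongside the STOP-Bang
and NoSAS comparators, and a full diagnostic-performance engine for
judging any of them against an AHI reference standard.

## The SAS score

Each of four routine measurements is standardised by a fixed, clinically
conventional reference value, and the standardised components are summed:

$$
\mathrm{SAS} \;=\; \frac{\mathrm{BMI}}{30}
\;+\; \frac{\mathrm{NC}}{40\ (\text{women})\ \text{or}\ 43\ (\text{men})}
\;+\; \frac{\mathrm{SysBP}}{140}
\;+\; \frac{\mathrm{ESS}}{11},
$$

with BMI in kg/m², neck circumference (NC) in cm, systolic blood pressure
in mmHg and the Epworth sleepiness score (ESS, an integer 0–24). The score
is dimensionless, has no hard bounds, but falls in (2, 7) for essentially
all physiologically plausible inputs; each component equals exactly 1 at
its reference value, which is what the printable sub-score charts
(`subscore_table()`, `autoplot()`) display. Risk bands partition the score
with left-closed boundaries at 3, 3.5, 4 and 5 (Low, Mild, Moderate,
High, Very high); `scorecard_grid()` tabulates the score over binned
measurements for fully offline use.

A worked example: a man with BMI 39, NC 46, SysBP 140 and ESS 11 − 3 = 8
scores 39/30 + 46/43 + 140/140 + 8/11 = 4.0970, band High. Reading the
same patient off the printed charts gives roughly 4.15 — chart reading is
only accurate to about one decimal per component, so formula and chart can
disagree by up to ~0.06. The formula is canonical in this package; chart
artifacts are rendered from it, never the other way around.

Comparisons are deliberately literal to each instrument's definition:
STOP-Bang items use strict thresholds (age > 50, BMI > 35, NC > 41/43
women/men), NoSAS items are inclusive (NC ≥ 40, age ≥ 55, BMI bands at
25 and 30), and positivity is inclusive for all three scores
(`score ≥ cutoff`). Two documented ambiguities in the NoSAS literature are
exposed as configuration switches rather than silently resolved:
`nosas_bmi_two_band` (default `TRUE`: 3 points for 25 ≤ BMI < 30, 5 for
BMI ≥ 30; `FALSE` gives a single 5-point band at BMI ≥ 30) and the NC
threshold, which defaults to the inclusive ≥ 40 cm reading.

Two fallbacks matter in practice and follow a fixed precedence. A
recorded hypertension flag always wins; only when it is unknown and both
pressures are present is it derived from the 140/90 mmHg rule
(`hypertension_from_bp()`). The STOP-Bang tiredness item may optionally
(`tiredness_from_ess = TRUE`, off by default, logged when used) fall back
to ESS ≥ 11, the conventional sleepiness threshold. Nothing is ever
imputed: a missing required measurement is an error naming the field, or
a per-row rejection in the file pipeline.

## The evaluation engine

`confusion_counts()` cross-classifies `score ≥ score_cutoff` against
`ahi ≥ ahi_cutoff` (both inclusive), excluding and counting records with
a missing score or AHI. `classification_metrics()` computes sensitivity,
specificity, PPV, NPV and predicted prevalence with each metric using its
own denominator; a zero denominator yields `NA` for that metric only,
with a classed warning. PPV is exactly Bayes-consistent with sensitivity,
specificity and prevalence, which the tests assert.

The AUC is the trapezoidal area under the empirical ROC curve over all
distinct score thresholds. This equals the Mann–Whitney probability that
a diseased record outscores a non-diseased one with ties credited ½ — the
tie rule has to be stated explicitly because the comparator scores are
small integers with heavy ties. The test suite checks the trapezoidal
implementation against an exhaustive pair-counting oracle on random tied
data, and against an independent reference implementation (pROC), which
it matches to machine precision.

Confidence intervals use DeLong's asymptotic variance by default (clipped
to [0, 1]); a class-stratified bootstrap percentile interval (2000
replicates, mandatory seed) is the alternative. The two agree to within
about 0.02 at n = 500 in the tests. Published AUC intervals computed with
unknown methods are therefore comparable only approximately, and the
package makes no attempt to reproduce any specific published CI bound.

`cutoff_sweep()` evaluates sensitivity and specificity over an increasing
cut-off grid (default 2.5–6.0 by 0.05). Monotonicity — sensitivity
non-increasing, specificity non-decreasing — is asserted on every run as
an internal invariant, not just in tests. The *crossover* cut-off is the
grid point minimising |sensitivity − specificity|, ties broken toward the
smallest cut-off; on the reference clinical cohort this balance point is
reported at 3.7 with both metrics near 0.6, which motivates 3.7 as the
default screening cut-off for population monitoring while 3 (the Low/Mild
boundary) maximises sensitivity.

## The synthetic cohort generator

The generator exists so every pipeline stage is testable end-to-end
without access to clinical data. It emulates the descriptive statistics
of a large Western-Romanian sleep-laboratory referral cohort (N = 2595):
age 52.2 ± 13.25 y, BMI 33.73 ± 7.11 kg/m², NC 43.15 ± 5.25 cm,
ESS 11.16 ± 5.40, AHI 43.54 ± 26.57 events/h, 69.2% male, 78.0% snorers,
67.5% hypertensive, and 64.4% with AHI ≥ 30. Those values are the
generator's defaults (`westro_cohort_spec()`); they are study conditions,
not tuning knobs.

The dependence structure is a single latent severity factor
`z ~ N(0, 1)`: each continuous variable is
`mean + SD·(λz + √(1−λ²)·ε)`, which preserves the stated marginal mean
and SD exactly while making all variables co-vary through severity. The
published account documents Gaussian marginals and a score that rises
with AHI, but no covariance matrix; one factor is the simplest structure
realizing both. Loadings default to 0.5 for BMI, neck and ESS and 0.8
for AHI; age (0.2) and systolic pressure (0.3) get mild positive loadings
as a package choice — older, more hypertensive patients tend to be the
sicker ones in referral cohorts — since no source value exists for them.

Three further choices were genuinely open:

* **AHI marginal.** A normal AHI with mean 43.54 and SD 26.57 implies
  P(AHI ≥ 30) = 0.695, but the reported prevalence is 0.644; the three
  published numbers are mutually inconsistent under normality because
  real AHI distributions are right-skewed. The default therefore uses a
  *shifted-gamma* marginal, applied as a monotone quantile transform of
  the latent AHI index, with the shape solved deterministically
  (k ≈ 2.89) so that mean, SD and prevalence all hold simultaneously. A
  plain linear-in-z normal family remains available
  (`ahi_family = "normal"`), and `calibrate_prevalence()` bisects the AHI
  mean for any spec that needs to hit a prevalence target with it.
* **Blood pressure.** Systolic pressure is not among the published
  descriptives (only the 67.5% hypertension rate is); the default
  N(135, 18) mmHg, with diastolic modelled as
  `14.4 + 0.6·sys + N(0, 8)`, makes the 140/90 rule flag ≈ 67.5% of
  patients. The intercept is the one free constant that calibration
  requirement pins down (checked against a 2·10⁶-draw quadrature before
  any cohort was generated). All three constants are overridable.
* **Symptoms.** Snoring (78.0%) and tiredness (65.9%, mirroring the
  reported ESS ≥ 11 rate) have published marginal rates; witnessed apnea
  does not and defaults to 55%, a typical sleep-laboratory referral
  figure. Each symptom follows a logistic model in `z` with slope 0.8;
  intercepts are solved by quadrature so the marginal rates hold.

Numerical housekeeping: ESS is rounded to an integer and clipped to
0–24; measurements are clipped to documented plausibility bounds
(BMI 14–70, NC 25–60, SysBP 80–240, AHI 0–150, age 18–95), with clip
counts reported; men's NC is shifted +1.5 cm about the sex-mix mean so
the overall marginal is unchanged; sex has no other interaction. One
master seed drives everything through an isolated RNG stream, so a spec
reproduces its cohort bit-for-bit without disturbing the caller's RNG.

What passing the recovery tests shows — and does not. At n = 10 000 the
generator recovers every marginal mean within 3 standard errors, the
AHI ≥ 30 prevalence within ±0.02 of 0.644, and a strictly positive
Spearman correlation between the SAS score and AHI. It does *not*
reproduce the real cohort's joint distribution: the true inter-variable
correlations live only in the deposited patient-level data, and the
single-factor stand-in is weaker than reality. Consequently
screening-performance numbers measured on synthetic cohorts (e.g. an SAS
sensitivity/specificity of about 0.99/0.10 at cut-off 3, a crossover
near 4.05) differ from the clinical values (0.829/0.359, crossover 3.7)
and are reported as synthetic-cohort properties only. Re-analysing the
deposited tables requires exporting them as delimited text and supplying
a column mapping (`read_cohort()` takes both), after which the same
engine reproduces the published figures — the metric layer already does
so exactly when fed the published classification counts.

## Degenerate inputs and error design

Single-class reference labels abort ROC/AUC with a degenerate-input
error; fewer than two records per class abort the CI methods; empty
cohorts, empty grids and non-increasing grids are structured errors.
Every user-facing failure carries a condition class
(`sasscreen_validation_error`, `sasscreen_config_error`,
`sasscreen_degenerate_error`, …) which the command-line front end maps
to distinct exit codes (2, 3, 4). Per-row data problems in file runs are
collected into a machine-readable rejects table rather than aborting —
partial data is the norm in screening practice.

## Problem sizes used by the checks

The test-suite and acceptance-script sizes are package choices balancing
Monte-Carlo error against runtime: marginal/prevalence recovery uses one
draw of n = 10 000 (standard errors small enough that 3-SE bounds are
meaningful), AUC oracle equivalence uses 1000 random cohorts of n ≤ 200
(exhaustive pair counting is quadratic), CI cross-validation uses
n = 500 with 2000 bootstrap replicates, and sweep invariants use
n = 1500 cohorts across several seeds.
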