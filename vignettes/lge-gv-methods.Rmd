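---
title: "Methods: low-glucose eating, glycemic variability, and their association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-glucose eating, glycemic variability, and their association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lgegv)
```

## The analysis in one paragraph

`lgegv` estimates the association between a change in low-glucose eating
(LGE — the percentage of eating events initiated at or below a personalized
fasting-glucose threshold) and concurrent changes in glycemic variability
(GV), in a two-timepoint cohort wearing a blinded 15-min CGM. The unit of
analysis is the participant; the outcome scale is the percent change in
each GV measure between assessments; the estimator is the Pearson
product-moment correlation with ΔLGE (percentage points), backed by an
ordinary-least-squares model that adjusts for the concurrent change in body
weight. Everything upstream of the estimator — event validity, preprandial
matching, inclusion rules, the GV metric battery, glucotype fractions — is
deterministic given the inputs.

## Event scoring and inclusion rules

Raw food-log records are chain-merged when consecutive records fall less
than 15 min apart: energy and macronutrients are summed and the merged
event takes the earliest timestamp. The chain rule (A–B 10 min and B–C
10 min merge all three even though A–C is 20 min) is deterministic and
order-independent; the 25-kcal validity floor is applied *after* merging,
so two small items eaten together can still constitute one valid event.
Both choices are auditable in `consolidate_events()`.

Preprandial glucose is the nearest value of the trace linearly resampled to
a 5-min grid (gaps longer than 60 min are never interpolated) within ±5 min
of the event, preferring the instant at or before the meal on ties —
"preprandial" semantics. Events with no candidate reading are dropped from
numerator *and* denominator of LGE, so LGE remains a percentage of events
with corresponding CGM. A calendar day is valid with at least two matched
events on a plausible trace (strictly more than 95% of readings at or above
70 mg/dL); participants enter the analysis with at least three valid days
at both assessments.

The personalized threshold is the unrounded mean of exactly two morning
fasting glucose values from the anthropometrics table. Because re-deriving
thresholds at the second assessment is a substantive choice, both modes are
supported; the default carries the week-0 threshold forward
(`threshold_mode = "carry_forward"`), and `"per_assessment"` re-derives it
where week-16 fasting values exist.

## The GV battery: fixed formulas

The battery is computed on the trace at native cadence (interpolation is
used only for meal matching and windowing), glucose in mg/dL internally,
K = 18.016 mg/dL per mmol/L for conversion. Several of these metrics have
multiple published variants; the variant used here is fixed explicitly and
verified against independent brute-force implementations in the test suite.

| Metric | Definition here | Output unit |
|---|---|---|
| mean, SD | arithmetic mean; sample (n−1) SD | mg/dL |
| CONGA | sample SD of differences at a 60-min lag (nearest reading within half a cadence) | mmol/L |
| LI | Σ(ΔG)²/Δt over 60-min grid readings (G mmol/L, t hours), per day of observation, span floored at one day | (mmol/L)²/h |
| J-index | 0.001 (mean + SD)², moments in mg/dL | – |
| LBGI/HBGI | f(G)=1.509[(ln G)^1.084 − 5.381], r = 10f²; means of the low/high branch | – |
| ADRR | mean over days of (max low risk + max high risk); days with < 12 readings excluded | – |
| GRADE | mean of min{50, 425[log₁₀(log₁₀ G_mmol) + 0.16]²}; readings ≤ 1 mmol/L excluded and counted | – |
| MAGE | mean amplitude between consecutive interior turning points (three-point rule, plateaus collapsed) exceeding 1 trace-SD, both directions | mmol/L |
| MODD | mean |G(t) − G(t+24 h)| over pairs within half a cadence of 24 h | mmol/L |
| M-value | mean |10 log₁₀(G/120)|³, no sparse-sampling range correction | – |

Notes on deliberate choices:

* **CONGA** uses the sample SD of lag differences (the original
  definition). Widely-used spreadsheet implementations are known to
  compute a different quantity with a much larger numeric scale; published
  cohort CONGA values of ~5 under those tools are therefore *not*
  reproducible from this definition, and no numeric claim is made for it.
* **LI** is normalized per whole day of observation with the span floored
  at one day, so that a short demonstrative series ("hourly 5, 6, 5
  mmol/L") evaluates to 2.0. With multi-day wear this normalization yields
  values an order of magnitude above spreadsheet-style weekly
  normalizations; like CONGA it is treated as scale-incomparable across
  tools.
* **MAGE** has many variants; the turning-point rule here (interior
  three-point extrema after collapsing plateaus, qualifying excursions in
  both directions averaged) is documented and oracle-tested, not claimed
  identical to any external tool. Strictly monotone traces have no interior
  turning points and return 0 with a flag.
* **M-value** omits the classical range/20 correction aimed at sparse
  (pre-CGM) sampling; CGM series are dense.
* **ADRR**'s 12-reading minimum avoids degenerate per-day maxima on
  near-empty calendar days (e.g. the first partial wear day).
* The risk-transform root is ≈ 112.5 mg/dL: constant traces there give
  LBGI = HBGI = 0, a fixed point asserted in the tests.

## Glucotype fractions

Time windows of 150 min, stepped by 30 min on the 5-min grid (windows
overlapping an uninterpolated gap are dropped), are summarized by four
cadence-independent features: mean, SD, range, and maximum absolute rate of
change per hour. Feature vectors are standardized and clustered by spectral
clustering — RBF affinity with bandwidth equal to the median pairwise
distance, symmetric-normalized Laplacian, top-3 eigenvectors row-normalized,
k-means (fixed seed, 25 restarts) — into exactly three classes, relabeled
low < moderate < severe by ascending centroid window-SD. Every
participant-week's windows are then assigned to the nearest centroid in the
standardized feature space and reported as time fractions summing to 1.

The training pool is all windows of the analyzed cohort (self-trained — no
external reference clusters are shipped). Because the dense affinity
eigendecomposition is quadratic in the pool, pools above 1,200 windows are
thinned by an even deterministic stride before clustering; assignment still
covers every window. Two numerical guards matter in degenerate settings:
features whose pool-wide spread is below 1e-8 mg/dL are left unscaled
(standardizing by numerical dust would amplify rounding noise into spurious
structure), and self-affinity is kept at exp(0) = 1 so duplicated windows
have identical affinity rows and hence identical spectral embeddings. The
window geometry and feature set are an explicitly parameterized
reconstruction of glucotyping; fractions are not claimed numerically
identical to any external tool's.

## Change scores and the association model

Per participant present at both assessments: ΔLGE in percentage points,
Δweight in kg, and per GV measure both the percent change
100·(post − pre)/pre and the absolute change. Percent change is undefined
(flagged `NA`) when the week-0 value is 0 — common for the severe-glucotype
fraction — and such participants drop from that measure's association only.
The percent-change scale is the primary analysis scale; absolute changes
are emitted alongside.

For each measure the package reports Pearson's r with the t-based two-sided
p-value on n−2 df, and the OLS fit ΔGV% ~ ΔLGE + Δweight with coefficient
t-tests, adjusted R² = 1 − (1−R²)(n−1)/(n−3), and the per-10-pp effect
10·β. When the weight covariate is constant the model collapses to the
simple regression, whose slope test then equals the Pearson test — an
identity asserted in the tests. No multiple-testing correction is applied
(the analysis is exploratory by design); a Benjamini–Hochberg column is
emitted alongside for transparency.

## The synthetic cohort generator

The generator emulates the study conditions: by default 17 postmenopausal
women without diabetes, two assessments 16 weeks apart, 7 days of 15-min
CGM per assessment, 3–6 meals/day, fasting thresholds near 85–110 mg/dL.
Glucose is basal level + 24-h sinusoid + postprandial excursions (linear
30-min rise, exponential decay with 60-min time constant — the simplest
shape producing realistic excursions) + AR(1) sensor noise, clipped at the
40 mg/dL reporting floor.

Meals are scheduled chronologically so each decision sees all earlier
excursions. With probability equal to the participant's LGE *propensity*, a
meal is placed at a random instant where current simulated glucose is at or
below the threshold (skipped if none remains that day); otherwise at a
random instant in usual eating hours (08:00–21:00; deliberate low-glucose
meals may also use the early 06:00+ window, where glucose is naturally low
— precisely the behavior being emulated). The week-16 propensity adds a
heterogeneous uniform shift, and the week-16 excursion amplitude moves by
`effect_size` (default −30 mg/dL per unit propensity) times that shift:
this *plants* the negative ΔLGE–ΔGV association that the pipeline should
recover. Weight loss is drawn independently of the propensity shift, so
weight adjustment must not destroy the planted signal. True per-participant
parameters are returned in a `truth` table for recovery tests.

Default parameter values were calibrated once so that the week-0 cohort
battery lands at the order of magnitude of published non-diabetic cohorts
(mean ≈ 97 mg/dL, SD ≈ 0.9 mmol/L, J-index ≈ 13, LBGI ≈ 1.5, HBGI ≈ 0.2,
MAGE ≈ 2.2 mmol/L, MODD ≈ 0.6 mmol/L, cohort LGE ≈ 25–30%) — the
acceptance script prints the realized values for any seed. What the
generator does *not* emulate: glucose–insulin physiology, realistic
dietary composition, sensor dropout beyond hard gaps, or circadian phase
heterogeneity. Consequently, passing recovery tests show that the pipeline
measures what the generator plants; they cannot certify accuracy on real
cohorts whose noise structure differs.

## Problem sizes and numerical tolerances in the test suite

Oracle equivalence is asserted on 200 random 2-day traces against naive
loop implementations at 1e-9 relative tolerance; Pearson/OLS against
closed-form normal equations at 1e-10 on n = 17 designs. The planted-effect
recovery runs 100 seeds of 40-participant cohorts (the J-index as
representative outcome, glucotyping disabled in the loop for speed) and
requires the negative Pearson sign in ≥ 95/100 and the negative adjusted
slope in ≥ 90/100; a directly planted regression slope at n = 200 must be
recovered within 10%. Rank recovery of the planted propensity by computed
LGE% is asserted as a median Spearman ≥ 0.7 over five 40-participant
cohorts. These sizes keep the default suite within a few minutes while
leaving the Monte-Carlo margins wide.

## Known limitations

* CONGA and LI magnitudes are tool-dependent (see above); cross-tool
  numeric comparisons are only meaningful for mean, SD, J-index, the risk
  indices, MODD, M-value and GRADE.
* The glucotype classes are self-trained per run; fractions are comparable
  within a cohort, not across independently trained runs.
* Thresholds rely on supplied fasting values; the optional carry-forward
  default means week-16 LGE is insensitive to week-16 fasting drift.
* Day boundaries assume a single timezone (single-site wear) and local
  midnight; ADRR therefore shifts with clock offsets that cross midnight.
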