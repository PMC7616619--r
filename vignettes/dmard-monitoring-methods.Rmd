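---
title: "Methods: missed-monitoring indicators for shared-care DMARDs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: missed-monitoring indicators for shared-care DMARDs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmardmon)
```

## The problem

Azathioprine, leflunomide and methotrexate are disease-modifying
antirheumatic drugs (DMARDs) usually continued in primary care under
shared-care arrangements. All three require three-monthly safety
monitoring — full blood count (FBC), liver function tests (LFT) and
urea & electrolytes (U&E), plus a blood-pressure (BP) check for
leflunomide — because of their risk of blood dyscrasias and
hepatotoxicity. `dmardmon` measures how often that monitoring is
*missed* in routine electronic health record (EHR) data, how the rate
moved around an acute service disruption (the March 2020 lockdown is
the motivating case), how it varies between GP practices, and whether
the disruption hit some patient groups harder than others.

Because real pseudonymised GP records cannot be redistributed, the
package pairs the measurement engine with a seeded synthetic EHR
generator that reproduces the event structure the engine assumes. All
tests and the acceptance script run on synthetic data alone.

## Cohort and indicator definitions

**Index months.** Each monthly measure uses the last day of the named
month as its search date. The test lookback is the named month plus the
two preceding calendar months, a closed interval; the series is
therefore a 3-month rolling measure by construction, with no post-hoc
smoothing. Calendar-month subtraction clamps to month ends
(31 May − 3 months → 28/29 February), which keeps windows reproducible
without day-count approximations. Whether the original audit used
calendar months or 91/182-day windows is not documented; the calendar
form matches the way the windows are described ("1 March to 31 May")
and is what we adopt throughout.

**On drug.** A patient is on a drug at an index month if they have at
least two issues: one in `(index − 3 months, index]` and one in
`(index − 6 months, index − 3 months]`. Two issues across adjacent
3-month windows indicate an active repeat course, since the large
majority of English repeat prescriptions run 3 months or less.

**Eligible.** Alive at the index date, aged 18–120, registered at a
practice, and with none of age, sex, IMD quintile or rural–urban
classification missing (missing core fields flag poor data quality).
Registration is a single start date with no de-registration: the
synthetic data has no churn and no rule for it exists in the indicator
definition.

**Missed monitoring.** A patient in a drug's denominator enters the
numerator if *any* test required for that drug has no record in the
lookback. Combined scopes count patient-drug pairs, so a patient on two
drugs contributes twice; this pair-level aggregation is what makes the
overall denominator equal the sum of the per-drug denominators.
Per-test indicators intersect the test with each drug's requirements,
and requesting a test a drug does not require (BP for azathioprine) is
a configuration error rather than a zero.

**Disclosure rounding.** Every reported numerator and denominator is
rounded to the nearest 5 — separately, at every reported granularity
(population, drug, test, subgroup, practice) — before the percentage is
formed. Integer counts never tie, so no tie-break rule is needed.
Whether the original outputs rounded subgroup counts before or after
summing is not stated; rounding at each granularity independently is
the conservative disclosure-control reading and is what `round5()`
implements. Percentages are reported to one decimal, rounded half away
from zero; cohort-description percentages use the *rounded* subgroup
total as their denominator, matching the published convention.

## Inferential statistics

**Change between periods.** The period-to-period change in an
aggregate rate is tested with a two-proportion z-test (pooled variance,
two-sided), applied to the rounded counts, with a Wald 95% interval on
the percentage-point difference. The source analysis names its test
only as a "t-test" without stating the unit of analysis; since the
compared quantities are aggregate proportions, the z-on-aggregate form
is the natural reading and is the default here. A practice-level Welch
two-sample alternative (`change_test_practice()`) is exposed for users
who prefer the practice as the unit.

**Heterogeneity of change.** For each subgroup family (age band, sex,
region, ...), each category's percentage-point change between a
baseline and a comparison month gets the sampling variance
`p1(1−p1)/n1 + p2(1−p2)/n2`; proportions are clamped to
`[0.5/n, 1 − 0.5/n]` first so no category gets an infinite weight.
Cochran's Q is the inverse-variance-weighted sum of squared deviations
from the weighted mean change, referred to a chi-square with `k − 1`
degrees of freedom. Q is invariant to any common rescaling of the
weights, so working in percentage points or proportions gives the same
statistic provided deltas and variances share a scale (the package
reconciles them internally).

**Practice deciles.** Per-practice rates (rounded counts, practices
with a zero rounded denominator excluded) are summarised by the nine
deciles using linear interpolation between order statistics
(`quantile()` type 7) — the mainstream default and reproducible across
environments; the interpolation rule used for the original decile
charts is not documented, making this a free choice.

## What the generator emulates

The simulation draws, per patient: practice (uniform over
`n_practices`), demographics (independent categoricals defaulting to
the published cohort's marginals), a registration date predating the
study, and a small death fraction. Courses start at a uniform date in
the first prescribing interval and repeat every 84 ± 7 days until a
per-interval discontinuation hazard (default 0.02), death or study
end.

Monitoring is a per-patient cycle: due windows anchored at the
patient's first prescription, every 91 days while any course is
active. One attendance draw covers the whole blood panel (the three
blood tests are conducted together and share one date); the BP check
is a separate draw, made only while a leflunomide course is active,
with an extra miss offset. The per-window miss probability is

π = logit⁻¹( β₀ + practice effect + subgroup offsets + frailty + shock(t) )

with `shock(t)` equal to the configured logit shock inside the
disruption window and decaying linearly on the logit scale to zero by
the recovery end — the simplest shape that reproduces an acute rise
with rapid recovery. Attendance compares a uniform draw against π, so
runs sharing a seed are coupled: raising the shock can only convert
attendances into misses, which gives a clean monotonicity property for
testing.

Default parameters were fixed once from the published aggregates:
drug prevalences 0.27/0.06/0.67 (azathioprine/leflunomide/methotrexate,
mirroring the per-drug denominator shares), β₀ = logit(0.25) (blood-test
miss rates cluster near 25%), BP extra offset 1.4 (BP ≈ 57% vs ≈ 25%),
shock logit 0.55 (= logit(0.408) − logit(0.284)), practice-effect SD
0.8 (a wide baseline interdecile range), and demographic marginals from
the published cohort description. A patient-level frailty term is
exposed but defaults to 0: no published quantity pins its value, and
persistent practice and subgroup effects already produce repeat missing
(the events-to-unique-patients ratio).

**What it does not emulate.** Courses all begin inside the study
window, so the first two or three measure months are burn-in with small
denominators (real cohorts have long-standing courses). There is no
registration churn, no secondary-care testing, no drug switching, no
seasonal structure, and missingness is conditionally independent across
windows given the random effects. Passing tests therefore demonstrate
the *correctness of the measurement rules* and the recoverability of
known parameters — not that the generator reproduces every feature of
real primary-care data.

## Numerical and testing choices

- Month windows come from `lubridate`'s clamped month arithmetic;
  deciles from `stats::quantile(type = 7)`; tail probabilities from
  `stats`. The indicator engine, rounding, z-test and Q aggregation are
  implemented here and cross-checked in the tests against a separate
  brute-force reference (hand-coded calendar arithmetic and per-patient
  loops) and against `prop.test(correct = FALSE)`.
- Degenerate inputs: a zero rounded denominator yields an `NA`
  percentage (undefined, not an error); fewer than two practice rates
  or subgroup categories raise an insufficient-data condition; a zero
  unique-patient count leaves the repeat ratio undefined.
- Parameter-recovery checks run with a single drug
  (`drug_prevalence = c(methotrexate = 1)`), no practice or subgroup
  effects, and a shock window opening 1 March 2020. With one drug the
  per-patient monitoring cycle makes the configured π the marginal miss
  probability (multi-drug patients would share attendances across
  denominators); with the shock spanning March–June the May lookback
  (1 March – 31 May) lies wholly inside the disruption. The measured
  rates are then compared at 3 binomial standard errors.
- Problem sizes: unit tests use 40–600 simulated patients;
  engine-vs-oracle equivalence uses 50 randomized micro-cohorts of up
  to 200 patients; recovery runs use 5 000 patients over the full
  33-month series; Q calibration uses 2 000 replicates of k = 9
  binomial draws at n = 1 500 per category. These sizes keep the whole
  suite under a few minutes while leaving Monte-Carlo error well inside
  the asserted tolerances.

## Known limitations

- The published full-scale results (e.g. the real practice-median
  baseline rate or the regional Q on 24 million records) cannot be
  reproduced without the underlying records; the package validates the
  method, not those numbers.
- The z-on-aggregate change test treats rounded aggregate counts as
  binomial counts; rounding adds a small non-binomial error component,
  negligible at the scales reported.
- Monthly indicator values in adjacent months share two of three
  lookback months and are therefore serially dependent; the package
  reports the series as-is and fits no time-series model.
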