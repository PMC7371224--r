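---
title: "Methods: chart-based CVD risk stratification and treatment costing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chart-based CVD risk stratification and treatment costing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chartrisk)
```

## The model

A non-laboratory cardiovascular risk chart is a complete lookup table
over 2 × 2 × 7 × 5 × 5 = 700 cells — sex, current smoking, seven 5-year
age bands covering 40–74, five systolic-blood-pressure bands and five
body-mass-index bands — each holding a 10-year risk percentage for a
first fatal or non-fatal myocardial infarction or stroke.  Risk
estimation for a person is therefore pure binning plus a single table
read; all statistical content lives in the chart itself, which this
package deliberately treats as *replaceable data* rather than code.
Published chart values are copyrighted tables maintained elsewhere and
differ by epidemiological region; users supply their region's chart as a
CSV, and the package bundles only synthetic fixture charts.

Risk percentages are graded into five categories with boundaries at 5,
10, 20 and 30 percent, boundary values falling upward.  Two
treatment-eligibility policies are evaluated per scored record:

* rule **A**: chart risk ≥ 20 % (total-risk approach);
* rule **B**: rule A, or severe hypertension (BP ≥ 160/100 mm Hg);
* rule **C**: hypertension (BP ≥ 140/90 mm Hg) — the single-risk-factor
  approach.

Blood-pressure rules use OR semantics across the systolic and diastolic
thresholds, both inclusive: "BP ≥ 140/90" means SBP ≥ 140 *or* DBP ≥ 90.
Rule A membership is a subset of rule B by construction; on cohorts where
every high-risk record is also hypertensive (the pattern observed in the
low-risk populations this pipeline targets), B is in turn a subset of C.

Annual drug-cost projection is linear: a prevalence `p` (percent of
adults aged ≥ 40 requiring treatment) corresponds to `round(p × 10 000)`
people per million (half-up rounding), each costing
`price_per_100_tablets / 100 × tablets_per_day × 365` US$ per year per
drug, summed over the regimen.

## Interval conventions and other chart-engine choices

Printed chart axes are ambiguous at their seams ("120–139" next to
"140–159"; "30–35" next to "≥35").  All bands are implemented as
half-open intervals `[lower, upper)`: SBP `[120, 140)`, BMI `[30, 35)`
and so on, which closes every printed gap and resolves the BMI overlap
at 35 the same way the SBP axis resolves 180.  The printed age list
contains a band "64–69" overlapping its neighbour; five-year banding
forces `[65, 70)` and that is what is implemented.

Ages of 75 and over fall off the chart.  The default policy (`exclude`)
reports such records as unscorable and counts them in the exclusion
ledger; a `clamp` policy assigns them to the 70–74 band and flags them.
Exclude is the default because the top band genuinely ends at 75 and
extrapolating a 5-year band to open-ended old age understates risk
heterogeneity; clamping is provided for sensitivity analyses.

Plausibility guards (SBP 50–300 mm Hg, DBP 30–200, BMI 10–80, age
40–120, with height/weight guards implied by the BMI and height ranges)
are hard errors, not missingness: a value outside them indicates data
corruption, and silently dropping it would bias complete-case counts.

## The scoring pipeline

Final blood pressure is the mean of two seated readings; if only one
reading is present it is used and flagged rather than dropped, since
missingness is accounted per final value.  BMI uses a directly recorded
value when present, otherwise weight/(height/100)².  Complete-case
filtering drops, in a fixed precedence order — prior CVD (the charts
apply to people without established disease), unscorable age, then
missing smoking, SBP, DBP, BMI — and counts each record under exactly
one reason, so the exclusion report always reconciles:
retained + excluded = input.

Flags are never silently false: a missing input yields a missing flag,
except that an OR-rule is already decided true by one present input
(SBP 145 with missing DBP is hypertensive; SBP 145 with missing DBP is
*unknown* for severe hypertension).

Report percentages are displayed with one decimal using half-up rounding
(`round_half_up()`), matching survey-table conventions; underlying
tables keep full precision.  Costing applies prevalences as given — the
bundled scenario's prevalences are printed at one decimal, and using
them as-is is what reproduces its published cost cells (29/5977 =
0.485 % would give 140 269, not the published 144 540).  Users who want
unrounded prevalences simply pass them to `cost_per_million()`.

## Statistics

Confidence intervals for category proportions use the Wilson score
interval by default, with the Wald interval available for audit.  The
emulated survey does not state its CI method; at the proportions
involved both methods print identically at one decimal (29/5977 renders
as "0.3 to 0.7" either way), and Wilson is preferred for its behaviour
at very small proportions (rows with 0–1 events occur in these tables).
Sex comparisons are Pearson χ² tests on the per-category 2 × 2 table
(in/out of category × men/women), one degree of freedom, *no continuity
correction*: the only published p-value reproducible from crude counts
(0.272 for 1/2708 vs 0/3269) matches the uncorrected statistic, which
also fixes the 2 × 2-per-category reading over a single 2 × 5 test.  A
zero margin leaves the statistic undefined and is flagged rather than
coerced.

## Drug prices

The default regimen prices aspirin at 0.45, enalapril at 2.38,
hydrochlorothiazide at 0.83 and simvastatin at **4.26** US$ per 100
tablets.  The bundled scenario's source footnote quotes simvastatin at
4.29, but every one of its published cost cells implies a per-person
annual cost of 15.549 = 4.26/100 × 365 (for example 77 745/5000); the
footnote value is treated as a typo and remains selectable
(`simvastatin_footnote = TRUE`).  The year is fixed at 365 days, as all
published per-person costs imply.  Both strategies are costed on the
full four-drug regimen by default — the published comparison prices all
four drugs under the hypertension rule too — with an
antihypertensive-only regimen available by flag.  Population
projections multiply census strata (thousands) by stratum prevalences;
their totals are computed as sums of strata, which is why the bundled
scenario's internally inconsistent published "in thousands" column is
deliberately not reproduced.

## The synthetic-data generator

`generate_cohort()` emulates the marginal structure of a national
Bangladeshi survey of adults aged ≥ 40 (n = 6189): integer ages with
mean 52.9 and SD 9.9; SBP 119.7 (15.2) and DBP 80.3 (9.5) mm Hg; per-sex
BMI 21.4 (3.7) men / 22.3 (4.4) women; current smoking 50.7 % of men and
1.8 % of women; random glucose mean 6.9 SD 3.0 mmol/L; 30.2 % urban;
per-variable missingness 0.3–0.5 % (glucose 1.4 %), applied
independently (MCAR — the survey's own complete-case justification,
"missingness under 2 %", presumes ignorability).

Because the survey reports the moments of the *observed* (age ≥ 40,
integer-valued) variable, the generator calibrates the underlying
normal so that, after truncation and flooring to whole years, the
generated ages hit the target moments: flooring subtracts ≈ 1/2 from the
mean and adds ≈ 1/12 to the variance, and the truncation inversion is
solved numerically (`tnorm_moments` closed forms + Nelder–Mead).
Infeasible requests — e.g. SD 9.9 on an age range capped at 75, where
no truncated normal exceeds SD ≈ 9.6 — are rejected with an error rather
than silently approximated.  Flooring rather than rounding is used so
that band-occupancy probabilities of the integer ages equal those of
the continuous distribution, keeping the analytic oracle exact.  SBP and
BMI guards sit more than four SDs from their means, so their truncation
corrections are negligible and omitted.

Several joint features are *invented*, because the survey publishes only
marginals, and are therefore synthetic-only assumptions: the SBP–DBP
correlation (0.6), per-reading measurement noise (SD 2 mm Hg, two
readings per person, so the mean-of-two carries noise SD √2 mm Hg),
per-sex heights (162/151 cm, SD ≈ 6) used to derive weight from BMI, a
lognormal glucose shape matched to the stated mean and SD, and a 3 %
prior-CVD rate.  Consequently, passing parameter-recovery tests shows
the pipeline is *internally consistent* — scoring recovers exactly the
prevalences the generating distributions imply — not that real survey
data follow these distributions.  Cluster sampling, urban/rural
intra-class correlation, and any dependence of missingness on risk
factors are explicitly not emulated.

`expected_prevalences()` is the analytic oracle: cell-occupancy
probabilities are products of per-axis band probabilities (age bands
from the calibrated truncated normal conditioned on the scorable range
40–74; SBP bands from the measured-SBP normal, whose variance adds half
the squared reading noise; per-sex BMI bands; per-sex smoking), and
hypertension probabilities integrate the bivariate measured-BP normal
(conditional-normal exceedance integrated over SBP, `stats::integrate`,
relative tolerance 1e-10).  Across 20 seeds at n = 6189, per-stratum
per-category z-scores against these expectations behave as standard
normal (about 480 comparisons; the test allows at most 2 % beyond 3 SE
and none beyond 6 SE, the false-alarm budget a 0.27 % two-sided tail
implies).  A one-million-record Monte-Carlo run agrees with the oracle
to within 0.2 percentage points.

## Chart fixtures

`generate_chart_fixture()` builds multiplicative charts:
`risk = base × age_mult^(i−1) × sbp_mult^(j−1) × bmi_mult^(k−1) ×
smoke_mult^smoker`, capped at 100.  Multipliers ≥ 1 guarantee
monotonicity along every axis, which the chart-engine property suite
asserts via `lookup_risk`.  The defaults (base 0.8 %, multipliers 1.5 /
1.35 / 1.15 / 1.6) were chosen once to make the fixture *shaped like* a
low-risk South-Asian non-laboratory chart: a typical middle-aged
normotensive non-smoker sits near 2 %, the top cell (male smoker, 70–74,
≥180, ≥35) near 85 %, and a default synthetic cohort lands
overwhelmingly below 10 % risk with a fraction of a percent at ≥ 20 % —
the regime in which the two treatment strategies are compared.  Fixture
values are synthetic and carry no clinical meaning.

## Numerical choices

* Half-up rounding is implemented by flooring after absorbing binary
  representation error (values such as 520.4999…94 tenths round up);
  base `round()` would round to even.
* Chart lookup keys are exact string matches over validated band
  labels; validation rejects missing, duplicated and out-of-range cells
  before any lookup can happen.
* Boundary values are exercised explicitly in tests (SBP 140 and 180,
  BMI 25 and 35, risk 5/10/20/30, BP thresholds at equality).
* Degenerate inputs: empty cohorts score to empty tables; an empty risk
  category yields a flagged undefined percentage, never 0; a zero-cost
  denominator yields a flagged undefined ratio.

## Problem sizes in the test suite

The suite scores cohorts of 50 records against brute-force recount
oracles, uses 50 000 records for marginal-convergence checks, 20 seeds
of 6189 for parameter recovery and complete-case retention, 10 000
random profiles against a rebinning oracle, 1 000 random 2 × 2 tables
against an expected-counts χ² oracle, and one 10⁶-record Monte-Carlo
consistency run; these sizes give the oracles' statistical bounds
comfortable margins while keeping the default run fast.

## Known limitations

* Survey-design weighting and cluster-robust variance are out of scope;
  all proportions and tests are crude.  A few published figures in the
  bundled scenario appear non-crude (a women's category CI and one
  rounded percentage) and are intentionally not reproduced.
* Missing values are dropped, never imputed.
* The laboratory-based chart variant (cholesterol, diabetes) is not
  modelled; a user-supplied chart must be the non-laboratory layout.
* Costing covers drugs only — facility and workforce costs are assumed
  equal across strategies — with no currency conversion or discounting.
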