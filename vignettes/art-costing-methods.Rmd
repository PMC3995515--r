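---
title: "Methods: retention, utilization, and provider costs for ART cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retention, utilization, and provider costs for ART cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artcost)
library(dplyr)
```

This vignette documents the models and conventions behind the package:
the outcome-classification rule, the utilization accounting, the
unit-cost estimators, the clustered inference, and — at some length —
what the shipped synthetic cohort does and does not emulate. Nothing
here reports an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Outcome classification

Patients are assigned exactly one of three outcomes at each endpoint
(12, 24, or 36 calendar months after ART initiation):

* **known to have died** — a death confirmation in the chart dated
  before the endpoint;
* **lost to follow-up (LTFU)** — at the endpoint, at least `grace_days`
  late for the last scheduled consultation or medication pickup, with
  no death confirmation;
* **retained in care** — everyone else.

Death takes precedence over lateness because LTFU is *defined* as
unexplained absence. Several details of this rule are conventions
rather than facts, and each is exposed as an argument:

* **"Three months late" = 90 days** (`grace_days = 90`). Programs
  define the grace period variously as 90 days or 3 calendar months;
  90 days is the conventional reading and the default.
* **The scheduled-contact basis** is the latest of all explicit
  next-appointment dates, supply-implied return dates (pickup date +
  months' supply × 30.44 days, used when no appointment was recorded),
  and the last attended contact itself. The last term covers a patient
  who attended their final booked visit with nothing further
  scheduled.
* **Lateness is measured to the endpoint date**
  (`lateness_to = "endpoint"`). Measuring to the data-collection date
  instead (`"censor_date"`) classifies more patients as LTFU; source
  descriptions of such rules rarely say which was used, so both are
  implemented and the endpoint reading is the default.
* A patient with **no recorded events at all** is LTFU with
  `basis_date = initiation_date` — a documented convention, not an
  error, since silent charts are common in retrospective abstraction.
* A death note dated **after** the endpoint does not affect that
  endpoint: the rule is evaluated strictly before it.

Two invariants are asserted on simulated cohorts: the three labels
partition every cohort, and widening the grace period never moves a
patient from retained to LTFU.

## Utilization accounting

Utilization is accumulated over half-open calendar-month windows
`[initiation + s, initiation + s + W)`; an event dated exactly at the
boundary belongs to the following window, so contiguous windows add:
counted quantities (drug patient-months, tests, visits) add exactly,
and fixed months add up to a small day-rounding tolerance at calendar
boundaries (asserted at 0.15 months in the tests).

Fixed-resource months in care follow the status at the window end:
retained patients accrue the full window (not the day count, which can
differ by a day from `W × 30.44`); patients who died accrue to the
death date; dropouts accrue to their last attended contact — not to
the lateness cutoff, which is what produces the gap between all-patient
and retained-subset months in care.

Same-day visits to the *same* provider type count once by default
(`visit_counting = "per_provider_day"`), since multi-row same-day
records usually reflect charting duplication; per-row counting is
available as a flag. Visits to different provider types on one day
count once each: a patient can genuinely see a clinician, a counselor,
and a pharmacist in one attendance.

The guideline audit compares a first-year profile against the 2007
Zambian adult schedule (≥ 2 CD4, ≥ 2 blood chemistry, ≥ 2 full blood
count tests, ≥ 5 clinic visits, 12 months' drug supply) and reports
per-item shortfalls plus NRTI-backbone coverage as a proportion of 12
months.

## Unit costs

All estimators are deliberately simple compositions, in line with
standard health-facility costing practice:

* **Annuity factor** `A(r, L) = (1 − (1+r)^(−L))/r`, with `A(0, L) = L`
  as the continuity limit. Defaults: 3%/year discount rate, 5-year
  equipment and 50-year building lives. An item's annualized cost is
  its replacement cost divided by the factor. The capital-recovery
  form is the WHO costing convention; the factor is strictly
  increasing in life, which the tests assert.
* **Patient equivalents** `n_ART + n_nonART × v_nonART / v_ART` convert
  non-ART patients into ART-patient units by relative visit frequency
  before shared fixed costs are divided through.
* **Laboratory tests** cost reagents/consumables per test plus annual
  equipment-labor-space overhead divided by annual volume; sites using
  a centralized laboratory instead carry that laboratory's per-test
  price verbatim. Supplying both parameterizations is an ambiguity
  error, not a silent preference.
* **Visits** cost ART-attributed annual staff cost divided by annual
  consultations, per provider type.
* **Currency**: amounts are tagged ZMK or USD with an observation
  year; ZMK amounts are CPI-inflated to the 2011 reference year and
  converted once, at unit-cost construction, at 4,861 ZMK/$. All
  downstream arithmetic is in 2011 USD, so rounding from repeated
  conversion cannot compound. Untagged currencies are rejected.

Every unit cost is homogeneous of degree 1 in monetary inputs and −1
in its volume divisor (tested), so errors of scale surface immediately.

## Cost aggregation and clustered inference

Per-patient costs are quantity × unit cost summed into five components
whose sum *is* the total (asserted to 1e-9 relative). Group summaries
report the component means and percent shares computed from unrounded
means — shares can therefore differ by a point from ratios of rounded
dollars, which is the honest version of the printed-table arithmetic.

For means pooled across sites, the 95% interval uses the CR1
cluster-robust variance of an intercept-only regression:
`V = G/(G−1) × Σ_g (Σ_{i∈g}(x_i − x̄))² / N²`, with a Student-t
quantile at `G − 1` degrees of freedom. This matches the convention of
clustered regression standard errors with the usual small-sample
factor (the `(N−1)/(N−k)` term is 1 for the intercept-only model); the
implementation is checked against both a brute-force enumeration and
`sandwich::vcovCL(type = "HC1")` on `lm(x ~ 1)`. With a single cluster
the clustered variance has zero degrees of freedom, so single-site
summaries use conventional i.i.d. t intervals — reported as such, since
it is genuinely unknown whether published per-site intervals were
adjusted. A simulation with site-level cost effects (6 sites, 100
replicates) checks that the t(G−1) intervals cover the true mean in at
least 85% of replicates.

The *cost to produce one retained patient* divides spending on **all**
patients by the count retained; it is necessarily at least the
all-patient mean, and exceeds the retained-subset mean whenever
dropouts consumed resources. Multi-year annualized costs divide the
mean cumulative cost among patients retained at `12k` months by `k`.

## What the synthetic cohort emulates

The shipped configuration (`six_site_config()`) emulates a six-site
Zambian ART program: two urban primary health clinics in Lusaka, one
urban clinic on the Copperbelt, two hospitals in Western/Southern
provinces and one rural mission hospital; 846 adults (site samples
149/149/147/149/102/150) initiating ART between July 2007 and October
2008; 12-month follow-up at four sites and 36-month at two.

Each patient draws sex, a log-normal age (truncated at 15 years, the
adult-cohort inclusion bound) and baseline CD4 parameterized by the
published medians and IQRs (CD4 distributions are right-skewed, so a
log-normal matched on quartiles is used rather than a normal), an NRTI
backbone and NNRTI/PI third drug from site-specific mixes, and then
lives on a monthly contact grid (every 30.44 days):

* at each grid month in care the patient attends the pickup with a
  site-specific probability; the initiation contact and the final
  scheduled contact of each follow-up year are always attended, so a
  patient still in care always has a contact within 90 days of the
  endpoint;
* attended pickups dispense the backbone (with probability
  `p_dispense` after initiation) with `1 + Poisson` months' supply,
  plus the third drug and co-trimoxazole with their own probabilities;
  the pharmacist visit is the pickup itself;
* doctor/clinical-officer, nurse, and counselor visits and the three
  laboratory tests arrive as monthly Poisson counts on distinct days
  within the month;
* each month applies a death hazard and, in months 1–9 of each
  follow-up year, an LTFU (stop-attending) hazard.

Two design choices deserve emphasis:

* **LTFU stops are restricted to months 1–9 of each year.** A dropout
  in the last quarter of a follow-up year would be under 90 days late
  at the endpoint and hence *unclassifiable* as LTFU there. Real
  cohorts contain such patients — which is exactly why a 90-day rule
  underestimates attrition — but simulating them would make the
  generator's truth diverge from anything the classifier can see. The
  generator therefore only simulates classifiable dropouts, and the
  classifier recovers its truth exactly; the under-ascertainment
  phenomenon itself can still be studied via
  `death_recorded_probability < 1`, which turns deaths into silent
  disappearances.
* **Outcome and regimen draws use randomized-systematic (stratified)
  uniforms** fed through the exact terminal-state CDF (enumerated by
  `terminal_distribution()`, with each state's months contiguous), so
  realized cohort composition tracks the design fractions within about
  one patient per site while every patient remains marginally
  correct. Event-level details use per-patient RNG substreams derived
  by stable string hashing, making cohorts independent of site and
  patient processing order.

Calibration: monthly hazards are solved (fixed-point on the enumerated
terminal distribution) to hit the published per-site 12-, 24-, and
36-month retention and death fractions; attendance, supply, dispensing,
visit, and laboratory parameters are backed out of the published
retained-subset annual totals (e.g. site-6 patients average 8.6
pharmacist visits but 13.6 NRTI patient-months, implying multi-month
supplies of mean 1.58). Backbone mixes use the retained-subset
patient-month shares rather than the initiation shares: the generator
does not simulate regimen switching, so the two must coincide, and the
month-share parameterization reproduces both the ARV cost components
and (within 4 points per site) the published initiation shares.
Year-2/3 visit and laboratory rates decay to 85% and 75% of first-year
rates, reproducing the observed decline in annualized cost with time
on ART in direction, which is all the tests assert. Where no source
value exists (visit-interval jitter of 0–3 days, within-month event
days, the 480-day enrollment window), values were chosen once as
clinically unremarkable and are documented here.

**What is not emulated:** disease progression and viral load, regimen
switching, transfers between clinics, inpatient care, seasonality,
within-site heterogeneity in adherence beyond Bernoulli attendance,
correlation between attendance and mortality, and non-ARV drugs other
than co-trimoxazole. The last omission is visible: published non-ARV
component costs exceed co-trimoxazole months × price by roughly $5 per
retained patient-year (other, unitemized drugs), so the simulated
retained-subset total runs ~3% below the published $243 — well within
the 10% property band the acceptance checks use, and deliberately not
patched with a phantom drug. Passing tests on this cohort show the
pipeline's arithmetic and rules are right; they do not certify any
real program's data quality.

The site cost inputs shipped for the fixture
(`fixture_site_cost_inputs()`) are synthetic reconstructions: capital,
staff, volume, and laboratory inputs chosen so the derived unit-cost
table equals the published one exactly (building costs are recorded at
2010 ZMK price levels to exercise the CPI path). They are labeled as
reconstructions in their documentation; `generate_site_cost_inputs()`
draws random but internally consistent inputs for arbitrary profiles,
with a facility-level capital base so higher-volume sites get lower
fixed unit costs.

## Numerical conventions and degenerate inputs

* Durations in days convert to months at 30.44 days/month; drug
  supply is natively in months and never converted.
* Dates are ISO-8601 calendar dates; endpoints and windows use
  calendar-month arithmetic.
* `annuity_factor(0, L) = L` exactly (continuity limit).
* Zero retained patients make conditional retention and
  cost-per-retained errors, not NaN.
* A single cluster with clustering requested is an error (zero
  degrees of freedom), not a silent fallback.
* Ambiguous laboratory inputs (both on-site and external) and unknown
  currency tags are construction-time errors.
* Ties in stratified categorical draws are broken by the random
  permutation of the systematic grid.

## Problem sizes

The test suite simulates the full 846-patient cohort once (shared
across test files), one 5,000-patient single-site cohort for the
closed-form attrition check, and smaller cohorts (30–60 patients) for
reproducibility and additivity properties; the clustered-interval
coverage check uses 100 replicates of 90 observations. These sizes
keep Monte-Carlo error well inside the asserted tolerances while the
whole suite runs in about a minute.

## Limitations

The pipeline inherits the retrospective design's blind spots: outcomes
are only as good as chart completeness (unrecorded deaths are counted
as LTFU or even retained), costs exclude inpatient and above-facility
resources, and six sites support clustered intervals only through the
small-G t approximation, which is exact under within-cluster
exchangeability but approximate otherwise. The generator reproduces
published *marginal* site statistics; joint distributions (e.g.
whether low-CD4 patients attend less) are not calibrated and should
not be read off simulated cohorts.
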