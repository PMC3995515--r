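# artcost

Retention in care, resource utilization, and provider-perspective costs
for adults on antiretroviral therapy (ART), implemented as a reusable,
tested analysis pipeline. The package is written for health economists
and HIV program analysts who need to turn longitudinal clinic records
(visits, drug pickups, laboratory tests, death notes) and site-level
financial inputs into the standard reporting surface of a treatment-
program costing study: retention at fixed endpoints, per-patient
resource quantities, site unit costs, and average cost per patient with
confidence intervals adjusted for site-level clustering.

Because chart-abstraction data cannot be redistributed, the package
ships a calibrated synthetic cohort generator emulating a six-site
Zambian ART program (846 adults initiating ART in 2007–2008, followed
12 or 36 months), so every stage of the pipeline runs, and is tested,
without any patient data.

## The methods in brief

**Outcome classification.** At an endpoint *E* months after ART
initiation a patient is *known to have died* if a death confirmation
precedes the endpoint; otherwise *lost to follow-up* (LTFU) if they are
≥ 90 days (configurable) late for their last scheduled consultation or
medication pickup; otherwise *retained in care*. When no explicit next
appointment is recorded, a pickup of *s* months' supply implies a
return date *s* × 30.44 days later.

**Utilization.** Over a half-open calendar-month window
[initiation, initiation + *W*), each patient accrues drug
patient-months (summed months' supply per drug), laboratory test
counts, clinic visit counts per provider type, and fixed-resource
months in care (full window if retained; to the death date or last
attended contact otherwise).

**Unit costs.** Capital is annualized with the annuity
(capital-recovery) factor

    A(r, L) = (1 − (1 + r)^−L) / r

at *r* = 3%/year over *L* = 5 years (equipment) or 50 years
(buildings). Annualized capital and support-staff costs are divided by
active-patient equivalents — `n_ART + n_nonART × (v_nonART / v_ART)`,
weighting non-ART patients by relative visit frequency — to give a
fixed cost per patient-month in care. Laboratory tests cost reagents
plus annual overheads divided by test volume (or a centralized-lab
price); visits cost ART-attributed staff time divided by annual
consultations. ZMK amounts are CPI-adjusted to 2011 and converted at
4,861 ZMK/$.

**Cost aggregation.** Per-patient costs are unit cost × quantity,
summed into five components (ARV drugs, non-ARV drugs, laboratory,
visits, fixed). Combined-site means carry CR1 cluster-robust
("sandwich") standard errors for the intercept-only regression,

    V = G/(G−1) · Σ_g (Σ_{i∈g} (x_i − x̄))² / N²,

with Student-t intervals at G − 1 degrees of freedom (G = sites). The
*cost to produce one retained patient* divides total spending on all
patients by the number still in care.

## Worked example

```r
library(artcost)
library(dplyr)

cohort    <- generate_cohort(six_site_config(seed = 20110101))
outcomes  <- classify_outcomes(cohort, endpoint_months = 12, grace_days = 90)
retention <- retention_table(outcomes)
retention |> filter(site_id == "all")
#>   endpoint_months site_id   n retained died ltfu pct_retained pct_died pct_ltfu
#> 1              12     all 846      633   89  124      74.8227 10.52009 14.65721

util   <- accumulate_utilization(cohort, window_months = 12)
costs  <- cost_patients(util, fixture_unit_costs())
summarize_costs(costs, outcomes) |>
  filter(site_id == "all") |>
  select(subset, n, mean, ci_low, ci_high)
#>     subset   n     mean   ci_low  ci_high
#> 1      all 846 200.6566 160.5755 240.7376
#> 2 retained 633 234.3485 186.8960 281.8009

cost_per_retained(costs, outcomes)
#> [1] 268.1761
```

Run as a workflow, the numbered scripts under `analysis/` perform the
same steps and leave their tables under `results/`. At the default
seed they report 75% twelve-month retention (11% died, 15% LTFU), a
mean first-year cost of $201 per patient (95% CI $161–$241,
site-clustered), $234 per retained patient, $268 to produce one
retained patient, ARV drugs at 66% of retained-subset cost, and a
guideline audit in which clinic visits exceed the recommended five but
CD4 testing (1.5 of 2 tests) and drug coverage (0.94 of a full year)
fall short:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_outcomes.R
Rscript analysis/03_utilization.R
Rscript analysis/04_unit_costs.R
Rscript analysis/05_costs.R
```

Example configuration files for the price table and one site's cost
inputs are installed under `inst/extdata/` (`prices.yaml`,
`site3_costs.yaml`) and load with `read_price_table()` /
`read_site_cost_inputs()`.

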