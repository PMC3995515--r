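# The shipped six-site study configuration. Site parameters are
# calibrated so that the simulated cohort's composition, 12-month
# retention, and retained-subset utilization reproduce the reference
# site statistics (see reference_site_statistics()); visit-interval and
# supply distributions are calibrated, not sourced, since only annual
# totals are published.

# Given retained-subset targets for annual pharmacist contacts (pv) and
# backbone patient-months (m), back out the monthly pickup process: the
# initiation and month-11 contacts are forced, the other ten months are
# attended with probability `pa`; contacts beyond one per month arrive at
# rate `extra`; the initiation pickup always dispenses, later attended
# pickups dispense with probability `p_disp` and mean supply `mu` months.
pickup_parameters <- function(pv, m) {
  if (pv <= 12) {
    pa <- (pv - 2) / 10
    extra <- 0
  } else {
    pa <- 1
    extra <- (pv - 12) / 12
  }
  eligible <- 1 + 10 * pa # dispensing-eligible non-initiation pickups
  if (m / (1 + eligible) <= 1) {
    p_disp <- (m - 1) / eligible
    mu <- 1
  } else {
    p_disp <- 1
    mu <- m / (1 + eligible)
  }
  list(attendance = pa, extra = extra, p_dispense = p_disp,
       supply_mean = mu)
}

# Conditional per-year (died, ltfu) increments from cumulative fractions.
yearly_hazards <- function(cum_died, cum_ltfu) {
  n_years <- length(cum_died)
  dh <- lh <- numeric(n_years)
  prev_d <- 0; prev_l <- 0
  for (y in seq_len(n_years)) {
    in_care <- 1 - prev_d - prev_l
    hz <- solve_monthly_hazards((cum_died[[y]] - prev_d) / in_care,
                                (cum_ltfu[[y]] - prev_l) / in_care)
    dh[[y]] <- hz$death_hazard
    lh[[y]] <- hz$ltfu_hazard
    prev_d <- cum_died[[y]]; prev_l <- cum_ltfu[[y]]
  }
  list(death_hazard = dh, ltfu_hazard = lh)
}

#' The shipped six-site study configuration
#'
#' Returns the calibrated [generator_config()] emulating the six-site
#' Zambian ART cohort: per-site sample sizes (149, 149, 147, 149, 102,
#' 150), regimen mixes, baseline age/CD4/sex distributions, visit, pickup,
#' and laboratory processes, and monthly attrition hazards solved to hit
#' the published 12-month (and, for the two 36-month sites, 24- and
#' 36-month) retention. Follow-up is 12 months at sites 1, 3, 4, and 5 and
#' 36 months at sites 2 and 6, whose visit and laboratory rates decay to
#' 85% and 75% of first-year rates in years two and three.
#'
#' @param seed Master seed (default 104729).
#' @return A [generator_config()].
#' @export
six_site_config <- function(seed = 104729) {
  ref <- reference_site_statistics()
  co <- ref$cohort
  rt <- ref$retention
  ur <- ref$utilization_retained

  # cumulative attrition fractions by follow-up year; the combined
  # two- and three-year death proportion at the 36-month sites is 18%
  cum_died <- list(
    site1 = 13 / 149, site2 = c(23 / 149, 0.18, 0.183),
    site3 = 14 / 147, site4 = 7 / 149, site5 = 6 / 102,
    site6 = c(26 / 150, 0.18, 0.183))
  cum_ltfu <- list(
    site1 = 20 / 149, site2 = c(23 / 149, 1 - 0.64 - 0.18, 1 - 0.61 - 0.183),
    site3 = 24 / 147, site4 = 26 / 149, site5 = 20 / 102,
    site6 = c(11 / 150, 1 - 0.72 - 0.18, 1 - 0.64 - 0.183))

  profiles <- lapply(seq_len(6), function(s) {
    u <- ur[s, ]
    backbone <- c(u$`TDF/FTC`, u$`AZT/3TC`, u$`ABC/3TC`, u$`d4T/3TC`)
    backbone <- setNames(backbone / sum(backbone), nrti_codes())
    third <- c(u$NVP, u$EFV, u$`LPV/r`)
    third <- setNames(third / sum(third), nnrti_pi_codes())
    pk <- pickup_parameters(u$pharmacist, u$any_nrti)
    hz <- yearly_hazards(cum_died[[s]], cum_ltfu[[s]])
    n_years <- ceiling(co$followup_months[[s]] / 12)
    site_profile(
      site_id = co$site_id[[s]],
      n_patients = co$n[[s]],
      n_active_patients = co$n_active_2008[[s]],
      followup_months = co$followup_months[[s]],
      pct_female = co$pct_female[[s]] / 100,
      age_median = co$median_age[[s]],
      age_iqr = c(co$age_q1[[s]], co$age_q3[[s]]),
      cd4_median = co$median_cd4[[s]],
      cd4_iqr = c(co$cd4_q1[[s]], co$cd4_q3[[s]]),
      backbone_mix = backbone, third_mix = third,
      pickup_attendance = pk$attendance,
      extra_pharmacist_rate = pk$extra,
      p_dispense = pk$p_dispense, supply_mean = pk$supply_mean,
      p_third_drug = min(1, u$any_nnrti_pi / u$any_nrti),
      p_ctx = min(1, u$CTX / u$any_nrti),
      visit_rates = c(
        doctor_or_clinical_officer = (u$doctor_or_clinical_officer - 1) / 12,
        nurse = u$nurse / 12,
        counselor = u$counselor / 12),
      lab_rates = c(cd4 = u$cd4, blood_chemistry = u$blood_chemistry,
                    full_blood_count = u$full_blood_count),
      death_hazard = hz$death_hazard,
      ltfu_hazard = hz$ltfu_hazard,
      rate_decay = c(1, 0.85, 0.75)[seq_len(n_years)])
  })
  generator_config(profiles, seed = seed,
                   calendar_start = as.Date("2007-07-01"),
                   enrollment_days = 480)
}

#' Deterministic site cost inputs reproducing the reference unit costs
#'
#' Constructs, for each site, a set of capital, staff, laboratory, and
#' provider inputs (in ZMK, with building costs recorded at 2010 price
#' levels to exercise the CPI restatement) whose derived unit-cost table
#' ([build_unit_cost_table()]) equals [reference_unit_costs()]: external
#' laboratory prices at sites 1-2, on-site laboratory inputs at sites 3-6,
#' and fixed costs allocated over active-patient equivalents. These inputs
#' are synthetic reconstructions consistent with the published unit costs,
#' not collected financial records.
#'
#' @return Named list of [site_cost_inputs()], one per site.
#' @export
fixture_site_cost_inputs <- function() {
  ref <- reference_site_statistics()$cohort
  uc <- reference_unit_costs()
  pt <- reference_price_table()
  fx <- pt$exchange_rate
  cpi10 <- pt$cpi_series[["2010"]] / pt$cpi_series[["2011"]]
  params <- annualization_params()

  inputs <- lapply(seq_len(6), function(s) {
    sid <- ref$site_id[[s]]
    target <- function(class, code) {
      uc$unit_cost_usd[uc$site_id == sid & uc$resource_class == class &
                         uc$code == code]
    }
    n_art <- ref$n_active_2008[[s]]
    n_nonart <- round(0.8 * n_art)
    equivalents <- patient_equivalents(n_art, n_nonart, 4, 8)

    annual_fixed_usd <- target("fixed", "months_in_care") * 12 * equivalents
    capital <- tibble::tibble(
      item = c("buildings", "equipment"),
      replacement_cost = c(
        0.5 * annual_fixed_usd *
          annuity_factor(params$discount_rate, params$life_buildings) *
          fx * cpi10,
        0.2 * annual_fixed_usd *
          annuity_factor(params$discount_rate, params$life_equipment) * fx),
      life_years = c(params$life_buildings, params$life_equipment),
      year = c(2010, 2011))
    staff <- tibble::tibble(
      role = "art_clinic_support",
      annual_salary_allowances = 0.3 * annual_fixed_usd / 0.6 * fx,
      art_fraction = 0.6, year = 2011)

    providers <- tibble::tibble(
      provider_type = provider_types(),
      consultations_per_year = round(n_art * c(6, 7, 8, 9)),
      art_fraction = 0.65, year = 2011)
    providers$annual_cost <- vapply(seq_len(4), function(i) {
      target("visit", providers$provider_type[[i]]) *
        providers$consultations_per_year[[i]] / 0.65 * fx
    }, numeric(1))

    if (s %in% 1:2) {
      labs <- tibble::tibble(
        test_code = test_codes(),
        reagent_consumable_cost_per_test = NA_real_,
        annual_equipment_labor_space = NA_real_,
        tests_per_year = NA_real_,
        external_price_per_test = vapply(
          test_codes(), function(tc) target("lab_test", tc), numeric(1)),
        year = 2011)
    } else {
      vol <- round(n_art * c(1.5, 1.1, 1.3))
      per_test <- vapply(test_codes(), function(tc) target("lab_test", tc),
                         numeric(1))
      labs <- tibble::tibble(
        test_code = test_codes(),
        reagent_consumable_cost_per_test = 0.6 * per_test * fx,
        annual_equipment_labor_space = 0.4 * per_test * vol * fx,
        tests_per_year = vol,
        external_price_per_test = NA_real_,
        year = 2011)
    }
    site_cost_inputs(
      site_id = sid, capital_items = capital, support_staff = staff,
      n_art_patients = n_art, n_nonart_patients = n_nonart,
      visits_per_year_art = 8, visits_per_year_nonart = 4,
      provider_costs = providers, lab_inputs = labs, currency = "ZMK")
  })
  names(inputs) <- ref$site_id
  inputs
}

#' Unit-cost tables for the shipped fixture, one row set per site
#'
#' Convenience wrapper: derives each site's unit costs from
#' [fixture_site_cost_inputs()] with [build_unit_cost_table()] and binds
#' them.
#'
#' @return Tidy unit-cost tibble covering all six sites.
#' @export
fixture_unit_costs <- function() {
  pt <- reference_price_table()
  dplyr::bind_rows(lapply(fixture_site_cost_inputs(),
                          build_unit_cost_table, pt = pt))
}
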