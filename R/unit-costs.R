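# Unit-cost estimation: capital annualization, patient-equivalent
# allocation of shared fixed costs, per-test and per-visit costing, and
# restatement of local-currency amounts to reference-year USD.

#' Annualization parameters for capital items
#'
#' The WHO costing convention: replacement costs are annualized with an
#' annuity (capital-recovery) factor at a 3% annual discount rate over a
#' working life of 5 years for equipment and 50 years for buildings.
#'
#' @param discount_rate Annual discount rate (proportion, default 0.03).
#' @param life_equipment,life_buildings Working lives in years.
#' @export
annualization_params <- function(discount_rate = 0.03, life_equipment = 5,
                                 life_buildings = 50) {
  stopifnot(discount_rate >= 0, life_equipment > 0, life_buildings > 0)
  structure(list(discount_rate = discount_rate,
                 life_equipment = life_equipment,
                 life_buildings = life_buildings),
            class = "annualization_params")
}

#' Annuity (capital-recovery) factor
#'
#' `(1 - (1 + rate)^(-life)) / rate`, with the continuity limit `life` at
#' `rate = 0`. An item's annualized cost is its replacement cost divided by
#' this factor. The factor is strictly increasing in `life` and decreasing
#' in `rate`.
#'
#' @param rate Annual discount rate (proportion, >= 0).
#' @param life Working life in years (> 0).
#' @return Dimensionless factor (years of equivalent annual payments).
#' @export
annuity_factor <- function(rate, life) {
  if (any(life <= 0)) stop("life must be > 0", call. = FALSE)
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  n <- max(length(rate), length(life))
  rate <- rep_len(rate, n)
  life <- rep_len(life, n)
  ifelse(rate == 0, life, (1 - (1 + rate)^(-life)) / rate)
}

#' Active-patient equivalents for shared fixed-cost allocation
#'
#' Non-ART patients are converted to ART-patient units by the ratio of
#' average annual visit counts, then added to the ART patient count:
#' `n_art + n_nonart * visits_nonart / visits_art`.
#'
#' @param n_art,n_nonart Active ART and non-ART patients per year.
#' @param visits_per_year_nonart,visits_per_year_art Average visits per
#'   patient per year for each group.
#' @return Equivalent patient-years.
#' @export
patient_equivalents <- function(n_art, n_nonart, visits_per_year_nonart,
                                visits_per_year_art) {
  if (any(visits_per_year_art <= 0)) {
    stop("visits_per_year_art must be > 0", call. = FALSE)
  }
  stopifnot(all(n_art >= 0), all(n_nonart >= 0),
            all(visits_per_year_nonart >= 0))
  n_art + n_nonart * visits_per_year_nonart / visits_per_year_art
}

#' Fixed cost per patient-month in care
#'
#' Annualized capital (buildings and equipment via [annuity_factor()]) plus
#' ART-attributed support-staff cost, divided by active-patient
#' equivalents, divided by 12. Amounts must already be in reference-year
#' USD (see [to_reference_usd()]).
#'
#' @param capital_items Data frame with `replacement_cost` (USD) and
#'   `life_years`.
#' @param support_staff Data frame with `annual_salary_allowances` (USD)
#'   and `art_fraction`.
#' @param params [annualization_params()].
#' @param equivalents Active-patient equivalents (> 0).
#' @return USD per patient-month in care.
#' @export
fixed_cost_per_patient_month <- function(capital_items, support_staff,
                                         params = annualization_params(),
                                         equivalents) {
  if (equivalents <= 0) stop("equivalents must be > 0", call. = FALSE)
  annual_capital <- if (nrow(capital_items) == 0) 0 else
    sum(capital_items$replacement_cost /
          annuity_factor(params$discount_rate, capital_items$life_years))
  annual_staff <- if (nrow(support_staff) == 0) 0 else
    sum(support_staff$annual_salary_allowances * support_staff$art_fraction)
  (annual_capital + annual_staff) / equivalents / 12
}

#' Cost per laboratory test
#'
#' For an on-site laboratory: reagent and consumable cost per test plus the
#' annual equipment, labor, and space cost divided by annual test volume.
#' For tests run at a centralized laboratory, the external per-test price
#' is used verbatim. Supplying both is an ambiguity error.
#'
#' @param reagent_consumable_cost_per_test,annual_equipment_labor_space
#'   On-site inputs in reference-year USD (NA when external).
#' @param tests_per_year Annual on-site test volume (> 0 when on-site).
#' @param external_price_per_test Centralized-laboratory price in USD
#'   (NA when on-site).
#' @return USD per test.
#' @export
lab_cost_per_test <- function(reagent_consumable_cost_per_test = NA,
                              annual_equipment_labor_space = NA,
                              tests_per_year = NA,
                              external_price_per_test = NA) {
  onsite <- !is.na(reagent_consumable_cost_per_test)
  external <- !is.na(external_price_per_test)
  if (onsite && external) {
    stop("ambiguous laboratory inputs: give on-site inputs or an external ",
         "price, not both", call. = FALSE)
  }
  if (external) return(external_price_per_test)
  if (!onsite) stop("no laboratory inputs supplied", call. = FALSE)
  if (is.na(tests_per_year) || tests_per_year <= 0) {
    stop("tests_per_year must be > 0 for on-site costing", call. = FALSE)
  }
  reagent_consumable_cost_per_test +
    annual_equipment_labor_space / tests_per_year
}

#' Cost per clinic visit for one provider type
#'
#' ART-attributed annual staff cost divided by annual patient
#' consultations: `annual_cost * art_fraction / consultations_per_year`.
#'
#' @param annual_cost Annual staff cost for the provider type
#'   (reference-year USD).
#' @param art_fraction Proportion of staff time on ART care.
#' @param consultations_per_year Annual patient consultations (> 0).
#' @return USD per visit.
#' @export
visit_cost <- function(annual_cost, art_fraction, consultations_per_year) {
  if (any(consultations_per_year <= 0)) {
    stop("consultations_per_year must be > 0", call. = FALSE)
  }
  stopifnot(all(annual_cost >= 0),
            all(art_fraction >= 0 & art_fraction <= 1))
  annual_cost * art_fraction / consultations_per_year
}

#' Restate a local-currency amount in reference-year USD
#'
#' The amount is first inflated to the reference-year price level with the
#' consumer price index and then converted at the reference-year exchange
#' rate: `amount * (cpi[reference] / cpi[year]) / exchange_rate`.
#'
#' @param amount Amount in local currency (ZMK).
#' @param year Year the amount was observed in.
#' @param pt A [price_table()] carrying the CPI series and exchange rate.
#' @return Reference-year USD.
#' @export
to_reference_usd <- function(amount, year, pt) {
  stopifnot(inherits(pt, "price_table"))
  yr <- as.character(year)
  ref <- as.character(pt$reference_year)
  missing_years <- setdiff(unique(yr), names(pt$cpi_series))
  if (length(missing_years) > 0) {
    stop("CPI series is missing year(s): ",
         paste(missing_years, collapse = ", "), call. = FALSE)
  }
  amount * (pt$cpi_series[[ref]] / unname(pt$cpi_series[yr])) /
    pt$exchange_rate
}

#' Build a site's unit-cost table
#'
#' Composes the unit-costing operations: drug prices are copied from the
#' price table unchanged (and are therefore identical across sites);
#' laboratory, visit, and fixed unit costs are derived from the site's
#' cost inputs, with ZMK amounts restated to reference-year USD once, here.
#'
#' @param site_inputs A [site_cost_inputs()] object.
#' @param pt A [price_table()].
#' @param params [annualization_params()].
#' @return Tidy unit-cost tibble (`site_id`, `resource_class`, `code`,
#'   `unit_cost_usd`); see [read_unit_cost_table()].
#' @export
build_unit_cost_table <- function(site_inputs, pt,
                                  params = annualization_params()) {
  stopifnot(inherits(site_inputs, "site_cost_inputs"),
            inherits(pt, "price_table"))
  usd <- function(amount, year) {
    if (site_inputs$currency == "USD") amount
    else to_reference_usd(amount, year, pt)
  }
  wrap <- function(component, expr) {
    tryCatch(expr, error = function(e) {
      stop("unit-cost construction failed for site ", site_inputs$site_id,
           ", component '", component, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  drugs <- tibble::tibble(
    code = names(pt$drug_prices),
    unit_cost_usd = unname(pt$drug_prices),
    resource_class = ifelse(names(pt$drug_prices) %in% arv_codes(),
                            "arv_drug", "non_arv_drug"))

  li <- site_inputs$lab_inputs
  labs <- wrap("laboratory tests", tibble::tibble(
    code = li$test_code,
    resource_class = "lab_test",
    unit_cost_usd = vapply(seq_len(nrow(li)), function(i) {
      if (!is.na(li$external_price_per_test[[i]])) {
        lab_cost_per_test(external_price_per_test =
                            li$external_price_per_test[[i]])
      } else {
        lab_cost_per_test(
          reagent_consumable_cost_per_test =
            usd(li$reagent_consumable_cost_per_test[[i]], li$year[[i]]),
          annual_equipment_labor_space =
            usd(li$annual_equipment_labor_space[[i]], li$year[[i]]),
          tests_per_year = li$tests_per_year[[i]])
      }
    }, numeric(1))))

  pc <- site_inputs$provider_costs
  visits <- wrap("clinic visits", tibble::tibble(
    code = pc$provider_type,
    resource_class = "visit",
    unit_cost_usd = visit_cost(usd(pc$annual_cost, pc$year),
                               pc$art_fraction,
                               pc$consultations_per_year)))

  equivalents <- wrap("patient equivalents", patient_equivalents(
    site_inputs$n_art_patients, site_inputs$n_nonart_patients,
    site_inputs$visits_per_year_nonart, site_inputs$visits_per_year_art))
  ci <- site_inputs$capital_items
  ci$replacement_cost <- usd(ci$replacement_cost, ci$year)
  ss <- site_inputs$support_staff
  ss$annual_salary_allowances <- usd(ss$annual_salary_allowances, ss$year)
  fixed <- wrap("fixed resources", tibble::tibble(
    code = "months_in_care",
    resource_class = "fixed",
    unit_cost_usd = fixed_cost_per_patient_month(ci, ss, params,
                                                 equivalents)))

  out <- dplyr::bind_rows(drugs, labs, visits, fixed)
  out$site_id <- site_inputs$site_id
  out[c("site_id", "resource_class", "code", "unit_cost_usd")]
}
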