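# Published six-site Zambian ART program reference statistics (2011 USD)
# used to calibrate the shipped synthetic cohort and as desk-scale
# reproduction surfaces. Sites 1-3 are urban primary health clinics, site 4
# a second-level general hospital, site 5 a first-level district hospital,
# and site 6 a rural second-level mission hospital; patients initiated ART
# between July 2007 and October 2008 and were followed for 12 months
# (sites 1, 3, 4, 5) or 36 months (sites 2, 6).

SITE_IDS <- paste0("site", 1:6)

#' Reference six-site cohort statistics
#'
#' The published site-level summary statistics of the Zambian ART costing
#' cohort that the shipped generator is calibrated to: cohort composition,
#' 12-month retention counts, per-patient resource utilization means (full
#' sample and retained subset), and mean cost per patient. All monetary
#' values are 2011 USD.
#'
#' @return A named list of tibbles: `cohort`, `retention`,
#'   `utilization_retained`, `utilization_all`, `costs`.
#' @export
reference_site_statistics <- function() {
  cohort <- tibble::tibble(
    site_id = SITE_IDS,
    n = c(149, 149, 147, 149, 102, 150),
    n_active_2008 = c(5488, 5102, 1167, 5748, 524, 2981),
    followup_months = c(12, 36, 12, 12, 12, 36),
    median_age = c(35, 35, 34, 33, 35, 37),
    age_q1 = c(30, 30, 29, 29, 31, 31),
    age_q3 = c(40, 43, 40, 42, 41, 46),
    pct_female = c(63, 52, 68, 66, 45, 58),
    median_cd4 = c(149, 127, 136, 150, 140, 160),
    cd4_q1 = c(97, 67, 84, 77, 74, 106),
    cd4_q3 = c(211, 206, 199, 237, 273, 209),
    pct_tdf = c(36, 86, 80, 15, 54, 80),
    pct_azt = c(30, 5, 13, 4, 30, 7),
    pct_abc = c(0, 5, 0, 76, 0, 0),
    pct_d4t = c(34, 5, 7, 5, 16, 13))

  retention <- tibble::tibble(
    site_id = SITE_IDS,
    n = cohort$n,
    retained_12 = c(116, 103, 109, 116, 76, 113),
    died_12 = c(13, 23, 14, 7, 6, 26),
    ltfu_12 = c(20, 23, 24, 26, 20, 11),
    pct_retained_24 = c(NA, 64, NA, NA, NA, 72),
    pct_retained_36 = c(NA, 61, NA, NA, NA, 64))

  utilization_retained <- tibble::tibble(
    site_id = SITE_IDS,
    `TDF/FTC` = c(4.3, 10.2, 9.3, 1.6, 5.1, 10.8),
    `AZT/3TC` = c(3.3, 0.0, 1.0, 0.6, 2.9, 1.3),
    `ABC/3TC` = c(0.1, 1.2, 0.0, 7.6, 0.0, 0.1),
    `d4T/3TC` = c(3.1, 0.9, 0.8, 0.5, 1.7, 1.4),
    any_nrti = c(10.9, 12.2, 11.1, 10.4, 9.6, 13.6),
    NVP = c(7.9, 10.3, 5.1, 2.9, 4.6, 5.1),
    EFV = c(2.6, 2.0, 5.6, 7.4, 5.0, 8.1),
    `LPV/r` = c(0.2, 0.0, 0.0, 0.0, 0.0, 0.0),
    any_nnrti_pi = c(10.7, 12.3, 10.7, 10.2, 9.6, 13.2),
    CTX = c(7.9, 11.8, 1.6, 3.8, 0.3, 12.1),
    cd4 = c(1.8, 1.9, 1.6, 0.6, 1.7, 1.5),
    blood_chemistry = c(0.1, 2.5, 1.0, 0.3, 1.0, 2.6),
    full_blood_count = c(1.6, 1.6, 1.0, 0.5, 2.2, 1.6),
    doctor_or_clinical_officer = c(5.9, 6.6, 6.4, 3.8, 8.0, 8.7),
    nurse = c(8.8, 8.6, 6.5, 4.8, 8.0, 8.7),
    counselor = c(11.1, 11.9, 7.4, 8.9, 8.0, 7.8),
    pharmacist = c(11.4, 13.0, 7.4, 8.5, 8.0, 8.6),
    months_in_care = c(12, 12, 12, 12, 12, 12))

  utilization_all <- tibble::tibble(
    site_id = SITE_IDS,
    any_nrti = c(8.9, 9.1, 8.8, 8.7, 7.8, 11.1),
    any_nnrti_pi = c(8.8, 9.2, 8.5, 8.6, 7.7, 10.8),
    CTX = c(6.4, 8.8, 1.3, 3.2, 0.2, 9.8),
    cd4 = c(1.5, 1.3, 1.4, 0.5, 1.5, 1.2),
    doctor_or_clinical_officer = c(5.0, 5.3, 5.3, 3.4, 6.6, 7.4),
    pharmacist = c(9.5, 10.0, 6.1, 7.2, 6.6, 7.3),
    months_in_care = c(9.9, 9.3, 9.6, 10.1, 9.6, 9.8))

  costs <- tibble::tibble(
    site_id = SITE_IDS,
    mean_all = c(151, 185, 166, 209, 251, 242),
    mean_retained = c(184, 245, 205, 247, 304, 296),
    arv_retained = c(123, 166, 148, 207, 116, 178),
    non_arv_retained = c(12, 20, 4, 5, 0, 22),
    lab_retained = c(11, 18, 27, 11, 49, 23),
    visit_retained = c(26, 27, 11, 17, 67, 33),
    fixed_retained = c(12, 14, 15, 7, 72, 39))

  list(cohort = cohort, retention = retention,
       utilization_retained = utilization_retained,
       utilization_all = utilization_all, costs = costs)
}

#' Reference price table
#'
#' Per-patient-month ARV and co-trimoxazole prices in 2011 USD (national
#' procurement averages, identical across sites), the Zambian CPI series
#' used to restate older ZMK amounts, and the 2011 average exchange rate of
#' 4,861 ZMK/$.
#'
#' @return A [price_table()].
#' @export
reference_price_table <- function() {
  price_table(
    drug_prices = c("TDF/FTC" = 10.54, "AZT/3TC" = 8.41, "ABC/3TC" = 18.64,
                    "d4T/3TC" = 3.01, "NVP" = 2.34, "EFV" = 4.26,
                    "LPV/r" = 36.70, "CTX" = 0.93),
    cpi_series = c("2008" = 78.9, "2009" = 89.4, "2010" = 92.5,
                   "2011" = 100),
    exchange_rate = 4861, reference_year = 2011)
}

#' Reference unit-cost table for the six sites
#'
#' Site-level unit costs in 2011 USD: drug prices (constant across sites),
#' laboratory cost per test, cost per clinic visit by provider type, and
#' fixed cost per patient-month in care. Sites 1 and 2 send laboratory
#' tests to a centralized high-volume laboratory; sites 3-6 run them
#' on site.
#'
#' @return Tidy unit-cost tibble (see [read_unit_cost_table()]).
#' @export
reference_unit_costs <- function() {
  pt <- reference_price_table()
  drugs <- dplyr::cross_join(
    tibble::tibble(site_id = SITE_IDS),
    tibble::tibble(code = names(pt$drug_prices),
                   unit_cost_usd = unname(pt$drug_prices))) |>
    dplyr::mutate(resource_class = ifelse(.data$code %in% arv_codes(),
                                          "arv_drug", "non_arv_drug"))
  labs <- tibble::tibble(
    site_id = rep(SITE_IDS, each = 3),
    resource_class = "lab_test",
    code = rep(test_codes(), times = 6),
    unit_cost_usd = c(2.87, 2.93, 2.80, 2.87, 2.93, 2.80,
                      11.90, 5.01, 2.14, 10.56, 7.23, 5.24,
                      18.16, 5.11, 5.60, 10.06, 2.27, 1.11))
  visits <- tibble::tibble(
    site_id = rep(SITE_IDS, each = 4),
    resource_class = "visit",
    code = rep(provider_types(), times = 6),
    unit_cost_usd = c(1.71, 0.52, 0.56, 0.42,
                      1.82, 1.01, 0.15, 0.32,
                      0.57, 0.48, 0.31, 0.29,
                      0.37, 0.40, 1.00, 0.45,
                      2.86, 1.91, 2.11, 1.50,
                      1.01, 0.59, 2.21, 0.28))
  fixed <- tibble::tibble(
    site_id = SITE_IDS, resource_class = "fixed", code = "months_in_care",
    unit_cost_usd = c(1.03, 1.17, 1.21, 0.60, 6.04, 3.31))
  dplyr::bind_rows(drugs, labs, visits, fixed)[
    c("site_id", "resource_class", "code", "unit_cost_usd")]
}
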