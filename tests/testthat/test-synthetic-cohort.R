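test_that("identical configuration and seed reproduce the cohort exactly", {
  cfg <- generator_config(list(tiny_profile(n = 40)), seed = 99)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_identical(cohort_truth(c1), cohort_truth(c2))
})

test_that("generation is independent of profile order", {
  p1 <- tiny_profile("siteA", n = 30)
  p2 <- tiny_profile("siteB", n = 30, death_hazard = 0.03)
  ab <- generate_cohort(generator_config(list(p1, p2), seed = 5))
  ba <- generate_cohort(generator_config(list(p2, p1), seed = 5))
  strip <- function(x) {
    attr(x, "truth") <- NULL
    as.data.frame(x)
  }
  for (s in c("siteA", "siteB")) {
    expect_identical(
      strip(dplyr::filter(ab, site_id == s)),
      strip(dplyr::arrange(dplyr::filter(ba, site_id == s),
                           site_id, patient_id, event_date)))
    expect_identical(
      dplyr::arrange(dplyr::filter(cohort_truth(ab), site_id == s),
                     patient_id),
      dplyr::arrange(dplyr::filter(cohort_truth(ba), site_id == s),
                     patient_id))
  }
})

test_that("with zero hazards and full attendance every patient is retained", {
  p <- tiny_profile(n = 60, death_hazard = 0, ltfu_hazard = 0,
                    pickup_attendance = 1)
  coh <- generate_cohort(generator_config(list(p), seed = 3))
  out <- classify_outcomes(coh, 12)
  expect_true(all(out$outcome == "retained"))
  expect_true(all(cohort_truth(coh)$terminal_state == "retained"))
})

test_that("invalid profiles are rejected before any generation", {
  expect_error(tiny_profile(n = 0), "n_patients")
  expect_error(tiny_profile(death_hazard = 1.2), "hazard")
  expect_error(site_profile("x", 10,
                            backbone_mix = c("TDF/FTC" = 0.5, "AZT/3TC" = 0.2,
                                             "ABC/3TC" = 0.1, "d4T/3TC" = 0.1),
                            third_mix = c(NVP = 0.5, EFV = 0.5, `LPV/r` = 0)),
               "summing to 1")
  expect_error(generator_config(list(tiny_profile("a"), tiny_profile("a"))),
               "unique")
})

test_that("observed death fraction matches geometric survival closed form", {
  p_m <- 0.02
  expected <- 1 - (1 - p_m)^12
  prof <- tiny_profile(n = 5000, death_hazard = p_m, ltfu_hazard = 0,
                       pickup_attendance = 0.7,
                       visit_rates = c(doctor_or_clinical_officer = 0.2,
                                       nurse = 0.2, counselor = 0.2),
                       lab_rates = c(cd4 = 0.5, blood_chemistry = 0.5,
                                     full_blood_count = 0.5))
  coh <- generate_cohort(generator_config(list(prof), seed = 11))
  truth <- cohort_truth(coh)
  observed <- mean(truth$terminal_state == "died")
  mc_se <- sqrt(expected * (1 - expected) / 5000)
  expect_lt(abs(observed - expected), 3 * mc_se)

  # and the classifier recovers the generator's attrition fractions
  cls <- classify_outcomes(coh, 12)
  tru <- truth_outcomes(truth, 12)
  for (o in c("died", "ltfu", "retained")) {
    p_true <- mean(tru$outcome == o)
    se <- sqrt(max(p_true * (1 - p_true), 1e-6) / 5000)
    expect_lt(abs(mean(cls$outcome == o) - p_true), 3 * se + 1e-12)
  }
})

test_that("no patient has events after death, and dropouts go silent", {
  coh <- fixture_cohort()
  truth <- cohort_truth(coh)
  deaths <- dplyr::filter(coh, event_kind == "death")
  ev <- dplyr::filter(coh, !is.na(event_kind)) |>
    dplyr::inner_join(deaths[c("patient_id", "event_date")],
                      by = "patient_id", suffix = c("", ".death"))
  expect_true(all(ev$event_date <= ev$event_date.death))

  # retained patients have an attended contact within 90 days of the
  # 12-month endpoint
  ret <- truth$patient_id[truth$terminal_state == "retained"]
  last_contact <- coh |>
    dplyr::filter(patient_id %in% ret,
                  event_kind %in% c("visit", "dispensation")) |>
    dplyr::group_by(patient_id, initiation_date) |>
    dplyr::summarise(last = max(event_date), .groups = "drop")
  endpoint <- last_contact$initiation_date %m+% lubridate::period(12, "months")
  in_window <- as.numeric(endpoint - last_contact$last)
  expect_true(all(in_window < 90))
})

test_that("terminal distribution probabilities are exact and sum to one", {
  td <- terminal_distribution(0.01, 0.02, 12)
  expect_equal(sum(td$prob), 1)
  # death hazard applied first each month; LTFU only months 1-9
  expect_equal(td$prob[td$state == "died" & td$month == 1], 0.01)
  expect_equal(td$prob[td$state == "ltfu" & td$month == 1], 0.99 * 0.02)
  expect_equal(sum(td$state == "ltfu"), 9)
  expect_equal(sum(td$state == "died"), 12)

  hz <- solve_monthly_hazards(0.11, 0.15)
  td2 <- terminal_distribution(hz$death_hazard, hz$ltfu_hazard, 12)
  expect_equal(sum(td2$prob[td2$state == "died"]), 0.11, tolerance = 1e-9)
  expect_equal(sum(td2$prob[td2$state == "ltfu"]), 0.15, tolerance = 1e-9)
})

test_that("site cost inputs are reproducible and volumes scale linearly", {
  prof <- tiny_profile(n = 10)
  a <- generate_site_cost_inputs(prof, seed = 42)
  b <- generate_site_cost_inputs(prof, seed = 42)
  expect_identical(a, b)

  prof2 <- prof
  prof2$n_active_patients <- 2 * prof$n_active_patients
  c2 <- generate_site_cost_inputs(prof2, seed = 42)
  expect_equal(c2$lab_inputs$tests_per_year, 2 * a$lab_inputs$tests_per_year)
  expect_equal(c2$provider_costs$consultations_per_year,
               2 * a$provider_costs$consultations_per_year)

  # shared facility base: higher volume means a lower fixed unit cost
  pt <- reference_price_table()
  fixed_of <- function(si) {
    uc <- build_unit_cost_table(si, pt)
    uc$unit_cost_usd[uc$resource_class == "fixed"]
  }
  expect_lt(fixed_of(c2), fixed_of(a))
})

test_that("the shipped configuration reproduces the published cohort shape", {
  coh <- fixture_cohort()
  sizes <- dplyr::count(dplyr::distinct(coh, patient_id, site_id), site_id)
  expect_equal(sizes$n, c(149, 149, 147, 149, 102, 150))

  first_nrti <- coh |>
    dplyr::filter(event_kind == "dispensation", drug_code %in% nrti_codes()) |>
    dplyr::group_by(patient_id) |>
    dplyr::slice_min(event_date, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  tdf_share <- 100 * mean(first_nrti$drug_code == "TDF/FTC")
  expect_lt(abs(tdf_share - 59), 5)

  out <- classify_outcomes(coh, 12)
  overall <- retention_table(out)
  overall <- overall[overall$site_id == "all", ]
  expect_lt(abs(overall$pct_retained - 75), 5)
})
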