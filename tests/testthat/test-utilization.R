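test_that("drug months, counts, and fixed months accumulate as stated", {
  pat <- make_patient(events = c(
    monthly_pickups(12),
    list(list(day = 10, kind = "lab", test = "cd4"),
         list(day = 40, kind = "visit",
              provider = "doctor_or_clinical_officer"))))
  u <- accumulate_utilization(pat, 12)
  get <- function(code) u$quantity[u$code == code]
  expect_equal(get("TDF/FTC"), 12)
  expect_equal(get("cd4"), 1)
  expect_equal(get("doctor_or_clinical_officer"), 1)
  expect_equal(get("months_in_care"), 12) # retained: full window

  # a patient with no events accrues nothing
  none <- make_patient(patient_id = "p2")
  u0 <- accumulate_utilization(dplyr::bind_rows(pat, none), 12)
  expect_true(all(u0$quantity[u0$patient_id == "p2"] == 0))
})

test_that("fixed months stop at death, in 30.44-day months", {
  pat <- make_patient(events = c(
    monthly_pickups(6),
    list(list(day = 182, kind = "death"))))
  u <- accumulate_utilization(pat, 12)
  expect_equal(u$quantity[u$code == "TDF/FTC"], 6)
  expect_equal(u$quantity[u$code == "months_in_care"], 182 / 30.44,
               tolerance = 1e-9)
})

test_that("fixed months for dropouts stop at the last attended contact", {
  pat <- make_patient(events = monthly_pickups(4)) # last pickup day 91
  u <- accumulate_utilization(pat, 12)
  expect_equal(u$quantity[u$code == "months_in_care"],
               round(30.44 * 3) / 30.44, tolerance = 1e-9)
})

test_that("window boundaries are half-open and windows are additive", {
  pat <- make_patient(events = list(
    list(day = 0, kind = "dispensation", drug = "TDF/FTC", supply = 1,
         sched_day = 30)))
  # event exactly at the window start of [12, 24) is counted there only
  w_end_day <- as.numeric(
    (as.Date("2019-01-01") %m+% lubridate::period(12, "months")) -
      as.Date("2019-01-01"))
  boundary <- make_patient(patient_id = "pb", events = list(
    list(day = w_end_day, kind = "lab", test = "cd4")))
  u1 <- accumulate_utilization(boundary, 12)
  u2 <- accumulate_utilization(boundary, 12, window_start_months = 12)
  expect_equal(sum(u1$quantity[u1$code == "cd4"]), 0)
  expect_equal(sum(u2$quantity[u2$code == "cd4"]), 1)

  # additivity on a simulated 36-month site
  coh <- dplyr::filter(fixture_cohort(), site_id == "site2")
  ids <- unique(coh$patient_id)[1:60]
  coh <- dplyr::filter(coh, patient_id %in% ids)
  u_a <- accumulate_utilization(coh, 12)
  u_b <- accumulate_utilization(coh, 12, window_start_months = 12)
  u_ab <- accumulate_utilization(coh, 24)
  key <- c("patient_id", "resource_class", "code")
  merged <- u_ab |>
    dplyr::left_join(u_a, by = key, suffix = c("", ".a")) |>
    dplyr::left_join(u_b, by = key, suffix = c("", ".b"))
  counted <- merged[merged$resource_class != "fixed", ]
  expect_equal(counted$quantity,
               counted$quantity.a + counted$quantity.b)
  fixed <- merged[merged$resource_class == "fixed", ]
  # month accrual is additive up to day-rounding at calendar boundaries
  expect_lt(max(abs(fixed$quantity - (fixed$quantity.a + fixed$quantity.b))),
            0.15)
})

test_that("same-day visits to one provider count once by default", {
  pat <- make_patient(events = list(
    list(day = 10, kind = "visit", provider = "nurse"),
    list(day = 10, kind = "visit", provider = "nurse"),
    list(day = 10, kind = "visit", provider = "counselor")))
  u <- accumulate_utilization(pat, 12)
  expect_equal(u$quantity[u$code == "nurse"], 1)
  expect_equal(u$quantity[u$code == "counselor"], 1)
  u_rows <- accumulate_utilization(pat, 12, visit_counting = "per_row")
  expect_equal(u_rows$quantity[u_rows$code == "nurse"], 2)
})

test_that("overall averages are count-weighted site means (pooled oracle)", {
  ref <- reference_site_statistics()
  w <- ref$retention$retained_12
  m <- ref$utilization_retained$any_nrti
  expect_equal(round(sum(w * m) / sum(w), 1), 11.4)

  coh <- fixture_cohort()
  out <- classify_outcomes(coh, 12)
  util <- accumulate_utilization(coh, 12)
  avg <- average_utilization(util, out, "retained")
  # brute-force pooled mean over retained patients
  ret <- out$patient_id[out$outcome == "retained"]
  pooled <- util |>
    dplyr::filter(patient_id %in% ret, code == "any_nrti" |
                    (resource_class == "arv_drug" & code %in% nrti_codes())) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(q = sum(quantity), .groups = "drop")
  expect_equal(avg$mean_quantity[avg$site_id == "all" &
                                   avg$code == "any_nrti"],
               mean(pooled$q))
  # weighted-mean identity between site rows and the overall row
  site_rows <- avg[avg$code == "any_nrti" & avg$site_id != "all", ]
  overall <- avg[avg$code == "any_nrti" & avg$site_id == "all", ]
  expect_equal(sum(site_rows$mean_quantity * site_rows$n) / sum(site_rows$n),
               overall$mean_quantity)
  expect_error(average_utilization(util, out[0, ], "retained"), "empty")
})

test_that("retained patients accrue full fixed months; dropouts fewer", {
  coh <- fixture_cohort()
  out <- classify_outcomes(coh, 12)
  util <- accumulate_utilization(coh, 12)
  fixed <- util[util$code == "months_in_care", ] |>
    dplyr::inner_join(out[c("patient_id", "outcome")], by = "patient_id")
  expect_true(all(fixed$quantity[fixed$outcome == "retained"] == 12))
  expect_true(mean(fixed$quantity[fixed$outcome != "retained"]) < 12)
  # retained-subset drug means dominate all-patient means
  avg_all <- average_utilization(util)
  avg_ret <- average_utilization(util, out, "retained")
  drugs <- dplyr::inner_join(
    avg_all[avg_all$site_id == "all" & avg_all$resource_class %in%
              c("arv_drug", "non_arv_drug"), ],
    avg_ret[avg_ret$site_id == "all", c("code", "mean_quantity")],
    by = "code")
  expect_true(all(drugs$mean_quantity.y >= drugs$mean_quantity.x))
})

test_that("guideline audit flags shortfalls and drug coverage", {
  profile <- tibble::tibble(
    resource_class = c("lab_test", "lab_test", "lab_test", "visit",
                       "arv_drug"),
    code = c("cd4", "blood_chemistry", "full_blood_count",
             "doctor_or_clinical_officer", "TDF/FTC"),
    mean_quantity = c(1.5, 1.3, 1.4, 6.5, 11.4))
  audit <- guideline_concordance(profile)
  expect_equal(audit$met, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(audit$shortfall[audit$item == "cd4_tests"], 0.5)
  expect_equal(audit$observed[audit$item == "drug_coverage"], 11.4 / 12)

  at_minimum <- tibble::tibble(
    resource_class = c(rep("lab_test", 3), "visit", "arv_drug"),
    code = c("cd4", "blood_chemistry", "full_blood_count",
             "doctor_or_clinical_officer", "TDF/FTC"),
    quantity = c(2, 2, 2, 5, 12))
  audit_min <- guideline_concordance(at_minimum)
  expect_true(all(audit_min$met))
  expect_true(all(audit_min$shortfall == 0))

  zero <- dplyr::mutate(at_minimum, quantity = 0)
  audit_zero <- guideline_concordance(zero)
  expect_equal(audit_zero$shortfall[1:4], c(2, 2, 2, 5))
})

test_that("a non-positive window is an argument error", {
  expect_error(accumulate_utilization(make_patient(), 0), "positive")
})
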