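# Shared fixtures. The calibrated six-site cohort is generated once per
# test run and reused; hand-built patients are constructed per test.

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(seed = 20110101) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(six_site_config(seed = seed))
  }
  .fixture_env[[key]]
}

# One patient as long-format event rows. events is a list of lists with
# fields: day (since initiation), kind, and optional provider, drug,
# supply, test, sched_day.
make_patient <- function(patient_id = "p1", site_id = "s1",
                         initiation_date = as.Date("2019-01-01"),
                         age = 35, sex = "female", cd4 = 145,
                         events = list()) {
  if (length(events) == 0) {
    return(tibble::tibble(
      patient_id = patient_id, site_id = site_id,
      initiation_date = initiation_date, age_at_initiation = age,
      sex = sex, baseline_cd4 = cd4, event_date = as.Date(NA),
      event_kind = NA_character_, provider_type = NA_character_,
      drug_code = NA_character_, months_supply = NA_real_,
      test_code = NA_character_, next_scheduled_date = as.Date(NA)))
  }
  rows <- lapply(events, function(e) {
    tibble::tibble(
      patient_id = patient_id, site_id = site_id,
      initiation_date = initiation_date, age_at_initiation = age,
      sex = sex, baseline_cd4 = cd4,
      event_date = initiation_date + e$day,
      event_kind = e$kind,
      provider_type = e$provider %||% NA_character_,
      drug_code = e$drug %||% NA_character_,
      months_supply = e$supply %||% NA_real_,
      test_code = e$test %||% NA_character_,
      next_scheduled_date = if (is.null(e$sched_day)) as.Date(NA) else
        initiation_date + e$sched_day)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# n monthly pickups (supply 1 month each) of a drug, scheduled monthly
monthly_pickups <- function(n, drug = "TDF/FTC", supply = 1) {
  lapply(seq_len(n) - 1, function(k) {
    list(day = round(30.44 * k), kind = "dispensation", drug = drug,
         supply = supply, sched_day = round(30.44 * (k + 1)))
  })
}

# minimal single-site profile for generator property tests
tiny_profile <- function(site_id = "s1", n = 50, ...) {
  site_profile(
    site_id = site_id, n_patients = n, n_active_patients = 1000,
    backbone_mix = c("TDF/FTC" = 0.6, "AZT/3TC" = 0.2, "ABC/3TC" = 0.1,
                     "d4T/3TC" = 0.1),
    third_mix = c(NVP = 0.5, EFV = 0.5, `LPV/r` = 0),
    ...)
}
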