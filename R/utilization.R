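# Per-patient accounting of costed resources within an analysis window,
# plus the guideline-concordance audit.
#
# Windows are half-open calendar-month intervals [start, end): an event
# dated exactly at the window end is excluded, so contiguous windows never
# double count and utilization over [0, 12) + [12, 24) equals [0, 24).

window_dates <- function(initiation_date, start_months, end_months) {
  list(start = initiation_date %m+%
         lubridate::period(as.integer(start_months), "months"),
       end = initiation_date %m+%
         lubridate::period(as.integer(end_months), "months"))
}

#' Accumulate per-patient resource utilization over an analysis window
#'
#' Sums, for each patient, the quantity of every costed resource with an
#' event date inside `[initiation + window_start_months, initiation +
#' window_start_months + window_months)` (calendar months, half-open):
#' drug patient-months (summed `months_supply` per drug code), laboratory
#' test counts, and clinic visit counts per provider type. Fixed-resource
#' months in care are `days / 30.44` from the window start to the earliest
#' of the window end, the death date, or — for patients who stopped
#' attending (classified lost to follow-up at the window end) — the last
#' attended contact; patients retained at the window end accrue the full
#' window.
#'
#' @param patients Validated patient event tibble.
#' @param window_months Window length in calendar months (> 0).
#' @param window_start_months Window start, months after initiation
#'   (default 0).
#' @param grace_days Grace period handed to the internal outcome
#'   classification that decides fixed-month accrual (default 90).
#' @param visit_counting `"per_provider_day"` (default): several visit rows
#'   for the same provider type on the same day count once;
#'   `"per_row"`: every visit row counts.
#' @return Long tibble with columns `patient_id`, `site_id`,
#'   `resource_class` (`arv_drug`, `non_arv_drug`, `lab_test`, `visit`,
#'   `fixed`), `code`, `quantity`, covering every patient crossed with
#'   every resource observed in the cohort (zeros filled in), plus a
#'   `fixed` / `months_in_care` row per patient.
#' @export
accumulate_utilization <- function(patients, window_months,
                                   window_start_months = 0, grace_days = 90,
                                   visit_counting = c("per_provider_day",
                                                      "per_row")) {
  visit_counting <- match.arg(visit_counting)
  if (!is.numeric(window_months) || length(window_months) != 1 ||
      window_months <= 0) {
    stop("window_months must be a single positive number", call. = FALSE)
  }
  end_months <- window_start_months + window_months

  header <- patients |>
    dplyr::distinct(.data$patient_id, .data$site_id, .data$initiation_date)
  wd <- window_dates(header$initiation_date, window_start_months, end_months)
  header$w_start <- wd$start
  header$w_end <- wd$end

  ev <- patients |>
    dplyr::filter(!is.na(.data$event_kind)) |>
    dplyr::left_join(header[c("patient_id", "w_start", "w_end")],
                     by = "patient_id") |>
    dplyr::filter(.data$event_date >= .data$w_start,
                  .data$event_date < .data$w_end)

  drug <- ev |>
    dplyr::filter(.data$event_kind == "dispensation") |>
    dplyr::group_by(.data$patient_id, code = .data$drug_code) |>
    dplyr::summarise(quantity = sum(.data$months_supply), .groups = "drop") |>
    dplyr::mutate(resource_class = dplyr::if_else(
      .data$code %in% arv_codes(), "arv_drug", "non_arv_drug"))

  lab <- ev |>
    dplyr::filter(.data$event_kind == "lab") |>
    dplyr::group_by(.data$patient_id, code = .data$test_code) |>
    dplyr::summarise(quantity = as.numeric(dplyr::n()), .groups = "drop") |>
    dplyr::mutate(resource_class = "lab_test")

  vis <- ev |> dplyr::filter(.data$event_kind == "visit")
  if (visit_counting == "per_provider_day") {
    vis <- vis |>
      dplyr::distinct(.data$patient_id, .data$provider_type, .data$event_date)
  }
  vis <- vis |>
    dplyr::group_by(.data$patient_id, code = .data$provider_type) |>
    dplyr::summarise(quantity = as.numeric(dplyr::n()), .groups = "drop") |>
    dplyr::mutate(resource_class = "visit")

  # fixed months: accrual end depends on status at the window end
  status <- classify_outcomes(patients, end_months, grace_days = grace_days)
  care <- patients |>
    dplyr::filter(!is.na(.data$event_kind)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      death_date = suppressWarnings(min(
        .data$event_date[.data$event_kind == "death"], na.rm = TRUE)),
      last_contact = suppressWarnings(max(
        .data$event_date[.data$event_kind %in% c("visit", "dispensation")],
        na.rm = TRUE)),
      .groups = "drop")
  fixed <- header |>
    dplyr::left_join(status[c("patient_id", "outcome")], by = "patient_id") |>
    dplyr::left_join(care, by = "patient_id")
  care_end <- dplyr::case_when(
    fixed$outcome == "retained" ~ as.numeric(fixed$w_end),
    fixed$outcome == "died" ~ pmin(as.numeric(fixed$death_date),
                                   as.numeric(fixed$w_end)),
    TRUE ~ pmin(ifelse(is.finite(as.numeric(fixed$last_contact)),
                       as.numeric(fixed$last_contact),
                       as.numeric(fixed$initiation_date)),
                as.numeric(fixed$w_end))
  )
  months_in_care <- pmax(0, (care_end - as.numeric(fixed$w_start)) /
                           DAYS_PER_MONTH)
  # retained patients accrue exactly the full window, not its day-count
  months_in_care[fixed$outcome == "retained"] <- window_months
  months_in_care <- pmin(months_in_care, window_months)
  fixed_rows <- tibble::tibble(patient_id = fixed$patient_id,
                               code = "months_in_care",
                               quantity = months_in_care,
                               resource_class = "fixed")

  long <- dplyr::bind_rows(drug, lab, vis, fixed_rows)
  grid <- dplyr::cross_join(
    tibble::tibble(patient_id = header$patient_id),
    dplyr::distinct(long, .data$resource_class, .data$code))
  out <- grid |>
    dplyr::left_join(long, by = c("patient_id", "resource_class", "code")) |>
    dplyr::mutate(quantity = dplyr::coalesce(.data$quantity, 0)) |>
    dplyr::left_join(header[c("patient_id", "site_id")], by = "patient_id")
  out[c("patient_id", "site_id", "resource_class", "code", "quantity")] |>
    dplyr::arrange(.data$site_id, .data$patient_id, .data$resource_class,
                   .data$code)
}

#' Average utilization per patient, by site and overall
#'
#' Site means are per-patient means within the site; the overall (`"all"`)
#' row is the patient-count-weighted mean of site means, which equals the
#' pooled per-patient mean. Roll-up rows `any_nrti` and `any_nnrti_pi` are
#' added for the ARV backbone and third-drug components.
#'
#' @param utilization Output of [accumulate_utilization()].
#' @param outcomes Outcome assignments (required for `subset = "retained"`).
#' @param subset `"all"` patients or the `"retained"` subset.
#' @return Tibble of per-resource means with columns `site_id`,
#'   `resource_class`, `code`, `n`, `mean_quantity`.
#' @export
average_utilization <- function(utilization, outcomes = NULL,
                                subset = c("all", "retained")) {
  subset <- match.arg(subset)
  if (subset == "retained") {
    if (is.null(outcomes)) {
      stop("outcomes are required for the retained subset", call. = FALSE)
    }
    keep <- outcomes$patient_id[outcomes$outcome == "retained"]
    utilization <- dplyr::filter(utilization, .data$patient_id %in% keep)
    if (nrow(utilization) == 0) {
      stop("retained subset is empty", call. = FALSE)
    }
  }
  if (nrow(utilization) == 0) stop("empty utilization table", call. = FALSE)

  rollup <- function(codes, new_code, class) {
    utilization |>
      dplyr::filter(.data$code %in% codes) |>
      dplyr::group_by(.data$patient_id, .data$site_id) |>
      dplyr::summarise(quantity = sum(.data$quantity), .groups = "drop") |>
      dplyr::mutate(resource_class = class, code = new_code)
  }
  full <- dplyr::bind_rows(utilization,
                           rollup(nrti_codes(), "any_nrti", "arv_drug"),
                           rollup(nnrti_pi_codes(), "any_nnrti_pi",
                                  "arv_drug"))
  by_site <- full |>
    dplyr::group_by(.data$site_id, .data$resource_class, .data$code) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$patient_id),
                     mean_quantity = mean(.data$quantity), .groups = "drop")
  overall <- full |>
    dplyr::group_by(.data$resource_class, .data$code) |>
    dplyr::summarise(site_id = "all",
                     n = dplyr::n_distinct(.data$patient_id),
                     mean_quantity = mean(.data$quantity), .groups = "drop")
  dplyr::bind_rows(by_site, overall)[
    c("site_id", "resource_class", "code", "n", "mean_quantity")]
}

#' Guideline schedule for the first year on ART
#'
#' The 2007 Zambian adult guidelines: at least two CD4, two blood
#' chemistry, and two full blood count (hemoglobin plus white cell count)
#' tests, at least five clinic visits with a doctor or clinical officer,
#' and an uninterrupted 12 months' drug supply during the first year.
#'
#' @param min_cd4_tests,min_chemistry_tests,min_fbc_tests,min_clinic_visits
#'   Annual minimum counts.
#' @param full_drug_months Months of ARV supply for uninterrupted treatment.
#' @export
guideline_schedule <- function(min_cd4_tests = 2, min_chemistry_tests = 2,
                               min_fbc_tests = 2, min_clinic_visits = 5,
                               full_drug_months = 12) {
  sched <- list(min_cd4_tests = min_cd4_tests,
                min_chemistry_tests = min_chemistry_tests,
                min_fbc_tests = min_fbc_tests,
                min_clinic_visits = min_clinic_visits,
                full_drug_months = full_drug_months)
  stopifnot(all(unlist(sched) >= 0))
  structure(sched, class = "guideline_schedule")
}

#' Audit utilization against guideline-recommended care
#'
#' Compares a first-year utilization profile — either one patient's rows
#' from [accumulate_utilization()] or a mean profile from
#' [average_utilization()] (using its `mean_quantity` as the quantity) —
#' against a [guideline_schedule()]. Clinic visits are audited against the
#' doctor / clinical-officer count; drug coverage is total NRTI-backbone
#' patient-months divided by `full_drug_months`.
#'
#' @param utilization Long utilization rows for a single profile (one
#'   patient, or one site's means).
#' @param schedule A [guideline_schedule()].
#' @return Tibble with one row per audited item: `item`, `required`,
#'   `observed`, `met`, `shortfall`; drug supply is reported as the row
#'   `drug_coverage` whose `observed` is the coverage proportion.
#' @export
guideline_concordance <- function(utilization, schedule = guideline_schedule()) {
  stopifnot(inherits(schedule, "guideline_schedule"))
  qty_col <- if ("mean_quantity" %in% names(utilization)) "mean_quantity"
  else "quantity"
  get <- function(codes) {
    sum(utilization[[qty_col]][utilization$code %in% codes])
  }
  item <- function(name, req, obs) {
    tibble::tibble(item = name, required = req, observed = obs,
                   met = obs >= req, shortfall = max(0, req - obs))
  }
  nrti_months <- get(nrti_codes())
  dplyr::bind_rows(
    item("cd4_tests", schedule$min_cd4_tests, get("cd4")),
    item("blood_chemistry_tests", schedule$min_chemistry_tests,
         get("blood_chemistry")),
    item("full_blood_count_tests", schedule$min_fbc_tests,
         get("full_blood_count")),
    item("clinic_visits", schedule$min_clinic_visits,
         get("doctor_or_clinical_officer")),
    item("drug_coverage", 1, nrti_months / schedule$full_drug_months)
  )
}
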