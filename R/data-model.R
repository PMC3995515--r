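# Domain vocabulary and flat-file schemas shared by every pipeline stage.
#
# Patient records are long-format: one row per clinical event, with the
# patient header columns (id, site, initiation date, baseline covariates)
# repeated on every row. A patient with no recorded events keeps a single
# header row with event_kind = NA.

#' Controlled vocabularies for patient event records
#'
#' @return Character vectors of the allowed codes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
event_kinds <- function() c("visit", "dispensation", "lab", "death")

#' @rdname vocabularies
#' @export
provider_types <- function() {
  c("doctor_or_clinical_officer", "nurse", "counselor", "pharmacist")
}

#' @rdname vocabularies
#' @export
test_codes <- function() c("cd4", "blood_chemistry", "full_blood_count")

#' @rdname vocabularies
#' @export
nrti_codes <- function() c("TDF/FTC", "AZT/3TC", "ABC/3TC", "d4T/3TC")

#' @rdname vocabularies
#' @export
nnrti_pi_codes <- function() c("NVP", "EFV", "LPV/r")

#' @rdname vocabularies
#' @export
arv_codes <- function() c(nrti_codes(), nnrti_pi_codes())

#' Average length of a month in days
#'
#' Durations recorded in days are converted to months as `days / 30.44`;
#' quantities natively recorded in months (drug `months_supply`) are not
#' converted.
#' @export
DAYS_PER_MONTH <- 30.44

patient_columns <- function() {
  c("patient_id", "site_id", "initiation_date", "age_at_initiation", "sex",
    "baseline_cd4", "event_date", "event_kind", "provider_type", "drug_code",
    "months_supply", "test_code", "next_scheduled_date")
}

patient_col_spec <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    site_id = readr::col_character(),
    initiation_date = readr::col_date(),
    age_at_initiation = readr::col_double(),
    sex = readr::col_character(),
    baseline_cd4 = readr::col_double(),
    event_date = readr::col_date(),
    event_kind = readr::col_character(),
    provider_type = readr::col_character(),
    drug_code = readr::col_character(),
    months_supply = readr::col_double(),
    test_code = readr::col_character(),
    next_scheduled_date = readr::col_date()
  )
}

#' Validate a long-format patient record table
#'
#' Checks the schema and the record invariants: known event vocabulary,
#' ages at least 15 years (adult cohort inclusion), no event dated before
#' the patient's ART initiation, at most one death event per patient and no
#' events after it, positive `months_supply` on dispensations, and
#' `next_scheduled_date` strictly after the event it was issued at.
#'
#' @param patients A data frame in the documented long event schema.
#' @return `patients` (as a tibble, sorted by site, patient, and event
#'   date), invisibly usable downstream.
#' @export
validate_patients <- function(patients) {
  missing <- setdiff(patient_columns(), names(patients))
  if (length(missing) > 0) {
    stop("patient record schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  patients <- tibble::as_tibble(patients)[patient_columns()]
  patients <- dplyr::arrange(patients, .data$site_id, .data$patient_id,
                             .data$event_date)

  fail <- function(ids, what) {
    stop("patient record validation error: ", what, " for patient(s) ",
         paste(utils::head(unique(ids), 5L), collapse = ", "), call. = FALSE)
  }

  ev <- dplyr::filter(patients, !is.na(.data$event_kind))
  bad <- ev$patient_id[!ev$event_kind %in% event_kinds()]
  if (length(bad) > 0) fail(bad, "unknown event_kind")
  bad <- patients$patient_id[!is.na(patients$age_at_initiation) &
                               patients$age_at_initiation < 15]
  if (length(bad) > 0) fail(bad, "age_at_initiation below 15 years")
  bad <- patients$patient_id[!patients$sex %in% c("female", "male")]
  if (length(bad) > 0) fail(bad, "sex must be 'female' or 'male'")
  bad <- ev$patient_id[is.na(ev$event_date)]
  if (length(bad) > 0) fail(bad, "event with missing date")
  bad <- ev$patient_id[ev$event_date < ev$initiation_date]
  if (length(bad) > 0) fail(bad, "event dated before ART initiation")

  disp <- dplyr::filter(ev, .data$event_kind == "dispensation")
  bad <- disp$patient_id[is.na(disp$months_supply) | disp$months_supply <= 0]
  if (length(bad) > 0) fail(bad, "dispensation without positive months_supply")
  vis <- dplyr::filter(ev, .data$event_kind == "visit")
  bad <- vis$patient_id[!vis$provider_type %in% provider_types()]
  if (length(bad) > 0) fail(bad, "visit with unknown provider_type")
  lab <- dplyr::filter(ev, .data$event_kind == "lab")
  bad <- lab$patient_id[!lab$test_code %in% test_codes()]
  if (length(bad) > 0) fail(bad, "lab event with unknown test_code")
  sched <- ev[!is.na(ev$next_scheduled_date), ]
  bad <- sched$patient_id[sched$next_scheduled_date <= sched$event_date]
  if (length(bad) > 0) fail(bad, "next_scheduled_date not after event date")

  death_check <- ev |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_death = sum(.data$event_kind == "death"),
      after_death = {
        d <- .data$event_date[.data$event_kind == "death"]
        length(d) > 0 && any(.data$event_date > min(d))
      },
      .groups = "drop"
    )
  bad <- death_check$patient_id[death_check$n_death > 1]
  if (length(bad) > 0) fail(bad, "more than one death event")
  bad <- death_check$patient_id[death_check$after_death]
  if (length(bad) > 0) fail(bad, "event dated after a death event")

  header <- patients |>
    dplyr::distinct(.data$patient_id, .data$site_id, .data$initiation_date,
                    .data$age_at_initiation, .data$sex, .data$baseline_cd4)
  bad <- header$patient_id[duplicated(header$patient_id)]
  if (length(bad) > 0) fail(bad, "inconsistent header columns across rows")

  patients
}

#' Read patient records from a long-format CSV or JSON-lines file
#'
#' @param path Path to a `patients.csv` (or `.jsonl`) file in the
#'   documented schema.
#' @param format `"csv"` or `"jsonl"`; guessed from the file extension by
#'   default.
#' @return A validated tibble of events sorted by `(site_id, patient_id,
#'   event_date)`.
#' @export
read_patient_records <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    df <- readr::read_csv(path, col_types = patient_col_spec(),
                          na = c("", "NA"), progress = FALSE)
    probs <- readr::problems(df)
    if (nrow(probs) > 0) {
      stop("malformed patient record rows (line numbers include header): ",
           paste(sprintf("line %d [%s]", probs$row + 1L, probs$expected),
                 collapse = "; "), call. = FALSE)
    }
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) stop("malformed JSON at line ", i,
                                               ": ", conditionMessage(e),
                                               call. = FALSE))
      tibble::as_tibble(rec[lengths(rec) > 0])
    })
    df <- dplyr::bind_rows(rows)
    for (col in setdiff(patient_columns(), names(df))) df[[col]] <- NA
    for (col in c("initiation_date", "event_date", "next_scheduled_date")) {
      df[[col]] <- as.Date(df[[col]])
    }
    df$age_at_initiation <- as.numeric(df$age_at_initiation)
    df$baseline_cd4 <- as.numeric(df$baseline_cd4)
    df$months_supply <- as.numeric(df$months_supply)
  }
  validate_patients(df)
}

#' Write patient records
#'
#' Inverse of [read_patient_records()]; output is bit-stable for identical
#' inputs.
#'
#' @param patients Validated patient event tibble.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`.
#' @export
write_patient_records <- function(patients, path,
                                  format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  patients <- validate_patients(patients)
  if (format == "csv") {
    readr::write_csv(patients, path, na = "", progress = FALSE)
  } else {
    con <- file(path, open = "wt")
    on.exit(close(con))
    for (i in seq_len(nrow(patients))) {
      row <- as.list(patients[i, ])
      row <- row[!vapply(row, function(x) is.na(x[[1]]), logical(1))]
      row <- lapply(row, function(x) if (inherits(x, "Date")) format(x) else x)
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Write a tabular summary with an optional JSON metadata sidecar
#'
#' Column order and numeric formatting are fixed, so identical inputs give
#' byte-identical files. When `meta` is supplied (e.g. seed, configuration
#' hash, package version) it is written next to the table as `<path>.meta.json`.
#'
#' @param rows A data frame (may have zero rows; the header is still written).
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @param meta Optional named list of provenance metadata.
#' @export
write_table <- function(rows, path, format = c("csv", "json"), meta = NULL) {
  format <- match.arg(format)
  if (!is.data.frame(rows)) stop("rows must be a data frame", call. = FALSE)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(rows), path, na = "", progress = FALSE)
  } else {
    writeLines(jsonlite::toJSON(rows, dataframe = "rows", na = "null",
                                digits = NA, pretty = TRUE), path)
  }
  if (!is.null(meta)) {
    meta$package_version <- as.character(utils::packageVersion("artcost"))
    writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               paste0(path, ".meta.json"))
  }
  invisible(path)
}

#' Construct a price table
#'
#' Holds per-patient-month drug prices (already in reference-year USD), the
#' consumer-price-index series used to restate older local-currency amounts,
#' and the reference-year exchange rate. Monetary inputs in local currency
#' are converted exactly once, at unit-cost construction.
#'
#' @param drug_prices Named numeric vector, USD per patient-month dispensed.
#' @param cpi_series Named numeric vector of CPI values; names are years.
#' @param exchange_rate Local currency units per USD in the reference year
#'   (default 4861 ZMK/$, the 2011 average).
#' @param reference_year Year whose price level and exchange rate define the
#'   reporting currency (default 2011).
#' @return An object of class `price_table`.
#' @export
price_table <- function(drug_prices, cpi_series,
                        exchange_rate = 4861, reference_year = 2011) {
  stopifnot(is.numeric(drug_prices), !is.null(names(drug_prices)),
            is.numeric(cpi_series), !is.null(names(cpi_series)))
  if (any(drug_prices < 0)) stop("drug prices must be >= 0", call. = FALSE)
  if (any(cpi_series <= 0)) stop("CPI values must be > 0", call. = FALSE)
  if (exchange_rate <= 0) stop("exchange_rate must be > 0", call. = FALSE)
  if (!as.character(reference_year) %in% names(cpi_series)) {
    stop("cpi_series must contain the reference year", call. = FALSE)
  }
  structure(list(drug_prices = drug_prices, cpi_series = cpi_series,
                 exchange_rate = exchange_rate,
                 reference_year = as.integer(reference_year)),
            class = "price_table")
}

#' @rdname price_table
#' @param path Path to a YAML file mirroring the `price_table` fields.
#' @export
read_price_table <- function(path) {
  y <- yaml::read_yaml(path)
  price_table(drug_prices = unlist(y$drug_prices),
              cpi_series = unlist(y$cpi_series),
              exchange_rate = y$exchange_rate %||% 4861,
              reference_year = y$reference_year %||% 2011)
}

#' @rdname price_table
#' @param x A `price_table`.
#' @export
write_price_table <- function(x, path) {
  stopifnot(inherits(x, "price_table"))
  yaml::write_yaml(list(drug_prices = as.list(x$drug_prices),
                        cpi_series = as.list(x$cpi_series),
                        exchange_rate = x$exchange_rate,
                        reference_year = x$reference_year), path)
  invisible(path)
}

#' Construct site-level cost inputs
#'
#' Everything needed to derive a site's unit costs: capital items for
#' annualization, support staff (non-clinical) with their ART time fraction,
#' patient and visit volumes for patient-equivalent allocation, per-provider
#' staffing costs and consultation volumes, and laboratory inputs (either
#' on-site reagent/overhead/volume inputs or an external per-test price).
#' All monetary amounts carry the site's `currency` ("ZMK" or "USD") and a
#' `year` tag used for CPI restatement; mixing untagged currencies is
#' rejected at construction.
#'
#' @param site_id Site label.
#' @param capital_items Data frame with columns `item`, `replacement_cost`,
#'   `life_years`, `year`.
#' @param support_staff Data frame with columns `role`,
#'   `annual_salary_allowances`, `art_fraction`, `year`.
#' @param n_art_patients,n_nonart_patients Active patients per year.
#' @param visits_per_year_art,visits_per_year_nonart Average visits per
#'   patient per year, used to weight non-ART patient-equivalents.
#' @param provider_costs Data frame with columns `provider_type`,
#'   `annual_cost`, `art_fraction`, `consultations_per_year`, `year`.
#' @param lab_inputs Data frame with columns `test_code`,
#'   `reagent_consumable_cost_per_test`, `annual_equipment_labor_space`,
#'   `tests_per_year`, `external_price_per_test` (USD), `year`. For each
#'   test either the three on-site fields or the external price must be
#'   given, not both.
#' @param currency "ZMK" (converted via the price table) or "USD".
#' @return An object of class `site_cost_inputs`.
#' @export
site_cost_inputs <- function(site_id, capital_items, support_staff,
                             n_art_patients, n_nonart_patients,
                             visits_per_year_art, visits_per_year_nonart,
                             provider_costs, lab_inputs,
                             currency = "ZMK") {
  if (!currency %in% c("ZMK", "USD")) {
    stop("currency must be 'ZMK' or 'USD'; untagged amounts are not allowed",
         call. = FALSE)
  }
  capital_items <- tibble::as_tibble(capital_items)
  support_staff <- tibble::as_tibble(support_staff)
  provider_costs <- tibble::as_tibble(provider_costs)
  lab_inputs <- tibble::as_tibble(lab_inputs)
  stopifnot(all(capital_items$replacement_cost >= 0),
            all(capital_items$life_years > 0),
            all(support_staff$annual_salary_allowances >= 0),
            all(support_staff$art_fraction >= 0 & support_staff$art_fraction <= 1),
            n_art_patients > 0, n_nonart_patients >= 0,
            visits_per_year_art > 0, visits_per_year_nonart >= 0,
            all(provider_costs$annual_cost >= 0),
            all(provider_costs$art_fraction >= 0 & provider_costs$art_fraction <= 1),
            all(provider_costs$consultations_per_year > 0))
  both <- !is.na(lab_inputs$external_price_per_test) &
    !is.na(lab_inputs$reagent_consumable_cost_per_test)
  if (any(both)) {
    stop("ambiguous laboratory inputs for test(s) ",
         paste(lab_inputs$test_code[both], collapse = ", "),
         ": give on-site inputs or an external price, not both",
         call. = FALSE)
  }
  onsite <- is.na(lab_inputs$external_price_per_test)
  if (any(onsite & (is.na(lab_inputs$tests_per_year) |
                      lab_inputs$tests_per_year <= 0))) {
    stop("on-site laboratory inputs need tests_per_year > 0", call. = FALSE)
  }
  structure(list(site_id = site_id, capital_items = capital_items,
                 support_staff = support_staff,
                 n_art_patients = n_art_patients,
                 n_nonart_patients = n_nonart_patients,
                 visits_per_year_art = visits_per_year_art,
                 visits_per_year_nonart = visits_per_year_nonart,
                 provider_costs = provider_costs, lab_inputs = lab_inputs,
                 currency = currency),
            class = "site_cost_inputs")
}

#' @rdname site_cost_inputs
#' @param path Path to a YAML file mirroring the fields above.
#' @export
read_site_cost_inputs <- function(path) {
  y <- yaml::read_yaml(path)
  df <- function(x) dplyr::bind_rows(lapply(x, tibble::as_tibble))
  lab <- df(y$lab_inputs)
  for (col in c("reagent_consumable_cost_per_test",
                "annual_equipment_labor_space", "tests_per_year",
                "external_price_per_test")) {
    if (is.null(lab[[col]])) lab[[col]] <- NA_real_
  }
  site_cost_inputs(site_id = y$site_id,
                   capital_items = df(y$capital_items),
                   support_staff = df(y$support_staff),
                   n_art_patients = y$n_art_patients,
                   n_nonart_patients = y$n_nonart_patients,
                   visits_per_year_art = y$visits_per_year_art,
                   visits_per_year_nonart = y$visits_per_year_nonart,
                   provider_costs = df(y$provider_costs),
                   lab_inputs = lab,
                   currency = y$currency %||% "ZMK")
}

#' @rdname site_cost_inputs
#' @param x A `site_cost_inputs` object.
#' @export
write_site_cost_inputs <- function(x, path) {
  stopifnot(inherits(x, "site_cost_inputs"))
  rows <- function(d) lapply(seq_len(nrow(d)), function(i) {
    r <- as.list(d[i, ])
    r[!vapply(r, function(v) is.na(v[[1]]), logical(1))]
  })
  yaml::write_yaml(list(site_id = x$site_id,
                        currency = x$currency,
                        capital_items = rows(x$capital_items),
                        support_staff = rows(x$support_staff),
                        n_art_patients = x$n_art_patients,
                        n_nonart_patients = x$n_nonart_patients,
                        visits_per_year_art = x$visits_per_year_art,
                        visits_per_year_nonart = x$visits_per_year_nonart,
                        provider_costs = rows(x$provider_costs),
                        lab_inputs = rows(x$lab_inputs)), path)
  invisible(path)
}

#' Read or write a unit-cost table
#'
#' Unit-cost tables are tidy tibbles with columns `site_id`,
#' `resource_class` (`arv_drug`, `non_arv_drug`, `lab_test`, `visit`,
#' `fixed`), `code`, and `unit_cost_usd` (reference-year USD per natural
#' unit: patient-month, test, visit, or month in care).
#'
#' @param path File path (CSV).
#' @export
read_unit_cost_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    site_id = readr::col_character(), resource_class = readr::col_character(),
    code = readr::col_character(), unit_cost_usd = readr::col_double()),
    progress = FALSE)
  if (any(df$unit_cost_usd < 0)) stop("unit costs must be >= 0", call. = FALSE)
  df
}

#' @rdname read_unit_cost_table
#' @param unit_costs Unit-cost tibble.
#' @export
write_unit_cost_table <- function(unit_costs, path) {
  write_table(unit_costs[c("site_id", "resource_class", "code",
                           "unit_cost_usd")], path)
}
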