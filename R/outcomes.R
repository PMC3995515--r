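# Outcome classification at fixed endpoints after ART initiation.
#
# The rule: a patient is "died" if a death confirmation is dated before the
# endpoint; otherwise "ltfu" (lost to follow-up) if, at the endpoint, they
# are at least `grace_days` late for their last scheduled consultation or
# medication pickup; otherwise "retained". Death takes precedence over
# lateness because LTFU is defined as lateness *without* a death note.

#' Classify patient outcomes at an endpoint
#'
#' Assigns each patient exactly one of `retained`, `died`, or `ltfu` at
#' `endpoint_months` calendar months after ART initiation.
#'
#' The last scheduled contact is taken as the latest of (a) every explicit
#' `next_scheduled_date` on a visit or dispensation before the endpoint,
#' (b) for dispensations without one, the pickup date plus
#' `months_supply * 30.44` days (the supply-implied return date), and
#' (c) the date of the last attended contact itself (which covers a patient
#' who attended their final scheduled visit and had nothing further
#' booked). Lateness is measured from that basis date to the endpoint date.
#' A patient with no contacts at all is classified `ltfu` with
#' `basis_date = initiation_date` (documented convention, not an error).
#'
#' "Three months late" defaults to 90 days; both the grace period and the
#' lateness reference are exposed because neither is standardized across
#' programs.
#'
#' @param patients Validated patient event tibble
#'   (see [read_patient_records()]).
#' @param endpoint_months Endpoint in calendar months after initiation
#'   (typically 12, 24, or 36).
#' @param grace_days Lateness threshold in days (default 90).
#' @param lateness_to Reference date lateness is measured to: the
#'   `"endpoint"` date (default) or a fixed `"censor_date"` (the data
#'   collection date), supplied via `censor_date`.
#' @param censor_date Data-collection date, required when
#'   `lateness_to = "censor_date"`.
#' @return Tibble with one row per patient: `patient_id`, `site_id`,
#'   `endpoint_months`, `outcome`, `basis_date` (death-note date or the
#'   scheduled-contact basis).
#' @export
classify_outcomes <- function(patients, endpoint_months, grace_days = 90,
                              lateness_to = c("endpoint", "censor_date"),
                              censor_date = NULL) {
  lateness_to <- match.arg(lateness_to)
  if (!is.numeric(endpoint_months) || length(endpoint_months) != 1 ||
      endpoint_months <= 0) {
    stop("endpoint_months must be a single positive number", call. = FALSE)
  }
  if (grace_days < 0) stop("grace_days must be >= 0", call. = FALSE)
  if (lateness_to == "censor_date" && is.null(censor_date)) {
    stop("censor_date is required when lateness_to = 'censor_date'",
         call. = FALSE)
  }

  per_patient <- patients |>
    dplyr::group_by(.data$patient_id, .data$site_id, .data$initiation_date) |>
    dplyr::summarise(
      death_date = suppressWarnings(
        min(.data$event_date[.data$event_kind %in% "death"], na.rm = TRUE)),
      .contacts = {
        d <- .data$event_date
        k <- .data$event_kind
        s <- .data$months_supply
        nx <- .data$next_scheduled_date
        list(tibble::tibble(date = d, kind = k, supply = s, sched = nx))
      },
      .groups = "drop"
    )

  endpoint_date <- per_patient$initiation_date %m+%
    lubridate::period(as.integer(endpoint_months), "months")
  ref_date <- if (lateness_to == "endpoint") endpoint_date else
    rep(as.Date(censor_date), nrow(per_patient))

  basis <- as.Date(rep(NA, nrow(per_patient)))
  outcome <- character(nrow(per_patient))
  for (i in seq_len(nrow(per_patient))) {
    dd <- per_patient$death_date[[i]]
    if (is.finite(dd) && dd < endpoint_date[[i]]) {
      outcome[[i]] <- "died"
      basis[[i]] <- as.Date(dd, origin = "1970-01-01")
      next
    }
    ct <- per_patient$.contacts[[i]]
    ct <- ct[!is.na(ct$kind) & ct$kind %in% c("visit", "dispensation") &
               ct$date < endpoint_date[[i]], ]
    if (nrow(ct) == 0) {
      outcome[[i]] <- "ltfu"
      basis[[i]] <- per_patient$initiation_date[[i]]
      next
    }
    implied <- ct$sched
    fallback <- is.na(implied) & ct$kind == "dispensation"
    implied[fallback] <- ct$date[fallback] +
      round(ct$supply[fallback] * DAYS_PER_MONTH)
    s <- max(c(implied, ct$date), na.rm = TRUE)
    basis[[i]] <- s
    late <- as.numeric(ref_date[[i]] - s)
    outcome[[i]] <- if (late >= grace_days) "ltfu" else "retained"
  }

  tibble::tibble(patient_id = per_patient$patient_id,
                 site_id = per_patient$site_id,
                 endpoint_months = as.integer(endpoint_months),
                 outcome = outcome,
                 basis_date = basis)
}

#' Tabulate retention by site and overall
#'
#' @param assignments Output of [classify_outcomes()] for one endpoint (or
#'   several; endpoints are tabulated separately).
#' @return Tibble with one row per site (plus an `"all"` row) per endpoint:
#'   counts `n`, `retained`, `died`, `ltfu` and the corresponding
#'   percentages. Site counts sum to site n and percentages to 100 within
#'   rounding.
#' @export
retention_table <- function(assignments) {
  dup <- assignments |>
    dplyr::count(.data$patient_id, .data$endpoint_months) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("duplicate patient-endpoint assignment(s) for patient(s) ",
         paste(head(dup$patient_id, 5), collapse = ", "), call. = FALSE)
  }
  tab <- function(df, label) {
    df |>
      dplyr::group_by(.data$endpoint_months) |>
      dplyr::summarise(
        site_id = label,
        n = dplyr::n(),
        retained = sum(.data$outcome == "retained"),
        died = sum(.data$outcome == "died"),
        ltfu = sum(.data$outcome == "ltfu"),
        .groups = "drop"
      )
  }
  by_site <- assignments |>
    dplyr::group_split(.data$site_id) |>
    purrr::map(~ tab(.x, .x$site_id[[1]])) |>
    dplyr::bind_rows()
  out <- dplyr::bind_rows(by_site, tab(assignments, "all")) |>
    dplyr::mutate(pct_retained = 100 * .data$retained / .data$n,
                  pct_died = 100 * .data$died / .data$n,
                  pct_ltfu = 100 * .data$ltfu / .data$n) |>
    dplyr::arrange(.data$endpoint_months, .data$site_id != "all", .data$site_id)
  out[c("endpoint_months", "site_id", "n", "retained", "died", "ltfu",
        "pct_retained", "pct_died", "pct_ltfu")]
}

#' Conditional probability of remaining in care
#'
#' P(retained at `to_months` | retained at `from_months`), computed as a
#' direct count ratio over patients assigned at both endpoints.
#'
#' @param assignments Outcome assignments covering both endpoints.
#' @param from_months,to_months Earlier and later endpoints in months.
#' @return A single probability.
#' @export
conditional_retention <- function(assignments, from_months, to_months) {
  if (to_months <= from_months) {
    stop("to_months must be greater than from_months", call. = FALSE)
  }
  wide <- assignments |>
    dplyr::filter(.data$endpoint_months %in% c(from_months, to_months)) |>
    dplyr::select("patient_id", "endpoint_months", "outcome") |>
    tidyr::pivot_wider(names_from = "endpoint_months",
                       values_from = "outcome", names_prefix = "m")
  f <- wide[[paste0("m", from_months)]]
  t <- wide[[paste0("m", to_months)]]
  keep <- !is.na(f) & !is.na(t)
  at_from <- sum(f[keep] == "retained")
  if (at_from == 0) {
    stop("no patients retained at ", from_months,
         " months: conditional retention undefined", call. = FALSE)
  }
  sum(f[keep] == "retained" & t[keep] == "retained") / at_from
}
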