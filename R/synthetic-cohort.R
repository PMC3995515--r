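# Synthetic six-site ART cohort generator.
#
# Patients are simulated on a monthly contact grid (one scheduled
# medication pickup every 30.44 days). Each month in care a patient
# attends the pickup with a site-specific probability (the initiation
# contact and the final scheduled contact of each follow-up year are
# always attended, so a patient still in care always has a contact within
# 90 days of the endpoint), is dispensed their assigned regimen with a
# site-specific months'-supply distribution, sees providers and receives
# laboratory tests at site-specific rates, and is exposed to monthly death
# and loss-to-follow-up hazards. LTFU is an absorbing "stop attending"
# state restricted to the first nine months of each follow-up year, so a
# simulated dropout is always at least 90 days late at the following
# endpoint and the outcome classifier recovers the generator's truth
# exactly.

#' Construct a site profile for the cohort generator
#'
#' @param site_id Site label.
#' @param n_patients Cohort sample size at the site.
#' @param n_active_patients Active ART patients enrolled at the site per
#'   year (drives cost-input volumes).
#' @param followup_months Follow-up horizon (12 or 36).
#' @param pct_female Proportion female.
#' @param age_median,age_iqr Median and `c(q1, q3)` of age at initiation
#'   (years, log-normal, truncated at 15).
#' @param cd4_median,cd4_iqr Median and IQR of baseline CD4 (cells/uL,
#'   log-normal).
#' @param backbone_mix Named probabilities over the NRTI backbones
#'   ([nrti_codes()]); must sum to 1.
#' @param third_mix Named probabilities over the NNRTI/PI third drugs
#'   ([nnrti_pi_codes()]); must sum to 1.
#' @param pickup_attendance Probability of attending a non-forced monthly
#'   pickup.
#' @param extra_pharmacist_rate Poisson rate of additional pharmacist
#'   contacts per month in care.
#' @param p_dispense Probability a non-initiation attended pickup includes
#'   a dispensation.
#' @param supply_mean Mean months' supply per dispensation (supply is
#'   `1 + Poisson(supply_mean - 1)`).
#' @param p_third_drug,p_ctx Probability the third ARV drug /
#'   co-trimoxazole is dispensed alongside the backbone.
#' @param visit_rates Named monthly Poisson rates for
#'   `doctor_or_clinical_officer` (excluding the forced initiation visit),
#'   `nurse`, and `counselor` visits.
#' @param lab_rates Named expected tests per year for [test_codes()].
#' @param death_hazard,ltfu_hazard Monthly probabilities, one value per
#'   follow-up year. LTFU applies only in months 1-9 of each year.
#' @param rate_decay Multiplier on visit and laboratory rates per
#'   follow-up year (first year is 1).
#' @param death_recorded_probability Probability a simulated death is
#'   confirmed in the chart (1 by default; below 1 the death looks like
#'   silent attrition, emulating under-ascertainment).
#' @return An object of class `site_profile`.
#' @export
site_profile <- function(site_id, n_patients, n_active_patients = 2000,
                         followup_months = 12, pct_female = 0.6,
                         age_median = 35, age_iqr = c(30, 42),
                         cd4_median = 145, cd4_iqr = c(86, 212),
                         backbone_mix, third_mix,
                         pickup_attendance = 0.8,
                         extra_pharmacist_rate = 0,
                         p_dispense = 1, supply_mean = 1.2,
                         p_third_drug = 1, p_ctx = 0.5,
                         visit_rates = c(doctor_or_clinical_officer = 0.45,
                                         nurse = 0.6, counselor = 0.7),
                         lab_rates = c(cd4 = 1.5, blood_chemistry = 1.3,
                                       full_blood_count = 1.4),
                         death_hazard = 0.01, ltfu_hazard = 0.015,
                         rate_decay = 1,
                         death_recorded_probability = 1) {
  n_years <- ceiling(followup_months / 12)
  recycle <- function(x) rep_len(x, n_years)
  p <- structure(list(
    site_id = site_id, n_patients = n_patients,
    n_active_patients = n_active_patients,
    followup_months = followup_months, pct_female = pct_female,
    age_median = age_median, age_iqr = age_iqr,
    cd4_median = cd4_median, cd4_iqr = cd4_iqr,
    backbone_mix = backbone_mix, third_mix = third_mix,
    pickup_attendance = pickup_attendance,
    extra_pharmacist_rate = extra_pharmacist_rate,
    p_dispense = p_dispense, supply_mean = supply_mean,
    p_third_drug = p_third_drug, p_ctx = p_ctx,
    visit_rates = visit_rates, lab_rates = lab_rates,
    death_hazard = recycle(death_hazard),
    ltfu_hazard = recycle(ltfu_hazard),
    rate_decay = recycle(rate_decay),
    death_recorded_probability = death_recorded_probability),
    class = "site_profile")
  validate_site_profile(p)
}

validate_site_profile <- function(p) {
  ok <- function(cond, what) {
    if (!cond) stop("invalid site profile '", p$site_id, "': ", what,
                    call. = FALSE)
  }
  ok(p$n_patients > 0, "n_patients must be > 0")
  ok(p$followup_months > 0, "followup_months must be > 0")
  ok(setequal(names(p$backbone_mix), nrti_codes()) &&
       abs(sum(p$backbone_mix) - 1) < 1e-8 && all(p$backbone_mix >= 0),
     "backbone_mix must be probabilities over the NRTI codes summing to 1")
  ok(setequal(names(p$third_mix), nnrti_pi_codes()) &&
       abs(sum(p$third_mix) - 1) < 1e-8 && all(p$third_mix >= 0),
     "third_mix must be probabilities over the NNRTI/PI codes summing to 1")
  probs <- c(p$pct_female, p$pickup_attendance, p$p_dispense, p$p_third_drug,
             p$p_ctx, p$death_recorded_probability)
  ok(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  ok(all(p$death_hazard >= 0 & p$death_hazard < 1) &&
       all(p$ltfu_hazard >= 0 & p$ltfu_hazard < 1),
     "monthly hazards must lie in [0, 1)")
  ok(p$supply_mean >= 1, "supply_mean must be >= 1")
  ok(all(p$visit_rates >= 0) && all(p$lab_rates >= 0) &&
       p$extra_pharmacist_rate >= 0, "rates must be >= 0")
  ok(setequal(names(p$lab_rates), test_codes()), "lab_rates must name all
     test codes")
  p
}

#' Construct a generator configuration
#'
#' @param profiles List of [site_profile()]s with unique site ids.
#' @param seed Integer master seed; per-site and per-patient substreams are
#'   derived from it by stable hashing, so generation is independent of
#'   profile order.
#' @param calendar_start First possible ART initiation date.
#' @param enrollment_days Length of the enrollment window in days
#'   (initiation dates are uniform over it; the default spans July 2007 to
#'   October 2008).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(profiles, seed = 104729,
                             calendar_start = as.Date("2007-07-01"),
                             enrollment_days = 480) {
  if (inherits(profiles, "site_profile")) profiles <- list(profiles)
  lapply(profiles, validate_site_profile)
  ids <- vapply(profiles, function(p) p$site_id, character(1))
  if (anyDuplicated(ids)) stop("site_ids must be unique", call. = FALSE)
  structure(list(profiles = profiles, seed = as.integer(seed),
                 calendar_start = as.Date(calendar_start),
                 enrollment_days = enrollment_days),
            class = "generator_config")
}

# Stable string hash onto [1, 2^31 - 2]: per-site / per-patient RNG
# substreams depend only on identity, not on generation order.
mix_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h) + 1L
}

# Randomized-systematic uniforms: one draw per unit stratified over [0, 1),
# randomly permuted. Inverse-CDF sampling with these makes realized
# category counts track expectations within one unit.
stratified_uniforms <- function(n) {
  (sample.int(n) - runif(n)) / n
}

draw_categorical <- function(u, probs) {
  names(probs)[findInterval(u, cumsum(probs) / sum(probs),
                            left.open = TRUE) + 1L]
}

qlnorm_from_quartiles <- function(u, median, q1, q3, lower = -Inf) {
  meanlog <- log(median)
  sdlog <- (log(q3) - log(q1)) / (2 * qnorm(0.75))
  p0 <- if (is.finite(lower)) stats::plnorm(lower, meanlog, sdlog) else 0
  qlnorm(p0 + u * (1 - p0), meanlog, sdlog)
}

#' Distribution of simulated terminal states
#'
#' Enumerates the exact probability of every terminal trajectory under the
#' monthly competing-hazard process: death in month `m` (hazard applied
#' first each month), loss to follow-up entered in month `m` (only in
#' months 1-9 of each follow-up year, so the dropout is classifiable at
#' the next endpoint), or retained through follow-up.
#'
#' @param death_hazard,ltfu_hazard Monthly probabilities per follow-up
#'   year.
#' @param followup_months Horizon.
#' @return Tibble with columns `state` (`died`, `ltfu`, `retained`),
#'   `month` (NA for retained), `prob`; probabilities sum to 1.
#' @export
terminal_distribution <- function(death_hazard, ltfu_hazard,
                                  followup_months) {
  n_years <- ceiling(followup_months / 12)
  death_hazard <- rep_len(death_hazard, n_years)
  ltfu_hazard <- rep_len(ltfu_hazard, n_years)
  s <- 1
  rows <- vector("list", 2 * followup_months + 1)
  j <- 0
  for (m in seq_len(followup_months)) {
    y <- (m - 1) %/% 12 + 1
    dh <- death_hazard[[y]]
    lh <- if ((m - 1) %% 12 + 1 <= 9) ltfu_hazard[[y]] else 0
    j <- j + 1
    rows[[j]] <- tibble::tibble(state = "died", month = m, prob = s * dh)
    if (lh > 0) {
      j <- j + 1
      rows[[j]] <- tibble::tibble(state = "ltfu", month = m,
                                  prob = s * (1 - dh) * lh)
    }
    s <- s * (1 - dh) * (1 - lh)
  }
  j <- j + 1
  rows[[j]] <- tibble::tibble(state = "retained", month = NA_integer_,
                              prob = s)
  out <- dplyr::bind_rows(rows[seq_len(j)])
  # keep each state's months contiguous in the CDF so stratified
  # inverse-CDF sampling reproduces state totals within one patient
  out[order(match(out$state, c("died", "ltfu", "retained")), out$month), ]
}

#' Solve monthly hazards that reach target one-year attrition fractions
#'
#' Finds the constant monthly death and LTFU hazards whose 12-month
#' terminal distribution has the requested death and (classifiable) LTFU
#' probabilities.
#'
#' @param target_died,target_ltfu Target 12-month fractions.
#' @return List with `death_hazard` and `ltfu_hazard`.
#' @export
solve_monthly_hazards <- function(target_died, target_ltfu) {
  stopifnot(target_died >= 0, target_ltfu >= 0,
            target_died + target_ltfu < 1)
  dh <- max(target_died / 12, 0)
  lh <- max(target_ltfu / 9, 0)
  for (iter in 1:200) {
    td <- terminal_distribution(dh, lh, 12)
    d_now <- sum(td$prob[td$state == "died"])
    l_now <- sum(td$prob[td$state == "ltfu"])
    if (abs(d_now - target_died) < 1e-12 &&
        abs(l_now - target_ltfu) < 1e-12) break
    if (target_died > 0) dh <- min(0.99, dh * target_died / max(d_now, 1e-15))
    if (target_ltfu > 0) lh <- min(0.99, lh * target_ltfu / max(l_now, 1e-15))
  }
  list(death_hazard = dh, ltfu_hazard = lh)
}

# One patient's event stream, in days since initiation. Assumes the RNG
# state has been set by the caller.
simulate_patient_events <- function(profile, terminal_state, terminal_month) {
  followup <- profile$followup_months
  grid <- function(k) DAYS_PER_MONTH * k

  death_day <- Inf
  if (terminal_state == "died") {
    death_day <- grid(terminal_month - 1) + runif(1, 0, 29)
    k_max <- min(floor(death_day / DAYS_PER_MONTH), followup - 1)
  } else if (terminal_state == "ltfu") {
    k_max <- terminal_month - 1
  } else {
    k_max <- followup - 1
  }
  k <- 0:k_max
  nk <- length(k)
  decay <- profile$rate_decay[pmin(k %/% 12 + 1, length(profile$rate_decay))]

  forced <- k == 0 | k %% 12 == 11
  attended <- forced | runif(nk) < profile$pickup_attendance
  dispensed <- attended & (k == 0 | runif(nk) < profile$p_dispense)
  supply <- 1 + rpois(nk, profile$supply_mean - 1)
  with_third <- dispensed & runif(nk) < profile$p_third_drug
  with_ctx <- dispensed & runif(nk) < profile$p_ctx
  contact_day <- grid(k) + runif(nk, 0, 3)
  next_sched <- grid(k + 1)

  day <- c(); kind <- c(); provider <- c(); drug <- c(); msupply <- c()
  test <- c(); sched <- c()
  add <- function(day_, kind_, provider_ = NA, drug_ = NA, msupply_ = NA,
                  test_ = NA, sched_ = NA) {
    n <- length(day_)
    day <<- c(day, day_); kind <<- c(kind, rep_len(kind_, n))
    provider <<- c(provider, rep_len(provider_, n))
    drug <<- c(drug, rep_len(drug_, n))
    msupply <<- c(msupply, rep_len(msupply_, n))
    test <<- c(test, rep_len(test_, n))
    sched <<- c(sched, rep_len(sched_, n))
  }

  # pickups: pharmacist visit, plus dispensation rows for the regimen
  att <- which(attended)
  add(contact_day[att], "visit", provider_ = "pharmacist",
      sched_ = next_sched[att])
  for (i in which(dispensed)) {
    codes <- profile$assigned_backbone
    if (with_third[i]) codes <- c(codes, profile$assigned_third)
    if (with_ctx[i]) codes <- c(codes, "CTX")
    add(rep(contact_day[i], length(codes)), "dispensation", drug_ = codes,
        msupply_ = supply[i], sched_ = next_sched[i])
  }
  # extra pharmacist contacts
  n_extra <- rpois(nk, profile$extra_pharmacist_rate)
  for (i in which(n_extra > 0)) {
    add(grid(k[i]) + sample(0:27, n_extra[i]), "visit",
        provider_ = "pharmacist")
  }
  # provider visits on distinct days within each month
  for (pv in c("doctor_or_clinical_officer", "nurse", "counselor")) {
    rate <- profile$visit_rates[[pv]]
    counts <- rpois(nk, rate * decay)
    if (pv == "doctor_or_clinical_officer") counts[1] <- counts[1] + 1L
    for (i in which(counts > 0)) {
      add(grid(k[i]) + sample(0:27, min(counts[i], 28)), "visit",
          provider_ = pv)
    }
  }
  # laboratory tests
  for (tc in test_codes()) {
    counts <- rpois(nk, profile$lab_rates[[tc]] / 12 * decay)
    for (i in which(counts > 0)) {
      add(grid(k[i]) + sample(0:27, min(counts[i], 28)), "lab", test_ = tc)
    }
  }

  keep <- day < death_day
  out <- tibble::tibble(day = day[keep], kind = kind[keep],
                        provider = provider[keep], drug = drug[keep],
                        msupply = msupply[keep], test = test[keep],
                        sched = sched[keep])
  if (terminal_state == "died" &&
      runif(1) < profile$death_recorded_probability) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      day = death_day, kind = "death", provider = NA, drug = NA,
      msupply = NA, test = NA, sched = NA))
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Simulates every site in the configuration and returns the long-format
#' patient event table ([read_patient_records()] schema). The generator's
#' own terminal states are attached as the `"truth"` attribute
#' ([cohort_truth()]); because simulated dropouts are always classifiable,
#' [classify_outcomes()] applied to the cohort reproduces them exactly
#' (when deaths are fully chart-recorded).
#'
#' @param config A [generator_config()].
#' @return Validated patient event tibble with a `truth` attribute.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  site_tables <- lapply(config$profiles, function(profile) {
    n <- profile$n_patients
    site_seed <- mix_seed(config$seed, profile$site_id)
    draws <- withr::with_seed(site_seed, {
      td <- terminal_distribution(profile$death_hazard,
                                  profile$ltfu_hazard,
                                  profile$followup_months)
      term_idx <- findInterval(stratified_uniforms(n),
                               cumsum(td$prob) / sum(td$prob),
                               left.open = TRUE) + 1L
      list(
        init_day = floor(runif(n, 0, config$enrollment_days)),
        sex = ifelse(stratified_uniforms(n) < profile$pct_female,
                     "female", "male"),
        age = round(qlnorm_from_quartiles(stratified_uniforms(n),
                                          profile$age_median,
                                          profile$age_iqr[1],
                                          profile$age_iqr[2], lower = 15)),
        cd4 = round(qlnorm_from_quartiles(stratified_uniforms(n),
                                          profile$cd4_median,
                                          profile$cd4_iqr[1],
                                          profile$cd4_iqr[2])),
        backbone = draw_categorical(stratified_uniforms(n),
                                    profile$backbone_mix),
        third = draw_categorical(stratified_uniforms(n), profile$third_mix),
        state = td$state[term_idx],
        month = td$month[term_idx])
    })
    ids <- sprintf("%s-p%04d", profile$site_id, seq_len(n))
    init_dates <- config$calendar_start + draws$init_day
    events <- lapply(seq_len(n), function(i) {
      p <- profile
      p$assigned_backbone <- draws$backbone[[i]]
      p$assigned_third <- draws$third[[i]]
      ev <- withr::with_seed(
        mix_seed(config$seed, profile$site_id, i),
        simulate_patient_events(p, draws$state[[i]], draws$month[[i]]))
      ev$patient_id <- ids[[i]]
      ev
    })
    events <- dplyr::bind_rows(events)
    # a patient whose death went unrecorded before any contact keeps a
    # header-only row so cohort membership is preserved
    missing_ids <- setdiff(ids, unique(events$patient_id))
    if (length(missing_ids) > 0) {
      events <- dplyr::bind_rows(events, tibble::tibble(
        day = NA_real_, kind = NA_character_, provider = NA_character_,
        drug = NA_character_, msupply = NA_real_, test = NA_character_,
        sched = NA_real_, patient_id = missing_ids))
    }
    header <- tibble::tibble(patient_id = ids, site_id = profile$site_id,
                             initiation_date = init_dates,
                             age_at_initiation = draws$age, sex = draws$sex,
                             baseline_cd4 = draws$cd4)
    tab <- events |>
      dplyr::left_join(header, by = "patient_id") |>
      dplyr::mutate(
        event_date = .data$initiation_date + round(.data$day),
        next_scheduled_date = .data$initiation_date + round(.data$sched),
        event_kind = .data$kind, provider_type = .data$provider,
        drug_code = .data$drug, months_supply = .data$msupply,
        test_code = .data$test)
    truth <- tibble::tibble(patient_id = ids, site_id = profile$site_id,
                            terminal_state = draws$state,
                            terminal_month = draws$month)
    list(events = tab[patient_columns()], truth = truth)
  })
  cohort <- validate_patients(
    dplyr::bind_rows(lapply(site_tables, `[[`, "events")))
  attr(cohort, "truth") <- dplyr::bind_rows(
    lapply(site_tables, `[[`, "truth"))
  cohort
}

#' Generator truth for a synthetic cohort
#'
#' @param cohort A cohort from [generate_cohort()].
#' @return Tibble `patient_id`, `site_id`, `terminal_state`,
#'   `terminal_month`.
#' @export
cohort_truth <- function(cohort) {
  truth <- attr(cohort, "truth")
  if (is.null(truth)) stop("cohort carries no generator truth", call. = FALSE)
  truth
}

#' Generator-truth outcome at an endpoint
#'
#' @param truth Output of [cohort_truth()].
#' @param endpoint_months Endpoint (multiple of 12 within follow-up).
#' @return Tibble `patient_id`, `site_id`, `outcome`.
#' @export
truth_outcomes <- function(truth, endpoint_months) {
  outcome <- ifelse(
    !is.na(truth$terminal_month) & truth$terminal_month <= endpoint_months,
    truth$terminal_state, "retained")
  tibble::tibble(patient_id = truth$patient_id, site_id = truth$site_id,
                 endpoint_months = as.integer(endpoint_months),
                 outcome = outcome)
}

#' Generate plausible site cost inputs for a profile
#'
#' Draws a random but internally consistent set of cost inputs for a site:
#' capital with a facility-level base plus a component proportional to
#' patient volume, support staff, per-provider staffing costs with
#' consultation volumes proportional to the active census, and on-site
#' laboratory inputs. Deterministic given `(profile, seed)`; all volumes
#' scale linearly with `n_active_patients`.
#'
#' @param profile A [site_profile()].
#' @param seed Integer seed.
#' @return A [site_cost_inputs()] object (amounts in ZMK).
#' @export
generate_site_cost_inputs <- function(profile, seed = 104729) {
  validate_site_profile(profile)
  n_active <- profile$n_active_patients
  withr::with_seed(mix_seed(seed, profile$site_id, "cost-inputs"), {
    jit <- function() runif(1, 0.85, 1.15)
    capital <- tibble::tibble(
      item = c("buildings", "equipment"),
      replacement_cost = c((2e8 + 3e4 * n_active) * jit(),
                           (4e7 + 1.5e4 * n_active) * jit()),
      life_years = c(50, 5),
      year = c(2010, 2011))
    staff <- tibble::tibble(
      role = c("data_clerk", "cleaner", "security"),
      annual_salary_allowances = c(2.2e7, 1.4e7, 1.6e7) * runif(3, 0.9, 1.1),
      art_fraction = runif(3, 0.4, 0.8),
      year = 2011)
    providers <- tibble::tibble(
      provider_type = provider_types(),
      annual_cost = c(3.5e8, 1.6e8, 9e7, 1.3e8) * runif(4, 0.9, 1.1),
      art_fraction = runif(4, 0.3, 0.6),
      consultations_per_year = round(n_active * c(6, 7, 8, 9)),
      year = 2011)
    labs <- tibble::tibble(
      test_code = test_codes(),
      reagent_consumable_cost_per_test = c(3.2e4, 1.6e4, 1.0e4) *
        runif(3, 0.8, 1.2),
      annual_equipment_labor_space = c(1.1e7, 6e6, 4e6) * runif(3, 0.8, 1.2),
      tests_per_year = round(n_active * c(1.5, 1.1, 1.3)),
      external_price_per_test = NA_real_,
      year = 2011)
    site_cost_inputs(
      site_id = profile$site_id, capital_items = capital,
      support_staff = staff, n_art_patients = n_active,
      n_nonart_patients = round(0.8 * n_active),
      visits_per_year_art = 8, visits_per_year_nonart = 4,
      provider_costs = providers, lab_inputs = labs, currency = "ZMK")
  })
}
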