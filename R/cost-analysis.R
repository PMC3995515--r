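# Combining utilization with unit costs into per-patient and per-group
# cost summaries, with site-clustered confidence intervals.

COST_COMPONENTS <- c("arv_drugs", "non_arv_drugs", "lab_tests",
                     "clinic_visits", "fixed")

class_to_component <- c(arv_drug = "arv_drugs", non_arv_drug = "non_arv_drugs",
                        lab_test = "lab_tests", visit = "clinic_visits",
                        fixed = "fixed")

#' Cost each patient's utilization
#'
#' Multiplies every utilized quantity by its site's unit cost and sums into
#' the five cost components (`arv_drugs`, `non_arv_drugs`, `lab_tests`,
#' `clinic_visits`, `fixed`) plus a `total` that equals their sum exactly.
#'
#' @param utilization Long utilization table from
#'   [accumulate_utilization()].
#' @param unit_costs Unit-cost tibble covering every site and resource that
#'   appears with a positive quantity (see [build_unit_cost_table()]).
#' @return Tibble with one row per patient: `patient_id`, `site_id`, the
#'   five component columns (USD), and `total`.
#' @export
cost_patients <- function(utilization, unit_costs) {
  joined <- utilization |>
    dplyr::left_join(unit_costs,
                     by = c("site_id", "resource_class", "code"))
  missing <- joined |>
    dplyr::filter(is.na(.data$unit_cost_usd), .data$quantity > 0) |>
    dplyr::distinct(.data$site_id, .data$resource_class, .data$code)
  if (nrow(missing) > 0) {
    stop("no unit cost for utilized resource(s): ",
         paste(sprintf("%s/%s at %s", missing$resource_class, missing$code,
                       missing$site_id), collapse = "; "), call. = FALSE)
  }
  joined$unit_cost_usd[is.na(joined$unit_cost_usd)] <- 0
  wide <- joined |>
    dplyr::mutate(component = class_to_component[.data$resource_class],
                  cost = .data$quantity * .data$unit_cost_usd) |>
    dplyr::group_by(.data$patient_id, .data$site_id, .data$component) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "component", values_from = "cost",
                       values_fill = 0)
  for (comp in COST_COMPONENTS) {
    if (is.null(wide[[comp]])) wide[[comp]] <- 0
  }
  wide$total <- rowSums(as.matrix(wide[COST_COMPONENTS]))
  wide[c("patient_id", "site_id", COST_COMPONENTS, "total")]
}

#' Mean with a cluster-robust (CR1) confidence interval
#'
#' The mean of `values` with a variance allowing arbitrary within-cluster
#' correlation: for the intercept-only regression the CR1 sandwich is
#' `V = G/(G-1) * (N-1)/(N-1) * sum_g (sum_{i in g} (x_i - mean))^2 / N^2`
#' with `G` clusters and `N` observations, and the interval uses the
#' Student-t quantile at `G - 1` degrees of freedom. This reproduces the
#' convention of clustered standard errors from an intercept-only OLS
#' regression with the usual small-sample correction. With
#' `clustered = FALSE` a conventional i.i.d. interval
#' (`t` at `N - 1` df) is returned instead — used for single-site groups.
#'
#' @param values Numeric vector.
#' @param clusters Cluster labels (site ids), same length as `values`.
#' @param alpha Two-sided significance level (default 0.05).
#' @param clustered Use the clustered variance (default TRUE).
#' @return List with `mean`, `se`, `ci_low`, `ci_high`, `n`, `g`.
#' @export
group_mean_ci <- function(values, clusters = NULL, alpha = 0.05,
                          clustered = TRUE) {
  n <- length(values)
  if (n == 0) stop("no values", call. = FALSE)
  m <- mean(values)
  if (clustered) {
    if (is.null(clusters) || length(clusters) != n) {
      stop("clusters must match values", call. = FALSE)
    }
    g <- length(unique(clusters))
    if (g < 2) {
      stop("clustered interval needs >= 2 clusters (zero degrees of ",
           "freedom with G = 1); use clustered = FALSE", call. = FALSE)
    }
    cluster_sums <- tapply(values - m, clusters, sum)
    v <- (g / (g - 1)) * ((n - 1) / (n - 1)) * sum(cluster_sums^2) / n^2
    df <- g - 1
  } else {
    g <- 1L
    v <- stats::var(values) / n
    if (n == 1) v <- 0
    df <- max(n - 1, 1)
  }
  se <- sqrt(v)
  tq <- stats::qt(1 - alpha / 2, df)
  list(mean = m, se = se, ci_low = m - tq * se, ci_high = m + tq * se,
       n = n, g = g)
}

#' Summarize costs by site and overall, for all patients and the retained
#' subset
#'
#' Produces the standard reporting surface: per-site and combined mean cost
#' per patient for the full sample and for the subset retained in care at
#' the endpoint, with component means and percent shares. Combined-site
#' intervals are adjusted for clustering at the site level
#' ([group_mean_ci()]); within a single site a conventional i.i.d.
#' interval is used. Percent shares are computed from unrounded component
#' means.
#'
#' @param patient_costs Output of [cost_patients()].
#' @param outcomes Outcome assignments at the matching endpoint.
#' @param subsets Which panels to produce (default both).
#' @param alpha Significance level for intervals.
#' @return Tibble with one row per (site or `"all"`) x subset: `n`, `mean`,
#'   `ci_low`, `ci_high`, component means `mean_<component>`, and shares
#'   `pct_<component>`.
#' @export
summarize_costs <- function(patient_costs, outcomes,
                            subsets = c("all", "retained"), alpha = 0.05) {
  one_group <- function(pc, label, subset) {
    if (nrow(pc) == 0) return(NULL)
    ci <- if (label == "all") {
      group_mean_ci(pc$total, pc$site_id, alpha = alpha, clustered = TRUE)
    } else {
      group_mean_ci(pc$total, alpha = alpha, clustered = FALSE)
    }
    comp_means <- colMeans(as.matrix(pc[COST_COMPONENTS]))
    shares <- 100 * comp_means / sum(comp_means)
    row <- tibble::tibble(site_id = label, subset = subset, n = ci$n,
                          mean = ci$mean, ci_low = ci$ci_low,
                          ci_high = ci$ci_high)
    for (comp in COST_COMPONENTS) {
      row[[paste0("mean_", comp)]] <- comp_means[[comp]]
      row[[paste0("pct_", comp)]] <- shares[[comp]]
    }
    row
  }
  panels <- list()
  for (subset in subsets) {
    pc <- patient_costs
    if (subset == "retained") {
      keep <- outcomes$patient_id[outcomes$outcome == "retained"]
      pc <- dplyr::filter(pc, .data$patient_id %in% keep)
    }
    site_rows <- pc |>
      dplyr::group_split(.data$site_id) |>
      purrr::map(~ one_group(.x, .x$site_id[[1]], subset))
    panels <- c(panels, site_rows, list(one_group(pc, "all", subset)))
  }
  dplyr::bind_rows(panels)
}

#' Cost to produce one patient retained in care
#'
#' Total costs over *all* patients (retained or not) divided by the number
#' of patients retained at the endpoint: what the program spends per
#' patient still in care, counting spending on those who died or were lost.
#' Always at least the all-patient mean.
#'
#' @param patient_costs Output of [cost_patients()].
#' @param outcomes Outcome assignments at the endpoint.
#' @return USD per retained patient.
#' @export
cost_per_retained <- function(patient_costs, outcomes) {
  n_ret <- sum(outcomes$outcome == "retained")
  if (n_ret == 0) stop("no retained patients", call. = FALSE)
  sum(patient_costs$total) / n_ret
}

#' Average annual cost among patients retained at a multi-year endpoint
#'
#' Mean cumulative cost over the first `k` years, among patients retained
#' in care at `k * 12` months, divided by `k`.
#'
#' @param patient_costs Costs accumulated over the full `k`-year window.
#' @param outcomes Outcome assignments at `k * 12` months.
#' @param k Horizon in years (1, 2, or 3).
#' @return USD per patient-year.
#' @export
annualized_cost <- function(patient_costs, outcomes, k) {
  stopifnot(k >= 1)
  keep <- outcomes$patient_id[outcomes$outcome == "retained"]
  pc <- dplyr::filter(patient_costs, .data$patient_id %in% keep)
  if (nrow(pc) == 0) stop("no retained patients at ", k * 12, " months",
                          call. = FALSE)
  mean(pc$total) / k
}
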