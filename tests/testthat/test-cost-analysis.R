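test_that("patient costs multiply quantities by unit costs and sum exactly", {
  uc <- reference_unit_costs()
  util <- tibble::tibble(
    patient_id = "p1", site_id = "site1",
    resource_class = c("arv_drug", "arv_drug", "fixed"),
    code = c("TDF/FTC", "NVP", "months_in_care"),
    quantity = c(12, 12, 0))
  pc <- cost_patients(util, uc)
  expect_equal(pc$arv_drugs, 12 * 10.54 + 12 * 2.34)
  expect_equal(pc$arv_drugs, 154.56)
  expect_equal(pc$total, pc$arv_drugs)

  doubled <- dplyr::mutate(util, quantity = 2 * quantity)
  expect_equal(cost_patients(doubled, uc)$total, 2 * pc$total)

  zero <- dplyr::mutate(util, quantity = 0)
  expect_true(all(cost_patients(zero, uc)$total == 0))

  orphan <- dplyr::mutate(util, code = c("XX/YY", "NVP", "months_in_care"))
  expect_error(cost_patients(orphan, uc), "XX/YY")
})

test_that("the clustered variance matches the hand-computed sandwich", {
  res <- group_mean_ci(c(1, 1, 3, 3), clusters = c("a", "a", "b", "b"))
  expect_equal(res$mean, 2)
  expect_equal(res$se, 1) # V = (2/1) * ((-2)^2 + 2^2) / 16 = 1
  tq <- qt(0.975, 1)
  expect_equal(res$ci_low, 2 - tq)
  expect_equal(res$ci_high, 2 + tq)
  # identical values give a zero-width interval
  flat <- group_mean_ci(rep(5, 9), clusters = rep(c("a", "b", "c"), 3))
  expect_equal(flat$se, 0)
  expect_equal(flat$ci_low, 5)
  expect_error(group_mean_ci(1:4, clusters = rep("a", 4)), "clusters")
})

test_that("the clustered variance equals the brute-force sandwich exactly", {
  brute_force_se <- function(x, g) {
    m <- mean(x)
    ug <- unique(g)
    s <- 0
    for (cl in ug) {
      u <- sum(x[g == cl] - m)
      s <- s + u * u
    }
    sqrt(length(ug) / (length(ug) - 1) * s / length(x)^2)
  }
  withr::with_seed(404, {
    for (rep in 1:25) {
      n <- sample(4:20, 1)
      g <- sample(letters[1:sample(2:5, 1)], n, replace = TRUE)
      if (length(unique(g)) < 2) next
      x <- round(rnorm(n, 100, 25), 2)
      expect_equal(group_mean_ci(x, g)$se, brute_force_se(x, g),
                   tolerance = 1e-14)
    }
  })
})

test_that("the clustered variance matches the regression-package oracle", {
  skip_if_not_installed("sandwich")
  withr::with_seed(42, {
    x <- rnorm(60, 200, 40) + rep(rnorm(6, 0, 30), each = 10)
    g <- rep(paste0("s", 1:6), each = 10)
  })
  ours <- group_mean_ci(x, g)
  fit <- stats::lm(x ~ 1)
  v <- sandwich::vcovCL(fit, cluster = g, type = "HC1")[1, 1]
  expect_equal(ours$se, sqrt(v), tolerance = 1e-12)
})

test_that("clustered intervals widen under between-site variation", {
  withr::with_seed(7, {
    site_effect <- rep(rnorm(6, 0, 50), each = 30)
    x <- 200 + site_effect + rnorm(180, 0, 5)
    g <- rep(paste0("s", 1:6), each = 30)
  })
  clustered <- group_mean_ci(x, g)
  naive <- group_mean_ci(x, clustered = FALSE)
  expect_gt(clustered$ci_high - clustered$ci_low,
            naive$ci_high - naive$ci_low)
})

test_that("clustered 95% intervals cover the truth at small G", {
  # 6 sites with site-level cost effects; t(G-1) intervals should cover
  # near nominally
  covered <- withr::with_seed(2718, vapply(1:100, function(r) {
    site_effect <- rep(rnorm(6, 0, 30), each = 15)
    x <- 250 + site_effect + rnorm(90, 0, 20)
    ci <- group_mean_ci(x, rep(1:6, each = 15))
    ci$ci_low <= 250 && 250 <= ci$ci_high
  }, logical(1)))
  expect_gte(mean(covered), 0.85)
})

test_that("cost summaries reproduce the published weighted aggregates", {
  ref <- reference_site_statistics()
  n_all <- ref$cohort$n
  n_ret <- ref$retention$retained_12
  expect_equal(round(sum(ref$costs$mean_all * n_all) / sum(n_all)), 198)
  expect_equal(round(sum(ref$costs$mean_retained * n_ret) / sum(n_ret)), 243)

  # summarize_costs on constructed patient-level data with exactly the
  # site means reproduces the same aggregates
  pats <- purrr::pmap(list(ref$cohort$site_id, n_all, n_ret,
                           ref$costs$mean_all, ref$costs$mean_retained),
                      function(sid, n, nr, m_all, m_ret) {
    total <- rep((n * m_all - nr * m_ret) / (n - nr), n)
    total[seq_len(nr)] <- m_ret
    list(
      costs = tibble::tibble(
        patient_id = sprintf("%s-%03d", sid, seq_len(n)), site_id = sid,
        arv_drugs = total, non_arv_drugs = 0, lab_tests = 0,
        clinic_visits = 0, fixed = 0, total = total),
      outcomes = tibble::tibble(
        patient_id = sprintf("%s-%03d", sid, seq_len(n)), site_id = sid,
        endpoint_months = 12L,
        outcome = rep(c("retained", "ltfu"), c(nr, n - nr)),
        basis_date = as.Date(NA)))
  })
  pc <- dplyr::bind_rows(purrr::map(pats, "costs"))
  oc <- dplyr::bind_rows(purrr::map(pats, "outcomes"))
  sm <- summarize_costs(pc, oc)
  all_row <- sm[sm$site_id == "all" & sm$subset == "all", ]
  ret_row <- sm[sm$site_id == "all" & sm$subset == "retained", ]
  expect_equal(round(all_row$mean), 198)
  expect_equal(round(ret_row$mean), 243)
  expect_equal(ret_row$n, 633)
  # cost to produce a retained patient
  expect_equal(round(cost_per_retained(pc, oc)),
               round(all_row$mean * 846 / 633))
  expect_gte(cost_per_retained(pc, oc), all_row$mean)
})

test_that("component means sum to the total mean in every group", {
  coh <- fixture_cohort()
  out <- classify_outcomes(coh, 12)
  util <- accumulate_utilization(coh, 12)
  pc <- cost_patients(util, fixture_unit_costs())
  expect_equal(pc$total,
               pc$arv_drugs + pc$non_arv_drugs + pc$lab_tests +
                 pc$clinic_visits + pc$fixed)
  sm <- summarize_costs(pc, out)
  comp_sum <- sm$mean_arv_drugs + sm$mean_non_arv_drugs + sm$mean_lab_tests +
    sm$mean_clinic_visits + sm$mean_fixed
  expect_equal(sm$mean, comp_sum, tolerance = 1e-9)
  share_sum <- sm$pct_arv_drugs + sm$pct_non_arv_drugs + sm$pct_lab_tests +
    sm$pct_clinic_visits + sm$pct_fixed
  expect_equal(share_sum, rep(100, nrow(sm)), tolerance = 1e-9)
  expect_true(all(sm$ci_low <= sm$mean & sm$mean <= sm$ci_high))
})

test_that("annualized cost declines with horizon on a declining fixture", {
  mk_costs <- function(total) tibble::tibble(
    patient_id = sprintf("p%02d", seq_along(total)), site_id = "s1",
    arv_drugs = total, non_arv_drugs = 0, lab_tests = 0, clinic_visits = 0,
    fixed = 0, total = total)
  mk_out <- function(n, months) tibble::tibble(
    patient_id = sprintf("p%02d", seq_len(n)), site_id = "s1",
    endpoint_months = months, outcome = "retained", basis_date = as.Date(NA))
  # yearly costs decline: 250, then 200, then 150
  y1 <- rep(250, 10)
  expect_equal(annualized_cost(mk_costs(y1), mk_out(10, 12L), 1), 250)
  a2 <- annualized_cost(mk_costs(y1 + 200), mk_out(10, 24L), 2)
  a3 <- annualized_cost(mk_costs(y1 + 200 + 150), mk_out(10, 36L), 3)
  expect_equal(a2, 225)
  expect_equal(a3, 200)
  expect_true(250 > a2 && a2 > a3)
  expect_error(annualized_cost(mk_costs(y1), mk_out(0, 24L)[0, ], 2),
               "retained")
})

test_that("simulated annual cost per retained patient declines over years", {
  coh <- dplyr::filter(fixture_cohort(), site_id %in% c("site2", "site6"))
  uc <- fixture_unit_costs()
  a_by_k <- vapply(1:3, function(k) {
    out <- classify_outcomes(coh, 12 * k)
    util <- accumulate_utilization(coh, 12 * k)
    annualized_cost(cost_patients(util, uc), out, k)
  }, numeric(1))
  expect_true(all(diff(a_by_k) < 0))
})
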