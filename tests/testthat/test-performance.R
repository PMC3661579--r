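test_that("ROC curve hits the textbook corners", {
  # perfect separation: passes through (0, 1), AUC = 1
  curve <- roc_curve(c(0.8, 0.9), c(0.1, 0.2, 0.3))
  expect_true(any(curve$fpr == 0 & curve$dr == 1))
  expect_equal(auc_empirical(c(0.8, 0.9), c(0.1, 0.2, 0.3)), 1)
  # identical distributions: AUC ~ 0.5
  set.seed(31)
  x <- runif(4000); y <- runif(4000)
  expect_equal(auc_empirical(x, y), 0.5, tolerance = 0.03)
  expect_error(roc_curve(numeric(0), 1), "non-empty")
})

test_that("DR at fixed FPR matches brute-force threshold enumeration", {
  # worked toy: cases {.05,.2,.3}, controls ten equally spaced .01...10
  cases <- c(0.05, 0.2, 0.3)
  controls <- seq(0.01, 0.10, by = 0.01)
  expect_equal(dr_at_fpr(target_fpr = 0.10, case_risks = cases,
                         control_risks = controls), 2 / 3)
  expect_equal(brute_force_dr(cases, controls, 0.10), 2 / 3)
  # boundaries
  expect_equal(dr_at_fpr(target_fpr = 1, case_risks = cases,
                         control_risks = controls), 1)
  expect_equal(dr_at_fpr(target_fpr = 0, case_risks = cases,
                         control_risks = controls), mean(cases > max(controls)))
  # random small cohorts, including heavy ties
  set.seed(32)
  for (r in 1:100) {
    n1 <- sample(3:40, 1); n0 <- sample(3:60, 1)
    vals <- round(runif(n1 + n0), sample(1:3, 1)) # rounding creates ties
    cas <- vals[seq_len(n1)]; ctl <- vals[-seq_len(n1)]
    f <- runif(1)
    expect_equal(dr_at_fpr(target_fpr = f, case_risks = cas,
                           control_risks = ctl),
                 brute_force_dr(cas, ctl, f))
  }
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(33)
  for (r in 1:20) {
    cas <- round(rnorm(sample(5:30, 1), 0.5, 0.4), 2)
    ctl <- round(rnorm(sample(5:30, 1), 0.0, 0.4), 2)
    expect_equal(auc_empirical(cas, ctl), brute_force_auc(cas, ctl),
                 tolerance = 1e-12)
    # and the wilcox.test statistic normalizes to the same value
    w <- suppressWarnings(stats::wilcox.test(cas, ctl))
    expect_equal(auc_empirical(cas, ctl),
                 unname(w$statistic) / (length(cas) * length(ctl)),
                 tolerance = 1e-12)
  }
})

test_that("bootstrap CI is seeded, degenerate under separation, and narrows with n", {
  expect_equal(bootstrap_dr_ci(c(10, 11, 12), c(1, 2, 3), 0.10, reps = 200,
                               seed = 1), c(1, 1))
  set.seed(30)
  cas0 <- rnorm(50, 1); ctl0 <- rnorm(80)
  ci_a <- bootstrap_dr_ci(cas0, ctl0, 0.10, reps = 300, seed = 2)
  ci_b <- bootstrap_dr_ci(cas0, ctl0, 0.10, reps = 300, seed = 2)
  expect_identical(ci_a, ci_b)
  set.seed(34)
  big_cas <- rnorm(2000, 1); big_ctl <- rnorm(2000)
  small_cas <- big_cas[1:20]; small_ctl <- big_ctl[1:20]
  w_small <- diff(bootstrap_dr_ci(small_cas, small_ctl, 0.10, 400, seed = 3))
  w_big <- diff(bootstrap_dr_ci(big_cas, big_ctl, 0.10, 400, seed = 3))
  expect_gt(w_small, w_big)
  expect_error(bootstrap_dr_ci(1:5, 1:5, 0.1, reps = 50), "200")
})

test_that("parametric model-predicted DR matches the Gaussian closed form", {
  # equal distributions: DR = FPR
  for (f in c(0.05, 0.10, 0.5))
    expect_equal(model_predicted_dr(c(0, 1), c(0, 1), f), f, tolerance = 1e-12)
  # mean shift in SD units: DR = Phi(shift - z_{1-FPR})
  z90 <- qnorm(0.90)
  expect_equal(model_predicted_dr(c(z90, 1), c(0, 1), 0.10), 0.5,
               tolerance = 1e-12)
  expect_equal(model_predicted_dr(c(2 * z90, 1), c(0, 1), 0.10), pnorm(z90),
               tolerance = 1e-12)
  expect_equal(round(model_predicted_dr(c(2 * z90, 1), c(0, 1), 0.10), 2), 0.9)
  expect_error(model_predicted_dr(c(0, -1), c(0, 1), 0.1), "finite")
})

test_that("parametric and empirical DR agree for Gaussian log-odds risks", {
  set.seed(35)
  n <- 50000
  lo_case <- rnorm(n, -1.0, 1.1)
  lo_ctl <- rnorm(n, -2.2, 1.0)
  emp <- dr_at_fpr(target_fpr = 0.10, case_risks = plogis(lo_case),
                   control_risks = plogis(lo_ctl))
  par <- model_predicted_dr(fit_logodds_normal(plogis(lo_case)),
                            fit_logodds_normal(plogis(lo_ctl)), 0.10)
  expect_equal(emp, par, tolerance = 0.02)
})

test_that("performance table is structurally sound and a null marker adds nothing", {
  cfg <- cohort_config(n_controls = 500, n_eo = 120, n_lo = 120, seed = 37)
  co <- generate_cohort(cfg)
  moms <- compute_cohort_moms(co)
  pm <- list("EO-PE" = reference_prior_model("EO-PE"),
             "LO-PE" = reference_prior_model("LO-PE"))
  gm <- list(
    unaffected = fit_group_distribution(
      moms$log10_mom[co$group == "control", ], "unaffected"),
    "EO-PE" = fit_group_distribution(
      moms$log10_mom[co$group == "EO-PE", ], "EO-PE"),
    "LO-PE" = fit_group_distribution(
      moms$log10_mom[co$group == "LO-PE", ], "LO-PE"))
  perf <- performance_table(co, pm, gm, moms = moms)
  expect_true(all(perf$dr >= 0 & perf$dr <= 1))
  expect_true(all(perf$auc >= 0 & perf$auc <= 1))
  # DR non-decreasing in FPR within each (outcome, subset, combo) cell
  key <- paste(perf$outcome, perf$subset, perf$combo)
  for (k in unique(key)) {
    cell <- perf[key == k, ]
    cell <- cell[order(cell$fpr), ]
    expect_true(all(diff(cell$dr) >= 0))
  }
  # an uninformative extra marker leaves DR unchanged within noise: give the
  # EO group model the control fb_hcg parameters so fb_hcg carries LR ~ 1
  gm_null <- gm
  gm_null[["EO-PE"]]$mean["fb_hcg"] <- gm$unaffected$mean["fb_hcg"]
  gm_null[["EO-PE"]]$sd["fb_hcg"] <- gm$unaffected$sd["fb_hcg"]
  r1 <- screen_cohort(co, pm[["EO-PE"]], gm_null[["EO-PE"]], gm$unaffected,
                      markers = c("map", "plgf"), moms = moms)
  r2 <- screen_cohort(co, pm[["EO-PE"]], gm_null[["EO-PE"]], gm$unaffected,
                      markers = c("map", "plgf", "fb_hcg"), moms = moms)
  cases <- co$group == "EO-PE"; ctl <- co$group == "control"
  d1 <- dr_at_fpr(target_fpr = 0.10, case_risks = r1$posterior[cases],
                  control_risks = r1$posterior[ctl])
  d2 <- dr_at_fpr(target_fpr = 0.10, case_risks = r2$posterior[cases],
                  control_risks = r2$posterior[ctl])
  expect_lt(abs(d1 - d2), 0.08)
})

test_that("baseline comparison routes tests and flags only real differences", {
  cfg <- cohort_config(n_controls = 400, n_eo = 150, n_lo = 0, seed = 41,
                       case_covariate_model = "none")
  co <- generate_cohort(cfg, missingness = FALSE)
  tab <- compare_baseline_groups(co)
  expect_true(all(tab$test[tab$variable %in% c("nulliparous", "smoking")] ==
                    "chi-square"))
  expect_true(all(tab$test[tab$variable %in% c("age", "weight")] ==
                    "mann-whitney"))
  # covariates are drawn identically for cases here: no flags expected on
  # maternal characteristics (birthweight differs by design)
  mat <- tab[tab$variable %in% c("age", "weight", "nulliparous", "smoking"), ]
  expect_lt(sum(mat$significant), 2)
  expect_true(all(tab$significant == (tab$p < 0.05 / 3)))
  # with the reference covariate tilt, nulliparity is flagged
  co2 <- generate_cohort(cohort_config(n_controls = 400, n_eo = 150, n_lo = 0,
                                       seed = 41), missingness = FALSE)
  tab2 <- compare_baseline_groups(co2)
  expect_true(tab2$significant[tab2$variable == "nulliparous" &
                                 tab2$group == "EO-PE"])
})
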