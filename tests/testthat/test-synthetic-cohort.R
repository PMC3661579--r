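test_that("config validation names the offending field", {
  expect_error(cohort_config(n_controls = -1), "n_controls")
  expect_error(cohort_config(sga_fraction_lo = 1.2), "sga_fraction_lo")
  expect_error(cohort_config(covariate_params = list(smoking = -0.1)),
               "smoking")
  expect_error(cohort_config(log10_mom_sd = c(papp_a = 0, fb_hcg = 0.25,
                                              adam12 = 0.15, plgf = 0.15,
                                              map = 0.05)), "log10_mom_sd")
})

test_that("generation is empty at n = 0 and bit-identical under a repeated seed", {
  cfg0 <- cohort_config(n_controls = 0L, n_eo = 0L, n_lo = 0L)
  expect_equal(nrow(generate_controls(cfg0)), 0)
  cfg <- cohort_config(n_controls = 120, n_eo = 40, n_lo = 40, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_identical(generate_cases(cfg, "EO-PE"), generate_cases(cfg, "EO-PE"))
  # different seeds differ
  cfg2 <- cohort_config(n_controls = 120, n_eo = 40, n_lo = 40, seed = 100)
  expect_false(identical(generate_cohort(cfg), generate_cohort(cfg2)))
})

test_that("control marker MoMs center on 1 when the pipeline inverts the generator", {
  co <- small_control_cohort(n = 5000, seed = 1)
  med <- sapply(compute_cohort_moms(co)$mom, stats::median, na.rm = TRUE)
  expect_true(all(abs(med - 1) < 0.02))
})

test_that("case groups carry the configured multiplicative MoM shifts", {
  cfg <- cohort_config(n_controls = 4000, n_eo = 2000, n_lo = 2000, seed = 2)
  co <- generate_cohort(cfg, missingness = FALSE)
  moms <- compute_cohort_moms(co)
  eo <- co$group == "EO-PE" & !co$sga
  lo <- co$group == "LO-PE" & !co$sga
  expect_equal(stats::median(moms$mom$plgf[eo], na.rm = TRUE), 0.94,
               tolerance = 0.03 / 0.94)
  expect_equal(stats::median(moms$mom$map[lo], na.rm = TRUE), 1.05,
               tolerance = 0.02 / 1.05)
  expect_equal(stats::median(moms$mom$map[eo], na.rm = TRUE), 1.08,
               tolerance = 0.02 / 1.08)
  # delivery-GA structure matches the onset definition
  expect_true(all(co$ga_delivery[co$group == "EO-PE"] < 238))
  expect_true(all(co$ga_delivery[co$group == "LO-PE"] >= 238))
  # requested SGA fractions
  expect_equal(mean(co$sga[co$group == "EO-PE"]), round(13 / 68 * 2000) / 2000,
               tolerance = 1e-9)
})

test_that("unit shifts make cases indistinguishable from controls in MoM", {
  shifts <- list(
    "EO-PE" = list(all = c(papp_a = 1, fb_hcg = 1, adam12 = 1, plgf = 1, map = 1),
                   sga = c(papp_a = 1, fb_hcg = 1, adam12 = 1, plgf = 1, map = 1)),
    "LO-PE" = list(all = c(papp_a = 1, fb_hcg = 1, adam12 = 1, plgf = 1, map = 1),
                   sga = c(papp_a = 1, fb_hcg = 1, adam12 = 1, plgf = 1, map = 1)))
  cfg <- cohort_config(n_controls = 1500, n_eo = 800, n_lo = 0, seed = 4,
                       case_mom_shifts = shifts,
                       case_covariate_model = "none")
  co <- generate_cohort(cfg, missingness = FALSE)
  moms <- compute_cohort_moms(co)
  for (mk in c("papp_a", "plgf", "map")) {
    ks <- suppressWarnings(stats::ks.test(
      moms$log10_mom[[mk]][co$group == "EO-PE"],
      moms$log10_mom[[mk]][co$group == "control"]))
    expect_gt(ks$p.value, 0.005)
  }
})

test_that("outcome assignment by a logistic model behaves at the limits and recovers parameters", {
  prof <- with(list(), {
    set.seed(5)
    data.frame(age = rnorm(4000, 33, 4), weight = rlnorm(4000, log(65.5), 0.15),
               height = rnorm(4000, 168, 6.5),
               nulliparous = runif(4000) < 0.5, smoking = runif(4000) < 0.3)
  })
  null_model <- risk_model("EO-PE",
                           data.frame(variable = character(0),
                                      transform = character(0),
                                      raw = numeric(0), shrunk = numeric(0)),
                           intercept_raw = 0, intercept_shrunk = 0)
  d <- assign_outcomes_by_model(prof, null_model, seed = 6)
  expect_equal(mean(d$case), 0.5, tolerance = 0.03)
  # strongly negative intercept: no cases
  none <- null_model; none$intercept_raw <- -50; none$intercept_shrunk <- -50
  expect_equal(sum(assign_outcomes_by_model(prof, none, seed = 6)$case), 0)
  # missing covariate is reported
  expect_error(assign_outcomes_by_model(prof[, -1],
                                        reference_prior_model("EO-PE")),
               "age")
  # parameter recovery under the reference model (raw scale)
  set.seed(7)
  n <- 30000
  pool <- data.frame(age = rnorm(n, 33, 4), weight = rlnorm(n, log(65.5), 0.145),
                     height = rnorm(n, 168, 6.5),
                     nulliparous = runif(n) < 0.466, smoking = runif(n) < 0.042)
  d2 <- assign_outcomes_by_model(pool, reference_prior_model("EO-PE"),
                                 seed = 8, use = "raw")
  fit <- glm(case ~ age + log(weight) + height + nulliparous + smoking,
             data = d2, family = binomial)
  sm <- summary(fit)$coefficients
  b <- sm["nulliparousTRUE", "Estimate"]; se <- sm["nulliparousTRUE", "Std. Error"]
  expect_lt(abs(b - 1.845 / 0.94), 3 * se)
})

test_that("missingness and below-DL injection follow the configured rates", {
  cfg <- cohort_config(n_controls = 400, n_eo = 50, n_lo = 50, seed = 9)
  co <- generate_cohort(cfg, missingness = FALSE)
  # all-zero rates: unchanged
  cfg0 <- cohort_config(n_controls = 400, n_eo = 50, n_lo = 50, seed = 9,
                        missingness_rates = c(adam12 = 0, plgf = 0, map = 0),
                        plgf_below_dl_rate = 0)
  expect_identical(apply_missingness(co, cfg0), co)
  # rate 1 for MAP: everything missing, pressures cleared too
  cfg1 <- cohort_config(n_controls = 400, n_eo = 50, n_lo = 50, seed = 9,
                        missingness_rates = c(adam12 = 0, plgf = 0, map = 1),
                        plgf_below_dl_rate = 0)
  m1 <- apply_missingness(co, cfg1)
  expect_true(all(is.na(m1$map)) && all(is.na(m1$sbp)))
  # default rates produce below-DL PlGF values that the MoM engine discards
  md <- apply_missingness(co, cfg)
  n_below <- sum(md$plgf < 5.9, na.rm = TRUE)
  expect_gt(n_below, 0)
  flags <- compute_cohort_moms(md)$flags
  expect_equal(sum(flags$plgf == "below_dl"), n_below)
})

test_that("marker values are positive and blood pressures invert to MAP", {
  co <- generate_cohort(cohort_config(n_controls = 300, n_eo = 60, n_lo = 60,
                                      seed = 10), missingness = FALSE)
  for (mk in pe_markers()) expect_true(all(co[[mk]] > 0))
  expect_true(all(co$sbp > co$dbp))
  expect_equal(compute_map(co$sbp, co$dbp), co$map, tolerance = 1e-9)
})

test_that("correlated marker noise propagates to fitted MoM correlations", {
  R <- diag(5)
  dimnames(R) <- list(pe_markers(), pe_markers())
  R["papp_a", "adam12"] <- R["adam12", "papp_a"] <- 0.6
  cfg <- cohort_config(n_controls = 3000, n_eo = 0, n_lo = 0, seed = 11,
                       marker_cor = R)
  co <- generate_cohort(cfg, missingness = FALSE)
  g <- fit_group_distribution(compute_cohort_moms(co)$log10_mom, "unaffected")
  expect_equal(g$cor["papp_a", "adam12"], 0.6, tolerance = 0.1)
  expect_lt(abs(g$cor["papp_a", "plgf"]), 0.08)
})
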