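#' Empirical ROC curve
#'
#' One point per distinct threshold (ties grouped), using the rule
#' "positive if risk >= threshold". Points are ordered by increasing FPR
#' and include the all-negative corner (0, 0).
#'
#' @param case_risks,control_risks Numeric risk vectors, both non-empty.
#' @return Data frame `threshold`, `fpr`, `dr`, ordered by `fpr`.
#' @export
roc_curve <- function(case_risks, control_risks) {
  if (!length(case_risks) || !length(control_risks))
    pe_stop("roc_curve", "both groups must be non-empty")
  u <- sort(unique(c(case_risks, control_risks)), decreasing = TRUE)
  sc <- sort(control_risks); sa <- sort(case_risks)
  n0 <- length(sc); n1 <- length(sa)
  fpr <- (n0 - findInterval(u, sc, left.open = TRUE)) / n0
  dr <- (n1 - findInterval(u, sa, left.open = TRUE)) / n1
  out <- data.frame(threshold = c(Inf, u), fpr = c(0, fpr), dr = c(0, dr))
  out[order(out$fpr, out$dr), , drop = FALSE]
}

#' Detection rate at a fixed false-positive rate
#'
#' Conservative step convention: the DR at the largest achievable FPR not
#' exceeding the target.
#'
#' @param curve A [roc_curve()] result, or `NULL` to compute from risks.
#' @param target_fpr Target FPR (e.g. 0.05 or 0.10).
#' @param case_risks,control_risks Alternative raw-risk interface.
#' @return Detection rate in [0, 1].
#' @export
dr_at_fpr <- function(curve = NULL, target_fpr,
                      case_risks = NULL, control_risks = NULL) {
  if (is.null(curve)) curve <- roc_curve(case_risks, control_risks)
  ok <- curve$fpr <= target_fpr
  if (!any(ok)) return(0)
  max(curve$dr[ok])
}

#' Empirical AUC
#'
#' The probability that a random case outranks a random control, with ties
#' counted one-half — the normalized Mann-Whitney U statistic, computed via
#' mid-ranks.
#'
#' @param case_risks,control_risks Numeric risk vectors.
#' @return AUC in [0, 1].
#' @export
auc_empirical <- function(case_risks, control_risks) {
  n1 <- length(case_risks); n0 <- length(control_risks)
  if (!n1 || !n0) pe_stop("auc_empirical", "both groups must be non-empty")
  r <- rank(c(case_risks, control_risks))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap CI for the DR at fixed FPR
#'
#' Percentile 2.5/97.5 interval over case/control resamples (each group
#' resampled with replacement at its own size).
#'
#' @param case_risks,control_risks Risk vectors.
#' @param target_fpr Target FPR.
#' @param reps Bootstrap replicates (>= 200; default 1000).
#' @param seed RNG seed.
#' @return Numeric `c(lo, hi)`.
#' @export
bootstrap_dr_ci <- function(case_risks, control_risks, target_fpr,
                            reps = 1000L, seed = 1L) {
  if (reps < 200L) pe_stop("bootstrap_dr_ci", "reps must be >= 200")
  n1 <- length(case_risks); n0 <- length(control_risks)
  with_seed(seed, {
    drs <- vapply(seq_len(reps), function(i) {
      dr_at_fpr(target_fpr = target_fpr,
                case_risks = case_risks[sample.int(n1, replace = TRUE)],
                control_risks = control_risks[sample.int(n0, replace = TRUE)])
    }, numeric(1))
    unname(stats::quantile(drs, c(0.025, 0.975), type = 1))
  })
}

#' Model-predicted detection rate under Gaussian log-odds
#'
#' Parametric DR: with group risks Gaussian on the log-odds scale, the
#' screening threshold is the unaffected (1 - FPR) quantile and the DR is
#' the affected-group tail mass beyond it.
#'
#' @param affected,unaffected Length-2 numeric `c(mean, sd)` of log-odds
#'   risk per group.
#' @param target_fpr Target FPR.
#' @return Detection rate.
#' @export
model_predicted_dr <- function(affected, unaffected, target_fpr) {
  if (any(!is.finite(c(affected, unaffected))) ||
      affected[2] <= 0 || unaffected[2] <= 0)
    pe_stop("model_predicted_dr", "group parameters must be finite, SDs > 0")
  thr <- stats::qnorm(1 - target_fpr, unaffected[1], unaffected[2])
  1 - stats::pnorm(thr, affected[1], affected[2])
}

#' Gaussian log-odds parameters of a risk distribution
#'
#' @param risks Probabilities in (0, 1).
#' @return `c(mean, sd)` of `qlogis(risks)`.
#' @export
fit_logodds_normal <- function(risks) {
  lo <- stats::qlogis(risks)
  c(mean = mean(lo), sd = stats::sd(lo))
}

#' Marker combinations of the standard screening report
#'
#' The row layout of the performance table: markers alone, marker
#' combinations, and maternal characteristics (the prior) plus single
#' markers or combinations, ending with the full panel.
#'
#' @return Data frame `name`, `markers` (list column), `use_prior`.
#' @export
default_screening_combos <- function() {
  combo <- function(name, markers, use_prior)
    data.frame(name = name, markers = I(list(markers)), use_prior = use_prior)
  rbind(
    combo("maternal_characteristics", character(0), TRUE),
    combo("papp_a", "papp_a", FALSE),
    combo("fb_hcg", "fb_hcg", FALSE),
    combo("adam12", "adam12", FALSE),
    combo("plgf", "plgf", FALSE),
    combo("map", "map", FALSE),
    combo("papp_a+plgf", c("papp_a", "plgf"), FALSE),
    combo("papp_a+adam12+plgf", c("papp_a", "adam12", "plgf"), FALSE),
    combo("prior+papp_a", "papp_a", TRUE),
    combo("prior+adam12", "adam12", TRUE),
    combo("prior+plgf", "plgf", TRUE),
    combo("prior+map", "map", TRUE),
    combo("prior+map+papp_a", c("map", "papp_a"), TRUE),
    combo("prior+map+plgf", c("map", "plgf"), TRUE),
    combo("prior+map+papp_a+plgf", c("map", "papp_a", "plgf"), TRUE),
    combo("prior+map+papp_a+adam12+plgf",
          c("map", "papp_a", "adam12", "plgf"), TRUE))
}

#' Screening performance table
#'
#' For each outcome (EO-PE, LO-PE), case subset (all cases, cases with an
#' SGA infant) and marker combination: the empirical DR at the target
#' FPRs (with optional stratified bootstrap CIs) and the AUC.
#'
#' @param cohort Cohort data frame (with `group` and `sga` columns).
#' @param prior_models Named list of [risk_model()]s (`"EO-PE"`,
#'   `"LO-PE"`).
#' @param group_models Named list of `gaussian_marker_model`s
#'   (`"unaffected"`, `"EO-PE"`, `"LO-PE"`).
#' @param moms Precomputed [compute_cohort_moms()] result (computed if
#'   `NULL`).
#' @param combos Combination table, default [default_screening_combos()].
#' @param fpr_targets FPR grid, default `c(0.05, 0.10)`.
#' @param boot_reps Bootstrap replicates for CIs (0 disables).
#' @param seed Seed for the bootstrap.
#' @param lr_mode Passed to [screen_cohort()].
#' @return Long data frame: `outcome`, `subset`, `combo`, `fpr`, `dr`,
#'   `ci_lo`, `ci_hi`, `auc`, `n_cases`, `n_controls`.
#' @export
performance_table <- function(cohort, prior_models, group_models,
                              moms = NULL,
                              combos = default_screening_combos(),
                              fpr_targets = c(0.05, 0.10),
                              boot_reps = 0L, seed = 1L,
                              lr_mode = "product") {
  if (is.null(moms)) moms <- compute_cohort_moms(cohort)
  is_control <- cohort$group == "control"
  outcomes <- intersect(c("EO-PE", "LO-PE"),
                        intersect(names(group_models), unique(cohort$group)))
  rows <- list()
  for (outcome in outcomes) {
    for (k in seq_len(nrow(combos))) {
      markers <- combos$markers[[k]]
      pm <- if (combos$use_prior[k]) prior_models[[outcome]] else NULL
      res <- screen_cohort(cohort, pm, group_models[[outcome]],
                           group_models[["unaffected"]],
                           markers = markers, moms = moms,
                           lr_mode = lr_mode)
      ctl <- res$posterior[is_control]
      for (subset in c("all", "with_sga")) {
        in_sub <- cohort$group == outcome &
          (subset == "all" | cohort$sga)
        cas <- res$posterior[in_sub]
        if (!length(cas)) next
        auc <- auc_empirical(cas, ctl)
        for (f in fpr_targets) {
          dr <- dr_at_fpr(target_fpr = f, case_risks = cas,
                          control_risks = ctl)
          ci <- if (boot_reps > 0L)
            bootstrap_dr_ci(cas, ctl, f, reps = boot_reps,
                            seed = seed + k) else c(NA_real_, NA_real_)
          rows[[length(rows) + 1L]] <- data.frame(
            outcome = outcome, subset = subset, combo = combos$name[k],
            fpr = f, dr = dr, ci_lo = ci[1], ci_hi = ci[2], auc = auc,
            n_cases = length(cas), n_controls = length(ctl))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Baseline group comparison
#'
#' Case groups vs controls, characteristic by characteristic: chi-square
#' for categorical variables, Mann-Whitney U for continuous, flagged at
#' the Bonferroni-adjusted alpha of 0.05/3 = 0.0167.
#'
#' @param cohort Cohort data frame.
#' @param variables Named character vector mapping cohort columns to
#'   `"categorical"` / `"continuous"`.
#' @param alpha Significance threshold after Bonferroni adjustment.
#' @return Data frame: `variable`, `group`, `test`, `statistic`, `p`,
#'   `significant`.
#' @export
compare_baseline_groups <- function(cohort,
                                    variables = c(age = "continuous",
                                                  weight = "continuous",
                                                  ga_sampling = "continuous",
                                                  birthweight = "continuous",
                                                  nulliparous = "categorical",
                                                  smoking = "categorical"),
                                    alpha = 0.05 / 3) {
  ctl <- cohort[cohort$group == "control", , drop = FALSE]
  rows <- list()
  for (grp in c("EO-PE", "LO-PE")) {
    cas <- cohort[cohort$group == grp, , drop = FALSE]
    if (!nrow(cas)) next
    for (v in names(variables)) {
      if (variables[[v]] == "categorical") {
        tab <- rbind(table(factor(ctl[[v]], c(FALSE, TRUE))),
                     table(factor(cas[[v]], c(FALSE, TRUE))))
        tst <- suppressWarnings(stats::chisq.test(tab))
        test_name <- "chi-square"
      } else {
        tst <- suppressWarnings(
          stats::wilcox.test(cas[[v]], ctl[[v]], exact = FALSE))
        test_name <- "mann-whitney"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = grp, test = test_name,
        statistic = unname(tst$statistic), p = tst$p.value,
        significant = tst$p.value < alpha)
    }
  }
  do.call(rbind, rows)
}
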