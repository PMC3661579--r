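# Seeded synthetic nested case-control cohorts.
#
# The generator is the package's stand-in for the study data: control
# marker levels are drawn log-normally around the generative median models
# (GA- and weight-dependent), case groups get multiplicative MoM shifts,
# outcomes (delivery GA, birthweight centile, PE flag) are consistent with
# the group label, and missingness/below-DL structure mirrors the assay
# bookkeeping of a real screening cohort.

# run code under a temporary RNG state so callers' streams are untouched
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  stats::qnorm(stats::runif(n, stats::pnorm(lo, mean, sd),
                            stats::pnorm(hi, mean, sd)), mean, sd)
}

#' Default case MoM shifts
#'
#' Per-marker multiplicative shifts of the median applied to case groups,
#' stratified by PE onset type and SGA status. Values follow the observed
#' median MoMs of a nested case-control series (e.g. EO-PE PlGF 0.94,
#' LO-PE PlGF 0.90, EO-PE MAP 1.08, LO-PE MAP 1.05; SGA subgroups show
#' stronger serum-marker reductions).
#'
#' @return Nested list `shifts[[group]][[subset]]` of named numeric
#'   vectors over [pe_markers()].
#' @export
default_case_shifts <- function() {
  list(
    "EO-PE" = list(
      all = c(papp_a = 0.89, fb_hcg = 0.92, adam12 = 0.93, plgf = 0.94, map = 1.08),
      sga = c(papp_a = 0.56, fb_hcg = 0.88, adam12 = 0.68, plgf = 0.83, map = 1.04)),
    "LO-PE" = list(
      all = c(papp_a = 1.04, fb_hcg = 1.04, adam12 = 1.02, plgf = 0.90, map = 1.05),
      sga = c(papp_a = 0.95, fb_hcg = 1.04, adam12 = 0.99, plgf = 0.81, map = 1.01)))
}

#' Synthetic cohort configuration
#'
#' Bundles every generative parameter with validation. Identical config +
#' seed yields a bit-identical cohort.
#'
#' @param n_controls,n_eo,n_lo Group sizes (defaults 500 / 68 / 99, the
#'   nested case-control structure the pipeline assumes).
#' @param sga_fraction_eo,sga_fraction_lo Fraction of cases with an SGA
#'   infant (defaults 13/68 and 49/99).
#' @param seed Integer RNG seed.
#' @param covariate_params List of distribution parameters: `age`
#'   (mean, sd, truncated to `[min, max]` years), `weight` (log-normal
#'   meanlog/sdlog, kg), `height` (mean/sd, cm), `nulliparity` and
#'   `smoking` (probabilities), `ga` (mean/sd in days, truncated to
#'   `ga_sampling_range`).
#' @param ga_sampling_range GA-at-sampling support in days.
#' @param marker_medians Named list of [median_model()]s used as
#'   generative truth; default [default_median_models()].
#' @param case_mom_shifts Nested shift list, default [default_case_shifts()].
#' @param log10_mom_sd Per-marker SD of log10 MoM noise.
#' @param marker_cor Optional 5x5 correlation matrix for the log10 MoM
#'   noise (default: independent markers).
#' @param missingness_rates Per-field missingness proportions
#'   (`adam12`, `plgf`, `map`).
#' @param plgf_below_dl_rate Fraction of records whose PlGF is replaced by
#'   a value below the 5.9 pg/mL detection limit.
#' @param case_covariate_model `"reference"` (default): case maternal
#'   covariates are importance-resampled with weights from the
#'   [reference_prior_model()] raw-scale risk, so cases show the expected
#'   excess of nulliparity, weight, etc.; `"none"` draws case covariates
#'   from the control distribution.
#' @param plgf_ga_effect Optional `list(break_day =, early =)`: case PlGF
#'   shifts apply only from `break_day` (GA days) onward; before it the
#'   shift is `early` (e.g. `list(break_day = 77, early = 1)` confines the
#'   PlGF deficit to sampling at 11 weeks or later). `NULL` (default)
#'   applies the group shift at all GAs.
#' @return Validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_controls = 500L, n_eo = 68L, n_lo = 99L,
                          sga_fraction_eo = 13 / 68,
                          sga_fraction_lo = 49 / 99,
                          seed = 20130522L,
                          covariate_params = list(),
                          ga_sampling_range = c(63, 97),
                          marker_medians = default_median_models(),
                          case_mom_shifts = default_case_shifts(),
                          log10_mom_sd = c(papp_a = 0.25, fb_hcg = 0.25,
                                           adam12 = 0.15, plgf = 0.15,
                                           map = 0.05),
                          marker_cor = NULL,
                          missingness_rates = c(adam12 = 0.02, plgf = 0.025,
                                                map = 0.04),
                          plgf_below_dl_rate = 0.012,
                          case_covariate_model = c("reference", "none"),
                          plgf_ga_effect = NULL) {
  case_covariate_model <- match.arg(case_covariate_model)
  if (!is.null(plgf_ga_effect))
    stopifnot(is.list(plgf_ga_effect),
              all(c("break_day", "early") %in% names(plgf_ga_effect)))
  cov_default <- list(
    age = c(mean = 33, sd = 4, min = 18, max = 45),
    weight = c(meanlog = log(65.5), sdlog = 0.145),
    height = c(mean = 168, sd = 6.5),
    nulliparity = 0.466,
    smoking = 0.042,
    ga = c(mean = 87, sd = 6))
  covariate_params <- utils::modifyList(cov_default, covariate_params)
  counts <- c(n_controls = n_controls, n_eo = n_eo, n_lo = n_lo)
  for (nm in names(counts))
    if (is.na(counts[nm]) || counts[nm] < 0)
      pe_stop("cohort_config", "field ", nm, " must be a count >= 0")
  probs <- c(sga_fraction_eo = sga_fraction_eo,
             sga_fraction_lo = sga_fraction_lo,
             nulliparity = covariate_params$nulliparity,
             smoking = covariate_params$smoking,
             missingness_rates, plgf_below_dl = plgf_below_dl_rate)
  for (nm in names(probs))
    if (is.na(probs[nm]) || probs[nm] < 0 || probs[nm] > 1)
      pe_stop("cohort_config", "field ", nm, " must be a probability in [0,1]")
  if (any(log10_mom_sd <= 0))
    pe_stop("cohort_config", "field log10_mom_sd must be positive")
  if (!is.null(marker_cor)) {
    marker_cor <- as.matrix(marker_cor)
    if (!isTRUE(all.equal(marker_cor, t(marker_cor))) ||
        any(diag(marker_cor) != 1))
      pe_stop("cohort_config", "field marker_cor must be a correlation matrix")
  }
  structure(list(
    n_controls = as.integer(n_controls), n_eo = as.integer(n_eo),
    n_lo = as.integer(n_lo),
    sga_fraction_eo = sga_fraction_eo, sga_fraction_lo = sga_fraction_lo,
    seed = as.integer(seed), covariate_params = covariate_params,
    ga_sampling_range = ga_sampling_range, marker_medians = marker_medians,
    case_mom_shifts = case_mom_shifts, log10_mom_sd = log10_mom_sd,
    marker_cor = marker_cor, missingness_rates = missingness_rates,
    plgf_below_dl_rate = plgf_below_dl_rate,
    case_covariate_model = case_covariate_model,
    plgf_ga_effect = plgf_ga_effect),
    class = "cohort_config")
}

# maternal covariates + GA at sampling for n pregnancies
generate_profiles <- function(n, config) {
  p <- config$covariate_params
  r <- config$ga_sampling_range
  data.frame(
    age = rnorm_trunc(n, p$age["mean"], p$age["sd"], p$age["min"], p$age["max"]),
    weight = stats::rlnorm(n, p$weight["meanlog"], p$weight["sdlog"]),
    height = stats::rnorm(n, p$height["mean"], p$height["sd"]),
    nulliparous = stats::runif(n) < p$nulliparity,
    smoking = stats::runif(n) < p$smoking,
    ga_sampling = round(rnorm_trunc(n, p$ga["mean"], p$ga["sd"], r[1], r[2])))
}

# marker concentrations (and blood pressure) around the generative medians;
# shift is a named vector or an n x 5 matrix of per-record MoM shifts
generate_markers <- function(profiles, config, shift) {
  n <- nrow(profiles)
  markers <- pe_markers()
  if (!is.matrix(shift))
    shift <- matrix(shift[markers], n, length(markers), byrow = TRUE,
                    dimnames = list(NULL, markers))
  sds <- config$log10_mom_sd[markers]
  z <- matrix(stats::rnorm(n * length(markers)), n, length(markers))
  if (!is.null(config$marker_cor)) {
    z <- z %*% chol(config$marker_cor[markers, markers])
  }
  eps <- sweep(z, 2, sds, `*`)
  colnames(eps) <- markers
  out <- profiles
  for (mk in markers) {
    mm <- config$marker_medians[[mk]]
    expv <- expected_value(mm, profiles$ga_sampling, profiles$weight,
                           profiles$smoking)
    if (!is.null(mm$weight_correction))
      expv <- expv * expected_mom_for_weight(mm$weight_correction,
                                             profiles$weight)
    out[[mk]] <- expv * shift[, mk] * 10^eps[, mk]
  }
  # decompose generated MAP into a systolic/diastolic pair with a
  # physiologic pulse pressure, so compute_map() inverts exactly
  pp <- pmax(stats::rnorm(n, 40, 5), 20)
  out$dbp <- out$map - pp / 3
  out$sbp <- out$dbp + pp
  out
}

# birthweights consistent with the SGA designation via the chart used for
# classification (SGA <=> centile < 10)
generate_birthweights <- function(ga_delivery, sex, nulliparous, sga,
                                  chart = synthetic_growth_chart()) {
  parity_class <- ifelse(nulliparous, "nulliparous", "parous")
  entry <- growth_chart_lookup(chart, ga_delivery, sex, parity_class)
  z10 <- stats::qnorm(0.10)
  n <- length(ga_delivery)
  z <- ifelse(sga,
              rnorm_trunc(n, 0, 1, -Inf, z10 - 1e-9),
              rnorm_trunc(n, 0, 1, z10, Inf))
  sd_g <- ((entry$p50_g - entry$minus1sd_g) + (entry$plus1sd_g - entry$p50_g)) / 2
  entry$p50_g + z * sd_g
}

# per-record MoM shift matrix for one case group, honouring the SGA
# stratification and the optional GA-dependent PlGF effect
case_shift_matrix <- function(profiles, config, group, sga) {
  n <- nrow(profiles)
  sh <- config$case_mom_shifts[[group]]
  shift <- matrix(sh$all[pe_markers()], n, 5, byrow = TRUE,
                  dimnames = list(NULL, pe_markers()))
  shift[sga, ] <- matrix(sh$sga[pe_markers()], sum(sga), 5, byrow = TRUE)
  eff <- config$plgf_ga_effect
  if (!is.null(eff)) {
    early <- profiles$ga_sampling < eff$break_day
    shift[early, "plgf"] <- eff$early
  }
  shift
}

assemble_records <- function(profiles, config, group, sga, ga_delivery) {
  n <- nrow(profiles)
  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  bw <- generate_birthweights(ga_delivery, sex, profiles$nulliparous, sga)
  shift <- if (group == "control")
    c(papp_a = 1, fb_hcg = 1, adam12 = 1, plgf = 1, map = 1)
  else case_shift_matrix(profiles, config, group, sga)
  rec <- generate_markers(profiles, config, shift)
  rec$group <- group
  rec$sga <- sga
  rec$ga_delivery <- ga_delivery
  rec$sex <- sex
  rec$birthweight <- bw
  rec$pe_flag <- group != "control"
  rec$proteinuria_flag <- rec$pe_flag
  rec
}

#' Generate synthetic control pregnancies
#'
#' Uncomplicated term deliveries (37+0 to 42+0 weeks), no PE, marker
#' concentrations drawn log-normally around the generative median models
#' evaluated at each record's GA and weight.
#'
#' @param config A [cohort_config()].
#' @return Data frame of control records (possibly 0 rows).
#' @export
generate_controls <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_controls
  if (n == 0L) return(empty_cohort())
  with_seed(config$seed + 1L, {
    profiles <- generate_profiles(n, config)
    ga_del <- round(rnorm_trunc(n, 280, 8, 259, 294))
    sga <- stats::runif(n) < 0.10 # population base rate, unlinked to markers
    assemble_records(profiles, config, "control", sga, ga_del)
  })
}

#' Generate synthetic preeclampsia cases
#'
#' Case marker medians equal the control median times the configured
#' per-group MoM shift; delivery is before 34 weeks for EO-PE and at or
#' after 34 weeks for LO-PE; the requested SGA fraction is met by drawing
#' birthweight z-scores from the matching side of the 10th-centile cut.
#'
#' @param config A [cohort_config()].
#' @param subtype `"EO-PE"` or `"LO-PE"`.
#' @return Data frame of case records.
#' @export
generate_cases <- function(config, subtype = c("EO-PE", "LO-PE")) {
  stopifnot(inherits(config, "cohort_config"))
  subtype <- match.arg(subtype)
  n <- if (subtype == "EO-PE") config$n_eo else config$n_lo
  frac <- if (subtype == "EO-PE") config$sga_fraction_eo else config$sga_fraction_lo
  if (n == 0L) return(empty_cohort())
  offset <- if (subtype == "EO-PE") 2L else 3L
  with_seed(config$seed + offset, {
    profiles <- generate_profiles(n, config)
    if (identical(config$case_covariate_model, "reference")) {
      # tilt case covariates toward the case-conditional distribution
      # implied by the reference prior-risk model: importance resampling
      # of an oversampled pool with weights proportional to exp(Y), so a
      # logistic refit of cases vs controls recovers the model coefficients
      pool <- generate_profiles(20L * n, config)
      w <- exp(linear_predictor(reference_prior_model(subtype), pool,
                                use = "raw"))
      profiles <- pool[sample.int(nrow(pool), n, prob = w, replace = TRUE),
                       , drop = FALSE]
      rownames(profiles) <- NULL
    }
    ga_del <- if (subtype == "EO-PE") round(rnorm_trunc(n, 217, 10, 175, 237))
              else round(rnorm_trunc(n, 261, 10, 238, 290))
    n_sga <- round(frac * n)
    sga <- rep(FALSE, n)
    sga[sample.int(n, n_sga)] <- TRUE
    assemble_records(profiles, config, subtype, sga, ga_del)
  })
}

empty_cohort <- function() {
  cols <- c("age", "weight", "height", "nulliparous", "smoking",
            "ga_sampling", pe_markers(), "sbp", "dbp", "group", "sga",
            "ga_delivery", "sex", "birthweight", "pe_flag",
            "proteinuria_flag")
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out$group <- character(0); out$sex <- character(0)
  out$nulliparous <- out$smoking <- out$sga <- logical(0)
  out$pe_flag <- out$proteinuria_flag <- logical(0)
  out
}

#' Mark fields missing and inject below-detection-limit PlGF values
#'
#' Applies the configured missingness proportions to ADAM12, PlGF and MAP
#' (MAP missingness clears both pressures) and replaces the configured
#' fraction of PlGF values with a left-tail value below the 5.9 pg/mL
#' detection limit, so the discard rule is exercised downstream.
#'
#' @param records Cohort data frame.
#' @param config A [cohort_config()].
#' @return The records with `NA`s and below-DL values injected.
#' @export
apply_missingness <- function(records, config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- nrow(records)
  if (n == 0L) return(records)
  rates <- config$missingness_rates
  with_seed(config$seed + 4L, {
    for (field in c("adam12", "plgf", "map")) {
      r <- if (field %in% names(rates)) rates[[field]] else 0
      miss <- stats::runif(n) < r
      records[[field]][miss] <- NA_real_
      if (field == "map")
        records$sbp[miss] <- records$dbp[miss] <- NA_real_
    }
    below <- stats::runif(n) < config$plgf_below_dl_rate & !is.na(records$plgf)
    records$plgf[below] <- stats::runif(sum(below), 3.0, 5.9)
    records
  })
}

#' Generate a complete synthetic nested case-control cohort
#'
#' Controls plus EO-PE and LO-PE cases, with missingness applied and record
#' ids assigned. The generative truth (median models, shifts, noise SDs)
#' is attached as the `"truth"` attribute.
#'
#' @param config A [cohort_config()].
#' @param missingness Apply the configured missingness (default TRUE).
#' @return Cohort data frame, one row per pregnancy.
#' @export
generate_cohort <- function(config = cohort_config(), missingness = TRUE) {
  cohort <- rbind(generate_controls(config),
                  generate_cases(config, "EO-PE"),
                  generate_cases(config, "LO-PE"))
  if (missingness) cohort <- apply_missingness(cohort, config)
  cohort <- cbind(id = seq_len(nrow(cohort)), cohort)
  attr(cohort, "truth") <- list(
    marker_medians = config$marker_medians,
    case_mom_shifts = config$case_mom_shifts,
    log10_mom_sd = config$log10_mom_sd)
  cohort
}

#' Assign case status from a logistic risk model
#'
#' Each profile becomes a case with probability odds/(1+odds) from the
#' model's linear predictor — the generative counterpart of the prior-risk
#' model, enabling parameter-recovery tests.
#'
#' @param profiles Data frame with the model's covariates (`age`, `weight`,
#'   `height`, `nulliparous`, `smoking` as needed).
#' @param model A [risk_model()].
#' @param seed RNG seed.
#' @param use `"raw"` (default; the generative scale) or `"shrunk"`.
#' @return `profiles` with a logical `case` column.
#' @export
assign_outcomes_by_model <- function(profiles, model, seed = 1L,
                                     use = c("raw", "shrunk")) {
  use <- match.arg(use)
  y <- linear_predictor(model, profiles, use = use)
  p <- prior_probability(y)
  with_seed(seed, {
    profiles$case <- stats::runif(nrow(profiles)) < p
    profiles
  })
}
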