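#' Gestation-specific median models
#'
#' A `median_model` describes the expected (median) value of a serum marker
#' or MAP as a function of gestational age at sampling (days), with optional
#' maternal-weight and smoking corrections. It is the denominator of the MoM
#' (multiple of the median) transform.
#'
#' Two sub-models are kept separate:
#' * the **base model**: median value vs gestational age, fitted by weighted
#'   regression on per-completed-week medians in controls;
#' * the **weight correction**: expected MoM vs maternal weight, fitted on
#'   the MoM residuals of the base model.
#'
#' Each sub-model carries a scale dialect because screening programs mix
#' them: the base model may regress `log10(median)` on GA
#' (`"log10_ga"`: PAPP-A, fbeta-hCG, PlGF), the median itself on GA
#' (`"linear_ga"`: ADAM12), the median on reciprocal weight with no GA term
#' (`"reciprocal_weight"`: MAP as published), or be a constant
#' (`"constant"`: the refitted MAP base). The weight correction may be
#' linear or reciprocal in weight, on the direct MoM scale or on the
#' log10 MoM scale.
#'
#' @param marker One of [pe_markers()].
#' @param base_dialect `"log10_ga"`, `"linear_ga"`, `"reciprocal_weight"`
#'   or `"constant"`.
#' @param base_coef Numeric `c(intercept, slope)` (slope ignored for
#'   `"constant"`).
#' @param weight_correction `NULL`, or a list with elements `coef`
#'   (`c(intercept, slope)`), `dialect` (`"linear"` or `"reciprocal"`) and
#'   `scale` (`"direct"` or `"log10"`).
#' @param smoking_divisors Length-2 numeric `c(nonsmoker, smoker)`; the GA
#'   log10 term is divided by the relevant entry before exponentiation
#'   (the PlGF dialect). Use `c(1, 1)` for no smoking correction.
#' @param ga_range Supported GA-at-sampling range in days.
#' @return An object of class `median_model`.
#' @seealso [expected_value()], [fit_median_regression()],
#'   [apply_weight_correction()]
#' @export
median_model <- function(marker,
                         base_dialect = c("log10_ga", "linear_ga",
                                          "reciprocal_weight", "constant"),
                         base_coef,
                         weight_correction = NULL,
                         smoking_divisors = c(1, 1),
                         ga_range = c(63, 97)) {
  base_dialect <- match.arg(base_dialect)
  marker <- match.arg(marker, pe_markers())
  if (!is.numeric(base_coef) || length(base_coef) > 2L)
    pe_stop("median_model", "base_coef must be numeric of length 1 or 2")
  if (length(base_coef) == 1L) base_coef <- c(base_coef, 0)
  if (!is.null(weight_correction)) {
    stopifnot(is.list(weight_correction),
              all(c("coef", "dialect", "scale") %in% names(weight_correction)))
    weight_correction$dialect <- match.arg(weight_correction$dialect,
                                           c("linear", "reciprocal"))
    weight_correction$scale <- match.arg(weight_correction$scale,
                                         c("direct", "log10"))
  }
  if (any(smoking_divisors <= 0))
    pe_stop("median_model", "smoking divisors must be positive")
  structure(
    list(marker = marker, base_dialect = base_dialect,
         base_coef = unname(base_coef),
         weight_correction = weight_correction,
         smoking_divisors = unname(smoking_divisors),
         ga_range = ga_range),
    class = "median_model")
}

#' @export
print.median_model <- function(x, ...) {
  cat(sprintf("<median_model: %s>\n", x$marker))
  cat(sprintf("  base: %s, coef = (%.5g, %.5g)\n",
              x$base_dialect, x$base_coef[1], x$base_coef[2]))
  if (!is.null(x$weight_correction))
    cat(sprintf("  weight correction: %s/%s, coef = (%.5g, %.5g)\n",
                x$weight_correction$dialect, x$weight_correction$scale,
                x$weight_correction$coef[1], x$weight_correction$coef[2]))
  if (any(x$smoking_divisors != 1))
    cat(sprintf("  smoking divisors: %.4g (non-smoker) / %.4g (smoker)\n",
                x$smoking_divisors[1], x$smoking_divisors[2]))
  invisible(x)
}

#' Mean arterial pressure from systolic and diastolic pressure
#'
#' MAP = DP + (SP - DP)/3.
#'
#' @param systolic,diastolic Pressures in mmHg; systolic must exceed
#'   diastolic.
#' @return MAP in mmHg (vectorized).
#' @examples
#' compute_map(120, 80)   # 93.33
#' @export
compute_map <- function(systolic, diastolic) {
  ok <- is.na(systolic) | is.na(diastolic) | (systolic > diastolic & diastolic > 0)
  if (!all(ok))
    pe_stop("compute_map", "systolic must exceed diastolic (> 0); offending index ",
            paste(which(!ok), collapse = ", "))
  diastolic + (systolic - diastolic) / 3
}

#' Expected marker value under a median model
#'
#' Evaluates the base GA regression at `ga` (applying the smoking divisor
#' where the model defines one). The weight correction is *not* applied
#' here; it acts on the MoM scale via [apply_weight_correction()].
#'
#' @param model A [median_model()].
#' @param ga Gestational age at sampling in days.
#' @param weight Maternal weight in kg (used only by the
#'   `"reciprocal_weight"` dialect).
#' @param smoking Logical, smoking status.
#' @return Expected median value in the marker's native units (vectorized).
#' @examples
#' mm <- published_median_models()
#' expected_value(mm$map, ga = 88, weight = 65.5)       # 80.87 mmHg
#' expected_value(mm$plgf, ga = 88, weight = 65.5)      # 35.7 pg/mL
#' @export
expected_value <- function(model, ga, weight, smoking = FALSE) {
  stopifnot(inherits(model, "median_model"))
  n <- max(length(ga), length(weight), length(smoking))
  ga <- rep_len(ga, n); weight <- rep_len(weight, n)
  smoking <- rep_len(as.logical(smoking), n)
  if (model$base_dialect %in% c("log10_ga", "linear_ga")) {
    bad <- !is.na(ga) & (ga < model$ga_range[1] | ga > model$ga_range[2])
    if (any(bad))
      pe_stop("expected_value", "GA outside supported range [",
              model$ga_range[1], ", ", model$ga_range[2], "] days")
  }
  if (any(!is.na(weight) & weight <= 0))
    pe_stop("expected_value", "maternal weight must be positive")
  a <- model$base_coef[1]; b <- model$base_coef[2]
  switch(model$base_dialect,
    log10_ga = {
      div <- ifelse(smoking, model$smoking_divisors[2], model$smoking_divisors[1])
      10^((a + b * ga) / div)
    },
    linear_ga = a + b * ga,
    reciprocal_weight = a + b / weight,
    constant = rep_len(a, n))
}

# expected MoM for weight under a weight-correction sub-model
expected_mom_for_weight <- function(wc, weight) {
  x <- if (wc$dialect == "reciprocal") 1 / weight else weight
  f <- wc$coef[1] + wc$coef[2] * x
  if (wc$scale == "log10") 10^f else f
}

#' Raw multiple of the median
#'
#' Divides the observed value by the expected median. Values flagged below
#' the detection limit yield `NA` (they are discarded from all MoM
#' statistics).
#'
#' @param observed Observed marker values.
#' @param expected Expected medians (same length or length 1), must be
#'   positive.
#' @param below_dl Logical vector; `TRUE` marks a below-detection-limit
#'   measurement.
#' @return Numeric MoM vector with `NA` for missing or below-DL entries.
#' @export
compute_mom <- function(observed, expected, below_dl = FALSE) {
  n <- max(length(observed), length(expected))
  observed <- rep_len(observed, n); expected <- rep_len(expected, n)
  below_dl <- rep_len(as.logical(below_dl), n)
  if (any(!is.na(expected) & expected <= 0))
    pe_stop("compute_mom", "expected median must be positive")
  out <- observed / expected
  out[below_dl] <- NA_real_
  out
}

#' Maternal-weight correction of MoM values
#'
#' Divides each raw MoM by the expected MoM for the record's maternal
#' weight under the model's weight-correction sub-model. Markers without a
#' weight correction (PlGF) are returned unchanged. The correction is not
#' idempotent; callers track corrected status (see [compute_cohort_moms()]).
#'
#' @param mom Raw MoM vector.
#' @param model A [median_model()] whose `weight_correction` is used.
#' @param weight Maternal weight in kg.
#' @return Corrected MoM vector.
#' @export
apply_weight_correction <- function(mom, model, weight) {
  stopifnot(inherits(model, "median_model"))
  if (is.null(model$weight_correction)) return(mom)
  mom / expected_mom_for_weight(model$weight_correction, weight)
}

#' Fit the gestational-age median regression and weight correction
#'
#' Reproduces the two-stage normal-median construction used in first-
#' trimester screening: (1) the median marker value is computed for each
#' completed gestational week in controls and regressed on GA, weighting
#' each week by the number of women tested; (2) raw MoMs from stage 1 are
#' regressed on maternal weight (log10 MoM on weight or 1/weight) and the
#' fitted curve becomes the weight-correction denominator. Fitting the
#' weight correction on the log10 scale keeps the correction
#' median-unbiased under multiplicative noise.
#'
#' @param values Observed marker values (controls).
#' @param ga GA at sampling, days.
#' @param weight Maternal weight, kg.
#' @param smoking Logical smoking status (used by the smoking-divisor
#'   refit for markers with `smoking = TRUE`).
#' @param marker Marker id, one of [pe_markers()].
#' @param base_dialect Base-model scale; defaults per marker
#'   (`log10_ga` for PAPP-A/fbeta-hCG/PlGF, `linear_ga` for ADAM12,
#'   `constant` for MAP).
#' @param weight_dialect `"linear"`, `"reciprocal"` or `"none"`; defaults
#'   per marker (reciprocal for PAPP-A and MAP, linear for fbeta-hCG and
#'   ADAM12, none for PlGF).
#' @param smoking_correction If `TRUE` (default for PlGF), the log10 GA
#'   term divisor is estimated separately for smokers from the median
#'   log10 MoM shift.
#' @param min_per_week Minimum controls per completed week for that week to
#'   enter the regression.
#' @return A fitted [median_model()].
#' @export
fit_median_regression <- function(values, ga, weight, smoking = FALSE,
                                  marker,
                                  base_dialect = NULL,
                                  weight_dialect = NULL,
                                  smoking_correction = NULL,
                                  min_per_week = 5L) {
  marker <- match.arg(marker, pe_markers())
  defaults <- list(
    papp_a = list(base = "log10_ga", wt = "reciprocal", smk = FALSE),
    fb_hcg = list(base = "log10_ga", wt = "linear", smk = FALSE),
    adam12 = list(base = "linear_ga", wt = "linear", smk = FALSE),
    plgf   = list(base = "log10_ga", wt = "none", smk = TRUE),
    map    = list(base = "constant", wt = "reciprocal", smk = FALSE))[[marker]]
  if (is.null(base_dialect)) base_dialect <- defaults$base
  if (is.null(weight_dialect)) weight_dialect <- defaults$wt
  if (is.null(smoking_correction)) smoking_correction <- defaults$smk

  keep <- !is.na(values) & !is.na(ga) & !is.na(weight)
  values <- values[keep]; ga <- ga[keep]; weight <- weight[keep]
  smoking <- rep_len(as.logical(smoking), length(keep))[keep]

  week <- floor(ga / 7)
  tab <- table(week)
  good_weeks <- as.integer(names(tab))[tab >= min_per_week]
  if (length(good_weeks) < 2L)
    pe_stop("fit_median_regression",
            "need >= 2 completed weeks with >= ", min_per_week,
            " controls; got ", length(good_weeks))
  in_week <- week %in% good_weeks
  wk_med <- tapply(values[in_week], week[in_week], stats::median)
  wk_ga  <- tapply(ga[in_week], week[in_week], stats::median)
  wk_n   <- as.numeric(table(week[in_week]))

  base_coef <- switch(base_dialect,
    log10_ga = stats::coef(stats::lm(log10(wk_med) ~ wk_ga, weights = wk_n)),
    linear_ga = stats::coef(stats::lm(wk_med ~ wk_ga, weights = wk_n)),
    constant = c(sum(wk_med * wk_n) / sum(wk_n), 0),
    pe_stop("fit_median_regression", "unsupported base dialect for refit: ",
            base_dialect))
  base_coef <- unname(base_coef)

  model <- median_model(marker, base_dialect, base_coef,
                        weight_correction = NULL)

  # smoking divisors: one per stratum, from the stratum's median log10 MoM
  # around the pooled base fit, expressed in the divide-the-GA-term dialect
  # (this is why published non-smoker divisors sit near, not at, 1: the
  # pooled weekly medians absorb part of the smoker shift)
  if (smoking_correction && base_dialect == "log10_ga") {
    mom0 <- values / expected_value(model, ga, weight, smoking = FALSE)
    L <- stats::median(base_coef[1] + base_coef[2] * ga) # typical GA term
    # stratum expected value = 10^(L + d) = 10^(L / div) => div = L/(L + d)
    div_for <- function(sel) {
      if (!any(sel)) return(1)
      L / (L + stats::median(log10(mom0[sel])))
    }
    model$smoking_divisors <- c(div_for(!smoking), div_for(smoking))
  }

  if (weight_dialect != "none") {
    mom <- values / expected_value(model, ga, weight, smoking)
    x <- if (weight_dialect == "reciprocal") 1 / weight else weight
    wc_coef <- unname(stats::coef(stats::lm(log10(mom) ~ x)))
    model$weight_correction <- list(coef = wc_coef, dialect = weight_dialect,
                                    scale = "log10")
  }
  model
}

#' One-pass trimming of outliers around the median
#'
#' Removes values farther than `k` standard deviations (estimated once, on
#' the full sample) from the sample median.
#'
#' @param x Numeric vector (typically log10 MoMs), length >= 10.
#' @param k SD multiple, default 3.
#' @return The retained subset of `x`.
#' @export
trim_outliers <- function(x, k = 3) {
  x <- x[!is.na(x)]
  if (length(x) < 10L)
    pe_stop("trim_outliers", "need >= 10 non-missing values")
  s <- stats::sd(x)
  if (s == 0) return(x)
  x[abs(x - stats::median(x)) <= k * s]
}

#' Per-group Gaussian model of log10 MoMs
#'
#' Fits, for one outcome group, the mean and SD of log10 corrected MoM per
#' marker (after one-pass 3-SD outlier trimming) and the pairwise marker
#' correlation matrix on complete pairs. These parameters drive the
#' Gaussian likelihood ratios.
#'
#' @param log10_moms Data frame or matrix of log10 corrected MoMs, one
#'   column per marker, `NA` for missing/below-DL.
#' @param group Group label, one of `"unaffected"`, `"EO-PE"`, `"LO-PE"`.
#' @param trim_k SD multiple for outlier trimming (3; `Inf` disables).
#' @return An object of class `gaussian_marker_model` with elements
#'   `group`, `mean`, `sd`, `cor`, `n`.
#' @export
fit_group_distribution <- function(log10_moms,
                                   group = c("unaffected", "EO-PE", "LO-PE"),
                                   trim_k = 3) {
  group <- match.arg(group)
  m <- as.matrix(as.data.frame(log10_moms))
  if (is.null(colnames(m)))
    pe_stop("fit_group_distribution", "log10_moms must have marker columns")
  mu <- sdv <- nn <- stats::setNames(numeric(ncol(m)), colnames(m))
  for (j in colnames(m)) {
    xj <- trim_outliers(m[, j], k = trim_k)
    nn[j] <- length(xj)
    mu[j] <- mean(xj)
    sdv[j] <- stats::sd(xj)
    if (!is.finite(sdv[j]) || sdv[j] <= 0)
      pe_stop("fit_group_distribution", "degenerate SD for marker ", j)
  }
  cm <- stats::cor(m, use = "pairwise.complete.obs")
  cm[!is.finite(cm)] <- 0
  structure(list(group = group, mean = mu, sd = sdv, cor = cm, n = nn),
            class = "gaussian_marker_model")
}

#' @export
print.gaussian_marker_model <- function(x, ...) {
  cat(sprintf("<gaussian_marker_model: %s>\n", x$group))
  print(round(data.frame(mean = x$mean, sd = x$sd, n = x$n), 4))
  invisible(x)
}

#' Published median-equation fixtures for PlGF and MAP
#'
#' Literal reference equations for the two markers whose printed constants
#' evaluate plausibly: log10 expected PlGF = (0.4999 + 0.0118 x GA days)
#' divided by 0.991 (non-smokers) or 1.33 (smokers), and expected MAP =
#' 101.052 - 1321.65 / weight(kg). The remaining markers have no literal
#' fixture; their medians are refitted on the cohort at hand (see
#' [fit_median_regression()] and [default_median_models()]).
#'
#' @return Named list of [median_model()] objects (`plgf`, `map`).
#' @export
published_median_models <- function() {
  list(
    plgf = median_model("plgf", "log10_ga", c(0.4999, 0.0118),
                        smoking_divisors = c(0.991, 1.33)),
    map = median_model("map", "reciprocal_weight", c(101.052, -1321.65)))
}

#' Default generative median models
#'
#' The full five-marker median-model set used as generative truth by the
#' synthetic cohort generator: published PlGF and MAP equations verbatim,
#' plus reconstructed GA/weight sub-models for PAPP-A, fbeta-hCG and ADAM12
#' whose weight corrections are anchored to evaluate to ~1 at the control
#' median weight (65.5 kg).
#'
#' @return Named list of [median_model()] objects, one per marker.
#' @export
default_median_models <- function() {
  pub <- published_median_models()
  list(
    papp_a = median_model("papp_a", "log10_ga", c(0.52405, 0.03234),
                          weight_correction = list(
                            coef = c(-0.19564, 76.2423),
                            dialect = "reciprocal", scale = "direct")),
    fb_hcg = median_model("fb_hcg", "log10_ga", c(2.64423, -0.01236),
                          weight_correction = list(
                            coef = c(1.2947, -0.00429),
                            dialect = "linear", scale = "direct")),
    adam12 = median_model("adam12", "linear_ga", c(-493.422, 10.6898),
                          weight_correction = list(
                            coef = c(1.29637, -0.00442),
                            dialect = "linear", scale = "direct")),
    plgf = pub$plgf,
    map = pub$map)
}

#' Corrected log10 MoMs for a whole cohort
#'
#' Fits (or takes) per-marker median models on the control subset and
#' returns raw, corrected and log10 corrected MoMs for every record, with
#' per-marker exclusion flags (missing, below detection limit).
#'
#' @param cohort A cohort data frame (see [read_cohort_csv()] for the
#'   column dictionary).
#' @param models Optional named list of [median_model()]s; if `NULL`
#'   (default) models are refitted on the rows with `group == "control"`.
#' @param markers Markers to process, default all.
#' @param truncate Optional length-2 numeric; if supplied, corrected MoMs
#'   are clamped to this range before the log transform (off by default).
#' @return A list with `mom` (data frame of corrected MoMs), `log10_mom`,
#'   `flags` (per-marker status: `"ok"`, `"missing"`, `"below_dl"`) and
#'   `models` (the median models used).
#' @export
compute_cohort_moms <- function(cohort, models = NULL,
                                markers = pe_markers(),
                                truncate = NULL) {
  markers <- match.arg(markers, pe_markers(), several.ok = TRUE)
  dl <- pe_detection_limits()
  if (is.null(models)) {
    ctl <- cohort[cohort$group == "control", , drop = FALSE]
    if (nrow(ctl) == 0L)
      pe_stop("compute_cohort_moms", "no control rows to fit median models on")
    models <- lapply(stats::setNames(markers, markers), function(mk) {
      fit_median_regression(ctl[[mk]], ctl$ga_sampling, ctl$weight,
                            ctl$smoking, marker = mk)
    })
  }
  mom <- log10_mom <- as.data.frame(
    matrix(NA_real_, nrow(cohort), length(markers),
           dimnames = list(NULL, markers)))
  flags <- as.data.frame(
    matrix("ok", nrow(cohort), length(markers),
           dimnames = list(NULL, markers)), stringsAsFactors = FALSE)
  for (mk in markers) {
    obs <- cohort[[mk]]
    below <- !is.na(obs) & !is.na(dl[mk]) & obs < dl[mk]
    flags[[mk]][is.na(obs)] <- "missing"
    flags[[mk]][below] <- "below_dl"
    expv <- expected_value(models[[mk]], cohort$ga_sampling, cohort$weight,
                           cohort$smoking)
    raw <- compute_mom(obs, expv, below_dl = below)
    cor_mom <- apply_weight_correction(raw, models[[mk]], cohort$weight)
    if (!is.null(truncate))
      cor_mom <- pmin(pmax(cor_mom, truncate[1]), truncate[2])
    mom[[mk]] <- cor_mom
    log10_mom[[mk]] <- log10(cor_mom)
  }
  list(mom = mom, log10_mom = log10_mom, flags = flags, models = models)
}
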