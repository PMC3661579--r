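#' Maternal-characteristics prior-risk model
#'
#' A logistic model of PE risk from maternal characteristics. Each term
#' carries the raw (maximum-likelihood) coefficient and the shrunk
#' coefficient (raw times the shrinkage factor `s`); the linear predictor
#' uses the shrunk scale by default. Weight enters through its natural
#' logarithm.
#'
#' @param outcome `"EO-PE"` or `"LO-PE"`.
#' @param terms Data frame with columns `variable` (one of `age`,
#'   `ln_weight`, `height`, `nulliparity`, `smoking`), `transform`
#'   (`"identity"` or `"log"`), `raw`, `shrunk`.
#' @param intercept_raw,intercept_shrunk Intercepts on the two scales.
#' @param shrinkage Shrinkage factor `s`.
#' @param chi2,df Model chi-square (from the log-likelihood statistic) and
#'   number of estimated parameters (including the intercept).
#' @return Object of class `risk_model`.
#' @export
risk_model <- function(outcome = c("EO-PE", "LO-PE"), terms,
                       intercept_raw, intercept_shrunk,
                       shrinkage = 1, chi2 = NA_real_, df = NA_real_) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(terms),
            all(c("variable", "transform", "raw", "shrunk") %in% names(terms)))
  structure(list(outcome = outcome, terms = terms,
                 intercept_raw = intercept_raw,
                 intercept_shrunk = intercept_shrunk,
                 shrinkage = shrinkage, chi2 = chi2, df = df),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model: %s>  s = %.3g, chi2 = %.4g, df = %s\n",
              x$outcome, x$shrinkage, x$chi2, x$df))
  tab <- rbind(data.frame(variable = "(intercept)", transform = "",
                          raw = x$intercept_raw, shrunk = x$intercept_shrunk),
               x$terms[c("variable", "transform", "raw", "shrunk")])
  print(tab, row.names = FALSE)
  invisible(x)
}

# covariate design column for one model variable
risk_covariate <- function(variable, profiles) {
  v <- switch(variable,
    age = profiles$age,
    ln_weight = log(profiles$weight),
    height = profiles$height,
    nulliparity = as.numeric(profiles$nulliparous),
    smoking = as.numeric(profiles$smoking),
    pe_stop("risk_model", "unknown model variable: ", variable))
  if (is.null(v) || anyNA(v))
    pe_stop("linear_predictor", "missing covariate '", variable,
            "' for record(s) ",
            paste(utils::head(which(is.na(v) | rep(is.null(v), length(v))), 5),
                  collapse = ", "))
  v
}

#' Linear predictor of a risk model
#'
#' Y = intercept + sum of coefficient x transformed covariate.
#'
#' @param model A [risk_model()].
#' @param profiles Data frame with `age`, `weight`, `height`,
#'   `nulliparous`, `smoking` as required by the model's terms.
#' @param use Coefficient scale, `"shrunk"` (default) or `"raw"`.
#' @return Numeric vector Y (log-odds).
#' @examples
#' m <- reference_prior_model("EO-PE")
#' p <- data.frame(age = 33, weight = 65, height = 165,
#'                 nulliparous = TRUE, smoking = FALSE)
#' linear_predictor(m, p)       # -1.469
#' @export
linear_predictor <- function(model, profiles, use = c("shrunk", "raw")) {
  use <- match.arg(use)
  stopifnot(inherits(model, "risk_model"))
  y <- rep(if (use == "shrunk") model$intercept_shrunk else model$intercept_raw,
           nrow(profiles))
  for (i in seq_len(nrow(model$terms))) {
    beta <- model$terms[[use]][i]
    y <- y + beta * risk_covariate(model$terms$variable[i], profiles)
  }
  y
}

#' Risk from log-odds
#'
#' risk = odds / (1 + odds) with odds = exp(Y).
#'
#' @param y Linear predictor (log-odds).
#' @return Probability in (0, 1).
#' @export
prior_probability <- function(y) stats::plogis(y)

#' Shrinkage factor from the model chi-square
#'
#' s = (chi2 - (df - 1)) / chi2, floored at 0, with `df` the number of
#' estimated parameters (including the intercept) and `chi2` the model
#' chi-square from the log-likelihood statistic. Applied multiplicatively
#' to all coefficients to adjust for overfitting.
#'
#' @param chi2 Model chi-square, > 0.
#' @param df Number of estimated parameters.
#' @return Shrinkage factor in [0, 1].
#' @export
shrinkage_factor <- function(chi2, df) {
  if (any(chi2 <= 0)) pe_stop("shrinkage_factor", "chi2 must be positive")
  pmax((chi2 - (df - 1)) / chi2, 0)
}

#' Apply a shrinkage factor to a fitted model
#'
#' Multiplies every coefficient and the intercept by `s` and records `s`.
#'
#' @param model A [risk_model()] with raw coefficients.
#' @param s Shrinkage factor; default recomputed from the model's
#'   `chi2`/`df`.
#' @return The model with shrunk coefficients set.
#' @export
apply_shrinkage <- function(model, s = NULL) {
  if (is.null(s)) s <- shrinkage_factor(model$chi2, model$df)
  model$terms$shrunk <- s * model$terms$raw
  model$intercept_shrunk <- s * model$intercept_raw
  model$shrinkage <- s
  model
}

# case/control analysis frame for one outcome: that outcome's cases vs
# controls (the other case group is set aside), mean imputation of missing
# continuous covariates
prior_frame <- function(cohort, outcome,
                        candidates = c("age", "ln_weight", "height",
                                       "nulliparity", "smoking")) {
  keep <- cohort$group %in% c("control", outcome)
  d <- cohort[keep, , drop = FALSE]
  y <- as.integer(d$group == outcome)
  X <- data.frame(row.names = seq_along(y))
  for (v in candidates) {
    x <- switch(v,
      age = d$age, ln_weight = log(d$weight), height = d$height,
      nulliparity = as.numeric(d$nulliparous),
      smoking = as.numeric(d$smoking))
    if (anyNA(x)) x[is.na(x)] <- mean(x, na.rm = TRUE)
    X[[v]] <- x
  }
  cbind(y = y, X)
}

#' Univariate odds-ratio screen of maternal characteristics
#'
#' Single-covariate logistic fits for each candidate variable, with Wald
#' 95% confidence intervals. Complete separation is flagged and the OR
#' reported as non-finite with a warning.
#'
#' @param cohort Cohort data frame.
#' @param outcome `"EO-PE"` or `"LO-PE"`.
#' @param candidates Candidate variable names.
#' @return Data frame: `variable`, `or`, `ci_lo`, `ci_hi`, `p`,
#'   `separation`.
#' @export
univariate_screen <- function(cohort, outcome = c("EO-PE", "LO-PE"),
                              candidates = c("age", "ln_weight", "height",
                                             "nulliparity", "smoking")) {
  outcome <- match.arg(outcome)
  d <- prior_frame(cohort, outcome, candidates)
  if (sum(d$y) < 10L)
    pe_stop("univariate_screen", "need >= 10 cases; got ", sum(d$y))
  rows <- lapply(candidates, function(v) {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(v, "y"), data = d, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    beta <- sm[v, "Estimate"]; se <- sm[v, "Std. Error"]
    sep <- !fit$converged || se > 100 || abs(beta) > 20
    if (sep) {
      warning("separation for variable '", v, "'; OR non-finite",
              call. = FALSE)
      or <- sign(beta) * Inf; lo <- hi <- NA_real_; p <- NA_real_
      if (or < 0) or <- 0
    } else {
      or <- exp(beta)
      lo <- exp(beta - 1.96 * se); hi <- exp(beta + 1.96 * se)
      p <- sm[v, "Pr(>|z|)"]
    }
    data.frame(variable = v, or = or, ci_lo = lo, ci_hi = hi, p = p,
               separation = sep)
  })
  do.call(rbind, rows)
}

#' Backward-elimination logistic prior-risk model
#'
#' Fits the full logistic model of case status on the candidate maternal
#' characteristics, then iteratively removes the least significant term
#' with Wald p above `removal_alpha` until all retained terms are
#' significant. The model chi-square (null minus residual deviance) and
#' parameter count feed [shrinkage_factor()]; the returned model carries
#' both raw and shrunk coefficients.
#'
#' @param cohort Cohort data frame.
#' @param outcome `"EO-PE"` or `"LO-PE"`.
#' @param candidates Candidate variables (weight enters as `ln_weight`).
#' @param removal_alpha Retention threshold on the Wald p-value (0.05).
#' @return A [risk_model()].
#' @export
fit_logistic_backward <- function(cohort, outcome = c("EO-PE", "LO-PE"),
                                  candidates = c("age", "ln_weight", "height",
                                                 "nulliparity", "smoking"),
                                  removal_alpha = 0.05) {
  outcome <- match.arg(outcome)
  d <- prior_frame(cohort, outcome, candidates)
  vars <- candidates
  repeat {
    form <- if (length(vars)) stats::reformulate(vars, "y") else y ~ 1
    fit <- stats::glm(form, data = d, family = stats::binomial())
    if (!length(vars)) break
    sm <- summary(fit)$coefficients
    pv <- sm[vars, "Pr(>|z|)", drop = TRUE]
    worst <- which.max(pv)
    if (pv[worst] <= removal_alpha) break
    vars <- vars[-worst]
  }
  if (!length(vars))
    warning("no term survived backward elimination; intercept-only model",
            call. = FALSE)
  beta <- stats::coef(fit)
  chi2 <- fit$null.deviance - fit$deviance
  df <- length(beta) # parameters estimated, intercept included
  s <- if (chi2 > 0) shrinkage_factor(chi2, df) else 1
  terms <- data.frame(
    variable = vars,
    transform = ifelse(vars == "ln_weight", "log", "identity"),
    raw = if (length(vars)) unname(beta[vars]) else numeric(0),
    shrunk = if (length(vars)) unname(beta[vars]) * s else numeric(0))
  risk_model(outcome, terms,
             intercept_raw = unname(beta[1]),
             intercept_shrunk = unname(beta[1]) * s,
             shrinkage = s, chi2 = chi2, df = df)
}

#' Built-in reference prior-risk models
#'
#' The shrunk-coefficient prior-risk equations used as fixtures throughout
#' the package (shrinkage factor 0.94 for both outcomes):
#'
#' * EO-PE: Y = -6.790 - 0.119 x height(cm) + 4.8565 x ln weight(kg)
#'   + 1.845 x nulliparity + 0.086 x age(y) + 1.353 x smoking
#' * LO-PE: Y = -14.374 + 2.300 x ln weight(kg) + 1.303 x nulliparity
#'   + 0.068 x age(y)
#'
#' Raw coefficients are recovered by dividing by 0.94.
#'
#' @param outcome `"EO-PE"` or `"LO-PE"`.
#' @return A [risk_model()].
#' @export
reference_prior_model <- function(outcome = c("EO-PE", "LO-PE")) {
  outcome <- match.arg(outcome)
  s <- 0.94
  if (outcome == "EO-PE") {
    shrunk <- c(height = -0.119, ln_weight = 4.8565, nulliparity = 1.845,
                age = 0.086, smoking = 1.353)
    intercept <- -6.790
  } else {
    shrunk <- c(ln_weight = 2.300, nulliparity = 1.303, age = 0.068)
    intercept <- -14.374
  }
  terms <- data.frame(
    variable = names(shrunk),
    transform = ifelse(names(shrunk) == "ln_weight", "log", "identity"),
    raw = unname(shrunk) / s,
    shrunk = unname(shrunk))
  risk_model(outcome, terms, intercept_raw = intercept / s,
             intercept_shrunk = intercept, shrinkage = s)
}

#' Reference univariate odds ratios
#'
#' Multivariate odds ratios of the maternal-characteristics prior-risk
#' models, used in consistency checks against the shrunk reference
#' equations (shrunk coefficient = 0.94 x ln OR).
#'
#' @param outcome `"EO-PE"` or `"LO-PE"`.
#' @return Named numeric vector of odds ratios.
#' @export
reference_odds_ratios <- function(outcome = c("EO-PE", "LO-PE")) {
  outcome <- match.arg(outcome)
  if (outcome == "EO-PE")
    c(age = 1.095, ln_weight = 175.634, height = 0.881, nulliparity = 7.1,
      smoking = 4.210)
  else
    c(age = 1.075, ln_weight = 11.437, nulliparity = 3.981)
}
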