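#' Univariate Gaussian likelihood ratio
#'
#' LR = N(x; affected mean, affected SD) / N(x; unaffected mean,
#' unaffected SD), evaluated on the log10 MoM scale.
#'
#' @param x log10 MoM value(s).
#' @param mean_aff,sd_aff Affected-group parameters.
#' @param mean_un,sd_un Unaffected-group parameters.
#' @return Likelihood ratio (vectorized).
#' @export
gaussian_lr <- function(x, mean_aff, sd_aff, mean_un, sd_un) {
  if (any(c(sd_aff, sd_un) <= 0))
    pe_stop("gaussian_lr", "SDs must be positive")
  exp(stats::dnorm(x, mean_aff, sd_aff, log = TRUE) -
        stats::dnorm(x, mean_un, sd_un, log = TRUE))
}

# multivariate normal log density via Cholesky (few markers, PD checked)
mvn_logdens <- function(x, mean, sigma) {
  ch <- tryCatch(chol(sigma), error = function(e)
    pe_stop("multivariate_lr", "covariance matrix not positive definite"))
  d <- length(mean)
  z <- backsolve(ch, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# covariance matrix of a gaussian_marker_model over a marker subset
gmm_cov <- function(model, markers, diagonal = FALSE) {
  s <- model$sd[markers]
  R <- if (diagonal) diag(length(markers)) else model$cor[markers, markers, drop = FALSE]
  diag(s, length(s)) %*% R %*% diag(s, length(s))
}

#' Correlation-aware multivariate likelihood ratio
#'
#' Ratio of multivariate normal densities of a log10 MoM vector under the
#' affected vs unaffected [fit_group_distribution()] models. With a
#' diagonal covariance this reduces exactly to the product of the
#' univariate [gaussian_lr()] values.
#'
#' @param x Named numeric vector of log10 MoMs.
#' @param affected,unaffected `gaussian_marker_model` objects.
#' @param markers Marker subset; default the names of `x`.
#' @param diagonal If TRUE, correlations are ignored.
#' @return Likelihood ratio (scalar).
#' @export
multivariate_lr <- function(x, affected, unaffected, markers = names(x),
                            diagonal = FALSE) {
  if (is.null(markers) || !length(markers))
    pe_stop("multivariate_lr", "marker subset must be non-empty")
  x <- x[markers]
  if (anyNA(x))
    pe_stop("multivariate_lr", "x must be complete for the marker subset")
  la <- mvn_logdens(x, affected$mean[markers],
                    gmm_cov(affected, markers, diagonal))
  lu <- mvn_logdens(x, unaffected$mean[markers],
                    gmm_cov(unaffected, markers, diagonal))
  exp(la - lu)
}

#' Posterior risk from prior risk and likelihood ratio
#'
#' posterior odds = prior odds x LR;
#' posterior = odds / (1 + odds).
#'
#' @param prior Prior probability in (0, 1).
#' @param lr Likelihood ratio, > 0.
#' @return Posterior probability (vectorized).
#' @export
posterior_risk <- function(prior, lr) {
  if (any(prior <= 0 | prior >= 1, na.rm = TRUE))
    pe_stop("posterior_risk", "prior must be in (0,1)")
  if (any(lr <= 0, na.rm = TRUE))
    pe_stop("posterior_risk", "lr must be positive")
  odds <- prior / (1 - prior) * lr
  odds / (1 + odds)
}

#' Screen a cohort: per-record posterior risks
#'
#' Combines the maternal-characteristics prior with per-marker Gaussian
#' likelihood ratios on corrected log10 MoMs. A missing or below-DL
#' marker contributes LR = 1 (it is dropped from the record's panel);
#' log10 MoMs beyond `winsor_k` unaffected-group SDs are winsorized before
#' density evaluation.
#'
#' @param cohort Cohort data frame.
#' @param prior_model A [risk_model()], or `NULL` for a marker-only screen
#'   (flat prior 0.1, ranking then depends only on the LR).
#' @param affected,unaffected `gaussian_marker_model`s for the target
#'   outcome and the controls.
#' @param markers Marker subset to use; `character(0)` gives a prior-only
#'   screen.
#' @param moms Optional precomputed result of [compute_cohort_moms()]
#'   (recomputed from the cohort's controls when `NULL`).
#' @param lr_mode `"product"` (univariate LRs multiplied; default) or
#'   `"multivariate"` (correlation-aware; records with an incomplete
#'   marker subset fall back to the product over observed markers).
#' @param winsor_k Winsorization bound in unaffected SDs (4; `Inf`
#'   disables).
#' @return Data frame: `id`, `outcome`, `prior`, `lr`, `posterior`,
#'   `markers_used`.
#' @export
screen_cohort <- function(cohort, prior_model, affected, unaffected,
                          markers = pe_markers(), moms = NULL,
                          lr_mode = c("product", "multivariate"),
                          winsor_k = 4) {
  lr_mode <- match.arg(lr_mode)
  if (nrow(cohort) == 0L)
    return(data.frame(id = integer(0), outcome = character(0),
                      prior = numeric(0), lr = numeric(0),
                      posterior = numeric(0), markers_used = character(0)))
  outcome <- if (is.null(prior_model)) affected$group else prior_model$outcome
  prior <- if (is.null(prior_model)) rep(0.1, nrow(cohort))
           else prior_probability(linear_predictor(prior_model, cohort))
  if (length(markers)) {
    markers <- match.arg(markers, pe_markers(), several.ok = TRUE)
    lm10 <- if (is.null(moms)) compute_cohort_moms(cohort)$log10_mom
            else moms$log10_mom
    x <- as.matrix(lm10[, markers, drop = FALSE])
    # winsorize on the unaffected scale
    if (is.finite(winsor_k)) {
      for (mk in markers) {
        lo <- unaffected$mean[mk] - winsor_k * unaffected$sd[mk]
        hi <- unaffected$mean[mk] + winsor_k * unaffected$sd[mk]
        x[, mk] <- pmin(pmax(x[, mk], lo), hi)
      }
    }
    lr <- numeric(nrow(cohort))
    used <- character(nrow(cohort))
    for (i in seq_len(nrow(cohort))) {
      xi <- x[i, ]
      present <- markers[!is.na(xi)]
      used[i] <- paste(present, collapse = "+")
      if (!length(present)) { lr[i] <- 1; next }
      if (lr_mode == "multivariate" && length(present) > 1L) {
        lr[i] <- multivariate_lr(xi, affected, unaffected, markers = present)
      } else {
        lr[i] <- prod(gaussian_lr(xi[present],
                                  affected$mean[present], affected$sd[present],
                                  unaffected$mean[present], unaffected$sd[present]))
      }
    }
  } else {
    lr <- rep(1, nrow(cohort))
    used <- rep("", nrow(cohort))
  }
  data.frame(id = cohort$id, outcome = outcome, prior = prior, lr = lr,
             posterior = posterior_risk(prior, lr), markers_used = used)
}
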