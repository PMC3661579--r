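# Independent brute-force oracles used across test files. These stay
# deliberately naive (pairwise loops, threshold enumeration) so they share
# no code path with the package implementation.

# DR at fixed FPR by enumerating every candidate threshold
brute_force_dr <- function(case_risks, control_risks, target_fpr) {
  thresholds <- c(sort(unique(c(case_risks, control_risks))), Inf)
  best <- 0
  for (t in thresholds) {
    fpr <- mean(control_risks >= t)
    if (fpr <= target_fpr) best <- max(best, mean(case_risks >= t))
  }
  best
}

# AUC by explicit pair counting (ties count one half)
brute_force_auc <- function(case_risks, control_risks) {
  s <- 0
  for (a in case_risks) for (b in control_risks)
    s <- s + (a > b) + 0.5 * (a == b)
  s / (length(case_risks) * length(control_risks))
}

# bivariate normal density from the explicit formula
bvn_density <- function(x, mu, sd, rho) {
  z1 <- (x[1] - mu[1]) / sd[1]; z2 <- (x[2] - mu[2]) / sd[2]
  q <- (z1^2 - 2 * rho * z1 * z2 + z2^2) / (1 - rho^2)
  exp(-q / 2) / (2 * pi * sd[1] * sd[2] * sqrt(1 - rho^2))
}

# small control-only cohort straight from the generator
small_control_cohort <- function(n = 400, seed = 42) {
  generate_cohort(cohort_config(n_controls = n, n_eo = 0L, n_lo = 0L,
                                seed = seed), missingness = FALSE)
}
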