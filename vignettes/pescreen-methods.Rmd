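---
title: "Methods: first-trimester preeclampsia screening in pescreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: first-trimester preeclampsia screening in pescreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pescreen)
```

## The screening problem

Preeclampsia (PE) — gestational hypertension with proteinuria after 20
weeks — affects roughly 2% of pregnancies. Early-onset PE (EO-PE,
delivery before 34 completed weeks) is the clinically severe form,
associated with impaired placentation and fetal growth restriction;
late-onset PE (LO-PE, delivery at or after 34 weeks) is more common and
milder. First-trimester screening tries to flag high-risk pregnancies at
9–13 weeks, when preventive low-dose aspirin is still effective, using
three information sources:

1. **maternal characteristics** (age, weight, height, parity, smoking),
2. **mean arterial pressure** (MAP = DP + (SP − DP)/3),
3. **placenta-derived serum markers**: PAPP-A (mU/L), free β-hCG (ng/mL),
   ADAM12 (ng/mL) and PlGF (pg/mL).

`pescreen` implements the full risk pipeline — MoM normalization, a
logistic prior-risk model with shrinkage, Gaussian likelihood ratios, and
detection-rate evaluation — together with a seeded synthetic
nested case-control generator (500 controls, 68 EO-PE, 99 LO-PE by
default) that stands in for patient data, which is not publicly
available for cohorts of this kind.

## MoM normalization

Raw marker levels vary strongly with gestational age (GA) and maternal
covariates, so each measurement is expressed as a multiple of the median
(MoM): the observed value divided by the median expected for that GA,
then corrected for maternal weight (and smoking for PlGF). The expected
medians are built in two weighted regression stages on controls
(`fit_median_regression()`):

* **Base model.** The median concentration is computed per completed
  gestational week (week = ⌊GA days / 7⌋, weeks with fewer than 5
  controls dropped) and regressed on GA in days, each week weighted by
  its count. The scale dialect is per marker: `log10(median) ~ GA` for
  PAPP-A, fβ-hCG and PlGF; `median ~ GA` for ADAM12; a weighted constant
  for MAP, whose expected value depends on weight only.
* **Weight correction.** Raw MoMs from stage 1 are regressed on weight —
  `log10(MoM) ~ weight` (fβ-hCG, ADAM12) or `log10(MoM) ~ 1/weight`
  (PAPP-A, MAP) — and each MoM is divided by `10^fit`. Fitting on the
  log10 scale keeps the correction *median*-unbiased under
  multiplicative noise: an ordinary least-squares fit of the raw MoM
  would estimate the conditional mean, which exceeds the median of a
  log-normal by `exp(σ²/2)` and would push the median corrected MoM
  noticeably below 1 (≈ 6% at a log10 SD of 0.25).
* **Smoking divisors (PlGF).** The GA log10 term is divided by a
  per-stratum constant estimated from each stratum's median log10 MoM
  around the pooled base fit. Because pooled weekly medians absorb part
  of the smoker deficit, the non-smoker divisor lands near — but not
  exactly at — 1, which is also why published divisor pairs of this form
  look asymmetric (e.g. 0.991 vs 1.33).

Two published equations evaluate plausibly and ship verbatim as fixtures
(`published_median_models()`): log10 expected PlGF =
(0.4999 + 0.0118·GA)/0.991 (non-smokers; /1.33 smokers) and expected MAP
= 101.052 − 1321.65/weight. The quotient-style constants printed for the
other three markers are not literally evaluable (their denominators
evaluate near 0 at typical weights), so the default pipeline *refits*
both sub-models on the cohort at hand — reproducing the procedure rather
than trusting garbled constants. The generative defaults in
`default_median_models()` reconstruct plausible sub-models from those
printed constants (weight-correction intercepts anchored so the
correction is ≈ 1 at the control median weight of 65.5 kg; the ADAM12 GA
model treated as direct-scale linear, which is the only reading that
yields concentrations in the physiologic 180–540 ng/mL range).

Assay detection limits are PAPP-A 5.0 mU/L, fβ-hCG 1.5 ng/mL, ADAM12
6.0 ng/mL, PlGF 5.9 pg/mL; measurements below the limit are flagged and
discarded from all MoM statistics. Records missing one marker still
contribute to the others (pairwise deletion). Log10 MoM group
distributions (`fit_group_distribution()`) use a single-pass trim of
values beyond 3 SD of the median, with the SD estimated once on the full
sample; the procedure is deliberately non-iterative.

## Prior risk from maternal characteristics

Case status (per outcome, cases vs controls) is modelled by logistic
regression on age (y), ln weight (kg), height (cm), nulliparity and
smoking, with backward elimination of the least significant term until
all retained Wald p-values are ≤ `removal_alpha` (default 0.05 — not
fixed by the source analysis, but consistent with every retained term
being significant at 5%). Missing height/weight are mean-imputed.
Overfitting is adjusted by the heuristic shrinkage factor

> s = (χ² − (df − 1)) / χ²,

with χ² the model chi-square (null minus residual deviance) and df the
number of estimated parameters *including* the intercept — the published
models cannot disambiguate this convention because both (6- and
4-parameter) models report s = 0.94. All coefficients and the intercept
are multiplied by s, so shrunk log-odds are exactly s × raw log-odds
pointwise. The patient risk is odds/(1 + odds), odds = exp(Y).

`reference_prior_model()` provides the shrunk reference equations (EO-PE:
−6.790 − 0.119·height + 4.8565·ln weight + 1.845·nulliparity +
0.086·age + 1.353·smoking; LO-PE: −14.374 + 2.300·ln weight +
1.303·nulliparity + 0.068·age, both s = 0.94). Their intercepts reflect
the nested case-control prevalence (~12%), not the ~2% population
prevalence; detection rates at fixed FPR depend only on risk ranking, so
no recalibration is applied.

## Posterior risk

For each record, per-marker Gaussian likelihood ratios on the log10 MoM
scale — `N(x; affected)/N(x; unaffected)` — multiply the prior odds:

> posterior odds = prior odds × LR, posterior = odds/(1 + odds).

The default combines markers as a product of univariate LRs (diagonal
covariance). The source analysis computes marker correlations but never
states they enter the LR, so the correlation-aware multivariate-normal
variant is available behind `lr_mode = "multivariate"` (its density is
evaluated via a Cholesky factorization and reduces exactly to the
product when the covariance is diagonal). A missing or below-DL marker
contributes LR = 1, mirroring the per-marker n differences of a real
cohort; log10 MoMs beyond ±4 unaffected SDs are winsorized before
density evaluation to keep a density ratio from exploding numerically
(configurable).

## Performance evaluation

`roc_curve()` enumerates all distinct thresholds under the rule
"positive if risk ≥ t"; `dr_at_fpr()` reports the detection rate at the
largest achievable FPR not exceeding the target (conservative step
convention; ties among control risks therefore lower, never raise, the
reported DR). AUC is the normalized Mann-Whitney U (mid-ranks, ties one
half). Confidence intervals are stratified percentile bootstrap
(case and control groups resampled separately, 1000 replicates by
default). A parametric "model-predicted" DR is also provided: group
risks are assumed Gaussian on the log-odds scale, the threshold is the
unaffected (1 − FPR) quantile and the DR the affected tail mass — the
empirical and parametric variants agree as n grows when the Gaussian
assumption holds, and both are reported because the phrase
"model-predicted detection rate" does not pin down a computation.
Baseline group tables use chi-square (categorical) and Mann-Whitney
(continuous) tests at the Bonferroni-adjusted α = 0.05/3 = 0.0167.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions so every stage is
testable without data:

* **Covariates** (calibrated to the control summary statistics): age ~
  N(33, 4²) truncated to [18, 45] y; weight log-normal with median 65.5
  kg and log-SD 0.145 (IQR ≈ 60–73); height ~ N(168, 6.5²) cm (not
  reported; typical Dutch maternal stature); nulliparity 46.6%; smoking
  4.2%; GA at sampling rounded N(87, 6²) truncated to [63, 97] days.
* **Markers**: value = expected median (generative model at the record's
  GA, weight, smoking) × group MoM shift × 10^ε, ε ~ N(0, σ²) with log10
  SDs 0.25 (PAPP-A, fβ-hCG), 0.15 (ADAM12, PlGF), 0.05 (MAP) — spreads
  chosen once as plausible screening-marker dispersions consistent with
  the reported IQRs; a correlation-matrix hook exists but defaults to
  independence since marker correlations are not reported. MAP is
  decomposed into a systolic/diastolic pair (pulse pressure ~ N(40, 5²)
  mmHg) so that `compute_map()` inverts the generator exactly.
* **Case shifts** default to the reported group medians (EO-PE: PAPP-A
  0.89, fβ-hCG 0.92, ADAM12 0.93, PlGF 0.94, MAP 1.08; LO-PE: 1.04,
  1.04, 1.02, 0.90, 1.05), with the stronger with-SGA column applied to
  SGA-designated cases. An optional `plgf_ga_effect` confines the PlGF
  deficit to sampling at ≥ 11 weeks, emulating its late emergence.
* **Case covariates** are importance-resampled from a 20× oversampled
  pool with weights exp(Y) under the raw-scale reference prior model, so
  cases show the expected nulliparity/weight/smoking excess and a
  logistic refit of cases against controls recovers the generating
  coefficients (exp(Y) tilting is exact for that recovery; probability
  weighting would attenuate the odds ratios).
* **Outcomes**: control deliveries at term (259–294 days); EO-PE
  deliveries N(217, 10²) truncated below 238 days, LO-PE N(261, 10²)
  truncated to [238, 290]. Birthweights are drawn from the package's
  synthetic growth chart with z-scores truncated on the correct side of
  the 10th centile so the requested SGA fractions (13/68 EO, 49/99 LO —
  the latter a free parameter, since how the source cohort arrived at
  its near-half split is not recorded) hold exactly up to rounding.
* **Missingness**: ADAM12 2%, PlGF 2.5%, MAP 4% missing at random, and
  1.2% of PlGF values replaced by uniform(3.0, 5.9) pg/mL so the
  below-detection-limit discard rule is exercised.

What the generator does **not** emulate: assay batch effects and
storage-time drift, conception-method and parity>1 structure, any real
marker–marker or marker–covariate dependence beyond the modelled
GA/weight/smoking effects, and the downward shift of non-SGA case
birthweight centiles. Passing tests therefore demonstrate that the
pipeline inverts its own generative assumptions and reproduces the
printed model arithmetic — not that the headline detection rates (72%
EO-PE, 49% LO-PE at 10% FPR) would be attained on real patients; those
depend on the original cohort and on distribution parameters that were
never printed, and the package checks them only directionally (EO-PE
easier to detect than LO-PE; with-SGA cases easier than all cases).

## Growth chart

National birthweight references are not redistributable, so
`synthetic_growth_chart()` ships a labelled-synthetic parametric chart: a
monotone (Hyman) spline through typical week-by-week median weights
(700 g at 24 weeks to 3 900 g at 44), +3% for male infants, −1.5% for
nulliparous mothers, and ±1 SD placed at ±12% of the median
(proportional SD). z = (birthweight − p50)/SD with SD the average of the
two one-sided SD distances; centile = 100·Φ(z); SGA is strictly under
the 10th centile (the defining phrase "under the 10th centile" is read
as strict). `read_growth_chart()` loads user-supplied tables with the
same six-column interface.

## Numerical and testing choices

* GA thresholds are handled in days (34 wk = 238 d, 37 wk = 259 d,
  24-wk exclusion = 168 d) to avoid week-rounding ambiguity; deliveries
  before 168 days raise an exclusion error rather than a class.
* Corrected-MoM truncation to [0.1, 5] before the log transform is
  available (`truncate =`) but off by default, so tests see the
  untouched distributions.
* All generation is seeded through a config object; identical config +
  seed reproduces cohorts bit-identically, and `run_pipeline()` logs
  seed, versions and per-marker exclusion accounting so a run can be
  re-executed from its log.
* Problem sizes in the test suite were chosen to make Monte-Carlo error
  small relative to the asserted tolerances: 5 000 controls for MoM
  self-consistency (median MoM = 1.00 ± 0.02), 50 000 profiles for
  logistic parameter recovery (estimates within 3 SEs), 2 000 cases for
  shift recovery (±0.02–0.03), and 100 random small cohorts for the
  exact brute-force ROC cross-checks.

## Known limitations

* The refitted median equations are only as good as the control sample;
  below ~2 completed weeks of GA spread the base regression is refused.
* Shrinkage is the simple chi-square heuristic, not penalized
  likelihood; with separation-prone small strata the univariate screen
  flags non-finite ORs instead of stabilizing them.
* The multivariate LR assumes joint normality of log10 MoMs; with the
  default product mode this reduces to per-marker normality, which the
  3-SD trim enforces only approximately in heavy-tailed data.
* Prior risks are on the case-control scale; absolute risk statements
  require an intercept offset for the population prevalence.
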