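#' Classify pregnancy outcome into control / EO-PE / LO-PE
#'
#' Early-onset preeclampsia (EO-PE) is PE with delivery before 34 completed
#' weeks (< 238 days); late-onset (LO-PE) is PE with delivery at or after
#' 34 weeks. Thresholds are applied in days to avoid week-rounding
#' ambiguity. Deliveries before 24 weeks (168 days) are excluded from the
#' study design and raise an error rather than a class.
#'
#' @param pe_flag Logical, preeclampsia diagnosis.
#' @param ga_delivery Gestational age at delivery, days.
#' @return Character vector in `{"control", "EO-PE", "LO-PE"}`.
#' @export
classify_pe <- function(pe_flag, ga_delivery) {
  n <- max(length(pe_flag), length(ga_delivery))
  pe_flag <- rep_len(as.logical(pe_flag), n)
  ga_delivery <- rep_len(ga_delivery, n)
  if (any(ga_delivery < 168, na.rm = TRUE))
    pe_stop("classify_pe",
            "delivery before 24 weeks (168 days) is an exclusion, not a class")
  ifelse(pe_flag & ga_delivery < 238, "EO-PE",
         ifelse(pe_flag, "LO-PE", "control"))
}

#' Birthweight z-score against a growth-chart stratum
#'
#' z = (birthweight - p50) / SD with SD the average of the distances from
#' the 50th centile to the -1 SD and +1 SD chart weights:
#' SD = ((p50 - minus1sd) + (plus1sd - p50)) / 2.
#'
#' @param birthweight Birthweight in grams.
#' @param chart_entry A one-row data frame (or list) with `p50_g`,
#'   `minus1sd_g`, `plus1sd_g` — see [growth_chart_lookup()].
#' @return Numeric z-score.
#' @export
birthweight_zscore <- function(birthweight, chart_entry) {
  p50 <- chart_entry$p50_g
  s <- ((p50 - chart_entry$minus1sd_g) + (chart_entry$plus1sd_g - p50)) / 2
  if (any(s <= 0, na.rm = TRUE))
    pe_stop("birthweight_zscore", "chart SD must be positive")
  (birthweight - p50) / s
}

#' Convert a z-score to an exact centile
#'
#' centile = 100 * Phi(z), Phi the standard normal CDF.
#'
#' @param z Numeric z-score(s).
#' @return Centile in (0, 100).
#' @export
zscore_to_centile <- function(z) 100 * stats::pnorm(z)

#' Small-for-gestational-age indicator
#'
#' SGA is a birthweight strictly under the 10th centile.
#'
#' @param centile Birthweight centile in (0, 100).
#' @return Logical.
#' @export
is_sga <- function(centile) centile < 10

#' Synthetic parametric growth chart
#'
#' A smooth stand-in for national birthweight-for-GA reference tables
#' (which are not redistributable): the 50th-centile weight follows a
#' monotone spline through typical week-by-week anchor weights, male
#' infants are offset +3% and nulliparous mothers -1.5%, and the -1/+1 SD
#' weights are placed at +/- 12% of the 50th centile (proportional SD).
#' Interface-compatible with user-supplied charts loaded by
#' [read_growth_chart()].
#'
#' @param ga_weeks Completed weeks covered by the chart (default 24-43).
#' @return Data frame with columns `ga_weeks`, `sex`, `parity_class`,
#'   `p50_g`, `minus1sd_g`, `plus1sd_g`.
#' @export
synthetic_growth_chart <- function(ga_weeks = 24:43) {
  anchors_wk <- c(24, 26, 28, 30, 32, 34, 36, 38, 40, 42, 44)
  anchors_g  <- c(700, 900, 1150, 1450, 1850, 2300, 2800, 3250, 3550, 3780, 3900)
  base <- stats::splinefun(anchors_wk, anchors_g, method = "hyman")
  grid <- expand.grid(ga_weeks = ga_weeks,
                      sex = c("male", "female"),
                      parity_class = c("nulliparous", "parous"),
                      stringsAsFactors = FALSE)
  p50 <- base(grid$ga_weeks) *
    ifelse(grid$sex == "male", 1.03, 1.00) *
    ifelse(grid$parity_class == "nulliparous", 0.985, 1.00)
  grid$p50_g <- p50
  grid$minus1sd_g <- p50 * 0.88
  grid$plus1sd_g <- p50 * 1.12
  grid
}

#' Load a growth chart from CSV
#'
#' Expected columns: `ga_weeks`, `sex`, `parity_class`, `p50_g`,
#' `minus1sd_g`, `plus1sd_g`.
#'
#' @param path CSV file path.
#' @return Validated growth-chart data frame.
#' @export
read_growth_chart <- function(path) {
  chart <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ga_weeks", "sex", "parity_class", "p50_g", "minus1sd_g", "plus1sd_g")
  miss <- setdiff(need, names(chart))
  if (length(miss))
    pe_stop("read_growth_chart", "missing columns: ", paste(miss, collapse = ", "))
  if (any(!(chart$minus1sd_g < chart$p50_g & chart$p50_g < chart$plus1sd_g)))
    pe_stop("read_growth_chart", "chart must satisfy minus1sd < p50 < plus1sd")
  chart
}

#' Look up chart entries for records
#'
#' @param chart A growth chart (see [synthetic_growth_chart()]).
#' @param ga_delivery GA at delivery in days (converted to completed weeks).
#' @param sex `"male"` / `"female"`.
#' @param parity_class `"nulliparous"` / `"parous"`.
#' @return Data frame of matched chart rows (one per record).
#' @export
growth_chart_lookup <- function(chart, ga_delivery, sex, parity_class) {
  wk <- floor(ga_delivery / 7)
  key <- paste(chart$ga_weeks, chart$sex, chart$parity_class)
  idx <- match(paste(wk, sex, parity_class), key)
  if (anyNA(idx))
    pe_stop("growth_chart_lookup", "no chart entry for stratum of record(s) ",
            paste(utils::head(which(is.na(idx)), 5), collapse = ", "))
  chart[idx, , drop = FALSE]
}

#' Birthweight centiles for a cohort
#'
#' Convenience wrapper: chart lookup, z-score, centile, SGA flag.
#'
#' @param cohort Cohort data frame with `ga_delivery`, `birthweight`,
#'   `sex`, `nulliparous` columns.
#' @param chart Growth chart, default [synthetic_growth_chart()].
#' @return Data frame with `zscore`, `centile`, `sga`.
#' @export
cohort_centiles <- function(cohort, chart = synthetic_growth_chart()) {
  parity_class <- ifelse(cohort$nulliparous, "nulliparous", "parous")
  entry <- growth_chart_lookup(chart, cohort$ga_delivery, cohort$sex,
                               parity_class)
  z <- birthweight_zscore(cohort$birthweight, entry)
  centile <- zscore_to_centile(z)
  data.frame(zscore = z, centile = centile, sga = is_sga(centile))
}
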