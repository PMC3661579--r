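# Cohort CSV schema, model JSON serialization, pipeline configuration and
# end-to-end orchestration.

cohort_schema <- function() {
  c(id = "integer", age = "numeric", weight = "numeric", height = "numeric",
    nulliparous = "logical", smoking = "logical", ga_sampling = "numeric",
    papp_a = "numeric", fb_hcg = "numeric", adam12 = "numeric",
    plgf = "numeric", sbp = "numeric", dbp = "numeric", map = "numeric",
    group = "character", sga = "logical", ga_delivery = "numeric",
    sex = "character", birthweight = "numeric", pe_flag = "logical",
    proteinuria_flag = "logical")
}

#' Write a cohort to CSV
#'
#' One row per pregnancy. Column dictionary (units): `id`; `age` (y);
#' `weight` (kg); `height` (cm); `nulliparous`, `smoking` (logical);
#' `ga_sampling` (days); `papp_a` (mU/L); `fb_hcg` (ng/mL); `adam12`
#' (ng/mL); `plgf` (pg/mL); `sbp`, `dbp`, `map` (mmHg); `group`
#' (control/EO-PE/LO-PE); `sga` (logical); `ga_delivery` (days); `sex`;
#' `birthweight` (g); `pe_flag`, `proteinuria_flag` (logical).
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  cols <- names(cohort_schema())
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    pe_stop("write_cohort_csv", "cohort lacks columns: ",
            paste(miss, collapse = ", "))
  utils::write.csv(cohort[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a cohort CSV
#'
#' Enforces the documented column dictionary (see [write_cohort_csv()]),
#' types each column, and reports row-level validation failures (e.g.
#' systolic not exceeding diastolic pressure, non-positive marker values)
#' with their line numbers.
#'
#' @param path CSV path.
#' @return Typed cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) pe_stop("read_cohort_csv", "file not found: ", path)
  schema <- cohort_schema()
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(d))
  if (length(miss))
    pe_stop("read_cohort_csv", "missing mandatory column(s): ",
            paste(miss, collapse = ", "))
  for (col in names(schema)) {
    d[[col]] <- switch(schema[[col]],
      integer = as.integer(d[[col]]),
      numeric = {
        v <- suppressWarnings(as.numeric(d[[col]]))
        bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "" &
                       d[[col]] != "NA")
        if (length(bad))
          pe_stop("read_cohort_csv", "non-numeric '", col, "' at row(s) ",
                  paste(utils::head(bad, 5), collapse = ", "))
        v
      },
      logical = as.logical(d[[col]]),
      character = as.character(d[[col]]))
  }
  bad_bp <- which(!is.na(d$sbp) & !is.na(d$dbp) & d$sbp <= d$dbp)
  if (length(bad_bp))
    pe_stop("read_cohort_csv", "systolic <= diastolic at row(s) ",
            paste(utils::head(bad_bp, 5), collapse = ", "))
  for (mk in pe_markers()) {
    bad <- which(!is.na(d[[mk]]) & d[[mk]] <= 0)
    if (length(bad))
      pe_stop("read_cohort_csv", "non-positive ", mk, " at row(s) ",
              paste(utils::head(bad, 5), collapse = ", "))
  }
  d
}

# --- model JSON serialization -----------------------------------------------

model_to_list <- function(x) {
  if (inherits(x, "median_model")) {
    c(list(type = "median_model"), unclass(x))
  } else if (inherits(x, "gaussian_marker_model")) {
    l <- unclass(x)
    # named atomic vectors lose names in JSON; store as objects
    l$mean <- as.list(l$mean); l$sd <- as.list(l$sd); l$n <- as.list(l$n)
    l$cor <- as.data.frame(l$cor)
    c(list(type = "gaussian_marker_model"), l)
  } else if (inherits(x, "risk_model")) {
    c(list(type = "risk_model"), unclass(x))
  } else pe_stop("write_model_json", "unsupported model class")
}

list_to_model <- function(l) {
  switch(l$type,
    median_model = {
      wc <- l$weight_correction
      if (!is.null(wc)) wc$coef <- as.numeric(wc$coef)
      median_model(l$marker, l$base_dialect, as.numeric(l$base_coef),
                   weight_correction = wc,
                   smoking_divisors = as.numeric(l$smoking_divisors),
                   ga_range = as.numeric(l$ga_range))
    },
    gaussian_marker_model = {
      cm <- as.matrix(as.data.frame(l$cor))
      rownames(cm) <- colnames(cm)
      structure(list(group = l$group, mean = unlist(l$mean),
                     sd = unlist(l$sd), cor = cm, n = unlist(l$n)),
                class = "gaussian_marker_model")
    },
    risk_model = risk_model(l$outcome, as.data.frame(l$terms),
                            l$intercept_raw, l$intercept_shrunk,
                            l$shrinkage, l$chi2,
                            if (is.null(l$df)) NA_real_ else l$df),
    pe_stop("read_model_json", "unknown model type: ", l$type))
}

#' Serialize fitted models to JSON
#'
#' Writes a named list of models ([median_model()], [risk_model()],
#' `gaussian_marker_model`) to JSON with full numeric precision; the
#' coefficient round-trip through [read_models_json()] is bit-exact.
#'
#' @param models Named list of model objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models_json <- function(models, path) {
  jsonlite::write_json(lapply(models, model_to_list), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_models_json
#' @export
read_models_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE)
  lapply(raw, list_to_model)
}

# --- pipeline ----------------------------------------------------------------

#' Pipeline configuration
#'
#' Validated run configuration for [run_pipeline()]. Unknown keys are
#' rejected; the object round-trips losslessly through JSON (and YAML if
#' the yaml package is installed) via [read_pipeline_config()].
#'
#' @param cohort_csv Optional path to an existing cohort CSV; when `NULL`
#'   a synthetic cohort is generated from `cohort` + `seed`.
#' @param output_dir Directory for artifacts.
#' @param markers Marker subset for the headline screen.
#' @param lr_mode `"product"` or `"multivariate"`.
#' @param removal_alpha Backward-elimination threshold.
#' @param fpr_targets FPR grid.
#' @param boot_reps Bootstrap replicates for performance CIs.
#' @param seed Integer seed controlling generation and bootstrap.
#' @param ga_min Optional GA-at-sampling filter in days (records below are
#'   dropped before analysis), e.g. 77 to restrict to >= 11 weeks.
#' @param cohort Optional list of [cohort_config()] overrides (sizes,
#'   fractions, rates).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_csv = NULL, output_dir = "pescreen-run",
                            markers = c("map", "papp_a", "adam12", "plgf"),
                            lr_mode = "product", removal_alpha = 0.05,
                            fpr_targets = c(0.05, 0.10), boot_reps = 0L,
                            seed = 20130522L, ga_min = NULL,
                            cohort = list()) {
  markers <- match.arg(markers, pe_markers(), several.ok = TRUE)
  lr_mode <- match.arg(lr_mode, c("product", "multivariate"))
  stopifnot(removal_alpha > 0, removal_alpha < 1,
            all(fpr_targets > 0 & fpr_targets < 1), boot_reps >= 0)
  structure(list(cohort_csv = cohort_csv, output_dir = output_dir,
                 markers = markers, lr_mode = lr_mode,
                 removal_alpha = removal_alpha, fpr_targets = fpr_targets,
                 boot_reps = as.integer(boot_reps), seed = as.integer(seed),
                 ga_min = ga_min, cohort = cohort),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path Config file (`.json`, `.yml`/`.yaml`).
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  l <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      pe_stop("read_pipeline_config", "yaml package required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(l), known)
  if (length(unknown))
    pe_stop("read_pipeline_config", "unknown config key(s): ",
            paste(unknown, collapse = ", "))
  do.call(pipeline_config, l)
}

#' Run the full screening pipeline
#'
#' End-to-end orchestration: load or generate the cohort, optionally
#' filter on GA at sampling, fit median models on controls and compute
#' MoMs, fit the prior-risk models by backward elimination with shrinkage,
#' fit the per-group Gaussian MoM distributions, screen every record for
#' both outcomes, and tabulate DR at the target FPRs. All artifacts are
#' written under `config$output_dir`:
#' `cohort.csv`, `median_models.json`, `prior_models.json`,
#' `group_models.json`, `risks.csv`, `performance.csv`, `run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the fitted models, risk results,
#'   performance table and artifact paths.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("pescreen run: %s", format(Sys.time())),
                 sprintf("seed: %d", config$seed),
                 sprintf("R version: %s", getRversion()))

  cohort <- if (!is.null(config$cohort_csv)) {
    read_cohort_csv(config$cohort_csv)
  } else {
    cc <- do.call(cohort_config, c(list(seed = config$seed), config$cohort))
    generate_cohort(cc)
  }
  n_total <- nrow(cohort)
  if (!is.null(config$ga_min)) {
    cohort <- cohort[cohort$ga_sampling >= config$ga_min, , drop = FALSE]
    log_lines <- c(log_lines,
                   sprintf("GA filter >= %s days: %d of %d records retained",
                           config$ga_min, nrow(cohort), n_total))
  }
  log_lines <- c(log_lines, sprintf(
    "cohort: %d records (%d controls, %d EO-PE, %d LO-PE)", nrow(cohort),
    sum(cohort$group == "control"), sum(cohort$group == "EO-PE"),
    sum(cohort$group == "LO-PE")))

  moms <- compute_cohort_moms(cohort)
  for (mk in pe_markers()) {
    fl <- table(factor(moms$flags[[mk]], c("ok", "missing", "below_dl")))
    log_lines <- c(log_lines, sprintf(
      "%s: %d retained, %d missing, %d below-DL (sum %d = %d records)",
      mk, fl["ok"], fl["missing"], fl["below_dl"], sum(fl), nrow(cohort)))
  }

  outcomes <- Filter(function(g) sum(cohort$group == g) >= 10,
                     c("EO-PE", "LO-PE"))
  if (!length(outcomes))
    pe_stop("run_pipeline", "no outcome group with >= 10 cases")
  prior_models <- lapply(
    stats::setNames(outcomes, outcomes),
    function(g) fit_logistic_backward(cohort, g,
                                      removal_alpha = config$removal_alpha))
  group_models <- c(
    list(unaffected = fit_group_distribution(
      moms$log10_mom[cohort$group == "control", ], "unaffected")),
    lapply(stats::setNames(outcomes, outcomes), function(g)
      fit_group_distribution(moms$log10_mom[cohort$group == g, ], g)))

  risks <- do.call(rbind, lapply(outcomes, function(g)
    screen_cohort(cohort, prior_models[[g]], group_models[[g]],
                  group_models$unaffected, markers = config$markers,
                  moms = moms, lr_mode = config$lr_mode)))

  perf <- performance_table(cohort, prior_models, group_models, moms = moms,
                            fpr_targets = config$fpr_targets,
                            boot_reps = config$boot_reps, seed = config$seed,
                            lr_mode = config$lr_mode)

  paths <- list(
    cohort = file.path(config$output_dir, "cohort.csv"),
    median_models = file.path(config$output_dir, "median_models.json"),
    prior_models = file.path(config$output_dir, "prior_models.json"),
    group_models = file.path(config$output_dir, "group_models.json"),
    risks = file.path(config$output_dir, "risks.csv"),
    performance = file.path(config$output_dir, "performance.csv"),
    log = file.path(config$output_dir, "run_log.txt"))
  write_cohort_csv(cohort, paths$cohort)
  write_models_json(moms$models, paths$median_models)
  write_models_json(prior_models, paths$prior_models)
  write_models_json(group_models, paths$group_models)
  utils::write.csv(risks, paths$risks, row.names = FALSE)
  utils::write.csv(perf, paths$performance, row.names = FALSE)
  writeLines(log_lines, paths$log)

  invisible(list(cohort = cohort, moms = moms, prior_models = prior_models,
                 group_models = group_models, risks = risks,
                 performance = perf, paths = paths))
}
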