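# Full-analysis orchestration: ingestion -> exclusions -> descriptives ->
# model suite -> ROC -> growth divergence, with graceful degradation of
# the later stages and a machine-readable report.

#' Configuration of a full analysis run
#'
#' Exactly one of `input` (path to a cohort delimited-text file) or
#' `simulate` (a [sim_config()]) must be supplied.
#'
#' @param input path to a cohort table file, or `NULL`.
#' @param simulate a [sim_config()] object, or `NULL`.
#' @param rules an [exclusion_rules()] object.
#' @param roc_positive positive sex label for the ROC stages.
#' @param divergence list of options for [bootstrap_difference()] and
#'   [detect_divergence_windows()]: `variable`, `grid_step`, `span`,
#'   `degree`, `B`, `alpha`, `min_run`, `stratified`.
#' @param seed integer seed recorded in, and used by, the run.
#' @param sep field separator for `input`.
#' @return an object of class `"analysis_config"`.
#' @export
analysis_config <- function(input = NULL, simulate = NULL,
                            rules = exclusion_rules(), roc_positive = "F",
                            divergence = list(), seed = 1L, sep = ",") {
  if (is.null(input) == is.null(simulate))
    stop("exactly one of 'input' and 'simulate' must be given",
         call. = FALSE)
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  div <- utils::modifyList(
    list(variable = "aub_mm", grid_step = 0.5, span = 0.75, degree = 1L,
         B = 1000L, alpha = 0.05, min_run = 2L, stratified = TRUE),
    divergence)
  structure(list(input = input, simulate = simulate, rules = rules,
                 roc_positive = roc_positive, divergence = div,
                 seed = as.integer(seed), sep = sep),
            class = "analysis_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: ingestion (file or simulation), exclusion
#' filtering, descriptive summaries, the three-model regression suite with
#' Holm correction, ROC curves for the lateral angle and for biauricular
#' breadth (on the subadult subset in which the angle is measured, for
#' comparability), the fixed 45-degree cut-off report, and the bootstrap
#' growth-divergence stage. Failure of a late stage (for example too few
#' adolescents for the divergence bootstrap) marks that stage absent with
#' its error message and leaves earlier stages intact; only ingestion or
#' exclusion failures propagate as errors.
#'
#' @param config an [analysis_config()].
#' @return an object of class `"analysis_report"`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  errors <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  cohort <- if (!is.null(config$input))
    read_cohort_table(config$input, sep = config$sep)
  else {
    sim <- config$simulate
    if (is.null(sim$seed)) sim$seed <- config$seed
    simulate_cohort(sim)
  }

  excl <- apply_exclusions(cohort, config$rules)
  retained <- excl$table
  if (nrow(retained) == 0L)
    stop("no specimens retained after exclusions", call. = FALSE)

  descriptives <- stage("descriptives", summarize_cohort(retained))
  models <- stage("models", model_suite(retained))
  roc_angle <- stage("roc_angle",
                     roc_curve(retained, "lateral_angle_deg",
                               positive = config$roc_positive))
  subadult <- retained[!is.na(retained$lateral_angle_deg), , drop = FALSE]
  class(subadult) <- c("cohort_table", "data.frame")
  roc_breadth <- stage("roc_breadth",
                       roc_curve(subadult, "aub_mm",
                                 positive = config$roc_positive))
  cutoff <- stage("cutoff", classify_cutoff(retained))

  div <- config$divergence
  ensemble <- stage("divergence", bootstrap_difference(
    retained, variable = div$variable, grid_step = div$grid_step,
    span = div$span, degree = div$degree, B = div$B,
    seed = config$seed, alpha = div$alpha, stratified = div$stratified))
  windows <- if (!is.null(ensemble))
    detect_divergence_windows(ensemble, min_run = div$min_run)
  else NULL

  structure(list(
    provenance = list(package_version =
                        as.character(utils::packageVersion("petrousgrowth")),
                      seed = config$seed,
                      config = config,
                      timestamp = format(Sys.time(), tz = "UTC")),
    n_input = nrow(cohort), exclusion_log = excl$log,
    n_retained = nrow(retained), cohort = retained,
    descriptives = descriptives, models = models,
    roc_angle = roc_angle, roc_breadth = roc_breadth, cutoff = cutoff,
    divergence = ensemble, windows = windows,
    stage_errors = errors),
    class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Lateral-angle dimorphism analysis report (seed ",
      x$provenance$seed, ")\n", sep = "")
  cat("Specimens: ", x$n_input, " ingested, ", nrow(x$exclusion_log),
      " excluded, ", x$n_retained, " retained\n", sep = "")
  if (!is.null(x$models)) {
    cat("\n"); print(x$models)
  }
  for (r in list(x$roc_angle, x$roc_breadth)) if (!is.null(r)) print(r)
  if (!is.null(x$cutoff)) print(x$cutoff)
  if (!is.null(x$divergence)) {
    cat("\n"); print(x$divergence); print(x$windows)
  }
  if (length(x$stage_errors) > 0L) {
    cat("\nStages absent:\n")
    for (nm in names(x$stage_errors))
      cat("  ", nm, ": ", x$stage_errors[[nm]], "\n", sep = "")
  }
  invisible(x)
}

# Flatten the report into plain lists for serialization.
.report_payload <- function(report) {
  ols_payload <- function(f) if (is.null(f)) NULL else
    list(coefficients = f$coefficients, r2 = f$r2, adj_r2 = f$adj_r2,
         n_used = f$n_used, residual_sd = f$residual_sd)
  roc_payload <- function(r) if (is.null(r)) NULL else
    list(auc = r$auc, positive_label = r$positive_label,
         orientation = r$orientation, thresholds = r$thresholds,
         fpr = r$fpr, tpr = r$tpr)
  m <- report$models
  div <- report$divergence
  list(
    schema_version = "1",
    provenance = list(
      package_version = report$provenance$package_version,
      seed = report$provenance$seed,
      resampling = if (is.null(div)) NULL else
        if (div$stratified) "stratified-by-sex" else "pooled"),
    n_input = report$n_input, n_retained = report$n_retained,
    exclusion_log = report$exclusion_log,
    descriptives = as.data.frame(report$descriptives),
    models = if (is.null(m)) NULL else list(
      model_a = ols_payload(m$model_a),
      model_b_angle_on_aub = ols_payload(m$model_b$angle_on_aub),
      model_b_aub_on_angle = ols_payload(m$model_b$aub_on_angle),
      model_b_r2 = m$model_b$r2,
      model_c = ols_payload(m$model_c),
      holm_adjusted_p = as.list(m$holm_adjusted_p)),
    roc_angle = roc_payload(report$roc_angle),
    roc_breadth = roc_payload(report$roc_breadth),
    divergence = if (is.null(div)) NULL else list(
      grid = div$observed$grid, diff = div$observed$diff,
      bca_lo = div$bca_lo, bca_hi = div$bca_hi,
      flagged = div$bca_lo > 0 | div$bca_hi < 0,
      B = div$B, n_failed = div$n_failed, alpha = div$alpha),
    windows = if (is.null(report$windows)) NULL
    else as.data.frame(report$windows),
    stage_errors = report$stage_errors)
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (machine-readable, round-trips through
#' [read_report()]), `report.txt` (the printed summary) and, when the
#' divergence stage ran, `divergence_curve.csv` with columns `grid_age`,
#' `diff`, `bca_lo`, `bca_hi`, `flagged`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- .report_payload(report)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "columns")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  div <- report$divergence
  if (!is.null(div)) {
    utils::write.table(
      data.frame(grid_age = div$observed$grid, diff = div$observed$diff,
                 bca_lo = div$bca_lo, bca_hi = div$bca_hi,
                 flagged = div$bca_lo > 0 | div$bca_hi < 0),
      file.path(dir, "divergence_curve.csv"), sep = ",",
      row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read back the machine-readable part of a report
#'
#' @param path path to a `report.json` written by [write_report()].
#' @return the deserialized payload (nested lists / data frames).
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
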