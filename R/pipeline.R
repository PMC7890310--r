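#' End-to-end run configuration
#'
#' Collects every knob of the pipeline -- cohort generation, labeling
#' horizon, selector and classifier lists, bootstrap counts, seed -- into a
#' single object that round-trips losslessly through JSON.
#'
#' @param seed Master seed for every stage.
#' @param n_patients Cohort size when simulating.
#' @param cohort_csv Optional path of an existing cohort to analyze instead
#'   of simulating.
#' @param outcomes,selectors,classifiers Stage lists.
#' @param horizon Label horizon (months).
#' @param train_fraction Training-side fraction.
#' @param B_boot Bootstrap replicates for metric confidence intervals.
#' @param mcdsl_B Bootstrap resamples inside the McDSL selector.
#' @param out_dir Output directory for artifacts.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_patients = 505, cohort_csv = NULL,
                       outcomes = c("pfs", "os"),
                       selectors = c("mcdsl", "lasso", "cox"),
                       classifiers = classifier_names(),
                       horizon = 36, train_fraction = 354 / 505,
                       B_boot = 1000, mcdsl_B = 20,
                       out_dir = "mcdsl-run") {
  structure(list(seed = seed, n_patients = n_patients,
                 cohort_csv = cohort_csv, outcomes = outcomes,
                 selectors = selectors, classifiers = classifiers,
                 horizon = horizon, train_fraction = train_fraction,
                 B_boot = B_boot, mcdsl_B = mcdsl_B, out_dir = out_dir),
            class = "run_config")
}

#' @rdname run_config
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(run_config, raw[!vapply(raw, is.null, TRUE)])
  cfg
}

#' Run the whole pipeline and write its artifacts
#'
#' simulate (or read) -> label -> select (per selector) -> benchmark ->
#' report. Every stage is seeded from the config; a `manifest.json` in the
#' output directory records seeds, configuration, stage status and the
#' output files, so the run is exactly reproducible from the manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the cohort, the bench report and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = unclass(config),
                   package_version = as.character(
                     utils::packageVersion("mcdsl")),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_csv)) read_cohort(config$cohort_csv)
    else generate_cohort(cohort_config(n_patients = config$n_patients,
                                       seed = config$seed))
  })
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)

  report <- stage("bench", run_bench(
    cohort, selectors = config$selectors, outcomes = config$outcomes,
    classifiers = config$classifiers,
    train_fraction = config$train_fraction, B_boot = config$B_boot,
    mcdsl_B = config$mcdsl_B, seed = config$seed,
    horizon = config$horizon))

  tsv <- file.path(config$out_dir, "report.tsv")
  utils::write.table(as.data.frame(report), tsv, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(as.data.frame(report),
                       file.path(config$out_dir, "report.json"),
                       digits = NA, pretty = TRUE, na = "null")
  manifest$outputs <- c(cohort = cohort_path, report_tsv = tsv,
                        report_json = file.path(config$out_dir,
                                                "report.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(list(cohort = cohort, report = report, manifest = manifest))
}
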