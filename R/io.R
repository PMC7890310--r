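#' Read and write cohort CSV files
#'
#' The on-disk format is one row per patient with the fixed column names of
#' [cohort_columns()]: categorical columns as string labels, times in months
#' with two decimals, events as 0/1. `write_cohort()` also writes a JSON
#' sidecar (`<path>.json`) recording the generating configuration and seed
#' when the table carries them. `read_cohort()` validates the schema -- an
#' unknown column, a misspelled level, or a missing required column errors
#' with row/column coordinates -- and logs row count per column missingness
#' to stderr.
#'
#' @param cohort A cohort table.
#' @param path CSV file path.
#' @return `read_cohort()` returns a validated `cohort_table`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)[, cohort_columns()]
  for (col in c("pfs_months", "os_months")) df[[col]] <- round(df[[col]], 2)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  cfg <- attr(cohort, "config")
  if (!is.null(cfg)) {
    side <- paste0(path, ".json")
    jsonlite::write_json(
      list(config = unclass(cfg),
           provenance = attr(cohort, "provenance")),
      side, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty cohort file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty cohort: ", path, " has no rows",
                          call. = FALSE)
  miss <- setdiff(cohort_columns(), names(df))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), c(cohort_columns(), "label_pfs", "label_os"))
  if (length(extra)) {
    stop("unknown column(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  df <- coerce_cohort_levels(df)
  message(sprintf("read_cohort: %d rows; missing values per column: %s",
                  nrow(df),
                  paste(names(df)[colSums(is.na(df)) > 0], collapse = ", ")))
  class(df) <- c("cohort_table", "data.frame")
  validate_cohort(df)
  df
}
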