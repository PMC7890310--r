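#' Feature schema of the glioma cohort
#'
#' The cohort carries 17 categorical predictors (clinical plus molecular) and
#' two censored endpoints: progression-free survival (PFS) and overall
#' survival (OS), both in months with 0/1 event indicators.
#'
#' @return `glioma_features()` returns the 17 predictor column names;
#'   `glioma_levels()` returns a named list with the allowed levels of every
#'   categorical column; `cohort_columns()` returns the full column set of a
#'   cohort table (predictors plus survival columns).
#' @examples
#' glioma_features()
#' glioma_levels()$who_grade
#' @export
glioma_features <- function() {
  c("age_group", "sex", "kps", "location", "who_grade", "histology",
    "resection", "radiotherapy", "chemotherapy",
    "idh1", "idh2", "idh", "del_1p", "del_19q", "codel_1p19q", "tert",
    "mol_group")
}

#' @rdname glioma_features
#' @export
glioma_levels <- function() {
  yn <- c("Yes", "No")
  list(
    age_group    = c("<=40", ">40"),
    sex          = c("Male", "Female"),
    kps          = c("<80", ">=80"),
    location     = c("Frontal", "Temporal", "Parietal", "Occipital",
                     "Insular", "Multicenter"),
    who_grade    = c("II", "III", "IV"),
    histology    = c("Astrocytoma", "Oligodendroglial", "Glioblastoma"),
    resection    = c("GTR", "STR"),
    radiotherapy = yn,
    chemotherapy = c("Temozolomide", "Nitrosourea", "None"),
    idh1         = yn,
    idh2         = yn,
    idh          = yn,
    del_1p       = yn,
    del_19q      = yn,
    codel_1p19q  = yn,
    tert         = yn,
    mol_group    = c("Triple-positive", "TERT+IDH", "IDH-only",
                     "TERT-only", "Triple-negative", "Others")
  )
}

#' @rdname glioma_features
#' @export
cohort_columns <- function() {
  c(glioma_features(), "pfs_months", "pfs_event", "os_months", "os_event")
}

# Coerce the categorical columns of a cohort data.frame to factors with the
# canonical level sets, erroring (with coordinates) on unknown levels.
coerce_cohort_levels <- function(df) {
  lv <- glioma_levels()
  for (col in names(lv)) {
    vals <- as.character(df[[col]])
    bad <- which(!(vals %in% lv[[col]]) & !is.na(vals))
    if (length(bad)) {
      stop(sprintf("column '%s': unknown level '%s' at row %d",
                   col, vals[bad[1]], bad[1]), call. = FALSE)
    }
    df[[col]] <- factor(vals, levels = lv[[col]])
  }
  df
}
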