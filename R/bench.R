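#' Split a cohort into training and validation sides
#'
#' Seeded random split with optional stratification on a binary outcome.
#' Sizes are `round(fraction * n)` and the remainder (505 patients at the
#' default fraction give 354 / 151). If a stratified split leaves a side
#' with one outcome class, the split is retried with a new derived seed a
#' few times before erroring.
#'
#' @param cohort A cohort data.frame.
#' @param train_fraction Training fraction (default 354/505).
#' @param seed Seed.
#' @param stratify_on Optional 0/1 vector to stratify on (e.g. the binary
#'   3-year outcome).
#' @return A list with integer row indices `train` and `validation`.
#' @export
split_cohort <- function(cohort, train_fraction = 354 / 505, seed = 1,
                         stratify_on = NULL) {
  n <- nrow(cohort)
  stopifnot(n >= 10, train_fraction > 0, train_fraction < 1)
  n_train <- round(train_fraction * n)
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    if (is.null(stratify_on)) {
      tr <- sample.int(n, n_train)
    } else {
      tr <- integer(0)
      for (cls in unique(stratify_on)) {
        idx <- which(stratify_on == cls)
        take <- round(length(idx) * train_fraction)
        tr <- c(tr, sample(idx, take))
      }
      # adjust to the exact target size
      pool <- setdiff(seq_len(n), tr)
      if (length(tr) > n_train) tr <- sample(tr, n_train)
      else if (length(tr) < n_train) {
        tr <- c(tr, sample(pool, n_train - length(tr)))
      }
    }
    va <- setdiff(seq_len(n), tr)
    if (is.null(stratify_on) ||
        (length(unique(stratify_on[tr])) > 1 &&
         length(unique(stratify_on[va])) > 1)) {
      return(list(train = sort(tr), validation = sort(va)))
    }
  }
  stop("could not produce a two-class split on either side", call. = FALSE)
}

#' Run the full selector-by-classifier benchmark
#'
#' Reproduces the structure of the source study's performance tables: the
#' cohort is split once into training and validation sides (stratified on
#' the binary 3-year PFS outcome); for each outcome each selector is run on
#' the training side; each classifier is trained on the selected factors;
#' the Youden threshold is learned on training scores (never re-optimized on
#' validation); and the six metrics with percentile-bootstrap confidence
#' intervals are reported per side.
#'
#' @param cohort A cohort table.
#' @param selectors Subset of `c("mcdsl", "lasso", "cox")`.
#' @param outcomes Subset of `c("pfs", "os")`.
#' @param classifiers Subset of [classifier_names()].
#' @param train_fraction,seed Split parameters (see [split_cohort()]).
#' @param B_boot Bootstrap replicates for the confidence intervals.
#' @param mcdsl_B Bootstrap resamples inside the McDSL selector.
#' @param horizon Outcome horizon in months.
#' @param selector_features Optional named list overriding the selected
#'   features per selector (mainly for tests).
#' @return A `bench_report` data.frame: one row per selector x classifier x
#'   outcome x cohort side, with point values and 95% CI bounds of the six
#'   measures plus the operating threshold. Cells whose selector or
#'   classifier failed are reported as missing rows, never an abort.
#' @export
run_bench <- function(cohort,
                      selectors = c("mcdsl", "lasso", "cox"),
                      outcomes = c("pfs", "os"),
                      classifiers = classifier_names(),
                      train_fraction = 354 / 505,
                      B_boot = 1000, mcdsl_B = 20, seed = 1,
                      horizon = 36,
                      selector_features = NULL) {
  X <- cohort[, glioma_features(), drop = FALSE]
  lab_pfs <- cohort_label(cohort, "pfs", horizon)
  sp <- split_cohort(cohort, train_fraction, seed,
                     stratify_on = lab_pfs$y)
  rows <- list()
  for (outc in outcomes) {
    lab <- cohort_label(cohort, outc, horizon)
    tr <- sp$train; va <- sp$validation
    for (sel in selectors) {
      feats <- if (!is.null(selector_features) &&
                   !is.null(selector_features[[sel]])) {
        selector_features[[sel]]
      } else {
        tryCatch(select_features(sel, X[tr, , drop = FALSE],
                                 lab$label[tr], lab$y[tr],
                                 cohort[[paste0(outc, "_months")]][tr],
                                 cohort[[paste0(outc, "_event")]][tr],
                                 mcdsl_B = mcdsl_B, seed = seed),
                 error = function(e) {
                   warning("selector '", sel, "' failed for ", outc, ": ",
                           conditionMessage(e))
                   NULL
                 })
      }
      if (is.null(feats) || length(feats) == 0) next
      for (clf in classifiers) {
        row <- tryCatch(
          bench_cell(clf, X, lab$y, tr, va, feats, B_boot, seed),
          error = function(e) {
            warning("classifier '", clf, "' failed: ", conditionMessage(e))
            NULL
          })
        if (is.null(row)) next
        row$selector <- sel; row$classifier <- clf; row$outcome <- outc
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    front <- c("selector", "classifier", "outcome", "cohort")
    out <- out[, c(front, setdiff(names(out), front))]
    rownames(out) <- NULL
  }
  structure(out, class = c("bench_report", "data.frame"),
            seed = seed, B_boot = B_boot)
}

select_features <- function(sel, Xtr, label3_tr, ybin_tr, time_tr, event_tr,
                            mcdsl_B, seed) {
  switch(sel,
    mcdsl = stability_select(Xtr, label3_tr, B = mcdsl_B,
                             seed = seed)$selected,
    lasso = lasso_select(Xtr, ybin_tr, lasso_config(seed = seed))$selected,
    cox   = cox_select(Xtr, time_tr, event_tr)$selected,
    stop("unknown selector: ", sel)
  )
}

bench_cell <- function(clf, X, ybin, tr, va, feats, B_boot, seed) {
  model <- train_classifier(clf, X[tr, feats, drop = FALSE], ybin[tr],
                            seed = seed)
  s_tr <- predict(model, X[tr, feats, drop = FALSE])
  s_va <- predict(model, X[va, feats, drop = FALSE])
  thr <- as.numeric(youden_threshold(s_tr, ybin[tr]))
  side_row <- function(scores, y, side) {
    pt <- compute_metrics(scores, y, thr)
    ci <- bootstrap_ci(function(d) {
      compute_metrics(d$scores, d$y,
                      thr)[c("auc", "f_score", "ppv", "npv",
                             "specificity", "sensitivity")]
    }, data.frame(scores = scores, y = y), B = B_boot, seed = seed)
    df <- data.frame(cohort = side,
                     threshold = thr,
                     n = length(y),
                     stringsAsFactors = FALSE)
    for (m in c("auc", "f_score", "ppv", "npv", "specificity",
                "sensitivity")) {
      df[[m]] <- unname(pt[[m]])
      df[[paste0(m, "_lo")]] <- unname(ci$lower95[[m]])
      df[[paste0(m, "_hi")]] <- unname(ci$upper95[[m]])
    }
    df
  }
  rbind(side_row(s_tr, ybin[tr], "training"),
        side_row(s_va, ybin[va], "validation"))
}

#' @export
print.bench_report <- function(x, ...) {
  cat("Benchmark report:", nrow(x), "rows",
      "(selector x classifier x outcome x side)\n")
  cols <- c("selector", "classifier", "outcome", "cohort", "auc",
            "f_score", "sensitivity", "specificity")
  print(utils::head(as.data.frame(x)[, cols], 12), digits = 3)
  invisible(x)
}
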