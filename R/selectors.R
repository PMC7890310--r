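#' LASSO feature selection by cross-validated AUC
#'
#' Fits an L1-penalized logistic model over a decreasing lambda grid on the
#' all-levels one-hot design and picks the lambda maximizing the 5-fold
#' cross-validated AUC (stratified folds). A clinical factor counts as
#' selected if any of its one-hot levels carries a nonzero coefficient at
#' the chosen lambda.
#'
#' @param X Data.frame of categorical predictors.
#' @param ybin 0/1 outcome (both classes required).
#' @param config A [lasso_config()].
#' @return A `selection_result`: `selected` (factor names), `lambda`, and
#'   `detail` (per-level nonzero coefficients).
#' @export
lasso_select <- function(X, ybin, config = lasso_config()) {
  if (length(unique(ybin)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  enc <- onehot_recipe(X)
  mm <- apply_onehot(X, enc)
  feat_of_col <- rep(names(X), vapply(enc, length, 0L))
  set.seed(config$seed)
  if (!is.null(config$lambda) && length(config$lambda) == 1) {
    fit <- glmnet::glmnet(mm, ybin, family = "binomial",
                          lambda = config$lambda)
    beta <- as.numeric(fit$beta)
    lambda_opt <- config$lambda
  } else {
    foldid <- integer(length(ybin))
    for (cls in unique(ybin)) {
      idx <- which(ybin == cls)
      foldid[idx] <- sample(rep_len(seq_len(config$folds), length(idx)))
    }
    args <- list(x = mm, y = ybin, family = "binomial",
                 type.measure = "auc", foldid = foldid)
    if (!is.null(config$lambda)) args$lambda <- config$lambda
    else {
      args$nlambda <- config$nlambda
      args$lambda.min.ratio <- config$lambda_min_ratio
    }
    cv <- suppressWarnings(do.call(glmnet::cv.glmnet, args))
    lambda_opt <- cv$lambda.min     # maximizer of the CV AUC
    beta <- as.numeric(stats::coef(cv, s = lambda_opt))[-1]
  }
  nz <- which(abs(beta) > 0)
  detail <- data.frame(level = colnames(mm)[nz],
                       feature = feat_of_col[nz],
                       coefficient = beta[nz],
                       stringsAsFactors = FALSE)
  structure(list(method = "lasso",
                 selected = unique(feat_of_col[nz]),
                 lambda = lambda_opt,
                 detail = detail),
            class = "selection_result")
}

#' @rdname lasso_select
#' @param lambda Optional explicit lambda grid (decreasing positive reals);
#'   default lets the path run over `nlambda` log-spaced values spanning
#'   four decades below the smallest all-zero lambda.
#' @param nlambda,lambda_min_ratio Path parameters when `lambda` is NULL.
#' @param folds CV folds.
#' @param seed Seed for the stratified fold assignment.
#' @export
lasso_config <- function(lambda = NULL, nlambda = 100,
                         lambda_min_ratio = 1e-4, folds = 5, seed = 1) {
  if (!is.null(lambda)) {
    stopifnot(length(lambda) >= 1, all(lambda > 0),
              !is.unsorted(rev(lambda)))
  }
  list(lambda = lambda, nlambda = nlambda,
       lambda_min_ratio = lambda_min_ratio, folds = folds, seed = seed)
}

#' Two-stage Cox proportional-hazards feature selection
#'
#' Stage 1: a univariate Cox model per factor (likelihood-ratio test); only
#' factors with p < `p_enter` proceed. Stage 2: a multivariate Cox fit with
#' backward elimination -- the current largest-p factor (likelihood-ratio
#' test of dropping it) is removed until every remaining factor has
#' p < `p_keep`. Non-converging univariate fits are dropped with a warning,
#' never an error.
#'
#' @param X Data.frame of categorical predictors (reference coding is used,
#'   as is conventional for Cox models).
#' @param time,event Survival times (months) and 0/1 event indicators.
#' @param p_enter,p_keep Stage thresholds (defaults 0.10 and 0.05).
#' @return A `selection_result` with `selected`, `detail` (per-level hazard
#'   ratios of the final model) and the per-stage p-values.
#' @export
cox_select <- function(X, time, event, p_enter = 0.10, p_keep = 0.05) {
  stopifnot(sum(event) >= 1)
  feats <- names(X)
  uni_p <- stats::setNames(rep(NA_real_, length(feats)), feats)
  for (f in feats) {
    x <- droplevels(factor(X[[f]]))
    if (nlevels(x) < 2) next
    fit <- tryCatch(
      suppressWarnings(survival::coxph(survival::Surv(time, event) ~ x)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$coefficients))) {
      warning("univariate Cox fit failed for '", f, "'; factor dropped")
      next
    }
    uni_p[f] <- stats::pchisq(2 * diff(fit$loglik),
                              df = sum(!is.na(fit$coefficients)),
                              lower.tail = FALSE)
  }
  entered <- feats[!is.na(uni_p) & uni_p < p_enter]
  current <- entered
  multi_p <- stats::setNames(numeric(0), character(0))
  while (length(current) > 0) {
    d <- droplevels(as.data.frame(lapply(X[current], factor)))
    d$.time <- time; d$.event <- event
    full <- tryCatch(
      suppressWarnings(survival::coxph(
        stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                paste(sprintf("`%s`", current),
                                      collapse = " + "))),
        data = d)),
      error = function(e) NULL)
    if (is.null(full)) { current <- current[-length(current)]; next }
    multi_p <- vapply(current, function(f) {
      rest <- setdiff(current, f)
      red <- if (length(rest) == 0) {
        survival::coxph(survival::Surv(.time, .event) ~ 1, data = d)
      } else {
        suppressWarnings(survival::coxph(
          stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                  paste(sprintf("`%s`", rest),
                                        collapse = " + "))),
          data = d))
      }
      stats::pchisq(2 * (full$loglik[2] - red$loglik[length(red$loglik)]),
                    df = sum(!is.na(full$coefficients)) -
                      sum(!is.na(red$coefficients)),
                    lower.tail = FALSE)
    }, 0)
    worst <- which.max(multi_p)
    if (multi_p[worst] >= p_keep) {
      current <- setdiff(current, names(multi_p)[worst])
    } else break
  }
  detail <- if (length(current)) {
    d <- droplevels(as.data.frame(lapply(X[current], factor)))
    d$.time <- time; d$.event <- event
    fit <- suppressWarnings(survival::coxph(
      stats::as.formula(paste("survival::Surv(.time, .event) ~",
                              paste(sprintf("`%s`", current),
                                    collapse = " + "))),
      data = d))
    data.frame(term = names(fit$coefficients),
               hazard_ratio = exp(unname(fit$coefficients)),
               p_factor = unname(multi_p[vapply(
                 names(fit$coefficients), function(tm) {
                   current[which.max(vapply(
                     current, function(f) startsWith(tm, paste0("`", f)) ||
                       startsWith(tm, f), TRUE))]
                 }, "")]),
               stringsAsFactors = FALSE)
  } else data.frame(term = character(), hazard_ratio = numeric(),
                    p_factor = numeric())
  structure(list(method = "cox", selected = current,
                 univariate_p = uni_p, entered = entered,
                 multivariate_p = multi_p, detail = detail),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(toupper(x$method), "selection:",
      if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(empty)", "\n")
  invisible(x)
}

#' Bootstrap stability profile of a feature selector
#'
#' Runs a selector on `B` bootstrap resamples and summarizes how stable its
#' selected feature set is: the per-resample set sizes (min / median / max)
#' and the per-feature selection frequency ranking.
#'
#' @param selector A function taking a row-index vector and returning the
#'   character vector of selected features for that resample.
#' @param n Number of rows available for resampling.
#' @param B Number of resamples (>= 2).
#' @param seed Seed.
#' @param resample Set FALSE to rerun the selector on the identical full
#'   sample (useful to verify a deterministic selector gives a zero-width
#'   size range).
#' @return A `stability_profile` list: `sizes`, `size_range`
#'   `(min, median, max)`, `feature_frequency`.
#' @export
stability_profile <- function(selector, n, B = 100, seed = 1,
                              resample = TRUE) {
  stopifnot(B >= 2)
  set.seed(seed)
  sizes <- integer(B)
  freq <- integer(0)
  for (b in seq_len(B)) {
    idx <- if (resample) sample.int(n, n, replace = TRUE) else seq_len(n)
    sel <- tryCatch(selector(idx), error = function(e) character(0))
    sizes[b] <- length(sel)
    for (f in sel) freq[f] <- (if (f %in% names(freq)) freq[[f]] else 0L) + 1L
  }
  structure(list(
    sizes = sizes,
    size_range = c(min = min(sizes), median = stats::median(sizes),
                   max = max(sizes)),
    feature_frequency = sort(freq / B, decreasing = TRUE)),
    class = "stability_profile")
}

#' @export
print.stability_profile <- function(x, ...) {
  cat("Selection stability over", length(x$sizes), "resamples: size",
      x$size_range["min"], "-", x$size_range["max"],
      "(median", x$size_range["median"], ")\n")
  invisible(x)
}
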