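#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic; tied scores receive half credit.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param y 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Youden-index operating threshold
#'
#' Chooses the score cutpoint maximizing J = sensitivity + specificity - 1
#' under the convention that `score >= threshold` predicts positive.
#' Candidate thresholds are the observed scores; ties in J are broken toward
#' the higher-specificity (larger) threshold. Constant scores give J = 0 and
#' the constant is returned as the threshold.
#'
#' @param scores Numeric scores.
#' @param y 0/1 labels (both classes required).
#' @return The threshold, with attribute `J` (the achieved Youden index).
#' @export
youden_threshold <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  cand <- sort(unique(scores))
  ord <- order(scores)
  ys <- y[ord]; ss <- scores[ord]
  # for threshold t: positives called = scores >= t
  # walk candidates ascending; count of labels below each candidate
  idx <- findInterval(cand, ss, left.open = TRUE)   # scores < t  (strictly)
  cum1 <- cumsum(ys); cum0 <- cumsum(1 - ys)
  below1 <- ifelse(idx == 0, 0, cum1[pmax(idx, 1)])
  below0 <- ifelse(idx == 0, 0, cum0[pmax(idx, 1)])
  sens <- (n1 - below1) / n1
  spec <- below0 / n0
  j <- sens + spec - 1
  best <- max(j)
  t <- max(cand[j >= best - 1e-12])   # ties -> higher specificity
  structure(t, J = best)
}

#' F-score from precision and sensitivity
#'
#' Harmonic-mean identity `2 * PPV * sens / (PPV + sens)`.
#'
#' @param ppv Positive predictive value (precision), in `[0, 1]`.
#' @param sens Sensitivity (recall), in `[0, 1]`.
#' @return The F-score; `NA` when `ppv + sens` is 0 or either input is `NA`.
#' @examples
#' f_score(0.900, 0.762)  # ~0.825
#' @export
f_score <- function(ppv, sens) {
  ifelse(is.na(ppv) | is.na(sens) | (ppv + sens) == 0,
         NA_real_, 2 * ppv * sens / (ppv + sens))
}

#' Six-measure classification metric set
#'
#' AUC (rank statistic), sensitivity, specificity, PPV, NPV and F-score at
#' the operating threshold, with the `score >= threshold` positive-call
#' convention. Undefined predictive values (no predicted positives or
#' negatives) are reported as `NA`, not 0.
#'
#' @param scores Numeric scores.
#' @param y 0/1 labels (both classes required).
#' @param threshold Operating threshold, e.g. from [youden_threshold()].
#' @return Named numeric vector `auc, f_score, ppv, npv, specificity,
#'   sensitivity, threshold`.
#' @export
compute_metrics <- function(scores, y, threshold) {
  y <- as.integer(y)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ppv <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  npv <- if (tn + fn == 0) NA_real_ else tn / (tn + fn)
  c(auc = auc_rank(scores, y),
    f_score = f_score(ppv, sens),
    ppv = ppv, npv = npv,
    specificity = spec, sensitivity = sens,
    threshold = threshold)
}

#' Percentile bootstrap of an evaluation-set metric
#'
#' Resamples the rows of `data` with replacement `B` times, applies
#' `metric_fn` to each resample, and returns the mean with percentile
#' 2.5/97.5% bounds (per component when `metric_fn` returns a vector).
#' Degenerate resamples -- single-class, or any error inside `metric_fn` --
#' are skipped and counted; more than 50% degenerate resamples is an error.
#'
#' @param metric_fn Function taking a resampled `data` object.
#' @param data A data.frame or list of equal-length vectors.
#' @param B Number of resamples (>= 2).
#' @param seed Seed.
#' @return A list with `mean`, `lower95`, `upper95` (each named as the
#'   metric components), `B_used`, and `skipped`.
#' @export
bootstrap_ci <- function(metric_fn, data, B = 1000, seed = 1) {
  stopifnot(B >= 2)
  n <- if (is.data.frame(data)) nrow(data) else length(data[[1]])
  set.seed(seed)
  vals <- vector("list", B)
  skipped <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    res <- if (is.data.frame(data)) data[idx, , drop = FALSE]
           else lapply(data, `[`, idx)
    v <- tryCatch(metric_fn(res), error = function(e) NULL)
    if (is.null(v)) skipped <- skipped + 1L else vals[[b]] <- v
  }
  if (skipped > B / 2) {
    stop("more than 50% of bootstrap resamples were degenerate",
         call. = FALSE)
  }
  mat <- do.call(rbind, vals[!vapply(vals, is.null, TRUE)])
  list(mean = colMeans(mat, na.rm = TRUE),
       lower95 = apply(mat, 2, stats::quantile, 0.025, na.rm = TRUE,
                       names = FALSE),
       upper95 = apply(mat, 2, stats::quantile, 0.975, na.rm = TRUE,
                       names = FALSE),
       B_used = B - skipped, skipped = skipped)
}
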