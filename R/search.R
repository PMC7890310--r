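#' Combination search for causal predictors of a discrete label
#'
#' First phase of McDSL. For every factor combination of scale 1 up to
#' `max_scale`, the combination is collapsed into a composite factor and
#' scored by the association measure [correlation_R()] against the label;
#' the `top_k` combinations per scale then undergo the additive-noise-model
#' direction test [anm_direction()], and those with a `forward` verdict are
#' retained as causal, sorted by descending association.
#'
#' @param X A data.frame of categorical predictors.
#' @param y Label vector (typically the 3-class label).
#' @param alpha Significance level of the ANM and association tests.
#' @param max_scale Largest combination scale searched; values above
#'   `ncol(X)` are clipped with a warning.
#' @param top_k Number of top-association combinations per scale forwarded
#'   to the ANM stage; use `Inf` to disable pruning.
#' @param measure Association measure, see [correlation_R()].
#' @return An object of class `mcdsl_search`: a data.frame `causal` with one
#'   row per causal combination (key, scale, R, p-values), the evaluated
#'   count, and the call parameters.
#' @export
mcdsl_search <- function(X, y, alpha = 0.05, max_scale = 4, top_k = 50,
                         measure = c("cramers_v", "nmi")) {
  measure <- match.arg(measure)
  p <- ncol(X)
  stopifnot(p >= 1, nrow(X) == length(y))
  if (max_scale > p) {
    warning("max_scale exceeds the number of features; clipped to ", p)
    max_scale <- p
  }
  enc <- lapply(X, int_codes)
  ks <- vapply(enc, `[[`, 0L, "k")
  codes <- lapply(enc, `[[`, "code")
  ey <- int_codes(y)
  nms <- names(X)

  rows <- list()
  n_eval <- 0L
  for (s in seq_len(max_scale)) {
    combos <- utils::combn(p, s)
    nc <- ncol(combos)
    rvals <- numeric(nc)
    ccache <- vector("list", nc)
    for (i in seq_len(nc)) {
      idx <- combos[, i]
      raw <- codes[[idx[1L]]] - 1
      if (s > 1L) for (j in idx[-1L]) raw <- raw * ks[j] + (codes[[j]] - 1)
      ux <- sort.int(unique(raw))
      cxi <- match(raw, ux)
      ccache[[i]] <- list(code = cxi, k = length(ux))
      rvals[i] <- cramers_v_codes(cxi, length(ux), ey$code, ey$k, measure)
    }
    n_eval <- n_eval + nc
    keep <- order(rvals, decreasing = TRUE)
    keep <- keep[seq_len(min(top_k, nc))]
    for (i in keep) {
      cx <- ccache[[i]]
      res <- anm_direction_codes(cx$code, cx$k, ey$code, ey$k, alpha)
      if (res$verdict == "forward") {
        rows[[length(rows) + 1L]] <- data.frame(
          key = paste(nms[combos[, i]], collapse = "+"),
          scale = s, R = rvals[i],
          p_assoc = res$p_assoc, p_forward = res$p_forward,
          p_backward = res$p_backward,
          stringsAsFactors = FALSE)
      }
    }
  }
  causal <- if (length(rows)) do.call(rbind, rows) else
    data.frame(key = character(), scale = integer(), R = numeric(),
               p_assoc = numeric(), p_forward = numeric(),
               p_backward = numeric())
  causal <- causal[order(-causal$R), , drop = FALSE]
  rownames(causal) <- NULL
  structure(list(causal = causal, n_evaluated = n_eval,
                 alpha = alpha, max_scale = max_scale, top_k = top_k,
                 measure = measure, features = nms),
            class = "mcdsl_search")
}

# association measure from pre-coded vectors (hot path)
cramers_v_codes <- function(cx, kx, cy, ky, measure = "cramers_v") {
  if (kx < 2 || ky < 2) return(0)
  counts <- matrix(tabulate((cx - 1L) * ky + cy, nbins = kx * ky),
                   nrow = kx, byrow = TRUE)
  m <- sum(counts)
  if (measure == "cramers_v") {
    expected <- outer(rowSums(counts), colSums(counts)) / m
    stat <- sum((counts - expected)^2 / expected)
    return(min(1, sqrt(stat / (m * (min(dim(counts)) - 1)))))
  }
  pm <- counts / m
  px <- rowSums(pm); py <- colSums(pm)
  nz <- pm > 0
  mi <- sum(pm[nz] * log(pm[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  max(0, min(1, mi / sqrt(hx * hy)))
}

#' @export
print.mcdsl_search <- function(x, ...) {
  cat("McDSL combination search: ", x$n_evaluated, " combinations scored, ",
      nrow(x$causal), " causal at alpha = ", x$alpha, "\n", sep = "")
  if (nrow(x$causal)) print(utils::head(x$causal, 10))
  invisible(x)
}

#' Bootstrap stability selection of a causal factor combination
#'
#' Second phase of McDSL. [mcdsl_search()] is run on `B` bootstrap resamples
#' of the training data; the candidate set is the collection of combinations
#' inferred causal in *all* resamples, and the final selection is the
#' candidate whose constituent factors maximize a cross-validated logistic
#' AUC on the binarized 3-year outcome. Per-feature selection frequencies
#' (membership of the per-resample top-association causal combination) and
#' the per-resample scale histogram are also returned.
#'
#' @inheritParams mcdsl_search
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed for resampling and fold assignment.
#' @param auc_fn Function `(X_subset, y) -> AUC` ranking candidate
#'   combinations; default is 5-fold cross-validated logistic AUC on
#'   [binarize_3yr()] of the label.
#' @return An object of class `mcdsl_run`: `candidates` (unanimous
#'   combinations with their AUCs), `selected` (character vector of the
#'   winning combination's factors), `feature_frequency`, `scale_histogram`,
#'   `set_sizes` (per-resample top causal combination size), and
#'   `unanimous` (FALSE when no combination survived every resample, in
#'   which case the most frequent ones are used instead).
#' @export
stability_select <- function(X, y, B = 100, seed = 1, alpha = 0.05,
                             max_scale = 4, top_k = 50,
                             measure = "cramers_v", auc_fn = NULL) {
  stopifnot(B >= 1)
  n <- nrow(X)
  set.seed(seed)
  freq <- integer(0)            # per-combination causal count
  best_feat_count <- stats::setNames(integer(ncol(X)), names(X))
  set_sizes <- integer(B)
  scales <- integer(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    sr <- mcdsl_search(X[idx, , drop = FALSE], y[idx], alpha = alpha,
                       max_scale = max_scale, top_k = top_k,
                       measure = measure)
    keys <- unique(sr$causal$key)
    for (k in keys) freq[k] <- (if (k %in% names(freq)) freq[[k]] else 0L) + 1L
    if (nrow(sr$causal)) {
      top <- strsplit(sr$causal$key[1L], "+", fixed = TRUE)[[1L]]
      best_feat_count[top] <- best_feat_count[top] + 1L
      set_sizes[b] <- length(top)
      scales[b] <- length(top)
    }
  }
  unanimous <- names(freq)[freq == B]
  flag <- length(unanimous) > 0
  if (!flag) {
    if (length(freq) == 0) {
      return(structure(list(
        candidates = data.frame(key = character(), auc = numeric()),
        selected = character(0), unanimous = FALSE,
        feature_frequency = best_feat_count / B,
        scale_histogram = table(factor(scales, levels = 0:max_scale)),
        set_sizes = set_sizes, B = B, seed = seed,
        note = "no causal combination in any resample"),
        class = "mcdsl_run"))
    }
    warning("no unanimous combination across the ", B,
            " resamples; falling back to the highest inferred fraction")
    unanimous <- names(freq)[freq == max(freq)]
  }
  if (is.null(auc_fn)) {
    # 3-class survival labels binarize on the event-within-horizon class;
    # other discrete labels fall back to a median dichotomization
    ybin <- if (all(y %in% 1:3)) binarize_3yr(y)
            else as.integer(y > stats::median(as.numeric(y)))
    if (length(unique(ybin)) < 2) ybin <- as.integer(y == max(y))
    auc_fn <- function(Xs, yy) cv_logistic_auc(Xs, ybin, folds = 5,
                                               seed = seed)
  }
  aucs <- vapply(unanimous, function(k) {
    feats <- strsplit(k, "+", fixed = TRUE)[[1L]]
    auc_fn(X[, feats, drop = FALSE], y)
  }, 0)
  ord <- order(-aucs)
  candidates <- data.frame(key = unanimous[ord], auc = aucs[ord],
                           frequency = freq[unanimous][ord] / B,
                           stringsAsFactors = FALSE)
  rownames(candidates) <- NULL
  selected <- strsplit(candidates$key[1L], "+", fixed = TRUE)[[1L]]
  structure(list(
    candidates = candidates,
    selected = selected,
    unanimous = flag,
    feature_frequency = sort(best_feat_count / B, decreasing = TRUE),
    scale_histogram = table(factor(scales, levels = 0:max_scale)),
    set_sizes = set_sizes,
    B = B, seed = seed),
    class = "mcdsl_run")
}

#' @export
print.mcdsl_run <- function(x, ...) {
  cat("McDSL stability selection over", x$B, "bootstrap resamples\n")
  if (!length(x$selected)) {
    cat("  no causal combination found\n"); return(invisible(x))
  }
  cat("  selected combination:", paste(x$selected, collapse = " + "),
      if (!x$unanimous) "(no unanimous combination; highest fraction used)",
      "\n")
  cat("  candidate AUC (top 5):\n")
  print(utils::head(x$candidates, 5))
  invisible(x)
}

#' Cross-validated logistic AUC of a factor subset
#'
#' Stratified k-fold cross-validation of an unpenalized logistic model on the
#' one-hot design of the given factors; held-out scores are pooled into a
#' single rank AUC. Used to rank unanimous McDSL candidates.
#'
#' @param X Data.frame of categorical predictors.
#' @param ybin 0/1 outcome.
#' @param folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @return Pooled out-of-fold AUC.
#' @export
cv_logistic_auc <- function(X, ybin, folds = 5, seed = 1) {
  mm <- apply_onehot(X, onehot_recipe(X))
  n <- nrow(mm)
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(ybin)) {
    idx <- which(ybin == cls)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  scores <- numeric(n)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, mm[tr, , drop = FALSE]), ybin[tr],
                     family = stats::binomial()))
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    scores[!tr] <- stats::plogis(
      cbind(1, mm[!tr, , drop = FALSE]) %*% beta)
  }
  auc_rank(scores, ybin)
}
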