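#' Empirical joint distribution of two categorical variables
#'
#' @param x,y Equal-length categorical vectors (factor, character, integer).
#' @return An object of class `joint_distribution`: observed levels of each
#'   variable, the matrix of cell probabilities (rows = levels of `x`,
#'   columns = levels of `y`), and the sample size `m`.
#' @examples
#' jd <- joint_distribution(c("a", "a", "b", "b"), c(1, 1, 2, 2))
#' jd$p  # 0.5 on the diagonal
#' @export
joint_distribution <- function(x, y) {
  if (length(x) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(x) == length(y))
  tab <- table(as.character(x), as.character(y))
  structure(list(
    p = unclass(tab) / length(x),
    counts = unclass(tab),
    levels_x = rownames(tab),
    levels_y = colnames(tab),
    m = length(x)
  ), class = "joint_distribution")
}

#' Association strength of a joint distribution
#'
#' A symmetric measure in `[0, 1]` of how far a joint distribution is from
#' the product of its marginals: 0 under exact independence, 1 under a
#' bijective deterministic relation. The default is Cramér's V,
#' `sqrt(chi2 / (m * (min(kx, ky) - 1)))`; normalized mutual information
#' (`I(X;Y) / sqrt(H(X) H(Y))`, natural logs) is available as an alternative.
#' This is the correlation score used to rank factor combinations in the
#' causal search.
#'
#' @param jd A [joint_distribution()], or a categorical vector (then `y` must
#'   be supplied).
#' @param y Optional second vector when `jd` is a vector.
#' @param measure `"cramers_v"` (default) or `"nmi"`.
#' @return A number in `[0, 1]`. A degenerate single-level variable yields 0
#'   with a warning.
#' @examples
#' correlation_R(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1: bijective
#' @export
correlation_R <- function(jd, y = NULL, measure = c("cramers_v", "nmi")) {
  measure <- match.arg(measure)
  if (!inherits(jd, "joint_distribution")) jd <- joint_distribution(jd, y)
  p <- jd$p
  if (nrow(p) < 2 || ncol(p) < 2) {
    warning("degenerate single-level factor: association set to 0")
    return(0)
  }
  if (measure == "cramers_v") {
    chi2 <- chi2_statistic(jd$counts)
    v <- sqrt(chi2 / (jd$m * (min(dim(p)) - 1)))
    return(min(v, 1))
  }
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(px, py)[nz]))
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx == 0 || hy == 0) return(0)
  max(0, min(1, mi / sqrt(hx * hy)))
}

# Pearson chi-squared statistic of a count matrix (no continuity correction);
# all-zero rows/columns are dropped first.
chi2_statistic <- function(counts) {
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) return(0)
  m <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / m
  sum((counts - expected)^2 / expected)
}

#' Pearson chi-squared independence test
#'
#' Plain Pearson chi-squared on the contingency table of two categorical
#' vectors, without continuity correction, with
#' `df = (k_a - 1) * (k_b - 1)` over the observed levels and an upper-tail
#' p-value. A variable with fewer than two observed levels gives p = 1.
#' Warns when more than 20% of expected counts fall below 5 (the usual
#' small-count caveat for the asymptotic reference distribution); the warning
#' can be silenced because the causal search evaluates many sparse composite
#' tables by design.
#'
#' @param a,b Equal-length categorical vectors.
#' @param warn_small Warn on sparse expected counts (default FALSE).
#' @return The upper-tail p-value.
#' @examples
#' a <- rep(c("x", "y"), c(30, 30))
#' b <- rep(c(1, 2, 1, 2), c(10, 20, 20, 10))
#' chi2_independence(a, b)  # ~0.0098
#' @export
chi2_independence <- function(a, b, warn_small = FALSE) {
  if (length(a) == 0) stop("empty input", call. = FALSE)
  stopifnot(length(a) == length(b))
  ia <- int_codes(a); ib <- int_codes(b)
  p_chi2_codes(ia$code, ia$k, ib$code, ib$k, warn_small = warn_small)
}

# 1-based integer codes in sorted level order, plus level count.
int_codes <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  ux <- sort(unique(x))
  list(code = match(x, ux), k = length(ux), levels = ux)
}

# chi-squared p-value from pre-coded vectors (hot path of the search)
p_chi2_codes <- function(ca, ka, cb, kb, warn_small = FALSE) {
  if (ka < 2 || kb < 2) return(1)
  counts <- matrix(tabulate((ca - 1L) * kb + cb, nbins = ka * kb),
                   nrow = ka, byrow = TRUE)
  counts <- counts[rowSums(counts) > 0, colSums(counts) > 0, drop = FALSE]
  r <- nrow(counts); cc <- ncol(counts)
  if (r < 2 || cc < 2) return(1)
  m <- sum(counts)
  expected <- outer(rowSums(counts), colSums(counts)) / m
  if (warn_small && mean(expected < 5) > 0.2) {
    warning("more than 20% of expected counts are below 5; ",
            "chi-squared p-value is approximate")
  }
  stat <- sum((counts - expected)^2 / expected)
  stats::pchisq(stat, df = (r - 1) * (cc - 1), lower.tail = FALSE)
}
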