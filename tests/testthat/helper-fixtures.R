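# Shared fixtures and independent oracles, built in code at test time.

small_cohort <- function(n = 200, seed = 11, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# Independent oracle for the association measure: Cramér's V straight from
# chisq.test on a base-R table.
oracle_cramers_v <- function(x, y) {
  tab <- table(x, y)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(0)
  stat <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  unname(sqrt(stat / (sum(tab) * (min(dim(tab)) - 1))))
}

# Independent oracle for the ANM direction test, written against base R
# (paste-composites, tapply modes, chisq.test) rather than package internals.
oracle_anm <- function(xvec, yvec, alpha = 0.05) {
  p_of <- function(a, b) {
    tab <- table(a, b)
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
    suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  }
  code <- function(v) match(v, sort(unique(v)))
  modal <- function(target, by) {
    m <- tapply(target, by, function(z) sort(unique(z))[
      which.max(tabulate(match(z, sort(unique(z)))))])
    unname(m[as.character(by)])
  }
  cx <- code(xvec); cy <- code(yvec)
  p_assoc <- p_of(cx, cy)
  e_f <- cy - modal(cy, cx)
  p_f <- p_of(cx, e_f)
  e_b <- cx - modal(cx, cy)
  p_b <- p_of(cy, e_b)
  verdict <- if (p_assoc >= alpha) "none"
  else if (p_f >= alpha && p_b < alpha) "forward"
  else if (p_b >= alpha && p_f < alpha) "backward"
  else if (p_f >= alpha && p_b >= alpha) "inconclusive"
  else "none"
  list(p_assoc = p_assoc, p_forward = p_f, p_backward = p_b,
       verdict = verdict)
}

# A small factor matrix with one feature driving the label through an
# additive-noise mechanism, plus independent distractors.
planted_singleton_data <- function(n = 400, n_distractors = 4, seed = 1) {
  set.seed(seed)
  x <- sample(c("a", "b", "c"), n, replace = TRUE)
  y <- c(a = 1L, b = 2L, c = 3L)[x] +
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = c(.05, .9, .05))
  X <- data.frame(cause = x, stringsAsFactors = FALSE)
  for (j in seq_len(n_distractors)) {
    X[[paste0("noise", j)]] <- sample(c("u", "v"), n, replace = TRUE)
  }
  list(X = X, y = unname(y))
}
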