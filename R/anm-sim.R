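#' Simulate a discrete additive-noise replicate
#'
#' Generates the synthetic mechanism used to validate the direction-inference
#' step: `scale` independent Bernoulli(1/2) binary cause factors, a
#' non-injective integer mapping `f` from their value-tuples to a small label
#' alphabet, and independent asymmetric integer noise, so that
#' `y = f(x_S) + N` with `N` independent of the cause -- the defining
#' property of the additive-noise model.
#'
#' The noise is added over the integers *without* clipping at the label
#' boundaries: clipping would make the residual distribution differ across
#' the boundary strata of the cause, which destroys the forward independence
#' that the model asserts (see the methods vignette for the calculation).
#' The label simply takes one extra integer level on each side.
#'
#' @param n Sample size.
#' @param scale Number of binary cause factors (the combination scale).
#' @param n_distractors Number of additional independent binary factors with
#'   no effect on the label.
#' @param noise_probs Probabilities of noise values `-1, 0, +1`.
#' @param f Optional integer mapping from 0-based composite codes
#'   (length `2^scale`); the default collapses the `2^scale` tuples onto
#'   `2^(scale-1) + 1` consecutive integers (non-injective for scale >= 2,
#'   identity for scale 1).
#' @param seed Optional seed.
#' @return A list: `data` (data.frame of the binary factors, causes named
#'   `x1..x<scale>`, distractors `d1..`), `cause` (cause column names),
#'   `composite` (the [combine()] composite of the causes), `y` (integer
#'   label), and `f`.
#' @examples
#' rep <- simulate_anm_replicate(n = 500, scale = 2, seed = 1)
#' anm_direction(rep$composite, rep$y)$verdict
#' @export
simulate_anm_replicate <- function(n = 2000, scale = 2, n_distractors = 0,
                                   noise_probs = c(0.05, 0.85, 0.10),
                                   f = NULL, seed = NULL) {
  stopifnot(scale >= 1, n >= 10, length(noise_probs) == 3,
            abs(sum(noise_probs) - 1) < 1e-9)
  if (!is.null(seed)) set.seed(seed)
  k <- 2L^scale
  if (is.null(f)) {
    # scale 1 -> identity 0,1; scale 2 -> 0,1,1,2 (3-class label);
    # scale >= 3 -> pairwise collapse floor(code/2), non-injective
    f <- if (scale == 1) 0:1
         else if (scale == 2) c(0L, 1L, 1L, 2L)
         else as.integer((seq_len(k) - 1L) %/% 2L)
  }
  stopifnot(length(f) == k)
  cause <- paste0("x", seq_len(scale))
  data <- as.data.frame(
    matrix(sample(c("0", "1"), n * scale, replace = TRUE), ncol = scale,
           dimnames = list(NULL, cause)),
    stringsAsFactors = FALSE)
  if (n_distractors > 0) {
    d <- matrix(sample(c("0", "1"), n * n_distractors, replace = TRUE),
                ncol = n_distractors,
                dimnames = list(NULL, paste0("d", seq_len(n_distractors))))
    data <- cbind(data, as.data.frame(d, stringsAsFactors = FALSE))
  }
  data[] <- lapply(data, factor, levels = c("0", "1"))
  composite <- combine(cause, data)
  # codebook rows are in lexicographic tuple order, so the 0-based raw code
  # of row i of the codebook is i - 1 when all tuples are observed; map via
  # the codebook to stay correct when some tuples are unobserved.
  raw0 <- mixed_radix_code(
    lapply(cause, function(nm) match(composite$codebook[[nm]], c("0", "1"))),
    rep(2L, scale)) - 1L
  y <- f[raw0 + 1L][composite$codes] +
    sample(c(-1L, 0L, 1L), n, replace = TRUE, prob = noise_probs)
  list(data = data, cause = cause, composite = composite,
       y = as.integer(y), f = f)
}
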