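# combination search and bootstrap stability selection

test_that("a determining singleton is retained and distractors are not", {
  d <- planted_singleton_data(n = 500, seed = 3)
  sr <- mcdsl_search(d$X, d$y, max_scale = 1, top_k = Inf)
  expect_true("cause" %in% sr$causal$key)
  expect_false(any(grepl("noise", sr$causal$key)))
})

test_that("max_scale beyond the feature count is clipped with a warning", {
  d <- planted_singleton_data(n = 200, n_distractors = 1, seed = 4)
  expect_warning(sr <- mcdsl_search(d$X, d$y, max_scale = 10, top_k = 5),
                 "clipped")
  expect_equal(sr$max_scale, 2)
})

test_that("type-I control: causal rate on pure noise stays near alpha", {
  set.seed(50)
  declared <- 0; tested <- 0; empty <- 0
  for (s in 1:60) {
    X <- data.frame(a = sample(c("x", "y"), 250, TRUE),
                    b = sample(c("x", "y"), 250, TRUE),
                    c = sample(1:3, 250, TRUE))
    y <- sample(1:3, 250, TRUE)
    sr <- mcdsl_search(X, y, max_scale = 2, top_k = Inf)
    declared <- declared + nrow(sr$causal)
    tested <- tested + sr$n_evaluated
    empty <- empty + (nrow(sr$causal) == 0)
  }
  rate <- declared / tested
  se <- sqrt(0.05 * 0.95 / tested)
  expect_lte(rate, 0.05 + 3 * se)
  # with the association gate the all-null search is empty nearly always
  expect_gte(empty / 60, 0.9)
})

test_that("search with pruning disabled equals brute-force enumeration", {
  # n = 5 features, all combinations, independent oracle from base R
  set.seed(77)
  n <- 300
  X <- data.frame(f1 = sample(c("a", "b"), n, TRUE),
                  f2 = sample(c("a", "b", "c"), n, TRUE),
                  f3 = sample(c("a", "b"), n, TRUE),
                  f4 = sample(c("a", "b"), n, TRUE),
                  f5 = sample(c("a", "b"), n, TRUE))
  y <- (X$f1 == "a") + (X$f2 == "b") + 1 +
    sample(0:1, n, TRUE, prob = c(.8, .2))
  sr <- mcdsl_search(X, y, max_scale = 5, top_k = Inf)
  # oracle: enumerate all 2^5 - 1 combinations by hand
  oracle_rows <- list()
  for (size in 1:5) {
    for (cols in utils::combn(names(X), size, simplify = FALSE)) {
      xs <- do.call(paste, c(X[cols], sep = "\r"))
      r <- oracle_cramers_v(xs, y)
      o <- oracle_anm(match(xs, sort(unique(xs))), y)
      if (o$verdict == "forward") {
        oracle_rows[[length(oracle_rows) + 1]] <-
          data.frame(key = paste(cols, collapse = "+"), R = r)
      }
    }
  }
  oracle <- do.call(rbind, oracle_rows)
  expect_setequal(sr$causal$key, oracle$key)
  m <- merge(sr$causal, oracle, by = "key")
  expect_equal(m$R.x, m$R.y, tolerance = 1e-10)
  # and the output is sorted by descending R
  expect_false(is.unsorted(rev(sr$causal$R)))
})

test_that("stability selection is deterministic and reports its structure", {
  d <- planted_singleton_data(n = 300, n_distractors = 2, seed = 9)
  r1 <- suppressWarnings(stability_select(d$X, d$y, B = 5, seed = 123,
                                          max_scale = 2, top_k = 10))
  r2 <- suppressWarnings(stability_select(d$X, d$y, B = 5, seed = 123,
                                          max_scale = 2, top_k = 10))
  expect_identical(r1$candidates, r2$candidates)
  expect_identical(r1$selected, r2$selected)
  expect_length(r1$set_sizes, 5)
  expect_equal(sum(r1$scale_histogram), 5)
  # the planted cause is the winning selection
  expect_true("cause" %in% r1$selected)
  expect_gte(unname(r1$feature_frequency["cause"]), 0.6)
})

test_that("B = 1 reduces to a single resampled search plus AUC ranking", {
  d <- planted_singleton_data(n = 300, n_distractors = 2, seed = 10)
  r <- suppressWarnings(stability_select(d$X, d$y, B = 1, seed = 5,
                                         max_scale = 2, top_k = 10))
  set.seed(5)
  idx <- sample.int(300, 300, replace = TRUE)
  sr <- mcdsl_search(d$X[idx, ], d$y[idx], max_scale = 2, top_k = 10)
  expect_setequal(r$candidates$key, unique(sr$causal$key))
})
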