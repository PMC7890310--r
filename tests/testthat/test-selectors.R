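# LASSO and Cox baseline selectors

make_binary_design <- function(n, p_noise, beta, seed) {
  set.seed(seed)
  X <- data.frame(strong = sample(c("lo", "hi"), n, TRUE))
  for (j in seq_len(p_noise)) {
    X[[paste0("noise", j)]] <- sample(c("u", "v"), n, TRUE)
  }
  eta <- beta * (X$strong == "hi") - beta / 2
  y <- stats::rbinom(n, 1, stats::plogis(eta))
  list(X = X, y = y)
}

test_that("full shrinkage with a huge lambda selects nothing", {
  d <- make_binary_design(200, 3, 2, seed = 1)
  res <- lasso_select(d$X, d$y, lasso_config(lambda = 1e6, seed = 1))
  expect_length(res$selected, 0)
})

test_that("a planted strong predictor is selected at the CV-AUC lambda", {
  hits <- 0
  for (s in 1:10) {
    d <- make_binary_design(500, 10, 2, seed = s)
    res <- lasso_select(d$X, d$y, lasso_config(seed = s))
    hits <- hits + ("strong" %in% res$selected)
  }
  expect_gte(hits, 9)
})

test_that("duplicated informative columns: at least one copy survives", {
  d <- make_binary_design(500, 4, 2, seed = 3)
  d$X$strong_copy <- d$X$strong
  res <- lasso_select(d$X, d$y, lasso_config(seed = 3))
  expect_true(any(c("strong", "strong_copy") %in% res$selected))
})

test_that("lasso path: selected-set size shrinks toward large lambda", {
  # note: strict monotonicity of the active-set size along a LASSO path is
  # not a true property (features can leave and re-enter); the honest
  # checkable properties are full shrinkage at lambda_max and a strongly
  # monotone trend
  d <- make_binary_design(400, 6, 1.5, seed = 5)
  enc <- mcdsl:::onehot_recipe(d$X)
  mm <- mcdsl:::apply_onehot(d$X, enc)
  fit <- glmnet::glmnet(mm, d$y, family = "binomial")
  sizes <- fit$df                      # along decreasing lambda
  expect_equal(sizes[1], 0)            # all-zero at the top of the path
  expect_lte(sizes[1], sizes[length(sizes)])
  expect_lt(stats::cor(log(fit$lambda), sizes, method = "spearman"), -0.85)
})

test_that("cox selection finds a planted hazard-ratio-3 factor", {
  set.seed(8)
  n <- 400
  X <- data.frame(risk = factor(sample(c("lo", "hi"), n, TRUE),
                                levels = c("lo", "hi")),
                  n1 = sample(c("u", "v"), n, TRUE),
                  n2 = sample(c("u", "v"), n, TRUE))
  rate <- 0.02 * ifelse(X$risk == "hi", 3, 1)
  t <- stats::rexp(n, rate)
  cens <- stats::runif(n, 36, 84)
  res <- cox_select(X, pmin(t, cens), as.integer(t <= cens))
  expect_true("risk" %in% res$selected)
  hr <- res$detail$hazard_ratio[grepl("risk", res$detail$term)]
  expect_gt(hr, 2)                     # 'lo' is reference, HR(hi) ~ 3
  expect_lt(hr, 4.5)
})

test_that("factors failing the univariate gate never reach stage 2", {
  set.seed(12)
  n <- 300
  X <- data.frame(a = sample(c("u", "v"), n, TRUE),
                  b = sample(c("u", "v"), n, TRUE))
  t <- stats::rexp(n, 0.03)
  cens <- stats::runif(n, 36, 84)
  res <- cox_select(X, pmin(t, cens), as.integer(t <= cens))
  weak <- names(res$univariate_p)[res$univariate_p >= 0.10]
  expect_true(all(!weak %in% res$entered))
  expect_true(all(!weak %in% res$selected))
})

test_that("cox null selection rate stays below the stage-wise expectation", {
  sel_count <- 0; trials <- 0
  for (s in 1:15) {
    set.seed(400 + s)
    n <- 300
    X <- as.data.frame(lapply(1:10, function(j)
      sample(c("u", "v"), n, TRUE)))
    names(X) <- paste0("f", 1:10)
    t <- stats::rexp(n, 0.03)
    cens <- stats::runif(n, 36, 84)
    res <- cox_select(X, pmin(t, cens), as.integer(t <= cens))
    sel_count <- sel_count + length(res$selected)
    trials <- trials + 10
  }
  expect_lt(sel_count / trials, 0.10)
})

test_that("stability profile: deterministic selector, zero-width size range", {
  d <- make_binary_design(300, 3, 2, seed = 21)
  selector <- function(idx) lasso_select(d$X[idx, ], d$y[idx],
                                         lasso_config(seed = 1))$selected
  prof <- stability_profile(selector, 300, B = 3, seed = 2,
                            resample = FALSE)
  expect_equal(unname(prof$size_range["min"]),
               unname(prof$size_range["max"]))
  prof2 <- stability_profile(selector, 300, B = 3, seed = 2,
                             resample = FALSE)
  expect_identical(prof$sizes, prof2$sizes)
})
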