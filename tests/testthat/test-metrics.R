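# metrics, thresholds, bootstrap

test_that("rank AUC matches pairwise concordance and handles ties", {
  expect_equal(auc_rank(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  # perfect and anti-perfect
  expect_equal(auc_rank(1:10, rep(0:1, each = 5)), 1)
  expect_equal(auc_rank(10:1, rep(0:1, each = 5)), 0)
  # all-tied scores: 0.5 credit
  expect_equal(auc_rank(rep(1, 10), rep(0:1, 5)), 0.5)
  expect_error(auc_rank(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(14)
  for (i in 1:20) {
    s <- stats::rnorm(50)
    y <- stats::rbinom(50, 1, stats::plogis(s))
    if (length(unique(y)) < 2) next
    a <- auc_rank(s, y)
    expect_equal(auc_rank(exp(s), y), a)
    expect_equal(auc_rank(stats::plogis(3 * s - 1), y), a)
  }
})

test_that("youden threshold follows the >= convention and spec tie-break", {
  t <- youden_threshold(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(as.numeric(t), 0.8)      # tie at J = 0.5 -> higher specificity
  expect_equal(attr(t, "J"), 0.5)
  # perfectly separating scores
  t2 <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(attr(t2, "J"), 1)
  expect_equal(as.numeric(t2), 0.8)
  # constant scores: J = 0, threshold reported as the constant
  t3 <- youden_threshold(rep(0.3, 8), rep(0:1, 4))
  expect_equal(as.numeric(t3), 0.3)
  expect_equal(attr(t3, "J"), 0)
  # exhaustive-enumeration oracle on random cases
  set.seed(6)
  for (i in 1:20) {
    s <- round(stats::runif(40), 2)
    y <- stats::rbinom(40, 1, 0.5)
    if (length(unique(y)) < 2) next
    best_j <- max(vapply(unique(s), function(tt) {
      pred <- s >= tt
      mean(pred[y == 1]) + mean(!pred[y == 0]) - 1
    }, 0))
    expect_equal(attr(youden_threshold(s, y), "J"), best_j,
                 tolerance = 1e-12)
  }
})

test_that("metric set reproduces hand values and conserves the confusion", {
  m <- compute_metrics(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1), 0.35)
  expect_equal(unname(m["auc"]), 0.75)
  expect_equal(unname(m["sensitivity"]), 1)
  expect_equal(unname(m["specificity"]), 0.5)
  # perfect classifier at its separating threshold
  mp <- compute_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1), 0.5)
  expect_true(all(mp[c("auc", "f_score", "ppv", "npv", "specificity",
                       "sensitivity")] == 1))
  # no predicted positives: PPV missing, not zero
  m0 <- compute_metrics(c(0.1, 0.2, 0.3, 0.4), c(0, 1, 0, 1), 0.9)
  expect_true(is.na(m0["ppv"]))
  # confusion conservation on random cases
  set.seed(31)
  for (i in 1:50) {
    s <- stats::runif(30); y <- stats::rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    thr <- stats::runif(1)
    m <- compute_metrics(s, y, thr)
    sens <- m[["sensitivity"]]; spec <- m[["specificity"]]
    expect_equal(sens * sum(y) + (1 - sens) * sum(y), sum(y))
    pred <- s >= thr
    expect_equal(sum(pred & y == 1) + sum(!pred & y == 1), sum(y == 1))
    expect_equal(sum(pred & y == 0) + sum(!pred & y == 0), sum(y == 0))
  }
})

test_that("F-score equals the harmonic identity on random confusions", {
  set.seed(9)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp == 0 || tp + fn == 0) next
    ppv <- tp / (tp + fp); sens <- tp / (tp + fn)
    expected <- if (ppv + sens == 0) NA_real_ else
      2 * ppv * sens / (ppv + sens)
    expect_equal(f_score(ppv, sens), expected)
  }
})

test_that("percentile bootstrap: determinism, zero width, coverage", {
  d <- data.frame(x = stats::rnorm(200, mean = 1))
  ci1 <- bootstrap_ci(function(d) c(m = mean(d$x)), d, B = 200, seed = 4)
  ci2 <- bootstrap_ci(function(d) c(m = mean(d$x)), d, B = 200, seed = 4)
  expect_identical(ci1, ci2)
  # constant metric: zero-width interval
  cic <- bootstrap_ci(function(d) c(k = 1), d, B = 50, seed = 1)
  expect_equal(unname(cic$lower95), unname(cic$upper95))
  # nested coverage check for the mean of iid normals
  set.seed(77)
  cover <- 0
  for (r in 1:60) {
    x <- data.frame(v = stats::rnorm(200))
    ci <- bootstrap_ci(function(d) c(m = mean(d$v)), x, B = 200, seed = r)
    cover <- cover + (ci$lower95 <= 0 && 0 <= ci$upper95)
  }
  expect_gte(cover / 60, 0.85)
  # degenerate-resample guard
  expect_error(
    bootstrap_ci(function(d) stop("always"), d, B = 10, seed = 1),
    "degenerate")
})
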