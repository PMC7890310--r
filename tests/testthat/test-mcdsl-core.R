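# joint distributions, association measure, chi-squared, composites

test_that("joint distribution matches hand counts and normalizes", {
  jd <- joint_distribution(c("a", "a", "b", "b"), c(1, 1, 2, 2))
  expect_equal(jd$p["a", "1"], 0.5)
  expect_equal(jd$p["b", "2"], 0.5)
  expect_equal(jd$p["a", "2"], 0)
  expect_equal(sum(jd$p), 1)
  jd2 <- joint_distribution(c("a", "b", "a", "b"), c(1, 1, 2, 2))
  expect_true(all(jd2$p == 0.25))
  expect_error(joint_distribution(character(0), character(0)), "empty")
})

test_that("association measure: independence 0, bijection 1, phi example 0.5", {
  # exact product table
  x <- rep(c("a", "b"), each = 50)
  y <- rep(rep(c("p", "q"), each = 25), 2)
  expect_equal(correlation_R(x, y), 0)
  expect_equal(correlation_R(x, y, measure = "nmi"), 0)
  # bijective deterministic relation
  expect_equal(correlation_R(c(1, 2, 3, 1, 2, 3), c("x", "y", "z", "x", "y", "z")), 1)
  # 2x2 counts [[30,10],[10,30]]: phi = 800/1600 = 0.5
  a <- rep(c("r1", "r2"), each = 40)
  b <- c(rep("c1", 30), rep("c2", 10), rep("c1", 10), rep("c2", 30))
  expect_equal(correlation_R(a, b), 0.5)
  expect_equal(correlation_R(a, b), oracle_cramers_v(a, b))
  # symmetry
  expect_equal(correlation_R(a, b), correlation_R(b, a))
  expect_warning(r <- correlation_R(rep("only", 10), b[1:10]), "degenerate")
  expect_equal(r, 0)
})

test_that("association measure agrees with the chisq.test oracle on random tables", {
  set.seed(7)
  for (i in 1:20) {
    x <- sample(letters[1:sample(2:4, 1)], 120, replace = TRUE)
    y <- sample(1:sample(2:3, 1), 120, replace = TRUE)
    expect_equal(correlation_R(x, y), oracle_cramers_v(x, y),
                 tolerance = 1e-10)
  }
})

test_that("chi-squared independence test matches hand computation", {
  # counts [[10,20],[20,10]]: chi2 = 60*(100-400)^2/30^4 = 6.667, df 1
  a <- rep(c("x", "y"), each = 30)
  b <- c(rep("1", 10), rep("2", 20), rep("1", 20), rep("2", 10))
  expect_equal(chi2_independence(a, b),
               stats::pchisq(20 / 3, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_lt(abs(chi2_independence(a, b) - 0.0098), 5e-4)
  # perfectly proportional table -> chi2 = 0 -> p = 1
  expect_equal(chi2_independence(rep(c("x", "y"), each = 20),
                                 rep(c("1", "2"), 20)), 1)
  # degenerate single level
  expect_equal(chi2_independence(rep("x", 20), rep(c("1", "2"), 10)), 1)
})

test_that("composite factors partition rows by agreement on S", {
  d <- data.frame(a = c("x", "x", "y", "y"), b = c("1", "2", "1", "2"))
  # identity case
  c1 <- combine("a", d)
  expect_equal(c1$codes, c(1L, 1L, 2L, 2L))
  # all four tuples observed -> 4 codes in lexicographic order
  c2 <- combine(c("a", "b"), d)
  expect_equal(c2$k, 4L)
  expect_equal(c2$codes, 1:4)
  expect_equal(c2$codebook$a, c("x", "x", "y", "y"))
  expect_equal(c2$codebook$b, c("1", "2", "1", "2"))
  # unobserved tuple excluded from the codebook
  d3 <- data.frame(a = c("x", "x", "y"), b = c("1", "2", "1"))
  c3 <- combine(c("a", "b"), d3)
  expect_equal(c3$k, 3L)
  expect_false(any(c3$codebook$a == "y" & c3$codebook$b == "2"))
  # enumeration oracle: same code iff same tuple
  set.seed(5)
  d4 <- data.frame(a = sample(letters[1:3], 60, TRUE),
                   b = sample(1:4, 60, TRUE),
                   c = sample(c("u", "v"), 60, TRUE))
  c4 <- combine(names(d4), d4)
  key <- paste(d4$a, d4$b, d4$c)
  expect_equal(length(unique(c4$codes)), length(unique(key)))
  expect_true(all(tapply(c4$codes, key, function(z) length(unique(z))) == 1))
  expect_error(combine("missing", d), "unknown factor")
  expect_error(combine(c("a", "a"), d), "duplicate")
})

test_that("interfere is the conditional mode with smallest-class tie-break", {
  # y fully determined by x
  expect_equal(interfere(c(1, 1, 2, 2), c("a", "a", "b", "b")), c(1, 1, 2, 2))
  # independence: constant global mode
  y <- c(1, 1, 1, 2, 2, 3)
  x <- rep("s", 6)
  expect_equal(interfere(y, x), rep(1, 6))
  # exact tie within a stratum resolves to the smaller class
  expect_equal(interfere(c(1, 2, 1, 2), c("a", "a", "a", "a")), rep(1, 4))
})

test_that("residuals are integer code differences with bounded range", {
  expect_equal(anm_residual(c(1, 2, 3), c(1, 2, 3)), c(0L, 0L, 0L))
  expect_equal(anm_residual(3, 1), 2L)
  expect_equal(anm_residual(c("a", "c"), c("b", "a")), c(-1L, 2L))
  set.seed(2)
  y <- sample(1:3, 200, TRUE)
  yt <- sample(1:3, 200, TRUE)
  expect_true(all(abs(anm_residual(y, yt)) <= 2))
})
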