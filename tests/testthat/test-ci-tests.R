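test_that("partial correlation matches its closed-form oracles", {
  set.seed(1)
  n <- 4000
  # identical columns: statistic exactly 1
  m <- cbind(X = rnorm(200), Y = 0)
  m[, "Y"] <- m[, "X"]
  r <- ci_test(m, "X", "Y", method = "parcorr", seed = 1,
               n_permutations = 99)
  expect_equal(r$statistic, 1)
  # common cause: analytic partial correlation is exactly 0
  w <- rnorm(n)
  m <- cbind(X = w + rnorm(n), Y = w + rnorm(n), W = w)
  r <- ci_test(m, "X", "Y", conds = data.frame(node = "W", lag = 0),
               method = "parcorr", seed = 1, n_permutations = 199)
  expect_lt(abs(r$statistic), 3 / sqrt(n))
  expect_gt(r$p_value, 0.01)
  # jointly Gaussian triple against the precision-matrix formula
  S <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.4, 0.5, 0.4, 1), 3, 3)
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(S)
  colnames(z) <- c("X", "Y", "W")
  rho <- (S[1, 2] - S[1, 3] * S[2, 3]) /
    sqrt((1 - S[1, 3]^2) * (1 - S[2, 3]^2))
  r <- ci_test(z, "X", "Y", conds = data.frame(node = "W", lag = 0),
               method = "parcorr", seed = 1, n_permutations = 199)
  expect_lt(abs(r$statistic - rho), 3 / sqrt(n))
  # residuals orthogonal to the conditioning column
  expect_lt(abs(sum(r$residuals$x * (z[, "W"] - mean(z[, "W"])))), 1e-6)
})

test_that("distance correlation matches the naive double-sum oracle", {
  set.seed(2)
  x <- rnorm(200)
  y <- x^2 + 0.3 * rnorm(200)
  expect_lt(abs(dcor(x, y) - dcor_naive(x, y)), 1e-10)
  expect_equal(dcor(x, x), 1, tolerance = 1e-12)
})

test_that("GPDC detects a quadratic link that partial correlation misses", {
  n <- 500
  stats <- t(vapply(1:10, function(s) {
    set.seed(s)
    m <- cbind(X = rnorm(n), Y = 0)
    m[, "Y"] <- m[, "X"]^2 + 0.3 * rnorm(n)
    pc <- ci_test(m, "X", "Y", method = "parcorr", seed = s,
                  n_permutations = 199)
    gp <- ci_test(m, "X", "Y", method = "gpdc", seed = s,
                  n_permutations = 199)
    c(pc = abs(pc$statistic), gp = gp$statistic, gp_p = gp$p_value)
  }, numeric(3)))
  # the correlation of X with X^2 is zero in truth; its sample value has a
  # heavy-tailed product, so the bound applies to the across-seed average
  expect_lt(mean(stats[, "pc"]), 3 / sqrt(n))
  expect_true(all(stats[, "gp"] > 0.3))
  expect_true(all(stats[, "gp_p"] < 0.01))
})

test_that("GP-residual conditioning removes a shared non-linear driver", {
  nonsig <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 400
    z <- 3 * runif(n)
    m <- cbind(X = sin(z) + 0.3 * rnorm(n), Y = sin(z) + 0.3 * rnorm(n),
               Z = z)
    r <- ci_test(m, "X", "Y", conds = data.frame(node = "Z", lag = 0),
                 method = "gpdc", seed = s, n_permutations = 199)
    r$p_value > 0.01
  }, logical(1))
  expect_gte(sum(nonsig), 9)
})

test_that("kNN CMI matches the Gaussian closed form and the independence null", {
  set.seed(4)
  n <- 2000
  rho <- 0.6
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  est <- cmi_knn(x, y, k = 10)
  expect_lt(abs(est - (-0.5 * log(1 - rho^2))), 0.03)
  # independent uniforms: estimate near zero
  est0 <- cmi_knn(runif(1000), runif(1000), k = 10)
  expect_lt(abs(est0), 0.05)
  # exact invariance under strictly monotone transforms (rank transform)
  expect_identical(cmi_knn(x, y, k = 10), cmi_knn(exp(x), y^3, k = 10))
})

test_that("CMIknn has power against pure multiplicative noise", {
  hits <- vapply(1:6, function(s) {
    set.seed(s)
    n <- 2000
    x <- rnorm(n)
    y <- (1 + abs(1.5 * x)) * rnorm(n)
    expect_lt(abs(cor(x, y)), 0.08)
    r <- ci_test(cbind(X = x, Y = y), "X", "Y", method = "cmiknn",
                 seed = s, n_permutations = 199, max_samples = 500)
    r$p_value < 0.01
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("parcorr and gpdc statistics are affine-invariant", {
  set.seed(5)
  n <- 300
  m <- cbind(X = rnorm(n), Y = rnorm(n), W = rnorm(n))
  m[, "Y"] <- 0.5 * m[, "X"] + m[, "Y"]
  m2 <- m
  m2[, "X"] <- 10 * m2[, "X"] - 3
  m2[, "Y"] <- -0.2 * m2[, "Y"] + 7
  for (meth in c("parcorr", "gpdc")) {
    r1 <- ci_test(m, "X", "Y", conds = data.frame(node = "W", lag = 0),
                  method = meth, seed = 5, n_permutations = 99)
    r2 <- ci_test(m2, "X", "Y", conds = data.frame(node = "W", lag = 0),
                  method = meth, seed = 5, n_permutations = 99)
    expect_equal(abs(r1$statistic), abs(r2$statistic), tolerance = 1e-6)
  }
})

test_that("permutation p-values are exact at the extremes and calibrated under the null", {
  set.seed(6)
  x <- rnorm(200)
  p <- permutation_null(x, x, stat_fn = cor, n_permutations = 199, seed = 1)
  expect_equal(as.numeric(p), 1 / 200)
  # calibration: mean p over independent white-noise pairs
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    as.numeric(permutation_null(rnorm(150), rnorm(150), stat_fn = cor,
                                n_permutations = 99, seed = s))
  }, numeric(1))
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})

test_that("block shuffling controls size under strong autocorrelation", {
  rates <- sapply(1:200, function(s) {
    m <- ar1_pair(300, phi = 0.9, seed = s)
    p_auto <- as.numeric(permutation_null(m[, 1], m[, 2], stat_fn = cor,
                                          n_permutations = 199, seed = s))
    p_iid <- as.numeric(permutation_null(m[, 1], m[, 2], stat_fn = cor,
                                         n_permutations = 199,
                                         block_length = 1, seed = s))
    c(auto = p_auto <= 0.01, iid = p_iid <= 0.01)
  })
  # the i.i.d. shuffle badly inflates size; the auto block length does not
  expect_lte(mean(rates["auto", ]), 0.035)
  expect_gt(mean(rates["iid", ]), 0.1)
  expect_lt(mean(rates["auto", ]), mean(rates["iid", ]))
})

test_that("input contracts are enforced", {
  m <- cbind(X = rnorm(50), Y = rnorm(50))
  expect_error(ci_test(m, "X", "Y", method = "parcorr", seed = NULL),
               "seed")
  expect_error(ci_test(m, "X", "Y", method = "parcorr", seed = 1,
                       n_permutations = 50), "99")
  expect_error(ci_test(m, "X", "Y", method = "cmiknn", seed = 1,
                       n_permutations = 99, k = 20), "10")
  expect_error(ci_test(m, "X", "Y", lag = 1,
                       conds = data.frame(node = "X", lag = 1),
                       method = "parcorr", seed = 1, n_permutations = 99),
               "source")
  expect_error(ci_test(m, "X", "Y",
                       conds = data.frame(node = "Y", lag = 0),
                       method = "parcorr", seed = 1, n_permutations = 99),
               "target")
  expect_error(permutation_null(rnorm(50), rnorm(50), block_length = 60,
                                n_permutations = 99), "block_length")
})
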