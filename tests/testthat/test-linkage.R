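# Statistical linkage stage: trends, detrending, transforms, backward
# AICc selection and autoregressive-error regression.

test_that("trend test recovers an exact line and the null is calibrated", {
  tt <- suppressWarnings(trend_test(2 * (1:20)))  # perfect-fit lm warning
  expect_equal(tt$slope, 2)
  expect_lt(tt$p_value, 1e-12)
  const <- trend_test(rep(3, 10))
  expect_equal(const$slope, 0)
  expect_equal(const$p_value, 1)
  # white-noise p-values are uniform (KS over replicates)
  set.seed(5)
  ps <- replicate(500, trend_test(rnorm(1000))$p_value)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("detrending zeroes a line, centres residuals, is idempotent", {
  expect_equal(detrend(5 + 2 * (1:15)), rep(0, 15))
  set.seed(6)
  for (i in 1:5) {
    y <- rnorm(20) + 0.3 * (1:20)
    r <- detrend(y)
    expect_equal(mean(r), 0, tolerance = 1e-12)
    expect_equal(detrend(r), r, tolerance = 1e-10)
  }
})

test_that("arcsin transform has the fixed points and is monotone", {
  expect_equal(arcsin_fraction(0), 0)
  expect_equal(arcsin_fraction(1), pi / 2)
  expect_equal(arcsin_fraction(0.5), pi / 4)
  grid <- seq(0, 1, by = 0.01)
  expect_true(all(diff(arcsin_fraction(grid)) > 0))
  expect_equal(arcsin_fraction(0.5, sqrt = FALSE), asin(0.5))
  expect_error(arcsin_fraction(1.1), "0, 1")
})

test_that("backward AICc selection keeps a strong covariate and is tidy", {
  set.seed(12)
  n <- 16
  X <- matrix(rnorm(n * 8), n, 8)
  colnames(X) <- c("cod_larvae", paste0("noise", 1:7))
  y <- 3 * X[, 1] + rnorm(n)
  tab <- data.frame(year = 1:n, y = y, X)
  sel <- backward_aicc_select(tab, "y", colnames(X))
  expect_true("cod_larvae" %in% sel$selected)
  # ledger invariants: Np strictly decreasing, accepted AICc never rises
  expect_true(all(diff(sel$steps$np) < 0))
  expect_true(all(diff(sel$steps$aicc) <= 0))
  expect_true(all(c("step", "removed", "np", "aicc", "adj_r2", "removal_p")
                  %in% names(sel$steps)))
  expect_true(all(c("estimate", "se", "t", "p") %in% names(sel$coefficients)))
})

test_that("selection retains the true covariate in >= 80% of replicates", {
  set.seed(12)
  keep <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    n <- 16
    X <- matrix(rnorm(n * 8), n, 8)
    colnames(X) <- c("true", paste0("noise", 1:7))
    tab <- data.frame(year = 1:n, y = 3 * X[, 1] + rnorm(n), X)
    if ("true" %in% backward_aicc_select(tab, "y", colnames(X))$selected) {
      keep <- keep + 1
    }
  }
  expect_gte(keep / reps, 0.8)
})

test_that("all-noise candidates: intercept-only is the modal outcome", {
  set.seed(6)
  sizes <- integer(200)
  for (i in 1:200) {
    X <- matrix(rnorm(16 * 7), 16, 7)
    colnames(X) <- paste0("n", 1:7)
    tab <- data.frame(year = 1:16, y = rnorm(16), X)
    sizes[i] <- length(backward_aicc_select(tab, "y", colnames(X))$selected)
  }
  expect_equal(as.integer(names(which.max(table(sizes)))), 0L)
})

test_that("collinear designs are rejected with the offender named", {
  tab <- data.frame(year = 1:16, y = rnorm(16), a = 1:16, b = 2 * (1:16),
                    c = rnorm(16))
  expect_error(backward_aicc_select(tab, "y", c("a", "b", "c")), "collinear")
})

test_that("AR(0) error fit reduces exactly to OLS", {
  set.seed(14)
  x <- rnorm(40); y <- 1 + 2 * x + rnorm(40)
  f <- ar_error_fit(y, x, order = 0)
  ols <- stats::lm(y ~ x)
  expect_equal(f$beta, unname(coef(ols)[2]), tolerance = 1e-6)
  expect_equal(f$intercept, unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("AR(2) fit recovers beta and runs at the 16-year regime", {
  set.seed(11)
  hits <- 0
  reps <- 100  # desk-scale; the acceptance suite runs 200
  for (r in seq_len(reps)) {
    p <- colony_sim_params(n_years = 500, trend = 0, beta = 2, phi1 = 0.4,
                           phi2 = -0.25, innovation_sd = 1.5,
                           seed = 2000 + r)
    x <- rnorm(500)
    d <- generate_colony_series(p, covariate = x)
    f <- ar_error_fit(d$wing_length, x, order = 2)
    if (abs(f$beta - 2) <= 2 * f$beta_se) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)

  # n = 16: fit runs and returns finite SEs
  p16 <- colony_sim_params(n_years = 16, beta = 3, seed = 13)
  x16 <- rnorm(16)
  d16 <- generate_colony_series(p16, covariate = x16)
  f16 <- ar_error_fit(d16$wing_length, x16, order = 2)
  expect_true(is.finite(f16$beta_se))
  expect_gte(f16$explained_variance, 0)
  expect_lte(f16$explained_variance, 1)
})

test_that("pairwise_r2 is sign-blind and null-calibrated", {
  x <- rnorm(50)
  expect_equal(pairwise_r2(x, x)$r2, 1)
  expect_equal(pairwise_r2(x, -x)$r2, 1)
  set.seed(15)
  nn <- pairwise_r2(rnorm(1e4), rnorm(1e4))
  expect_lt(nn$r2, 0.01)
  expect_error(pairwise_r2(rep(1, 10), rnorm(10)), "variance")
})
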