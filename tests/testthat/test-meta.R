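# independent restricted log-likelihood used as a grid-search oracle;
# written directly from the random-effects model density, not shared with
# the package internals
reml_ll_oracle <- function(tau2, y, v) {
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  -0.5 * (sum(log(v + tau2)) + log(sum(w)) + sum(w * (y - mu)^2))
}

test_that("hedges_g matches the hand-computed oracle", {
  # x_del = {0,1}, x_ctrl = {1,2}: d = -sqrt(2), J = 4/7
  eff <- hedges_g(c(0, 1), c(1, 2))
  expect_equal(eff$d, -sqrt(2), tolerance = 1e-9)
  expect_equal(eff$J, 4 / 7, tolerance = 1e-12)
  expect_equal(eff$g, -0.80812, tolerance = 1e-5)
  # var = J^2 * ((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2))) = (16/49)(1 + 0.25)
  expect_equal(eff$var_g, (16 / 49) * 1.25, tolerance = 1e-9)
  expect_true(eff$ci_lo <= eff$g && eff$g <= eff$ci_hi)
})

test_that("hedges_g is null for identical groups and scale invariant", {
  x <- c(1.2, 3.4, 2.2, 4.1)
  expect_equal(hedges_g(x, x)$g, 0)
  a <- rnorm(10); b <- rnorm(12, 0.5)
  expect_equal(hedges_g(a, b)$g, hedges_g(10 * a, 10 * b)$g, tolerance = 1e-12)
  expect_error(hedges_g(c(1), c(1, 2)), "n >= 2")
  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("hedges_g agrees with metafor's standardized mean difference", {
  skip_if_not_installed("metafor")
  set.seed(10)
  for (i in 1:5) {
    a <- rnorm(15, 1, 2); b <- rnorm(20, 0, 1.5)
    eff <- hedges_g(a, b)
    ref <- metafor::escalc(measure = "SMD", m1i = mean(a), m2i = mean(b),
                           sd1i = sd(a), sd2i = sd(b), n1i = length(a),
                           n2i = length(b))
    # metafor uses the exact gamma-function bias correction; this package
    # the standard J = 1 - 3/(4m - 1) approximation, so agreement is to ~1e-4
    expect_equal(eff$g, as.numeric(ref$yi), tolerance = 1e-3)
  }
})

test_that("bootstrap CIs are deterministic under a seed and degenerate for constants", {
  b <- bootstrap_mean_ci(rep(3.5, 10), seed = 1)
  expect_equal(b$ci_lo, 3.5)
  expect_equal(b$ci_hi, 3.5)
  x <- rnorm(30)
  b1 <- bootstrap_mean_ci(x, seed = 7)
  b2 <- bootstrap_mean_ci(x, seed = 7)
  b3 <- bootstrap_mean_ci(x, seed = 8)
  expect_identical(b1, b2)
  expect_false(identical(b1$ci_lo, b3$ci_lo))
  expect_true(b1$ci_lo <= b1$mean && b1$mean <= b1$ci_hi)
  expect_error(bootstrap_mean_ci(x), "seed")
})

test_that("Cochran's Q matches hand computation and is permutation invariant", {
  expect_equal(cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))$Q, 0)
  expect_equal(cochran_q(c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))$p, 1)
  # k = 2, g = {0, 1}, var = {0.5, 0.5}: FE mean 0.5, Q = 2*0.5*0.25 = 1
  expect_equal(cochran_q(c(0, 1), c(0.5, 0.5))$Q, 1)
  g <- c(0.1, 0.9, 0.4, -0.2); v <- c(0.2, 0.1, 0.3, 0.15)
  perm <- c(3, 1, 4, 2)
  expect_equal(cochran_q(g, v)$Q, cochran_q(g[perm], v[perm])$Q)
  expect_error(cochran_q(c(0, 1), c(0.5, -0.1)), "positive")
})

test_that("I-squared follows its closed form with truncation at zero", {
  expect_equal(i_squared(0, 4), 0)
  expect_equal(i_squared(4, 4), 0)
  expect_equal(i_squared(2, 4), 0)       # Q < df truncates
  expect_equal(i_squared(20, 4), 80)
  expect_error(i_squared(-1, 4), "non-negative")
})

test_that("REML tau2 is zero without heterogeneity and matches a grid search", {
  expect_equal(reml_tau2(rep(0.4, 5), rep(0.1, 5)), 0)
  set.seed(20)
  for (i in 1:10) {
    k <- 5
    v <- runif(k, 0.02, 0.3)
    y <- rnorm(k, 0.2, sqrt(v + runif(1, 0, 0.5)))
    est <- reml_tau2(y, v)
    grid <- seq(0, 5, by = 1e-4)
    # vectorized evaluation of the oracle over the grid
    V <- outer(v, grid, "+"); W <- 1 / V
    mu <- colSums(W * y) / colSums(W)
    resid2 <- (matrix(y, k, length(grid)) - matrix(mu, k, length(grid), byrow = TRUE))^2
    ll <- -0.5 * (colSums(log(V)) + log(colSums(W)) + colSums(W * resid2))
    best <- grid[which.max(ll)]
    expect_equal(max(ll), reml_ll_oracle(best, y, v), tolerance = 1e-9)
    expect_lt(abs(est - best), 1e-3)
  }
})

test_that("REML tau2 and pooled estimates agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(30)
  for (i in 1:10) {
    k <- sample(3:8, 1)
    v <- runif(k, 0.02, 0.3)
    y <- rnorm(k, -0.5, sqrt(v + 0.2))
    fit <- rema(y, v)
    ref <- metafor::rma(yi = y, vi = v, method = "REML")
    expect_equal(fit$tau2, ref$tau2, tolerance = 1e-4)
    expect_equal(fit$b, as.numeric(ref$b), tolerance = 1e-4)
    expect_equal(fit$se, as.numeric(ref$se), tolerance = 1e-4)
    expect_equal(fit$Q, as.numeric(ref$QE), tolerance = 1e-8)
  }
})

test_that("REML recovers a known between-study variance on average", {
  set.seed(40)
  true_tau2 <- 0.25
  est <- replicate(800, {
    y <- rnorm(5, 0, sqrt(0.05 + true_tau2))
    reml_tau2(y, rep(0.05, 5))
  })
  expect_lt(abs(mean(est) - true_tau2) / true_tau2, 0.15)
})

test_that("random-effects pooling has its closed-form and limiting behaviour", {
  # identical effects: tau2 = 0, pooled = g, CI = g +/- z * sqrt(var/2)
  fit <- rema(c(0.5, 0.5), c(0.1, 0.1))
  expect_equal(fit$b, 0.5)
  expect_equal(fit$tau2, 0)
  z <- qnorm(0.975)
  expect_equal(fit$ci_lo, 0.5 - z * sqrt(0.05), tolerance = 1e-9)
  expect_equal(fit$ci_hi, 0.5 + z * sqrt(0.05), tolerance = 1e-9)
  expect_equal(sum(fit$weights), 1)
  # dominant tau2 -> weights approach equality
  set.seed(50)
  y <- c(-3, 0, 3, 6); v <- c(0.01, 0.05, 0.02, 0.08)
  fit2 <- rema(y, v)
  w <- fit2$weights
  expect_lt(max(w) / min(w), 1.15)
  # fixing tau2 = 0 reproduces the fixed-effect answer exactly
  fit3 <- rema(y, v, tau2 = 0)
  expect_equal(fit3$b, sum(y / v) / sum(1 / v), tolerance = 1e-12)
})

test_that("the pooled estimate is a convex combination of subgroup effects", {
  set.seed(60)
  for (i in 1:20) {
    k <- sample(2:7, 1)
    y <- rnorm(k, 0, 1); v <- runif(k, 0.01, 0.5)
    fit <- rema(y, v)
    expect_gte(fit$b, min(y) - 1e-12)
    expect_lte(fit$b, max(y) + 1e-12)
  }
})

test_that("rema S3 methods expose the fit", {
  fit <- rema(c(0.2, 0.6, 0.4), c(0.05, 0.04, 0.06), labels = c("a", "b", "c"))
  expect_equal(unname(coef(fit)), fit$b)
  expect_equal(confint(fit), c(fit$ci_lo, fit$ci_hi))
  expect_equal(sum(weights(fit)), 1)
  expect_named(weights(fit), c("a", "b", "c"))
  expect_output(print(fit), "Random-effects meta-analysis")
  expect_output(print(summary(fit)), "Subgroups:")
})

test_that("status-stratified heterogeneity reacts to displaced subgroup means", {
  h0 <- status_heterogeneity(rep(5, 4), rep(1, 4), rep(30, 4))
  expect_equal(h0$I2, 0)
  means <- c(5, 5, 5, 5 + 10 / sqrt(30))  # one subgroup displaced by 10 SEs
  h1 <- status_heterogeneity(means, rep(1, 4), rep(30, 4))
  expect_gt(h1$I2, 90)
  set.seed(70)
  for (i in 1:10) {
    h <- status_heterogeneity(rnorm(5), runif(5, 0.5, 2), sample(5:50, 5))
    expect_true(h$I2 >= 0 && h$I2 <= 100)
  }
  expect_error(status_heterogeneity(c(1, 2), c(1, 1), c(1, 5)), "n >= 2")
})

test_that("the age-adjusted regression recovers exact and null effects", {
  status <- rep(c(0, 1), each = 20)
  ages <- rnorm(40, 70, 8)
  # noiseless construction: lm warns about the perfect fit, which is the point
  out <- suppressWarnings(age_adjusted_effect(2 * status, status, ages))
  expect_equal(out$estimate[out$term == "status"], 2, tolerance = 1e-9)
  # duplicating rows leaves coefficients unchanged
  out2 <- suppressWarnings(
    age_adjusted_effect(rep(2 * status, 2), rep(status, 2), rep(ages, 2))
  )
  expect_equal(out$estimate, out2$estimate, tolerance = 1e-9)
  expect_error(age_adjusted_effect(rnorm(10), rep(1, 10), rnorm(10)), "collinear")
  expect_error(age_adjusted_effect(rnorm(10), rep(0:1, 5), rep(3, 10)), "collinear")
  # with a pure status effect and independent age, the age p-value is uniform
  set.seed(80)
  pvals <- replicate(200, {
    st <- rep(c(0, 1), each = 15)
    ag <- rnorm(30, 70, 10)
    y <- st + rnorm(30)
    age_adjusted_effect(y, st, ag)$p[3]
  })
  frac <- mean(pvals < 0.05)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.12)
})
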