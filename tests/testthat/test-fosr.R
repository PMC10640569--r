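make_fosr_data <- function(n = 40, M = 20, beta_age = 0, sd = 0.02,
                           seed = 1) {
  set.seed(seed)
  d <- seq(0.3, 0.01, length.out = M)  # sweep orientation
  age <- runif(n, 4, 19)
  age_c <- age - mean(age)
  mu <- 0.2 + 0.5 * d
  Y <- outer(rep(1, n), mu) + beta_age * outer(age_c, rep(1, M)) +
    matrix(rnorm(n * M, 0, sd), n, M)
  list(Y = Y, d = d, dat = data.frame(age = age_c,
                                      x2 = rnorm(n)))
}

test_that("a constant response is recovered exactly", {
  n <- 20; M <- 15
  d <- seq(0.3, 0.01, length.out = M)
  Y <- matrix(2, n, M)
  dat <- data.frame(x = rnorm(n, 0, 1))
  fit <- fosr(Y ~ x, data = dat, argvals = d, light = TRUE)
  cf <- coef(fit)
  expect_lt(max(abs(cf[["(Intercept)"]] - 2)), 1e-6)
  expect_lt(max(abs(cf[["x"]])), 1e-6)
})

test_that("constant covariate effects are recovered within tolerance of a pointwise-OLS oracle", {
  dd <- make_fosr_data(n = 80, M = 20, beta_age = -0.01, sd = 0.02, seed = 2)
  Y <- dd$Y
  fit <- fosr(Y ~ age + x2, data = dd$dat, argvals = dd$d, light = TRUE)
  ba <- coef(fit)$age
  expect_lt(max(abs(ba - (-0.01))), 0.003)

  # independent oracle: per-density OLS
  ols <- vapply(seq_along(dd$d), function(m)
    coef(lm(Y[, m] ~ dd$dat$age + dd$dat$x2))[2], numeric(1))
  expect_lt(max(abs(ba - ols)), 0.003)
})

test_that("the constant-vs-functional test stays near nominal under constant truth", {
  set.seed(3)
  reps <- replicate(40, {
    dd <- make_fosr_data(n = 30, M = 12, beta_age = -0.01, sd = 0.02,
                         seed = sample.int(1e6, 1))
    Y <- dd$Y
    fit <- fosr(Y ~ age, data = dd$dat, argvals = dd$d, light = TRUE)
    c(lr_overall_test(fit, type = "constant")[["p"]],
      lr_overall_test(fit, type = "model")[["p"]])
  })
  # constant (nonzero) truth: the functional-variation test is null...
  # loose bound here; tight 200-replicate calibration is asserted elsewhere
  expect_lt(mean(reps[1, ] <= 0.05), 0.2)
  # ...while the model test must detect the constant age effect
  expect_gt(mean(reps[2, ] <= 0.05), 0.9)
})

test_that("density-varying effects are detected with high power", {
  set.seed(4)
  n <- 80; M <- 20
  d <- seq(0.3, 0.01, length.out = M)
  age <- runif(n, 4, 19); age_c <- age - mean(age)
  beta_d <- -0.02 * (d / 0.3)  # strongly density-varying age effect
  Y <- outer(rep(1, n), 0.2 + 0.5 * d) + outer(age_c, beta_d) +
    matrix(rnorm(n * M, 0, 0.02), n, M)
  fit <- fosr(Y ~ age, data = data.frame(age = age_c), argvals = d,
              light = TRUE)
  expect_lt(lr_overall_test(fit, type = "constant")[["p"]], 0.001)
  expect_lt(lr_overall_test(fit, type = "model")[["p"]], 0.001)
})

test_that("RSS never increases when a covariate is added at fixed smoothing", {
  dd <- make_fosr_data(n = 30, M = 15, beta_age = -0.005, seed = 5)
  Y <- dd$Y
  fit1 <- fosr(Y ~ age, data = dd$dat, argvals = dd$d, light = TRUE)
  sp2 <- c(fit1$sp, fit1$sp[2])
  fit2 <- fosr(Y ~ age + x2, data = dd$dat, argvals = dd$d, light = TRUE,
               sp = sp2)
  expect_lte(fit2$RSS, fit1$RSS + 1e-8)
})

test_that("functional R-squared separates signal from noise and respects nesting", {
  # noiseless single-covariate response: essentially all variance explained
  n <- 40; M <- 15
  d <- seq(0.3, 0.01, length.out = M)
  x <- rnorm(n)
  Y <- outer(rep(1, n), 0.1 + d) + 0.05 * outer(x, rep(1, M))
  fit <- suppressWarnings(fosr(Y ~ x, data = data.frame(x = x), argvals = d))
  expect_gt(functional_r2(fit)$overall, 0.99)

  # pure-noise response: near zero
  set.seed(6)
  fr2 <- replicate(20, {
    Yn <- outer(rep(1, n), 0.1 + d) + matrix(rnorm(n * M, 0, 0.02), n, M)
    xn <- rnorm(n)
    functional_r2(fosr(Yn ~ xn, data = data.frame(xn = xn), argvals = d))$overall
  })
  expect_lt(abs(mean(fr2)), 0.05)
})

test_that("semi-partial correlations vanish for null covariates and are clamped at zero", {
  set.seed(7)
  n <- 60; M <- 15
  d <- seq(0.3, 0.01, length.out = M)
  x1 <- rnorm(n); x0 <- rnorm(n)  # x0 has no effect
  Y <- outer(rep(1, n), 0.1 + d) + 0.05 * outer(x1, rep(1, M)) +
    matrix(rnorm(n * M, 0, 0.02), n, M)
  fit <- fosr(Y ~ x1 + x0, data = data.frame(x1 = x1, x0 = x0), argvals = d)
  r <- semipartial_r(fit)
  expect_gt(r[["x1"]], r[["x0"]])
  expect_lt(r[["x0"]], 0.1)
  expect_true(all(r >= 0))
})

test_that("bootstrap bands are deterministic, collapse without noise, and exclude into ranges", {
  n <- 25; M <- 12
  d <- seq(0.3, 0.01, length.out = M)
  x <- rnorm(n)
  Y <- outer(rep(1, n), 0.1 + d) + 0.05 * outer(x, rep(1, M))
  fit <- suppressWarnings(fosr(Y ~ x, data = data.frame(x = x), argvals = d,
                               light = TRUE))
  ci1 <- confint(fit, n_boot = 100, seed = 9)
  ci2 <- confint(fit, n_boot = 100, seed = 9)
  expect_identical(ci1$bands, ci2$bands)
  width <- ci1$bands$x[, "hi"] - ci1$bands$x[, "lo"]
  expect_lt(max(width), 1e-6)

  sig <- significance_summary(fit, ci1, alpha = 0.001)
  xrow <- sig[sig$term == "x", ]
  expect_true(all(xrow$significant))
  expect_equal(unique(xrow$sign), 1)
})

test_that("rank-deficient designs fail with the collinear column named", {
  dd <- make_fosr_data(n = 20, M = 12, seed = 8)
  dd$dat$dup <- 2 * dd$dat$age
  Y <- dd$Y
  expect_error(fosr(Y ~ age + dup, data = dd$dat, argvals = dd$d),
               "dup")
})

test_that("significance gating requires the overall test to pass", {
  # pure noise: overall test non-significant, so nothing is marked even if
  # a pointwise band strays from zero
  set.seed(10)
  n <- 30; M <- 12
  d <- seq(0.3, 0.01, length.out = M)
  x <- rnorm(n)
  Y <- outer(rep(1, n), 0.1 + d) + matrix(rnorm(n * M, 0, 0.02), n, M)
  fit <- fosr(Y ~ x, data = data.frame(x = x), argvals = d, light = TRUE)
  ci <- confint(fit, n_boot = 100, seed = 11)
  if (lr_overall_test(fit)[["p"]] > 0.001) {
    sig <- significance_summary(fit, ci, alpha = 0.001)
    expect_false(any(sig$significant))
  } else {
    succeed()
  }
})

test_that("simulate() reproduces the fitted model's distribution deterministically", {
  dd <- make_fosr_data(n = 20, M = 12, beta_age = -0.01, seed = 12)
  Y <- dd$Y
  fit <- fosr(Y ~ age, data = dd$dat, argvals = dd$d, light = TRUE)
  s1 <- simulate(fit, nsim = 2, seed = 3)
  s2 <- simulate(fit, nsim = 2, seed = 3)
  expect_identical(s1, s2)
  expect_equal(dim(s1[[1]]), dim(dd$Y))
})
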