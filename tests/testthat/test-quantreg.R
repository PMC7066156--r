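test_that("check loss closed forms and domain", {
  expect_equal(check_loss(1, 0.9), 0.9)
  expect_equal(check_loss(-1, 0.9), 0.1)
  expect_equal(check_loss(-2, 0.5), 1.0)
  expect_equal(check_loss(0, 0.3), 0)
  expect_error(check_loss(1, 0), "tau")
  expect_error(check_loss(1, 1.2), "tau")
})

test_that("single-level fits match exhaustive two-point enumeration", {
  # printed three-point instance: (0,0), (1,1), (2,4) at the median
  p3 <- make_pairs(c(0, 1, 2), c(0, 1, 4))
  f <- fit_weighted_quantile(p3, 0.5)
  expect_equal(unname(f["intercept"]), 0, tolerance = 1e-8)
  expect_equal(unname(f["slope"]), 2, tolerance = 1e-8)
  # its summed absolute residual (1) beats both alternative two-point
  # lines (2 each); at the median the check loss is half of that
  expect_equal(qr_objective(c(0, 1, 2), c(0, 1, 4), rep(1, 3), 0.5,
                            f["intercept"], f["slope"]), 0.5)
  expect_equal(enum_qr_oracle(c(0, 1, 2), c(0, 1, 4), rep(1, 3),
                              0.5)$objective, 0.5)

  # random weighted instances across the tau range
  set.seed(11)
  for (rep in 1:6) {
    n <- 60
    x <- rnorm(n)
    if (rep %% 2 == 0) x <- round(x, 1)  # value ties
    y <- 0.5 + 1.5 * x + rt(n, df = 3)
    w <- sample(c(0.5, 1, 2), n, TRUE)
    tau <- sample(c(0.05, 0.2, 0.5, 0.8, 0.95), 1)
    f <- fit_weighted_quantile(make_pairs(x, y, w), tau)
    oracle <- enum_qr_oracle(x, y, w, tau)
    got <- qr_objective(x, y, w, tau, f["intercept"], f["slope"])
    expect_lt(abs(got - oracle$objective), 1e-8 * (1 + abs(oracle$objective)))
  }

  # a perfect line is recovered at any tau
  pl <- make_pairs(1:10, 2 * (1:10) - 3)
  for (tau in c(0.1, 0.5, 0.9)) {
    f <- fit_weighted_quantile(pl, tau)
    expect_equal(unname(f), c(-3, 2), tolerance = 1e-9)
  }

  expect_error(fit_weighted_quantile(make_pairs(rep(1, 5), rnorm(5)), 0.5),
               "degenerate")
  expect_error(fit_weighted_quantile(p3, 1.5), "tau")
})

test_that("process fit agrees with single fits and respects affine equivariance", {
  set.seed(12)
  n <- 300
  x <- rnorm(n)
  y <- 1 + 0.4 * x + rlnorm(n, sdlog = 0.5)
  p <- make_pairs(x, y)
  grid <- quantile_grid(0.1, 0.9, 0.2)
  proc <- fit_quantile_process(p, grid)
  for (i in seq_along(proc$tau)) {
    f <- fit_weighted_quantile(p, proc$tau[i])
    expect_equal(proc$slope[i], unname(f["slope"]), tolerance = 1e-10)
  }
  # grid of length 1 degenerates to the single fit
  p1 <- fit_quantile_process(p, 0.35)
  expect_equal(unname(fit_weighted_quantile(p, 0.35)["slope"]), p1$slope)

  # scaling y by c scales slopes by c; scaling x by c scales by 1/c;
  # shifts move only intercepts
  base <- fit_quantile_process(p, grid)
  sy <- fit_quantile_process(make_pairs(x, 3 * y), grid)
  expect_equal(sy$slope, 3 * base$slope, tolerance = 1e-8)
  sx <- fit_quantile_process(make_pairs(2 * x, y), grid)
  expect_equal(sx$slope, base$slope / 2, tolerance = 1e-8)
  sh <- fit_quantile_process(make_pairs(x + 5, y + 7), grid)
  expect_equal(sh$slope, base$slope, tolerance = 1e-8)
  expect_equal(sh$intercept, base$intercept + 7 - 5 * base$slope,
               tolerance = 1e-8)
})

test_that("achieved check loss never exceeds the weighted-OLS line's", {
  set.seed(13)
  for (rep in 1:5) {
    n <- 120
    x <- rnorm(n); y <- 0.3 * x + rt(n, 4)
    w <- runif(n, 0.5, 2)
    p <- make_pairs(x, y, w)
    ols <- fit_weighted_ols(p)
    for (tau in c(0.1, 0.5, 0.9)) {
      f <- fit_weighted_quantile(p, tau)
      expect_lte(qr_objective(x, y, w, tau, f["intercept"], f["slope"]),
                 qr_objective(x, y, w, tau, ols$intercept, ols$slope) + 1e-10)
    }
  }
})

test_that("bivariate normal data give a flat slope process", {
  set.seed(14)
  n <- 4000
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n, sd = 0.9)
  p <- make_pairs(x, y)
  bp <- bootstrap_process(p, quantile_grid(0.1, 0.9, 0.1), n_boot = 100,
                          seed = 2)
  spread <- max(bp$slope) - min(bp$slope)
  expect_lt(spread, 4 * max(bp$slope_se))
})

test_that("lognormal-margin pairs give rising slopes", {
  set.seed(15)
  n <- 6000
  rho <- 0.35
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  p <- make_pairs(exp(0.6 * z1), exp(0.6 * z2))
  proc <- fit_quantile_process(p, c(0.1, 0.9))
  expect_gt(proc$slope[2], proc$slope[1])
})

test_that("bootstrap: determinism, rank bound, redraws, SE sanity", {
  set.seed(16)
  n <- 500
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  p <- make_pairs(x, y)
  g <- quantile_grid(0.25, 0.75, 0.25)
  b1 <- bootstrap_process(p, g, n_boot = 50, seed = 7)
  b2 <- bootstrap_process(p, g, n_boot = 50, seed = 7)
  expect_identical(b1$slope_cov, b2$slope_cov)
  b3 <- bootstrap_process(p, g, n_boot = 50, seed = 8)
  expect_false(identical(b1$slope_cov, b3$slope_cov))
  # family resampling is deterministic too
  f1 <- bootstrap_process(p, g, n_boot = 20, seed = 7,
                          resample_unit = "family")
  f2 <- bootstrap_process(p, g, n_boot = 20, seed = 7,
                          resample_unit = "family")
  expect_identical(f1$slope_cov, f2$slope_cov)

  # with two replicates the covariance has rank <= 1
  b4 <- bootstrap_process(p, g, n_boot = 2, seed = 1)
  expect_equal(qr(b4$slope_cov)$rank, 1L)

  # slope covariance is symmetric PSD with matching SE diagonal
  ev <- eigen(b1$slope_cov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-12))
  expect_equal(b1$slope_se, sqrt(diag(b1$slope_cov)))

  # bootstrap SE of the median slope close to the analytic sandwich SE
  set.seed(17)
  n <- 2000
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  p <- make_pairs(x, y)
  bp <- bootstrap_process(p, 0.5, n_boot = 300, seed = 3)
  # sandwich: tau(1-tau) * (X' f X)^-1 X'X (X' f X)^-1 with f the error
  # density at the tau-quantile (residuals are standard normal here)
  f0 <- dnorm(qnorm(0.5))
  X <- cbind(1, x)
  bread <- solve(f0 * crossprod(X))
  V <- 0.5 * 0.5 * bread %*% crossprod(X) %*% bread
  expect_lt(abs(bp$slope_se / sqrt(V[2, 2]) - 1), 0.25)
})

test_that("weighted least squares matches the normal equations and conventions", {
  # exact line
  p <- make_pairs(1:5, 2 * (1:5) + 1)
  ols <- fit_weighted_ols(p)
  expect_equal(ols$slope, 2, tolerance = 1e-12)
  expect_equal(ols$intercept, 1, tolerance = 1e-12)
  expect_equal(ols$correlation, 1, tolerance = 1e-12)

  # hand-solvable weighted four-point fixture vs normal equations
  x <- c(0, 1, 2, 4); y <- c(1, 0.5, 3, 2.5); w <- c(1, 2, 0.5, 1.5)
  p <- make_pairs(x, y, w)
  W <- diag(w); X <- cbind(1, x)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  ols <- fit_weighted_ols(p)
  expect_equal(c(ols$intercept, ols$slope), unname(drop(beta)),
               tolerance = 1e-10)

  # doubling all weights leaves slope and correlation unchanged
  p2 <- make_pairs(x, y, 2 * w)
  ols2 <- fit_weighted_ols(p2)
  expect_equal(ols2$slope, ols$slope, tolerance = 1e-12)
  expect_equal(ols2$correlation, ols$correlation, tolerance = 1e-12)
})
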