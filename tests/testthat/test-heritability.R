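test_that("Falconer conversions reproduce the published worked values", {
  # offspring-parent, raw and log triglycerides
  expect_equal(round(h2_from_op(0.0837, 0.0074, 0.15)$h2, 3), 0.146)
  expect_equal(round(h2_from_op(0.0837, 0.0074, 0.15)$se, 3), 0.013)
  expect_equal(round(h2_from_op(0.2357, 0.0152, 0.31)$h2, 3), 0.360)
  # offspring-midparent
  expect_equal(round(h2_from_om(0.1311, 0.0117)$h2, 3), 0.131)
  expect_equal(round(h2_from_om(0.3801, 0.0227)$h2, 3), 0.380)
  # full-sib: raw and log triglycerides, VLDL-cholesterol
  expect_equal(round(h2_from_fs(0.2434, 0.0154, 0.15)$h2, 3), 0.456)
  expect_equal(round(h2_from_fs(0.3096, 0.0151, 0.31)$h2, 3), 0.532)
  expect_equal(round(h2_from_fs(0.1767, 0.0231, 0.09)$h2, 3), 0.343)
})

test_that("conversion limits, inverses and continuity", {
  # r = 0 limits
  expect_equal(h2_from_op(0.21, 0.01, 0)$h2, 0.42)
  expect_equal(h2_from_om(0)$h2, 0)
  expect_equal(h2_from_fs(0.25, 0.01, 1e-12)$h2, 0.5)
  # continuity of the FS formula at r = 0
  expect_lt(abs(h2_from_fs(0.25, 0.01, 1e-8)$h2 - 0.5), 1e-6)

  # OP inverse beta = h2 (1 + r) / 2 round-trips
  for (h2 in c(0.1, 0.45, 0.9)) {
    for (r in c(-0.2, 0, 0.15, 0.4)) {
      beta <- h2 * (1 + r) / 2
      expect_equal(h2_from_op(beta, 0.01, r)$h2, h2, tolerance = 1e-12)
    }
  }
  # FS inverse: forward Falconer beta_FS = h2/2 + r h4/2 recovers h2
  for (h2 in c(0.2, 0.5, 0.8)) {
    for (r in c(0.05, 0.15, 0.3)) {
      beta <- h2 / 2 + r * h2^2 / 2
      expect_equal(h2_from_fs(beta, 0.01, r)$h2, h2, tolerance = 1e-10)
    }
  }
  expect_error(h2_from_fs(-0.5, 0.01, 0.5), "nonnegative")
  expect_error(h2_from_op(0.1, 0.01, -1), "r_spouse")
})

test_that("heritability curves transform slope processes pointwise", {
  proc <- data.frame(tau = c(0.10, 0.50, 0.90),
                     slope = c(0.019, 0.11, 0.246),
                     slope_se = c(0.006, 0.009, 0.034))
  curve <- h2_curve(proc, r_spouse = 0.15, method = "OP")
  expect_equal(round(curve$h2[c(1, 3)], 3), c(0.033, 0.428))
  expect_equal(curve$h2_se, 2 * proc$slope_se / 1.15, tolerance = 1e-12)

  # constant slopes give a constant curve; FS with r = 0 equals 2x slopes
  flat <- data.frame(tau = c(0.2, 0.5, 0.8), slope = 0.2, slope_se = 0.01)
  expect_equal(unique(h2_curve(flat, 0.15, "OP")$h2),
               2 * 0.2 / 1.15)
  fs0 <- h2_curve(flat, 1e-12, "FS")
  expect_equal(fs0$h2, 2 * flat$slope, tolerance = 1e-8)
})

test_that("orthogonal contrasts: classical shapes, orthonormality, exactness", {
  # three equally spaced points: linear (-1,0,1)/sqrt(2), quadratic (1,-2,1)/sqrt(6)
  C <- orthogonal_contrasts(c(0.1, 0.5, 0.9), max_degree = 2)
  expect_equal(C[, 1], c(-1, 0, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(C[, 2], c(1, -2, 1) / sqrt(6), tolerance = 1e-12)

  grid <- quantile_grid()
  C <- orthogonal_contrasts(grid)
  G <- crossprod(C)
  expect_equal(G, diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(abs(colSums(C)) < 1e-10))  # orthogonal to the constant

  # a slope vector exactly linear in tau has zero quadratic/cubic contrast
  beta <- 0.1 + 0.3 * as.numeric(grid)
  expect_lt(abs(sum(C[, 2] * beta)), 1e-10)
  expect_lt(abs(sum(C[, 3] * beta)), 1e-10)
  # and the rescaled linear contrast returns its per-percentile slope
  expect_equal(sum(attr(C, "linear_raw") * beta), 0.3 / 100,
               tolerance = 1e-12)
})

test_that("trend and difference tests use the bootstrap covariance correctly", {
  grid <- quantile_grid(0.1, 0.9, 0.1)
  C <- orthogonal_contrasts(grid)
  fake <- structure(list(grid = as.numeric(grid),
                         slope = C[, 1], slope_se = rep(1, 9),
                         slope_cov = diag(9), n_boot = 100L, seed = 1L,
                         df = 500L),
                    class = "qh_qrproc")
  tt <- trend_test(fake, 1)
  expect_equal(tt$estimate, 1, tolerance = 1e-12)
  expect_equal(tt$se, 1, tolerance = 1e-12)
  expect_equal(tt$p_value, 2 * pt(-1, 500))

  # adding a constant to all slopes leaves the degree-1 contrast unchanged
  fake2 <- fake
  fake2$slope <- fake$slope + 5
  expect_equal(trend_test(fake2, 1)$estimate, tt$estimate, tolerance = 1e-10)

  # difference test: identical slopes -> 0; equal-variance diagonal -> sqrt(2v)
  fake3 <- fake
  fake3$slope <- rep(0.25, 9)
  fake3$slope_cov <- diag(rep(0.04, 9))
  dt <- difference_test(fake3, 0.9, 0.1)
  expect_equal(dt$difference, 0)
  expect_equal(dt$se, sqrt(2 * 0.04))
  expect_error(difference_test(fake3, 0.85, 0.1), "grid")
})
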