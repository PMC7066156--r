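#' @name falconer
#' @title Narrow-sense heritability from familial regression slopes
#'
#' @description
#' The Falconer conversions from weighted familial regression slopes to
#' narrow-sense heritability, with delta-method standard errors treating the
#' spouse correlation as a fixed constant:
#'
#' * offspring-parent: `h2 = 2 beta_OP / (1 + r_spouse)`,
#'   `se = 2 se_beta / (1 + r_spouse)`;
#' * offspring-midparent: `h2 = beta_OM`, `se = se_beta`;
#' * full-sib: `h2 = (sqrt(1 + 8 r_spouse beta_FS) - 1) / (2 r_spouse)`,
#'   `se = 2 se_beta / sqrt(1 + 8 r_spouse beta_FS)`; the `r -> 0` limit is
#'   `h2 = 2 beta_FS`.
#'
#' The spouse correlation enters because phenotypic assortative mating
#' inflates familial resemblance beyond the additive-genetic expectation.
#'
#' @param beta_op,beta_om,beta_fs regression slope of the corresponding pair
#'   kind.
#' @param se_beta standard error of the slope.
#' @param r_spouse phenotypic spouse correlation in (-1, 1).
#' @return object of class `qh_h2`: list with `h2`, `se`, `method`,
#'   `r_spouse`, `source_slope`, `source_se`.
NULL

new_h2 <- function(h2, se, method, r_spouse, slope, se_beta) {
  structure(list(h2 = h2, se = se, method = method, r_spouse = r_spouse,
                 source_slope = slope, source_se = se_beta),
            class = "qh_h2")
}

#' @rdname falconer
#' @export
h2_from_op <- function(beta_op, se_beta = NA_real_, r_spouse) {
  if (r_spouse <= -1) stop("r_spouse must exceed -1")
  new_h2(2 * beta_op / (1 + r_spouse), 2 * se_beta / (1 + r_spouse),
         "OP", r_spouse, beta_op, se_beta)
}

#' @rdname falconer
#' @export
h2_from_om <- function(beta_om, se_beta = NA_real_) {
  new_h2(beta_om, se_beta, "MIDPARENT", NA_real_, beta_om, se_beta)
}

#' @rdname falconer
#' @export
h2_from_fs <- function(beta_fs, se_beta = NA_real_, r_spouse) {
  disc <- 1 + 8 * r_spouse * beta_fs
  if (disc < 0) stop("1 + 8 r beta must be nonnegative (got ", disc, ")")
  h2 <- if (abs(r_spouse) < 1e-8) {
    # series limit of (sqrt(1 + 8 r b) - 1) / (2 r) as r -> 0
    2 * beta_fs
  } else {
    (sqrt(disc) - 1) / (2 * r_spouse)
  }
  new_h2(h2, 2 * se_beta / sqrt(disc), "FS", r_spouse, beta_fs, se_beta)
}

#' Quantile-specific heritability curve
#'
#' Applies the method's Falconer conversion to every slope of a fitted
#' quantile process.
#'
#' @param fit a `qh_qrproc` from [bootstrap_process()] (or a data frame with
#'   `tau`, `slope`, `slope_se`).
#' @param r_spouse spouse correlation (ignored for `method = "MIDPARENT"`).
#' @param method which familial regression the slopes came from.
#' @return data frame `tau`, `slope`, `slope_se`, `h2`, `h2_se` with
#'   attributes `method`, `r_spouse`.
#' @export
h2_curve <- function(fit, r_spouse = NA_real_,
                     method = c("OP", "MIDPARENT", "FS")) {
  method <- match.arg(method)
  if (inherits(fit, "qh_qrproc")) {
    taus <- fit$grid; slope <- fit$slope; se <- fit$slope_se
  } else {
    taus <- fit$tau; slope <- fit$slope; se <- fit$slope_se
  }
  conv <- switch(method,
    OP = function(b, s) h2_from_op(b, s, r_spouse),
    MIDPARENT = function(b, s) h2_from_om(b, s),
    FS = function(b, s) h2_from_fs(b, s, r_spouse))
  hs <- mapply(function(b, s) {
    h <- conv(b, s); c(h$h2, h$se)
  }, slope, se)
  out <- data.frame(tau = taus, slope = slope, slope_se = se,
                    h2 = hs[1, ], h2_se = hs[2, ])
  attr(out, "method") <- method
  attr(out, "r_spouse") <- r_spouse
  out
}

#' Orthogonal polynomial contrasts over a quantile grid
#'
#' Degree 1..`max_degree` contrast vectors, orthonormal over the grid points
#' and orthogonal to the constant vector, built by QR orthonormalization of
#' the Vandermonde basis on the actual grid (so non-default grids work). The
#' attribute `linear_raw` holds the rescaled linear contrast whose inner
#' product with a slope vector is the least-squares slope of beta(tau) on
#' the percentile (units: per 1 percentile).
#'
#' @param grid a [quantile_grid()] or numeric vector of levels.
#' @param max_degree highest polynomial degree (default 3).
#' @return matrix with `length(grid)` rows and `max_degree` columns.
#' @export
orthogonal_contrasts <- function(grid, max_degree = 3) {
  taus <- as.numeric(grid)
  n <- length(taus)
  if (n <= max_degree) stop("grid must be longer than max_degree")
  pct <- 100 * taus
  V <- outer(pct, 0:max_degree, `^`)
  qr_d <- qr(V)
  Q <- qr.Q(qr_d)[, -1, drop = FALSE]          # drop the constant column
  # fix signs so each contrast increases with the percentile at its tail
  for (j in seq_len(ncol(Q))) if (Q[n, j] < 0) Q[, j] <- -Q[, j]
  colnames(Q) <- paste0("degree", seq_len(max_degree))
  ctr <- pct - mean(pct)
  attr(Q, "linear_raw") <- ctr / sum(ctr^2)
  Q
}

#' Trend test of the slope process across quantiles
#'
#' Tests whether the quantile-specific slope changes as a polynomial of the
#' given degree in the percentile, using the orthogonal contrast `c`:
#' the statistic is `t = c'beta / sqrt(c' V c)` with `V` the bootstrap
#' covariance of the slope process, referred to a t distribution on the pair
#' set's familial degrees of freedom. For `degree = 1` the least-squares
#' change in slope per one percentile (`per_percentile_slope`) and its SE
#' are also reported.
#'
#' @param fit a `qh_qrproc`.
#' @param degree 1 (linear), 2 (quadratic) or 3 (cubic).
#' @return object of class `qh_trend`: list with `degree`, `estimate`, `se`,
#'   `t_stat`, `p_value`, `df`, and for degree 1 `per_percentile_slope`,
#'   `per_percentile_se`.
#' @export
trend_test <- function(fit, degree) {
  stopifnot(inherits(fit, "qh_qrproc"), degree %in% 1:3)
  C <- orthogonal_contrasts(fit$grid, max_degree = max(3, degree))
  cc <- C[, degree]
  est <- sum(cc * fit$slope)
  v <- drop(crossprod(cc, fit$slope_cov %*% cc))
  if (v <= 0) stop("degenerate contrast variance")
  se <- sqrt(v)
  t_stat <- est / se
  p <- 2 * pt(-abs(t_stat), df = fit$df)
  out <- list(degree = degree, estimate = est, se = se, t_stat = t_stat,
              p_value = p, df = fit$df)
  if (degree == 1L) {
    cl <- attr(C, "linear_raw")
    out$per_percentile_slope <- sum(cl * fit$slope)
    out$per_percentile_se <- sqrt(drop(crossprod(cl, fit$slope_cov %*% cl)))
  }
  structure(out, class = "qh_trend")
}

#' Difference in slope between two quantiles
#'
#' `beta(tau_hi) - beta(tau_lo)` with its standard error from the bootstrap
#' variances and covariance, referred to a t distribution on the pair set's
#' degrees of freedom.
#'
#' @param fit a `qh_qrproc`.
#' @param tau_hi,tau_lo quantile levels; both must lie on the fitted grid.
#' @return object of class `qh_diff`: list with `tau_hi`, `tau_lo`,
#'   `difference`, `se`, `t_stat`, `p_value`, `df`.
#' @export
difference_test <- function(fit, tau_hi = 0.90, tau_lo = 0.10) {
  stopifnot(inherits(fit, "qh_qrproc"))
  i_hi <- match_tau(fit$grid, tau_hi)
  i_lo <- match_tau(fit$grid, tau_lo)
  diff <- fit$slope[i_hi] - fit$slope[i_lo]
  v <- fit$slope_cov[i_hi, i_hi] + fit$slope_cov[i_lo, i_lo] -
    2 * fit$slope_cov[i_hi, i_lo]
  se <- sqrt(max(v, 0))
  t_stat <- diff / se
  structure(list(tau_hi = tau_hi, tau_lo = tau_lo, difference = diff,
                 se = se, t_stat = t_stat,
                 p_value = 2 * pt(-abs(t_stat), df = fit$df), df = fit$df),
            class = "qh_diff")
}

match_tau <- function(grid, tau) {
  i <- which(abs(grid - tau) < 1e-9)
  if (length(i) != 1L) stop("tau = ", tau, " is not on the fitted grid")
  i
}

#' @export
print.qh_h2 <- function(x, ...) {
  cat(sprintf("<qh_h2> h2 = %.3f +/- %.3f (%s%s)\n", x$h2, x$se, x$method,
              if (is.na(x$r_spouse)) "" else
                sprintf(", r_spouse = %.2f", x$r_spouse)))
  invisible(x)
}

#' @export
print.qh_trend <- function(x, ...) {
  lbl <- c("linear", "quadratic", "cubic")[x$degree]
  cat(sprintf("<qh_trend> %s: estimate %.4g +/- %.4g, t = %.2f, P = %.3g (df = %d)\n",
              lbl, x$estimate, x$se, x$t_stat, x$p_value, x$df))
  if (!is.null(x$per_percentile_slope))
    cat(sprintf("  slope change per 1 percentile: %.4g +/- %.4g\n",
                x$per_percentile_slope, x$per_percentile_se))
  invisible(x)
}

#' @export
print.qh_diff <- function(x, ...) {
  cat(sprintf(
    "<qh_diff> beta(%.2f) - beta(%.2f) = %.4f +/- %.4f, P = %.3g (df = %d)\n",
    x$tau_hi, x$tau_lo, x$difference, x$se, x$p_value, x$df))
  invisible(x)
}
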