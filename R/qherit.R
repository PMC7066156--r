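#' Fit the quantile-specific heritability model to a pair set
#'
#' The central model fit. Given a weighted familial pair set, `qherit()`
#' estimates (i) the traditional weighted least-squares slope, (ii) the
#' weighted quantile-regression slope process over the grid with a bootstrap
#' estimate of its covariance, (iii) the quantile-specific heritability
#' curve via the method's Falconer conversion, and (iv) trend tests (linear,
#' quadratic, cubic orthogonal-polynomial contrasts) plus the high-minus-low
#' slope difference.
#'
#' @param pairs a `qh_pairs` object from one of the pair builders.
#' @param r_spouse spouse correlation used in the Falconer conversion;
#'   typically `weighted_correlation(build_spouse_pairs(...))`. Not needed
#'   for midparent pairs.
#' @param grid a [quantile_grid()].
#' @param n_boot bootstrap replicates for the slope covariance.
#' @param seed integer seed for the bootstrap.
#' @param resample_unit `"pair"` or `"family"`; see [bootstrap_process()].
#' @param tau_hi,tau_lo levels for the slope difference test.
#' @return an object of class `qherit`; see [print.qherit()],
#'   [summary.qherit()], [coef.qherit()], [vcov.qherit()], [plot.qherit()].
#' @examples
#' cfg <- signature_config(n_families = 300, seed = 7)
#' cohort <- generate_cohort(cfg)
#' adj <- adjust_phenotypes(cohort)
#' op <- build_op_pairs(adj, cohort)
#' rs <- weighted_correlation(build_spouse_pairs(adj, cohort))
#' fit <- qherit(op, r_spouse = rs, n_boot = 50, seed = 1)
#' fit
#' @export
qherit <- function(pairs, r_spouse = NA_real_, grid = quantile_grid(),
                   n_boot = 1000, seed, resample_unit = c("pair", "family"),
                   tau_hi = 0.90, tau_lo = 0.10) {
  resample_unit <- match.arg(resample_unit)
  kind <- attr(pairs, "kind")
  method <- switch(kind, OP = "OP", MIDPARENT = "MIDPARENT", FS = "FS",
                   stop("qherit() expects OP, MIDPARENT or FS pairs, got ",
                        kind))
  if (method != "MIDPARENT" && is.na(r_spouse))
    stop("r_spouse is required for ", method, " pairs")
  ols <- fit_weighted_ols(pairs)
  proc <- bootstrap_process(pairs, grid, n_boot = n_boot, seed = seed,
                            resample_unit = resample_unit)
  curve <- h2_curve(proc, r_spouse = r_spouse, method = method)
  trends <- lapply(1:3, function(d) trend_test(proc, d))
  names(trends) <- c("linear", "quadratic", "cubic")
  # the default 90th/10th contrast falls back to the grid extremes on grids
  # that do not contain those levels
  taus <- as.numeric(grid)
  on_grid <- function(t) any(abs(taus - t) < 1e-9)
  if (missing(tau_hi) && !on_grid(tau_hi)) tau_hi <- max(taus)
  if (missing(tau_lo) && !on_grid(tau_lo)) tau_lo <- min(taus)
  dif <- difference_test(proc, tau_hi = tau_hi, tau_lo = tau_lo)
  h2_trad <- switch(method,
    OP = h2_from_op(ols$slope, ols$slope_se, r_spouse),
    MIDPARENT = h2_from_om(ols$slope, ols$slope_se),
    FS = h2_from_fs(ols$slope, ols$slope_se, r_spouse))
  structure(list(kind = kind, method = method, r_spouse = r_spouse,
                 n_pairs = nrow(pairs), total_weight = sum(pairs$weight),
                 ols = ols, h2_traditional = h2_trad,
                 process = proc, h2 = curve,
                 trends = trends, difference = dif,
                 call = match.call()),
            class = "qherit")
}

#' @describeIn qherit concise report: traditional slope and heritability,
#'   the per-percentile trend, and the high-low difference.
#' @param x,object a `qherit` fit.
#' @param ... unused.
#' @export
print.qherit <- function(x, ...) {
  cat(sprintf("Quantile-specific heritability fit (%s pairs, n = %d, df = %d)\n",
              x$kind, x$n_pairs, x$process$df))
  if (!is.na(x$r_spouse))
    cat(sprintf("  spouse correlation: %.3f\n", x$r_spouse))
  cat(sprintf("  traditional slope: %.4f +/- %.4f (r = %.2f) -> h2 = %.3f +/- %.3f\n",
              x$ols$slope, x$ols$slope_se, x$ols$correlation,
              x$h2_traditional$h2, x$h2_traditional$se))
  tr <- x$trends$linear
  cat(sprintf("  slope change per 1 percentile: %.4g +/- %.4g (P = %.3g)\n",
              tr$per_percentile_slope, tr$per_percentile_se, tr$p_value))
  cat(sprintf("  quadratic P = %.3g, cubic P = %.3g\n",
              x$trends$quadratic$p_value, x$trends$cubic$p_value))
  d <- x$difference
  cat(sprintf("  beta(%.2f) - beta(%.2f) = %.4f +/- %.4f (P = %.3g)\n",
              d$tau_hi, d$tau_lo, d$difference, d$se, d$p_value))
  invisible(x)
}

#' @describeIn qherit the heritability curve plus selected quantiles.
#' @export
summary.qherit <- function(object, ...) {
  sel <- c(0.10, 0.25, 0.50, 0.75, 0.90)
  idx <- vapply(sel, function(t) {
    i <- which.min(abs(object$process$grid - t)); i
  }, integer(1))
  structure(list(fit = object,
                 selected = object$h2[idx, , drop = FALSE]),
            class = "summary.qherit")
}

#' @export
print.summary.qherit <- function(x, ...) {
  print(x$fit)
  cat("\nHeritability at selected quantiles:\n")
  print(transform(x$selected, h2 = round(h2, 3), h2_se = round(h2_se, 3),
                  slope = round(slope, 4), slope_se = round(slope_se, 4)),
        row.names = FALSE)
  invisible(x)
}

#' @describeIn qherit quantile-specific slopes (`what = "slope"`) or
#'   heritabilities (`what = "h2"`), named by grid level.
#' @param what which coefficients to return.
#' @export
coef.qherit <- function(object, what = c("slope", "h2"), ...) {
  what <- match.arg(what)
  setNames(object$h2[[what]], format(object$h2$tau))
}

#' @describeIn qherit bootstrap covariance matrix of the slope process.
#' @export
vcov.qherit <- function(object, ...) {
  v <- object$process$slope_cov
  dimnames(v) <- list(format(object$process$grid),
                      format(object$process$grid))
  v
}

#' @describeIn qherit heritability (or slope) versus quantile with a
#'   pointwise 95% band from the bootstrap.
#' @param band plot the +/- 1.96 SE band.
#' @export
plot.qherit <- function(x, what = c("h2", "slope"), band = TRUE, ...) {
  what <- match.arg(what)
  h <- x$h2
  yv <- h[[what]]
  se <- h[[paste0(what, "_se")]]
  ylab <- if (what == "h2") "heritability h2" else "slope"
  plot(h$tau, yv, type = "n", xlab = "quantile of the trait distribution",
       ylab = ylab,
       ylim = range(c(yv - 1.96 * se, yv + 1.96 * se), finite = TRUE), ...)
  if (band)
    polygon(c(h$tau, rev(h$tau)),
            c(yv - 1.96 * se, rev(yv + 1.96 * se)),
            border = NA, col = adjustcolor("steelblue", 0.3))
  lines(h$tau, yv, lwd = 2, col = "steelblue4")
  abline(h = 0, lty = 3)
  invisible(x)
}
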