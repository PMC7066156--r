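#' Quantile grid
#'
#' Ordered quantile levels at which the slope process is estimated. The
#' default grid spans the 5th to the 95th percentile in steps of one
#' percentile (91 levels).
#'
#' @param min,max,step grid limits and spacing on the quantile scale.
#' @return numeric vector of class `qh_grid`.
#' @export
quantile_grid <- function(min = 0.05, max = 0.95, step = 0.01) {
  stopifnot(min > 0, max < 1, min < max, step > 0)
  taus <- seq(min, max, by = step)
  if (any(diff(taus) <= 0)) stop("grid must be strictly increasing")
  structure(taus, class = "qh_grid")
}

#' Check (pinball) loss
#'
#' `rho_tau(u) = u * (tau - 1[u < 0])`, the objective whose minimizer is the
#' tau-th conditional quantile.
#'
#' @param u residual(s).
#' @param tau quantile level in (0, 1).
#' @return nonnegative loss, vectorized over `u`.
#' @export
check_loss <- function(u, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("tau must be a single number in (0, 1)")
  u * (tau - (u < 0))
}

pairs_xyw <- function(pairs) {
  stopifnot(inherits(pairs, "qh_pairs") || is.data.frame(pairs))
  list(x = as.numeric(pairs$x), y = as.numeric(pairs$y),
       w = as.numeric(pairs$weight))
}

check_regressable <- function(x, n_min = 3L) {
  if (length(x) < n_min) stop("need at least ", n_min, " pairs")
  if (length(unique(x)) < 2L)
    stop("degenerate predictor (all x equal): slope unidentifiable")
}

#' Weighted linear quantile regression at one level
#'
#' Minimizes the weighted check loss `sum_i w_i rho_tau(y_i - a - b x_i)`
#' exactly, by a simplex walk on the vertex set of the underlying linear
#' program (every optimum lies on a line through two data points), with an
#' interior-point solver as fallback for degenerate tie plateaus.
#'
#' @param pairs a `qh_pairs` object (or data frame with `x`, `y`, `weight`).
#' @param tau quantile level in (0, 1).
#' @return named vector `c(intercept, slope)`.
#' @export
fit_weighted_quantile <- function(pairs, tau) {
  if (tau <= 0 || tau >= 1) stop("tau must be in (0, 1)")
  d <- pairs_xyw(pairs)
  check_regressable(d$x)
  cf <- qr_process_cpp(d$x, d$y, d$w, tau)
  if (anyNA(cf)) stop("quantile fit failed at tau = ", tau)
  c(intercept = cf[1, 1], slope = cf[1, 2])
}

#' Quantile process: independent per-level fits over a grid
#'
#' @param pairs a `qh_pairs` object.
#' @param grid a [quantile_grid()] (or numeric vector of levels).
#' @return data frame with `tau`, `intercept`, `slope`.
#' @export
fit_quantile_process <- function(pairs, grid = quantile_grid()) {
  d <- pairs_xyw(pairs)
  check_regressable(d$x)
  taus <- as.numeric(grid)
  cf <- qr_process_cpp(d$x, d$y, d$w, taus)
  if (anyNA(cf))
    stop("quantile fit failed at tau = ",
         paste(taus[!complete.cases(cf)], collapse = ", "))
  data.frame(tau = taus, intercept = cf[, 1], slope = cf[, 2])
}

#' Bootstrap covariance of the quantile slope process
#'
#' Refits the whole quantile process on `n_boot` resamples drawn with
#' replacement (of single pairs, or of whole families with
#' `resample_unit = "family"`) and returns the point fits together with the
#' empirical covariance of the slopes across replicates. A replicate whose
#' resampled predictor is degenerate is redrawn; more than 10% redraws is an
#' error. The seed fully determines the output.
#'
#' @inheritParams fit_quantile_process
#' @param n_boot number of bootstrap replicates (the reference analysis used
#'   1000).
#' @param seed integer seed.
#' @param resample_unit `"pair"` resamples individual pairs; `"family"`
#'   resamples whole families (cluster bootstrap), appropriate when pairs
#'   within a family are dependent.
#' @return object of class `qh_qrproc` with elements `grid`, `intercept`,
#'   `slope`, `slope_cov`, `slope_se`, `n_boot`, `seed`, `resample_unit`,
#'   `df`, `n_redraws`.
#' @export
bootstrap_process <- function(pairs, grid = quantile_grid(), n_boot = 1000,
                              seed, resample_unit = c("pair", "family")) {
  resample_unit <- match.arg(resample_unit)
  if (n_boot < 2) stop("n_boot must be at least 2")
  if (missing(seed)) stop("a seed is required for the bootstrap")
  d <- pairs_xyw(pairs)
  check_regressable(d$x)
  taus <- as.numeric(grid)
  point <- fit_quantile_process(pairs, taus)

  n <- length(d$x)
  fam <- as.character(pairs$family_id)
  fam_rows <- if (resample_unit == "family") split(seq_len(n), fam) else NULL

  draw <- function() {
    if (resample_unit == "pair") {
      sample.int(n, n, replace = TRUE)
    } else {
      # resample families with replacement until >= n rows, then trim so the
      # replicate matches the original total count
      nf <- length(fam_rows)
      rows <- integer(0)
      while (length(rows) < n) {
        take <- sample.int(nf, nf, replace = TRUE)
        rows <- c(rows, unlist(fam_rows[take], use.names = FALSE))
      }
      rows[seq_len(n)]
    }
  }

  n_redraws <- 0L
  idx <- matrix(0L, nrow = n, ncol = n_boot)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      repeat {
        cand <- draw()
        if (length(unique(d$x[cand])) >= 2L) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 0.1 * n_boot)
          stop("more than 10% of bootstrap replicates degenerate")
      }
      idx[, b] <- cand
    }
  })
  if (n_redraws > 0L)
    message(n_redraws, " degenerate bootstrap replicate(s) redrawn")

  slopes <- qr_boot_cpp(d$x, d$y, d$w, taus, idx - 1L)
  if (anyNA(slopes)) stop("bootstrap refit failed")
  slope_cov <- stats::cov(slopes)
  slope_cov <- (slope_cov + t(slope_cov)) / 2
  structure(list(grid = taus,
                 intercept = point$intercept,
                 slope = point$slope,
                 slope_cov = slope_cov,
                 slope_se = sqrt(diag(slope_cov)),
                 n_boot = as.integer(n_boot),
                 seed = as.integer(seed),
                 resample_unit = resample_unit,
                 df = attr(pairs, "df"),
                 n_redraws = n_redraws),
            class = "qh_qrproc")
}

#' Traditional (weighted least squares) regression of a pair set
#'
#' Frequency-weighted least squares slope with a conventional standard error
#' computed on the pair set's familial degrees of freedom, plus the weighted
#' correlation.
#'
#' @param pairs a `qh_pairs` object.
#' @return object of class `qh_ols` with `intercept`, `slope`, `slope_se`,
#'   `correlation`, `df`.
#' @export
fit_weighted_ols <- function(pairs) {
  d <- pairs_xyw(pairs)
  check_regressable(d$x)
  w <- d$w
  mx <- weighted.mean(d$x, w)
  my <- weighted.mean(d$y, w)
  sxx <- sum(w * (d$x - mx)^2)
  sxy <- sum(w * (d$x - mx) * (d$y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  dof <- attr(pairs, "df")
  if (is.null(dof)) dof <- length(d$x) - 2L
  rss <- sum(w * (d$y - intercept - slope * d$x)^2)
  slope_se <- sqrt(rss / dof / sxx)
  structure(list(intercept = intercept, slope = slope, slope_se = slope_se,
                 correlation = weighted_correlation(pairs), df = dof),
            class = "qh_ols")
}

#' @export
print.qh_qrproc <- function(x, ...) {
  cat(sprintf(
    "<qh_qrproc> %d quantile levels in [%.2f, %.2f], %d bootstrap replicates (%s resampling), df = %d\n",
    length(x$grid), min(x$grid), max(x$grid), x$n_boot, x$resample_unit,
    x$df))
  i <- unique(round(seq(1, length(x$grid), length.out = 5)))
  print(data.frame(tau = x$grid[i], slope = x$slope[i], se = x$slope_se[i]),
        row.names = FALSE)
  invisible(x)
}

#' @export
print.qh_ols <- function(x, ...) {
  cat(sprintf("<qh_ols> slope %.4f +/- %.4f, r = %.2f, df = %d\n",
              x$slope, x$slope_se, x$correlation, x$df))
  invisible(x)
}
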