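#' Configuration of a full pipeline run
#'
#' Bundles either input paths or a simulator configuration with all analysis
#' settings. `read_run_config()` loads the same structure from a YAML file
#' (keys mirror the argument names; a `synthetic:` block is passed to
#' [synthetic_config()]).
#'
#' @param pedigree_path,exam_path input TSVs (ignored when `synthetic` is
#'   given).
#' @param synthetic a `qh_config` to simulate the cohort instead of reading
#'   files.
#' @param transform phenotype transform for the adjustment step.
#' @param pair_kinds subset of `c("OP", "MIDPARENT", "FS")` to analyse.
#' @param grid a [quantile_grid()].
#' @param n_boot,seed,resample_unit bootstrap settings; see
#'   [bootstrap_process()].
#' @param min_age eligibility threshold in years.
#' @param medication_rule see [apply_eligibility()].
#' @param out_dir where [run_pipeline()] writes its outputs (NULL: nowhere).
#' @return a `qh_runconfig` list.
#' @export
run_config <- function(pedigree_path = NULL, exam_path = NULL,
                       synthetic = NULL,
                       transform = c("identity", "log"),
                       pair_kinds = c("OP", "MIDPARENT", "FS"),
                       grid = quantile_grid(), n_boot = 1000, seed = NULL,
                       resample_unit = c("pair", "family"),
                       min_age = 16, medication_rule = c("exam", "subject"),
                       out_dir = NULL) {
  transform <- match.arg(transform)
  resample_unit <- match.arg(resample_unit)
  medication_rule <- match.arg(medication_rule)
  pair_kinds <- match.arg(pair_kinds, several.ok = TRUE)
  if (is.null(synthetic) && (is.null(pedigree_path) || is.null(exam_path)))
    stop("either input paths or a synthetic config is required")
  if (is.null(seed)) stop("a seed is required (bootstrap and/or simulation)")
  structure(list(pedigree_path = pedigree_path, exam_path = exam_path,
                 synthetic = synthetic, transform = transform,
                 pair_kinds = pair_kinds, grid = grid,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 resample_unit = resample_unit, min_age = min_age,
                 medication_rule = medication_rule, out_dir = out_dir),
            class = "qh_runconfig")
}

#' @rdname run_config
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (!is.null(s$offspring_dist))
      s$offspring_dist <- unlist(s$offspring_dist)
    syn <- do.call(synthetic_config, s)
  }
  grid <- if (is.null(y$grid)) quantile_grid() else
    do.call(quantile_grid, y$grid)
  args <- y[setdiff(names(y), c("synthetic", "grid"))]
  do.call(run_config, c(args, list(synthetic = syn, grid = grid)))
}

#' Run the full pipeline
#'
#' simulate/read -> eligibility filter -> per-cohort age/sex adjustment ->
#' pair building -> quantile-regression fits with bootstrap -> heritability
#' conversion -> trend and difference tests, then renders the result tables.
#' When `config$out_dir` is set the tables are written via [write_results()]
#' (`slopes.csv`, `h2_curve.csv`, `table1.csv`, `trend_tests.json`,
#' `run_summary.json`); a failed stage removes partial outputs.
#'
#' @param config a `qh_runconfig`.
#' @return list with the per-kind [qherit()] fits (`fits`), `r_spouse`, the
#'   result tables (`slopes`, `h2_curve`, `table1`, `trend_tests`) and
#'   `run_summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "qh_runconfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir) && dir.exists(config$out_dir))
        unlink(file.path(config$out_dir,
                         c("slopes.csv", "h2_curve.csv", "table1.csv",
                           "trend_tests.json", "run_summary.json")))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- stage("input", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else read_cohort(config$pedigree_path, config$exam_path)
  })
  cohort <- stage("eligibility",
                  apply_eligibility(cohort, min_age = config$min_age,
                                    medication_rule = config$medication_rule))
  adjusted <- stage("adjustment",
                    adjust_phenotypes(cohort, transform = config$transform))
  r_spouse <- stage("spouse_correlation",
                    weighted_correlation(build_spouse_pairs(adjusted, cohort)))
  fits <- list()
  for (kind in config$pair_kinds) {
    pairs <- stage(paste0("pairs_", kind), switch(kind,
      OP = build_op_pairs(adjusted, cohort),
      MIDPARENT = build_midparent_pairs(adjusted, cohort),
      FS = build_fullsib_pairs(adjusted, cohort)))
    fits[[kind]] <- stage(paste0("fit_", kind),
      qherit(pairs, r_spouse = r_spouse, grid = config$grid,
             n_boot = config$n_boot, seed = config$seed,
             resample_unit = config$resample_unit))
  }

  slopes <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(kind = k, tau = f$process$grid, slope = f$process$slope,
               slope_se = f$process$slope_se)
  }))
  h2c <- do.call(rbind, lapply(names(fits), function(k) {
    cbind(kind = k, fits[[k]]$h2)
  }))
  trend_tests <- lapply(fits, function(f) {
    lapply(f$trends, function(t) {
      t <- unclass(t); t
    })
  })
  table1 <- render_table1(fits)
  run_summary <- list(
    transform = config$transform,
    pair_kinds = config$pair_kinds,
    grid = list(min = min(as.numeric(config$grid)),
                max = max(as.numeric(config$grid)),
                n = length(config$grid)),
    n_boot = config$n_boot, seed = config$seed,
    resample_unit = config$resample_unit,
    min_age = config$min_age, medication_rule = config$medication_rule,
    r_spouse = r_spouse,
    n_individuals = nrow(cohort$individuals),
    n_exams = nrow(cohort$exams),
    n_pairs = lapply(fits, function(f) f$n_pairs),
    synthetic = if (!is.null(config$synthetic))
      unclass(config$synthetic) else NULL)

  out <- list(fits = fits, r_spouse = r_spouse, slopes = slopes,
              h2_curve = h2c, table1 = table1, trend_tests = trend_tests,
              run_summary = run_summary)
  if (!is.null(config$out_dir))
    write_results(list(slopes = slopes, h2_curve = h2c, table1 = table1,
                       trend_tests = trend_tests,
                       run_summary = run_summary),
                  config$out_dir)
  out
}

#' Render the summary table of traditional and quantile regression results
#'
#' One row per fitted pair kind: weighted correlation, traditional slope
#' with SE, change in slope per one percentile with SE, linear/quadratic/
#' cubic trend P values, and the 90th-minus-10th (by default) slope
#' difference with SE and P.
#'
#' @param fits named list of [qherit()] fits (as in [run_pipeline()]'s
#'   result).
#' @return data frame with one row per pair kind.
#' @export
render_table1 <- function(fits) {
  rows <- lapply(names(fits), function(k) {
    f <- fits[[k]]
    tr <- f$trends
    d <- f$difference
    data.frame(kind = k,
               correlation = f$ols$correlation,
               slope = f$ols$slope, slope_se = f$ols$slope_se,
               per_pct_slope = tr$linear$per_percentile_slope,
               per_pct_se = tr$linear$per_percentile_se,
               p_linear = tr$linear$p_value,
               p_quadratic = tr$quadratic$p_value,
               p_cubic = tr$cubic$p_value,
               diff_hi_lo = d$difference, diff_se = d$se,
               p_diff = d$p_value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
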