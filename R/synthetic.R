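#' Configuration for the Gaussian-copula pedigree simulator
#'
#' The simulator draws, per family, a multivariate normal latent vector
#' (father, mother, offspring...) with `corr(father, mother) = rho_spouse`,
#' `corr(parent, child) = rho_po` and `corr(child, child) = rho_ss`, maps
#' each latent value through the standard normal CDF and the inverse margin
#' CDF (a Gaussian copula, decoupling familial correlation from margin
#' shape), adds age/sex covariate effects on the measurement scale, and
#' replicates each individual over `n_exams` exams with independent noise.
#' A nonlinear (e.g. lognormal) margin makes conditional quantile slopes
#' rise with the quantile level on the raw scale even though the latent
#' dependence is constant — the generative mechanism for quantile-dependent
#' expressivity used throughout the package's tests.
#'
#' @param n_families number of two-generation families.
#' @param offspring_dist probability table over sibship sizes 1..6; the
#'   default approximates the cohort mix of the motivating study (mostly 2-3
#'   children, some singletons and large sibships).
#' @param rho_spouse,rho_po,rho_ss latent-scale correlations.
#' @param margin list: `list(dist = "normal", mean, sd)`,
#'   `list(dist = "lognormal", meanlog, sdlog)` or
#'   `list(dist = "gamma", shape, scale)`.
#' @param sex_effect additive measurement-scale shift for females.
#' @param age_effect,age2_effect measurement-scale coefficients on age and
#'   age squared.
#' @param n_exams exams per individual.
#' @param exam_noise_sd measurement-scale SD of independent per-exam noise.
#' @param age_range offspring age range in years (parents are offset +25).
#' @param seed integer seed; the one RNG stream drives everything.
#' @return object of class `qh_config` (a validated list).
#' @export
synthetic_config <- function(n_families = 1000,
                             offspring_dist = c(`1` = 0.25, `2` = 0.38,
                                                `3` = 0.22, `4` = 0.09,
                                                `5` = 0.04, `6` = 0.02),
                             rho_spouse = 0.15, rho_po = 0.35, rho_ss = 0.35,
                             margin = list(dist = "lognormal",
                                           meanlog = 0.6, sdlog = 0.6),
                             sex_effect = -0.3, age_effect = 0.015,
                             age2_effect = -1e-4,
                             n_exams = 2, exam_noise_sd = 0.2,
                             age_range = c(20, 60), seed = 1) {
  stopifnot(n_families >= 1, n_exams >= 1, exam_noise_sd >= 0,
            length(age_range) == 2, age_range[1] < age_range[2],
            age_range[1] > 0)
  if (abs(sum(offspring_dist) - 1) > 1e-8)
    stop("offspring_dist probabilities must sum to 1")
  sizes <- as.integer(names(offspring_dist))
  if (anyNA(sizes) || any(sizes < 1))
    stop("offspring_dist must be named by sibship sizes")
  k_max <- max(sizes[offspring_dist > 0])
  R <- family_corr(k_max, rho_spouse, rho_po, rho_ss)
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(ch))
    stop("family latent correlation matrix is not positive definite for ",
         "sibship size ", k_max)
  margin$dist <- match.arg(margin$dist, c("normal", "lognormal", "gamma"))
  structure(list(n_families = as.integer(n_families),
                 offspring_dist = offspring_dist,
                 rho_spouse = rho_spouse, rho_po = rho_po, rho_ss = rho_ss,
                 margin = margin, sex_effect = sex_effect,
                 age_effect = age_effect, age2_effect = age2_effect,
                 n_exams = as.integer(n_exams),
                 exam_noise_sd = exam_noise_sd,
                 age_range = age_range, seed = as.integer(seed)),
            class = "qh_config")
}

# latent correlation matrix for a family with k offspring,
# order: father, mother, child_1..child_k
family_corr <- function(k, rho_spouse, rho_po, rho_ss) {
  m <- diag(2 + k)
  m[1, 2] <- m[2, 1] <- rho_spouse
  if (k > 0) {
    m[1:2, 3:(2 + k)] <- rho_po
    m[3:(2 + k), 1:2] <- rho_po
    if (k > 1) {
      blk <- matrix(rho_ss, k, k); diag(blk) <- 1
      m[3:(2 + k), 3:(2 + k)] <- blk
    }
  }
  m
}

q_margin <- function(u, margin) {
  switch(margin$dist,
         normal = qnorm(u, margin$mean, margin$sd),
         lognormal = stats::qlnorm(u, margin$meanlog, margin$sdlog),
         gamma = stats::qgamma(u, shape = margin$shape,
                               scale = margin$scale))
}

#' Preset: constant-slope (null) generating conditions
#'
#' Normal margins: conditional quantiles of a bivariate normal are parallel
#' lines, so the quantile slope process is constant and trend tests should
#' reject at their nominal level only.
#'
#' @param n_families,seed passed through to [synthetic_config()].
#' @return a `qh_config`.
#' @export
null_config <- function(n_families = 1000, seed = 1) {
  synthetic_config(n_families = n_families,
                   margin = list(dist = "normal", mean = 2.4, sd = 1.2),
                   seed = seed)
}

#' Preset: quantile-dependent (signature) generating conditions
#'
#' Lognormal margins over the same constant latent correlations: raw-scale
#' quantile slopes rise with the quantile level, while on the log scale the
#' process is near-constant — the qualitative signature of
#' quantile-dependent expressivity.
#'
#' @param n_families,seed passed through to [synthetic_config()].
#' @return a `qh_config`.
#' @export
signature_config <- function(n_families = 1000, seed = 1) {
  synthetic_config(n_families = n_families,
                   margin = list(dist = "lognormal",
                                 meanlog = 0.6, sdlog = 0.6),
                   seed = seed)
}

#' Generate a synthetic two-generation cohort
#'
#' See [synthetic_config()] for the generative model. Parents are labelled
#' cohort `"offspring"` and children cohort `"gen3"`, mirroring the
#' two-cohort structure the adjustment step expects. Output is fully
#' determined by `config$seed`.
#'
#' @param config a `qh_config`.
#' @param out_dir if non-NULL, the pedigree/exam TSVs are also written here.
#' @return a `qh_cohort`.
#' @export
generate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "qh_config"))
  with_seed(config$seed, {
    sizes <- as.integer(names(config$offspring_dist))
    k_of_family <- sample(sizes, config$n_families, replace = TRUE,
                          prob = config$offspring_dist)
    fam_id <- sprintf("F%05d", seq_len(config$n_families))

    ind_list <- list()
    for (k in sort(unique(k_of_family))) {
      fams <- which(k_of_family == k)
      nk <- length(fams)
      R <- family_corr(k, config$rho_spouse, config$rho_po, config$rho_ss)
      Z <- matrix(rnorm(nk * (2 + k)), nk) %*% chol(R)
      G <- q_margin(pnorm(Z), config$margin)
      roles <- c("F", "M", paste0("O", seq_len(k)))
      ind_list[[length(ind_list) + 1L]] <- data.frame(
        individual_id = paste0(rep(fam_id[fams], each = 2 + k), "_",
                               rep(roles, nk)),
        family = rep(fam_id[fams], each = 2 + k),
        role = rep(roles, nk),
        genetic = as.vector(t(G)),
        stringsAsFactors = FALSE)
    }
    ind <- do.call(rbind, ind_list)
    is_parent <- ind$role %in% c("F", "M")
    ind$sex <- ifelse(ind$role == "F", "M",
                      ifelse(ind$role == "M", "F",
                             ifelse(rbinom(nrow(ind), 1, 0.5) == 1, "F", "M")))
    ind$father_id <- ifelse(is_parent, NA, paste0(ind$family, "_F"))
    ind$mother_id <- ifelse(is_parent, NA, paste0(ind$family, "_M"))
    ind$cohort <- ifelse(is_parent, "offspring", "gen3")
    base_age <- runif(nrow(ind), config$age_range[1], config$age_range[2]) +
      ifelse(is_parent, 25, 0)

    n <- nrow(ind)
    ne <- config$n_exams
    exam_age <- rep(base_age, each = ne) + 4 * (seq_len(ne) - 1)
    female <- rep(as.numeric(ind$sex == "F"), each = ne)
    value <- rep(ind$genetic, each = ne) +
      config$sex_effect * female +
      config$age_effect * exam_age +
      config$age2_effect * exam_age^2 +
      rnorm(n * ne, sd = config$exam_noise_sd)
    # positive-support phenotypes never go below the assay detection floor
    if (config$margin$dist %in% c("lognormal", "gamma"))
      value <- pmax(value, 0.01)
    exams <- data.frame(
      individual_id = rep(ind$individual_id, each = ne),
      exam_index = rep(seq_len(ne), n),
      age = exam_age,
      value = value,
      on_lipid_meds = FALSE,
      stringsAsFactors = FALSE)

    cohort <- new_cohort(
      ind[c("individual_id", "father_id", "mother_id", "sex", "cohort")],
      exams)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_cohort(cohort,
                   file.path(out_dir, "pedigree.tsv"),
                   file.path(out_dir, "exams.tsv"))
    }
    cohort
  })
}

#' Population quantile slope by brute-force Monte Carlo
#'
#' An independent oracle for the population linear quantile-regression slope
#' implied by a simulator configuration: simulates `n_mc` pairs of the given
#' kind directly from the latent model (no pedigree assembly, no covariate
#' effects -- the target is the adjusted scale; exam-averaged measurement
#' noise is included) and minimizes the Monte-Carlo expected check loss by a
#' one-dimensional search over the slope, with the intercept profiled out as
#' the tau-quantile of the slope-adjusted residuals. Entirely independent of
#' the package's LP solver.
#'
#' @param config a `qh_config`.
#' @param tau quantile level.
#' @param pair_kind `"OP"`, `"MIDPARENT"`, `"FS"` or `"SPOUSE"`.
#' @param n_mc number of simulated pairs (at least 1e5).
#' @param seed seed for the Monte-Carlo draw (defaults to `config$seed`).
#' @return the population slope estimate.
#' @export
oracle_quantile_slope <- function(config, tau,
                                  pair_kind = c("OP", "MIDPARENT", "FS",
                                                "SPOUSE"),
                                  n_mc = 1e5, seed = config$seed) {
  pair_kind <- match.arg(pair_kind)
  stopifnot(inherits(config, "qh_config"), n_mc >= 1e5)
  with_seed(seed, {
    rho <- switch(pair_kind, OP = config$rho_po, FS = config$rho_ss,
                  SPOUSE = config$rho_spouse, MIDPARENT = NA)
    # exam-averaged measurement: per-exam noise and detection floor as in
    # generate_cohort(), averaged over n_exams
    measure <- function(g) {
      acc <- 0
      for (e in seq_len(config$n_exams)) {
        v <- g + rnorm(length(g), sd = config$exam_noise_sd)
        if (config$margin$dist %in% c("lognormal", "gamma"))
          v <- pmax(v, 0.01)
        acc <- acc + v
      }
      acc / config$n_exams
    }
    if (pair_kind == "MIDPARENT") {
      R <- family_corr(1, config$rho_spouse, config$rho_po, config$rho_ss)
      Z <- matrix(rnorm(n_mc * 3), n_mc) %*% chol(R)
      G <- q_margin(pnorm(Z), config$margin)
      x <- (measure(G[, 1]) + measure(G[, 2])) / 2
      y <- measure(G[, 3])
    } else {
      z1 <- rnorm(n_mc)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_mc)
      x <- measure(q_margin(pnorm(z1), config$margin))
      y <- measure(q_margin(pnorm(z2), config$margin))
    }
    b_ls <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    prof <- function(b) {
      r <- y - b * x
      mean(check_loss(r - quantile(r, tau, names = FALSE, type = 8), tau))
    }
    optimize(prof, lower = b_ls - 1, upper = b_ls + 1, tol = 1e-6)$minimum
  })
}

#' @export
print.qh_config <- function(x, ...) {
  cat(sprintf(
    "<qh_config> %d families, margin %s, rho (spouse/po/ss) = %.2f/%.2f/%.2f, %d exam(s), seed %d\n",
    x$n_families, x$margin$dist, x$rho_spouse, x$rho_po, x$rho_ss,
    x$n_exams, x$seed))
  invisible(x)
}
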