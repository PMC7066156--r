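#' Fit the age/sex adjustment model for one cohort
#'
#' Ordinary least squares of the (optionally log-transformed) phenotype on
#' an intercept and the five covariates: female indicator, age, age^2,
#' female x age, and female x age^2, pooling all exam records of the cohort.
#' Rank-deficient designs (e.g. a single-sex cohort) are fitted with the
#' collinear columns dropped and a warning.
#'
#' @param cohort a `qh_cohort`.
#' @param cohort_label which cohort's exam records to pool.
#' @param transform `"identity"` or `"log"` (natural log; requires positive
#'   values).
#' @return an object of class `qh_adjustment` with elements `coefficients`
#'   (named, `NA` for dropped columns), `grand_mean` (mean of the transformed
#'   values), `n_obs`, `cohort`, `transform`.
#' @export
fit_adjustment_model <- function(cohort, cohort_label,
                                 transform = c("identity", "log")) {
  transform <- match.arg(transform)
  ids <- cohort$individuals$individual_id[
    cohort$individuals$cohort == cohort_label]
  exm <- cohort$exams[cohort$exams$individual_id %in% ids, , drop = FALSE]
  if (nrow(exm) < 7L)
    stop("need at least 7 exam records to fit the adjustment model, got ",
         nrow(exm))
  sex <- cohort$individuals$sex[match(exm$individual_id,
                                      cohort$individuals$individual_id)]
  female <- as.numeric(sex == "F")
  v <- exm$value
  if (transform == "log") {
    if (any(v <= 0)) stop("log transform requires strictly positive values")
    v <- log(v)
  }
  age <- exm$age
  dat <- data.frame(v = v, female = female, age = age, age2 = age^2,
                    fem_age = female * age, fem_age2 = female * age^2)
  fit <- lm(v ~ female + age + age2 + fem_age + fem_age2, data = dat)
  cf <- coef(fit)
  if (anyNA(cf))
    warning("collinear adjustment column(s) dropped for cohort ",
            cohort_label, ": ", paste(names(cf)[is.na(cf)], collapse = ", "))
  structure(list(coefficients = cf,
                 grand_mean = mean(v),
                 n_obs = nrow(exm),
                 cohort = cohort_label,
                 transform = transform),
            class = "qh_adjustment")
}

#' Adjust exam values and average per individual
#'
#' For each exam record of the model's cohort, the adjusted value is the
#' OLS residual plus the cohort grand mean of the (transformed) phenotype,
#' keeping the phenotype scale interpretable; each individual's adjusted
#' exams are then averaged.
#'
#' @param cohort a `qh_cohort`.
#' @param model a `qh_adjustment` from [fit_adjustment_model()].
#' @return data frame with `individual_id`, `value`, `n_exams`, `cohort`.
#' @export
adjust_and_average <- function(cohort, model) {
  stopifnot(inherits(model, "qh_adjustment"))
  ids <- cohort$individuals$individual_id[
    cohort$individuals$cohort == model$cohort]
  exm <- cohort$exams[cohort$exams$individual_id %in% ids, , drop = FALSE]
  sex <- cohort$individuals$sex[match(exm$individual_id,
                                      cohort$individuals$individual_id)]
  female <- as.numeric(sex == "F")
  v <- exm$value
  if (model$transform == "log") v <- log(v)
  age <- exm$age
  X <- cbind(1, female, age, age^2, female * age, female * age^2)
  cf <- model$coefficients
  cf[is.na(cf)] <- 0
  adjusted <- v - drop(X %*% cf) + model$grand_mean
  agg_mean <- tapply(adjusted, exm$individual_id, mean)
  agg_n <- tapply(adjusted, exm$individual_id, length)
  data.frame(individual_id = names(agg_mean),
             value = as.numeric(agg_mean),
             n_exams = as.integer(agg_n),
             cohort = model$cohort,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Age/sex-adjust all cohorts and average exams per individual
#'
#' Fits one adjustment model per cohort (per cohort and exam wave with
#' `scope = "cohort_exam"`) and returns one adjusted value per individual,
#' pooled over cohorts.
#'
#' @inheritParams fit_adjustment_model
#' @param scope `"cohort"` pools a cohort's exam records into one model;
#'   `"cohort_exam"` fits a separate model per exam wave.
#' @return data frame with `individual_id`, `value`, `n_exams`, `cohort`.
#' @export
adjust_phenotypes <- function(cohort, transform = c("identity", "log"),
                              scope = c("cohort", "cohort_exam")) {
  transform <- match.arg(transform)
  scope <- match.arg(scope)
  out <- list()
  for (lab in unique(cohort$individuals$cohort)) {
    ids <- cohort$individuals$individual_id[
      cohort$individuals$cohort == lab]
    has_exams <- any(cohort$exams$individual_id %in% ids)
    if (!has_exams) next
    if (scope == "cohort") {
      m <- fit_adjustment_model(cohort, lab, transform)
      out[[length(out) + 1L]] <- adjust_and_average(cohort, m)
    } else {
      sub <- cohort$exams[cohort$exams$individual_id %in% ids, , drop = FALSE]
      pieces <- lapply(unique(sub$exam_index), function(ei) {
        slice <- cohort
        slice$exams <- sub[sub$exam_index == ei, , drop = FALSE]
        m <- fit_adjustment_model(slice, lab, transform)
        adjust_and_average(slice, m)
      })
      merged <- do.call(rbind, pieces)
      agg <- tapply(merged$value, merged$individual_id, mean)
      n <- tapply(merged$n_exams, merged$individual_id, sum)
      out[[length(out) + 1L]] <- data.frame(
        individual_id = names(agg), value = as.numeric(agg),
        n_exams = as.integer(n), cohort = lab,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "transform") <- transform
  attr(res, "scope") <- scope
  res
}

#' @export
print.qh_adjustment <- function(x, ...) {
  cat(sprintf("<qh_adjustment> cohort %s, %s scale, n_obs = %d\n",
              x$cohort, x$transform, x$n_obs))
  print(round(x$coefficients, 6))
  invisible(x)
}
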