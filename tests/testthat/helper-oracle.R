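# Exhaustive LP-vertex oracle for weighted linear quantile regression:
# the optimum lies on a line through two data points, so enumerating all
# two-point lines and scoring the weighted check loss is an exact,
# independent solve (O(n^2 * n); fine for test-sized instances).
enum_qr_oracle <- function(x, y, w, tau) {
  best <- Inf
  coef <- c(NA_real_, NA_real_)
  n <- length(x)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      u <- y - a - b * x
      obj <- sum(w * u * (tau - (u < 0)))
      if (obj < best) {
        best <- obj
        coef <- c(a, b)
      }
    }
  }
  list(objective = best, intercept = coef[1], slope = coef[2])
}

qr_objective <- function(x, y, w, tau, intercept, slope) {
  u <- y - intercept - slope * x
  sum(w * u * (tau - (u < 0)))
}

# hand-built miniature cohort: two nuclear families plus one single-parent
# offspring, on a fixed phenotype so tests can assert exact values
tiny_cohort <- function() {
  ind <- data.frame(
    individual_id = c("f1", "m1", "c1a", "c1b", "c1c",
                      "f2", "m2", "c2a",
                      "m3", "c3a"),
    father_id = c(NA, NA, "f1", "f1", "f1",
                  NA, NA, "f2",
                  NA, NA),
    mother_id = c(NA, NA, "m1", "m1", "m1",
                  NA, NA, "m2",
                  NA, "m3"),
    sex = c("M", "F", "M", "F", "M",
            "M", "F", "F",
            "F", "M"),
    cohort = "offspring",
    stringsAsFactors = FALSE)
  exm <- data.frame(
    individual_id = ind$individual_id,
    exam_index = 1L,
    age = c(52, 50, 25, 27, 23, 58, 55, 30, 49, 26),
    value = c(2.0, 1.5, 1.8, 2.2, 1.1, 3.0, 2.4, 2.9, 1.9, 1.3),
    on_lipid_meds = FALSE,
    stringsAsFactors = FALSE)
  qherit:::new_cohort(ind, exm)
}

# adjusted values equal to raw values (identity passthrough) for pair tests
tiny_adjusted <- function(cohort = tiny_cohort()) {
  data.frame(individual_id = cohort$exams$individual_id,
             value = cohort$exams$value,
             n_exams = 1L,
             cohort = "offspring",
             stringsAsFactors = FALSE)
}

# synthetic pair set straight from vectors, for solver-level tests
make_pairs <- function(x, y, w = rep(1, length(x)), kind = "OP",
                       family = seq_along(x)) {
  df <- data.frame(y_id = paste0("y", seq_along(x)),
                   x_id = paste0("x", seq_along(x)),
                   y = y, x = x, weight = w,
                   family_id = as.character(family),
                   stringsAsFactors = FALSE)
  qherit:::new_pairs(df, kind, length(x) - 2L, rep(1L, length(x)))
}
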