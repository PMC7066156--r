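#' @name pair_builders
#' @title Build weighted bivariate familial pair sets
#'
#' @description
#' From per-individual adjusted phenotype values and the pedigree, build the
#' weighted pair sets underlying the familial regressions:
#'
#' * `build_op_pairs()`: offspring-parent pairs. An offspring with both
#'   parents measured contributes an offspring-father and an offspring-mother
#'   pair each with weight 1/2; with a single measured parent, one pair with
#'   weight 1. Degrees of freedom are `sum(k_i) - 2` where `k_i` counts the
#'   offspring (with at least one measured parent) of family `i`.
#' * `build_midparent_pairs()`: one pair per offspring whose parents are both
#'   measured, against the mean of the two parental values, weight 1.
#' * `build_fullsib_pairs()`: all `k_i (k_i - 1)` ordered sib pairs per
#'   sibship (shared father and mother, both known), each weighted
#'   `1 / (k_i - 1)` so that every sibling contributes total weight 1 as the
#'   dependent member; `flat_weights = TRUE` instead gives every ordered pair
#'   weight 1. Degrees of freedom are `sum(k_i - 1)`.
#' * `build_spouse_pairs()`: one pair per parental couple with both members
#'   measured, de-duplicated across their children, weight 1.
#'
#' The `y` member of each pair (offspring, sib) is the one whose quantile
#' positions the pair on the quantile-regression grid.
#'
#' @param adjusted data frame from [adjust_phenotypes()] (columns
#'   `individual_id`, `value`).
#' @param cohort the `qh_cohort` providing the pedigree.
#' @param flat_weights full-sib pairs only: give each ordered pair weight 1
#'   instead of `1/(k_i - 1)`.
#' @return an object of class `qh_pairs`: a data frame with columns `y_id`,
#'   `x_id`, `y`, `x`, `weight`, `family_id` and attributes `kind`, `df`,
#'   `family_sizes`.
NULL

new_pairs <- function(df, kind, dof, family_sizes) {
  if (nrow(df) == 0L) stop("empty ", kind, " pair set")
  stopifnot(all(df$weight > 0), all(df$y_id != df$x_id))
  rownames(df) <- NULL
  structure(df, kind = kind, df = as.integer(dof),
            family_sizes = family_sizes,
            class = c("qh_pairs", "data.frame"))
}

# value lookup helper
adj_value <- function(adjusted, ids) {
  adjusted$value[match(ids, adjusted$individual_id)]
}

#' @rdname pair_builders
#' @export
build_op_pairs <- function(adjusted, cohort) {
  ind <- cohort$individuals
  off <- ind[ind$individual_id %in% adjusted$individual_id &
               !(is.na(ind$father_id) & is.na(ind$mother_id)), , drop = FALSE]
  yv <- adj_value(adjusted, off$individual_id)
  fv <- adj_value(adjusted, off$father_id)
  mv <- adj_value(adjusted, off$mother_id)
  both <- !is.na(fv) & !is.na(mv)
  fa_only <- !is.na(fv) & !both
  mo_only <- !is.na(mv) & !both
  fam <- ifelse(is.na(off$father_id), paste0("m:", off$mother_id),
                ifelse(is.na(off$mother_id), paste0("f:", off$father_id),
                       paste0(off$father_id, "+", off$mother_id)))
  rows <- list()
  take <- function(sel, x_id, x, w) {
    if (!any(sel)) return(NULL)
    data.frame(y_id = off$individual_id[sel], x_id = x_id[sel],
               y = yv[sel], x = x[sel], weight = w,
               family_id = fam[sel], stringsAsFactors = FALSE)
  }
  rows <- rbind(take(both, off$father_id, fv, 0.5),
                take(both, off$mother_id, mv, 0.5),
                take(fa_only, off$father_id, fv, 1.0),
                take(mo_only, off$mother_id, mv, 1.0))
  used <- both | fa_only | mo_only
  k <- table(fam[used])
  new_pairs(rows, "OP", sum(k) - 2L, as.integer(k))
}

#' @rdname pair_builders
#' @export
build_midparent_pairs <- function(adjusted, cohort) {
  ind <- cohort$individuals
  off <- ind[ind$individual_id %in% adjusted$individual_id &
               !is.na(ind$father_id) & !is.na(ind$mother_id), , drop = FALSE]
  yv <- adj_value(adjusted, off$individual_id)
  fv <- adj_value(adjusted, off$father_id)
  mv <- adj_value(adjusted, off$mother_id)
  both <- !is.na(fv) & !is.na(mv)
  off <- off[both, , drop = FALSE]
  fam <- paste0(off$father_id, "+", off$mother_id)
  rows <- data.frame(y_id = off$individual_id,
                     x_id = paste0("mid:", fam),
                     y = yv[both], x = (fv[both] + mv[both]) / 2,
                     weight = 1.0, family_id = fam,
                     stringsAsFactors = FALSE)
  k <- table(fam)
  new_pairs(rows, "MIDPARENT", sum(k) - 2L, as.integer(k))
}

#' @rdname pair_builders
#' @export
build_fullsib_pairs <- function(adjusted, cohort, flat_weights = FALSE) {
  ind <- cohort$individuals
  sib <- ind[ind$individual_id %in% adjusted$individual_id &
               !is.na(ind$father_id) & !is.na(ind$mother_id), , drop = FALSE]
  fam <- paste0(sib$father_id, "+", sib$mother_id)
  split_ids <- split(sib$individual_id, fam)
  split_ids <- split_ids[lengths(split_ids) >= 2L]
  if (!length(split_ids)) stop("empty FS pair set")
  k <- lengths(split_ids)
  rows <- lapply(names(split_ids), function(f) {
    ids <- split_ids[[f]]
    ki <- length(ids)
    g <- expand.grid(y_id = ids, x_id = ids, stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[g$y_id != g$x_id, , drop = FALSE]
    g$weight <- if (flat_weights) 1.0 else 1 / (ki - 1)
    g$family_id <- f
    g
  })
  rows <- do.call(rbind, rows)
  rows$y <- adj_value(adjusted, rows$y_id)
  rows$x <- adj_value(adjusted, rows$x_id)
  rows <- rows[c("y_id", "x_id", "y", "x", "weight", "family_id")]
  new_pairs(rows, "FS", sum(k - 1L), as.integer(k))
}

#' @rdname pair_builders
#' @export
build_spouse_pairs <- function(adjusted, cohort) {
  ind <- cohort$individuals
  cp <- ind[!is.na(ind$father_id) & !is.na(ind$mother_id),
            c("father_id", "mother_id")]
  cp <- unique(cp)
  fv <- adj_value(adjusted, cp$father_id)
  mv <- adj_value(adjusted, cp$mother_id)
  ok <- !is.na(fv) & !is.na(mv)
  cp <- cp[ok, , drop = FALSE]
  rows <- data.frame(y_id = cp$mother_id, x_id = cp$father_id,
                     y = mv[ok], x = fv[ok], weight = 1.0,
                     family_id = paste0(cp$father_id, "+", cp$mother_id),
                     stringsAsFactors = FALSE)
  new_pairs(rows, "SPOUSE", nrow(rows) - 2L, rep(1L, nrow(rows)))
}

#' Weighted Pearson correlation of a pair set
#'
#' Weights are treated as frequency weights.
#'
#' @param pairs a `qh_pairs` object.
#' @return correlation in `[-1, 1]`.
#' @export
weighted_correlation <- function(pairs) {
  if (nrow(pairs) < 3L) stop("need at least 3 pairs")
  w <- pairs$weight
  mx <- weighted.mean(pairs$x, w)
  my <- weighted.mean(pairs$y, w)
  vx <- sum(w * (pairs$x - mx)^2)
  vy <- sum(w * (pairs$y - my)^2)
  if (vx <= 0 || vy <= 0) stop("zero variance: correlation undefined")
  sum(w * (pairs$x - mx) * (pairs$y - my)) / sqrt(vx * vy)
}

#' @export
print.qh_pairs <- function(x, ...) {
  cat(sprintf("<qh_pairs> kind %s: %d pairs, total weight %.1f, df = %d\n",
              attr(x, "kind"), nrow(x), sum(x$weight), attr(x, "df")))
  invisible(x)
}
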