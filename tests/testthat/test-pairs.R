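test_that("offspring-parent pairs follow the half/half and single-parent weighting", {
  cohort <- tiny_cohort()
  adj <- tiny_adjusted(cohort)
  op <- build_op_pairs(adj, cohort)

  # c1a..c1c and c2a have both parents -> two pairs each, weight 1/2
  for (id in c("c1a", "c1b", "c1c", "c2a")) {
    rows <- op[op$y_id == id, ]
    expect_equal(nrow(rows), 2L)
    expect_equal(rows$weight, c(0.5, 0.5))
    expect_setequal(rows$x_id, c(cohort$individuals$father_id[
      cohort$individuals$individual_id == id],
      cohort$individuals$mother_id[
        cohort$individuals$individual_id == id]))
  }
  # c3a has only a mother -> one pair, weight 1
  rows <- op[op$y_id == "c3a", ]
  expect_equal(nrow(rows), 1L)
  expect_equal(rows$weight, 1.0)
  expect_equal(rows$x_id, "m3")

  # total weight = number of offspring with >= 1 measured parent
  expect_equal(sum(op$weight), 5)
  # df = sum(k_i) - 2 over the three family sets (3 + 1 + 1 offspring)
  expect_equal(attr(op, "df"), 5L - 2L)
})

test_that("midparent pairs average the two parents and need both", {
  cohort <- tiny_cohort()
  adj <- tiny_adjusted(cohort)
  mp <- build_midparent_pairs(adj, cohort)
  expect_equal(sort(mp$y_id), c("c1a", "c1b", "c1c", "c2a"))  # c3a excluded
  expect_equal(mp$x[mp$y_id == "c1a"], (2.0 + 1.5) / 2)
  expect_equal(mp$x[mp$y_id == "c2a"], (3.0 + 2.4) / 2)
  expect_true(all(mp$weight == 1))
  # identical parents -> midparent equals either parent
  adj2 <- adj
  adj2$value[adj2$individual_id == "m2"] <- 3.0
  mp2 <- build_midparent_pairs(adj2, cohort)
  expect_equal(mp2$x[mp2$y_id == "c2a"], 3.0)
})

test_that("full-sib pairs enumerate all ordered pairs with per-sibling weight 1", {
  cohort <- tiny_cohort()
  adj <- tiny_adjusted(cohort)
  fs <- build_fullsib_pairs(adj, cohort)
  # only the size-3 sibship qualifies: 3 * 2 = 6 ordered pairs
  expect_equal(nrow(fs), 6L)
  expect_true(all(fs$weight == 0.5))
  yw <- tapply(fs$weight, fs$y_id, sum)
  expect_true(all(abs(yw - 1) < 1e-12))
  expect_equal(attr(fs, "df"), 2L)

  # a sibship of 4: 12 pairs of weight 1/3, y-weight sums to 1
  ind <- data.frame(individual_id = c("f", "m", paste0("c", 1:4)),
                    father_id = c(NA, NA, rep("f", 4)),
                    mother_id = c(NA, NA, rep("m", 4)),
                    sex = c("M", "F", rep("M", 4)), cohort = "offspring")
  exm <- data.frame(individual_id = ind$individual_id, exam_index = 1L,
                    age = 30, value = rnorm(6) + 2, on_lipid_meds = FALSE)
  big <- qherit:::new_cohort(ind, exm)
  adj4 <- data.frame(individual_id = ind$individual_id, value = exm$value)
  fs4 <- build_fullsib_pairs(adj4, big)
  expect_equal(nrow(fs4), 12L)
  expect_true(all(abs(fs4$weight - 1 / 3) < 1e-12))
  expect_true(all(abs(tapply(fs4$weight, fs4$y_id, sum) - 1) < 1e-12))
  expect_equal(attr(fs4, "df"), 3L)
  # flat-weight variant
  fs4f <- build_fullsib_pairs(adj4, big, flat_weights = TRUE)
  expect_true(all(fs4f$weight == 1))
})

test_that("spouse pairs are de-duplicated parental couples", {
  cohort <- tiny_cohort()
  adj <- tiny_adjusted(cohort)
  sp <- build_spouse_pairs(adj, cohort)
  # family 1 has 3 children but exactly one spouse pair; m3 is unmarried
  expect_equal(nrow(sp), 2L)
  expect_setequal(sp$family_id, c("f1+m1", "f2+m2"))
  expect_true(all(sp$weight == 1))
})

test_that("pair sets are invariant to input row order", {
  cohort <- tiny_cohort()
  adj <- tiny_adjusted(cohort)
  set.seed(5)
  cohort2 <- cohort
  cohort2$individuals <- cohort$individuals[sample(nrow(cohort$individuals)), ]
  adj2 <- adj[sample(nrow(adj)), ]
  for (builder in list(build_op_pairs, build_midparent_pairs,
                       build_fullsib_pairs, build_spouse_pairs)) {
    a <- builder(adj, cohort)
    b <- builder(adj2, cohort2)
    key <- function(p) {
      o <- order(p$y_id, p$x_id)
      list(p$y_id[o], p$x_id[o], p$y[o], p$x[o], p$weight[o])
    }
    expect_equal(key(a), key(b))
    expect_equal(attr(a, "df"), attr(b, "df"))
  }
})

test_that("weighted correlation: exact lines, frequency weights, MC recovery", {
  p <- make_pairs(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  expect_equal(weighted_correlation(p), 1.0)
  p <- make_pairs(x = c(1, 2, 3, 4), y = -c(1, 2, 3, 4))
  expect_equal(weighted_correlation(p), -1.0)
  expect_error(weighted_correlation(make_pairs(c(1, 1, 1), c(1, 2, 3))),
               "variance")

  # duplicating a pair is the same as doubling its weight
  x <- c(1, 2, 3, 5); y <- c(2, 1, 4, 3)
  dup <- make_pairs(c(x, 2), c(y, 1))
  wt <- make_pairs(x, y, w = c(1, 2, 1, 1))
  expect_equal(weighted_correlation(dup), weighted_correlation(wt))

  set.seed(99)
  n <- 1e5
  rho <- 0.31
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  p <- make_pairs(z1, z2)
  expect_lt(abs(weighted_correlation(p) - rho), 0.01)
})
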