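test_that("descriptor filtering drops missing, constant and collinear columns", {
  set.seed(42)
  x <- rnorm(30)
  mat <- cbind(d1 = x,
               d2 = x,                              # exact duplicate
               d3 = rep(2, 30),                     # constant
               d4 = rnorm(30),
               d5 = c(NA, rnorm(29)))               # missing value
  tab <- descriptor_table(mat)
  out <- filter_descriptors(tab)
  expect_setequal(out$report$dropped_missing, "d5")
  expect_setequal(out$report$dropped_low_variance, "d3")
  expect_equal(nrow(out$report$dropped_intercorrelated), 1)
  expect_setequal(out$report$surviving, c("d1", "d4"))
  # partition property: surviving plus dropped reconstruct the pool
  expect_setequal(c(out$report$surviving, out$report$dropped_missing,
                    out$report$dropped_low_variance,
                    out$report$dropped_intercorrelated$dropped),
                  colnames(mat))
})

test_that("the intercorrelated survivor is the one closer to the response", {
  set.seed(7)
  x <- rnorm(60)
  d2 <- x + rnorm(60, 0, 0.05)
  y <- d2 + rnorm(60, 0, 0.3)        # response generated from d2
  mat <- cbind(d1 = x, d2 = d2, d3 = rnorm(60), d4 = rnorm(60),
               d5 = rnorm(60))
  stopifnot(cor(x, d2)^2 > 0.95)
  # decide the expected survivor from the raw correlations
  expected <- if (abs(cor(d2, y)) > abs(cor(x, y))) "d2" else "d1"
  out <- filter_descriptors(descriptor_table(mat, y))
  expect_true(expected %in% out$report$surviving)
  expect_false(setdiff(c("d1", "d2"), expected) %in% out$report$surviving)
})

test_that("filtering an already-filtered table removes nothing", {
  tab <- generate_dataset(synthetic_spec(n_samples = 80, seed = 3))$table
  once <- filter_descriptors(tab)
  twice <- filter_descriptors(once$table)
  expect_equal(twice$report$surviving, once$report$surviving)
  expect_equal(nrow(twice$report$dropped_intercorrelated), 0)
})

test_that("autoscaling matches hand-computed values and inverts exactly", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  tab <- descriptor_table(cbind(a = x, b = 1:8))
  params <- fit_normalization(tab)
  scaled <- apply_normalization(tab, params)
  # hand arithmetic: mean 5, sample sd sqrt(32/7)
  expect_equal(scaled$values[, "a"], (x - 5) / sqrt(32 / 7),
               ignore_attr = TRUE)
  expect_equal(apply_normalization(descriptor_table(cbind(a = 1:3)),
                                   fit_normalization(
                                     descriptor_table(cbind(a = 1:3))))$
                 values[, "a"],
               c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(scaled$values), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(scaled$values, 2, sd), c(a = 1, b = 1),
               tolerance = 1e-10)
  back <- invert_normalization(scaled, params)
  expect_equal(back$values, tab$values, tolerance = 1e-10)
  expect_error(apply_normalization(descriptor_table(cbind(zz = 1:8)),
                                   params), "absent")
})

test_that("Kennard-Stone selection follows the max-min design", {
  # 1-D worked instance: seed pair {0,10}, then 4, then 2
  tab <- descriptor_table(cbind(x = c(0, 1, 2, 4, 10)))
  part <- kennard_stone_split(tab, train_fraction = 0.8)
  expect_equal(part$selection_order, c("s1", "s5", "s4", "s3"))
  expect_equal(part$test_ids, "s2")

  # two points, full training fraction
  pair <- descriptor_table(cbind(x = c(0, 1)))
  part2 <- kennard_stone_split(pair, train_fraction = 1.0)
  expect_setequal(part2$train_ids, c("s1", "s2"))
  expect_length(part2$test_ids, 0)

  # deterministic: identical inputs give identical partitions
  tab3 <- make_table(n = 25, p = 4, seed = 9)
  expect_identical(kennard_stone_split(tab3, 0.8),
                   kennard_stone_split(tab3, 0.8))
})

test_that("train-set sizes follow round-half-up of the fraction", {
  sizes <- vapply(c(63, 10, 11, 5), function(n) {
    tab <- make_table(n = n, p = 3, seed = n)
    length(kennard_stone_split(tab, 0.8)$train_ids)
  }, integer(1))
  expect_equal(sizes, c(50L, 8L, 9L, 4L))
})

test_that("chemical-space diagnostics match direct geometry", {
  # collinear points: one principal component carries all variance
  line <- descriptor_table(cbind(a = 1:6, b = 2 * (1:6), c = -(1:6)))
  st <- chemical_space_stats(line)
  expect_equal(st$pc_variance_explained[1], 1, tolerance = 1e-12)

  # unit-square corners: nearest neighbor at 1, diameter sqrt(2)
  sq <- descriptor_table(cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)))
  st2 <- chemical_space_stats(sq, n_components = 2)
  expect_equal(st2$nn_mean, 1)
  expect_equal(st2$max_distance, sqrt(2))

  # random table against an all-pairs brute force
  tab <- make_table(n = 20, p = 5, seed = 4)
  st3 <- chemical_space_stats(tab)
  d <- as.matrix(dist(tab$values))
  nn <- vapply(1:20, function(i) min(d[i, -i]), numeric(1))
  expect_equal(st3$nn_mean, mean(nn), tolerance = 1e-12)
  expect_equal(st3$nn_sd, sd(nn), tolerance = 1e-12)
  expect_equal(st3$max_distance, max(d), tolerance = 1e-12)
  expect_warning(chemical_space_stats(sq, n_components = 5), "truncating")
})

test_that("similarity check reports interval overlaps", {
  tab <- make_table(n = 20, p = 3, seed = 8)
  same <- similarity_check(tab, tab)
  expect_true(all(same$overlap == 1))

  a <- descriptor_table(cbind(x = 1:5), response = 1:5)
  b <- descriptor_table(cbind(x = 11:15), response = 11:15)
  expect_true(all(similarity_check(a, b)$overlap == 0))

  # seeded split: overlap equals direct interval intersection arithmetic
  part <- kennard_stone_split(tab, 0.7)
  tr <- subset_table(tab, ids = part$train_ids)
  te <- subset_table(tab, ids = part$test_ids)
  sim <- similarity_check(tr, te)
  for (nm in descriptor_names(tab)) {
    lo <- max(min(tr$values[, nm]), min(te$values[, nm]))
    hi <- min(max(tr$values[, nm]), max(te$values[, nm]))
    span <- diff(range(c(tr$values[, nm], te$values[, nm])))
    expect_equal(sim$overlap[sim$feature == nm], max(0, hi - lo) / span)
  }
})
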