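make_informative_table <- function(n = 60, noise_cols = 5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * (noise_cols + 1)), n, noise_cols + 1,
              dimnames = list(sprintf("s%02d", 1:n),
                              c("signal", paste0("noise", 1:noise_cols))))
  descriptor_table(x, 2 * x[, "signal"] + rnorm(n, 0, 0.1))
}

test_that("the GA finds the informative descriptor among pure noise", {
  tab <- make_informative_table(seed = 21)
  # exhaustive singleton check confirms 'signal' is the fittest singleton
  singles <- vapply(descriptor_names(tab), function(nm)
    cross_validate(tab, nm, default_fitness_config(), folds = 5,
                   seed = substream_seed(5, "ga_fitness"))$rmse,
    numeric(1))
  expect_equal(names(which.min(singles)), "signal")

  sel <- ga_subset_search(tab, population = 12, generations = 6,
                          subset_size_range = c(1, 3), seed = 5,
                          folds = 5)
  expect_true("signal" %in% sel$chosen)
  # best-so-far trace never worsens under minimization
  expect_true(all(diff(sel$fitness_trace$best) <= 1e-12))
})

test_that("GA degenerate runs and argument validation behave", {
  tab <- make_informative_table(n = 40, noise_cols = 2, seed = 2)
  g0 <- ga_subset_search(tab, population = 6, generations = 0,
                         subset_size_range = c(1, 2), seed = 3, folds = 3)
  expect_equal(nrow(g0$fitness_trace), 1)
  expect_gte(length(g0$chosen), 1)
  expect_error(ga_subset_search(tab, population = 1), "population")

  # same seed, same result
  a <- ga_subset_search(tab, population = 6, generations = 3,
                        subset_size_range = c(1, 2), seed = 9, folds = 3)
  b <- ga_subset_search(tab, population = 6, generations = 3,
                        subset_size_range = c(1, 2), seed = 9, folds = 3)
  expect_identical(a$chosen, b$chosen)
  expect_identical(a$fitness, b$fitness)
})

test_that("RFE discards the least-contributing descriptor first", {
  set.seed(31)
  n <- 60
  x <- cbind(inf1 = rnorm(n), inf2 = rnorm(n), noise = rnorm(n))
  rownames(x) <- sprintf("s%02d", 1:n)
  tab <- descriptor_table(x, x[, "inf1"] + x[, "inf2"] + rnorm(n, 0, 0.1))

  # direct leave-one-out evaluation: dropping 'noise' must be least harmful
  fit_seed <- substream_seed(4, "rfe_fitness")
  loo <- vapply(colnames(x), function(nm)
    cross_validate(tab, setdiff(colnames(x), nm),
                   default_fitness_config(), folds = 5,
                   seed = fit_seed)$rmse, numeric(1))
  expect_equal(names(which.min(loo)), "noise")

  sel <- rfe(tab, colnames(x), floor_size = 2, seed = 4, folds = 5)
  expect_equal(sel$elimination_order$name[1], "noise")
  expect_setequal(sel$chosen, c("inf1", "inf2"))
  # start size floor+1 means exactly one elimination round
  expect_equal(nrow(sel$elimination_order), 1)
})

test_that("RFE respects identity and reproducibility contracts", {
  tab <- make_informative_table(n = 40, noise_cols = 3, seed = 8)
  nms <- descriptor_names(tab)
  ident <- rfe(tab, nms, floor_size = length(nms), seed = 1, folds = 3)
  expect_equal(ident$chosen, nms)
  expect_equal(nrow(ident$elimination_order), 0)
  expect_error(rfe(tab, nms, floor_size = 0), "floor_size")

  # pure-noise response still eliminates deterministically under a seed
  noise_tab <- descriptor_table(tab$values, rnorm(40))
  r1 <- rfe(noise_tab, nms, floor_size = 2, seed = 7, folds = 3)
  r2 <- rfe(noise_tab, nms, floor_size = 2, seed = 7, folds = 3)
  expect_identical(r1$elimination_order, r2$elimination_order)
})

test_that("GA then RFE recovers the generative descriptors on synthetic data", {
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    ds <- generate_dataset(synthetic_spec(seed = 300 + i))
    filt <- filter_descriptors(ds$table)
    tab <- apply_normalization(filt$table, fit_normalization(filt$table))
    ga <- ga_subset_search(tab, population = 16, generations = 8,
                           subset_size_range = c(2, 7), seed = 300 + i,
                           folds = 5)
    sel <- rfe(tab, ga$chosen, floor_size = min(3, length(ga$chosen)),
               seed = 300 + i, folds = 5)
    # the volume signal may legitimately survive as its collinear MW proxy
    size_ok <- any(c("Vm", "MW") %in% sel$chosen)
    hits <- hits + (all(c("HBD", "nAr") %in% sel$chosen) && size_ok &&
                      length(sel$chosen) == 3)
  }
  expect_gte(hits / n_rep, 0.8)
})
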