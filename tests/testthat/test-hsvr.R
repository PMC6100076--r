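# Heterogeneous two-regime table: members trained on partial subsets act
# as local models; the second level must combine them.
make_regime_table <- function(n = 60, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("s%02d", 1:n), paste0("d", 1:4)))
  y <- ifelse(x[, 1] > 0, sin(2 * x[, 2]), 0.8 * x[, 3]) +
    rnorm(n, 0, 0.05)
  descriptor_table(x, y)
}

test_that("candidate pools carry one grid-searched model per subset", {
  tab <- make_regime_table(seed = 2)
  subsets <- list(c("d1", "d2"), c("d1", "d3"), c("d2", "d3", "d4"))
  pool <- build_candidate_pool(tab, subsets, grid = tiny_grid(),
                               folds = 5, seed = 1)
  expect_length(pool, 3)
  expect_equal(lapply(pool, function(m) m$descriptor_subset), subsets)
  for (m in pool) {
    expect_s3_class(m, "svr_model")
    expect_false(is.null(m$cv$q2cv))
    expect_false(is.null(m$train_metrics$r2))
  }
  expect_message(build_candidate_pool(tab, subsets[c(1, 1)],
                                      grid = tiny_grid(), folds = 5,
                                      seed = 1), "duplicate")
})

test_that("the hierarchical prediction is the meta model over member outputs", {
  tab <- make_regime_table(seed = 3)
  pool <- build_candidate_pool(tab, list(c("d1", "d2"), c("d1", "d3")),
                               grid = tiny_grid(), folds = 5, seed = 2)
  model <- fit_meta(pool, tab, grid = tiny_grid(), folds = 5, seed = 2)

  pm <- vapply(model$members, function(m) predict_svr(m, tab),
               numeric(nrow(tab$values)))
  colnames(pm) <- paste0("member", seq_along(model$members))
  expect_equal(predict_hsvr(model, tab),
               predict_svr(model$meta, descriptor_table(pm)))

  # member-order symmetry: swapped members with swapped meta inputs
  swapped <- fit_meta(pool[c(2, 1)], tab, grid = tiny_grid(), folds = 5,
                      seed = 2)
  expect_equal(unname(predict_hsvr(swapped, tab)),
               unname(predict_hsvr(model, tab)), tolerance = 1e-10)

  # single row agrees with its batch element
  one <- subset_table(tab, ids = "s05")
  expect_equal(predict_hsvr(model, one), predict_hsvr(model, tab)["s05"])

  # a missing descriptor names the offending member
  crippled <- descriptor_table(tab$values[, c("d1", "d2")], tab$response)
  expect_error(predict_hsvr(model, crippled), "member 2")
})

test_that("a perfect member protects the ensemble from a noise member", {
  tab <- make_regime_table(seed = 4)
  good <- train_svr(tab, c("d1", "d2", "d3"),
                    svr_config("epsilon", C = 64, gamma = 0.3,
                               epsilon = 0.01))
  noise <- train_svr(tab, "d4", svr_config("epsilon", C = 1, gamma = 1))
  model <- fit_meta(list(good, noise), tab, grid = tiny_grid(),
                    folds = 5, seed = 3)
  noise_cv <- cross_validate(tab, "d4", noise$config, folds = 5,
                             seed = substream_seed(3, "meta"))
  expect_lte(model$cv$rmse, noise_cv$rmse)
})

test_that("ensemble growth honors Occam ordering and fallback flags", {
  tab <- make_regime_table(seed = 5)
  pool <- build_candidate_pool(tab,
                               list(c("d1", "d2"), c("d1", "d3"),
                                    c("d2", "d3")),
                               grid = tiny_grid(), folds = 5, seed = 4)
  # permissive thresholds: the first passing size class must be 2
  easy <- utils::modifyList(default_criteria(),
                            list(coef_min = -10, rm2_min = -10,
                                 rm2_avg_min = -10, rm2_delta_max = 10,
                                 r2_q2cv_gap = 10, origin_rel_gap = 10,
                                 k_low = -10, k_high = 10,
                                 origin_abs_gap = 10))
  sel <- grow_and_select(tab, pool, criteria = easy, grid = tiny_grid(),
                         folds = 5, seed = 4)
  expect_true(sel$criteria_met)
  expect_length(sel$members, 2)

  # unsatisfiable thresholds: best-objective fallback, flagged
  impossible <- utils::modifyList(easy, list(rm2_delta_max = -1))
  fb <- grow_and_select(tab, pool, criteria = impossible,
                        grid = tiny_grid(), folds = 5, seed = 4)
  expect_false(fb$criteria_met)
  expect_s3_class(fb, "hsvr_model")
  expect_error(grow_and_select(tab, pool, max_members = 1), "max_members")
  expect_error(grow_and_select(tab, pool[1]), "pool")
})

test_that("hierarchical predictions interpolate member outputs mostly", {
  ds <- generate_dataset(synthetic_spec(n_samples = 120, seed = 6))
  filt <- filter_descriptors(ds$table)
  norm <- fit_normalization(filt$table)
  tab <- apply_normalization(filt$table, norm)
  part <- kennard_stone_split(tab, 0.8)
  train <- subset_table(tab, ids = part$train_ids)
  test <- subset_table(tab, ids = part$test_ids)
  pool <- build_candidate_pool(train,
                               list(c("HBD", "nAr", "Vm"),
                                    c("HBD", "nAr", "Vm", "SA", "PSA")),
                               grid = tiny_grid(), folds = 5, seed = 6)
  model <- fit_meta(pool, train, grid = tiny_grid(), folds = 5, seed = 6)
  hp <- predict_hsvr(model, test)
  pm <- vapply(model$members, function(m) predict_svr(m, test),
               numeric(length(hp)))
  inside <- hp >= apply(pm, 1, min) - 1e-9 & hp <= apply(pm, 1, max) + 1e-9
  expect_gte(mean(inside), 0.8)
})

test_that("the ensemble report mirrors member and ensemble statistics", {
  tab <- make_regime_table(seed = 7)
  pool <- build_candidate_pool(tab, list(c("d1", "d2"), c("d3", "d4")),
                               grid = tiny_grid(), folds = 5, seed = 7)
  model <- fit_meta(pool, tab, grid = tiny_grid(), folds = 5, seed = 7)
  rep_ <- ensemble_report(model, tab, tab)
  expect_equal(rep_$member_sizes, c(2L, 2L))
  expect_setequal(rep_$descriptor_union, paste0("d", 1:4))
  expect_equal(colnames(rep_$training), c("SVR_A", "SVR_B", "HSVR"))
  expect_equal(rownames(rep_$test),
               c("q2", "qF1", "qF2", "qF3", "ccc", "delta_max", "mae",
                 "s", "rmse"))
  # identical tables: the training r2 row must match a direct computation
  direct <- squared_correlation_coefficient(tab$response,
                                            predict_hsvr(model, tab))
  expect_equal(rep_$training["r2", "HSVR"], direct, tolerance = 1e-12)
})
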