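test_that("basic metrics reproduce direct arithmetic", {
  y <- c(1, 2, 3); yh <- c(1, 2, 4)
  rep_ <- basic_metrics(y, yh)
  expect_equal(rep_$residuals, c(0, 0, -1))
  expect_equal(rep_$mae, 1 / 3)
  expect_equal(rep_$rmse, 1 / sqrt(3))
  expect_equal(rep_$delta_max, 1)

  perfect <- basic_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$delta_max, 0)
})

test_that("degenerate denominators yield NA sentinels, never zero", {
  expect_true(is.na(squared_correlation_coefficient(rep(2, 5), rnorm(5))))
  os <- origin_stats(rep(0, 4), c(1, 2, 3, 4))
  expect_true(is.na(os$k))
  v <- check_criteria(list(r2 = NA_real_), NULL)
  expect_true(all(v$training %in% c("not_applicable", "pass", "fail")))
  expect_equal(v$training[v$criterion == "cv_gap_lt_max"], "not_applicable")
})

test_that("through-origin statistics behave under forced slopes and swaps", {
  y <- c(1, 2, 3, 4)
  os <- origin_stats(y, y)
  expect_equal(os$k, 1); expect_equal(os$ro2, 1)
  expect_equal(origin_stats(y, 2 * y)$k, 2)

  set.seed(11)
  a <- rnorm(8); b <- a + rnorm(8, 0, 0.4)
  fwd <- origin_stats(a, b); swp <- origin_stats(b, a)
  expect_equal(fwd$ro2, swp$ro2_prime)
  expect_equal(fwd$ro2_prime, swp$ro2)
  expect_equal(fwd$k, swp$k_prime)
})

test_that("rm2 family keeps its multiplier bounds in both variants", {
  for (variant in c("sqrt", "nosqrt")) {
    rm_ <- roy_metrics(0.9, 0.7, 0.85, variant)
    expect_lte(rm_$rm2, 0.9)
    expect_lte(rm_$rm2_prime, 0.9)
    expect_equal(rm_$rm2_avg, (rm_$rm2 + rm_$rm2_prime) / 2)
    expect_equal(rm_$rm2_delta, abs(rm_$rm2 - rm_$rm2_prime))
  }
  expect_equal(roy_metrics(0.8, 0.8, 0.8)$rm2_delta, 0)
  expect_equal(roy_metrics(0.9, 0.7, 0.85, "nosqrt")$rm2,
               0.9 * (1 - 0.2))
  expect_equal(roy_metrics(0.9, 0.7, 0.85, "sqrt")$rm2,
               0.9 * (1 - sqrt(0.2)))
})

test_that("external coefficients hit their fixed points", {
  ytr <- rnorm(20)
  y <- c(0.2, 0.5, 1.1, -0.3)
  ext <- external_metrics(y, y, ytr)
  expect_equal(ext$qF1, 1); expect_equal(ext$qF2, 1)
  expect_equal(ext$qF3, 1); expect_equal(ext$ccc, 1)

  # constant predictions at the external mean zero out qF2
  ext0 <- external_metrics(y, rep(mean(y), 4), ytr)
  expect_equal(ext0$qF2, 0)
})

test_that("concordance is 1 only at exact agreement and drops under scaling", {
  set.seed(3)
  y <- rnorm(15); yh <- y + rnorm(15, 0, 0.2)
  ytr <- rnorm(20)
  ccc_noisy <- external_metrics(y, yh, ytr)$ccc
  expect_lt(ccc_noisy, 1)
  ccc_exact <- external_metrics(y, y, ytr)$ccc
  expect_equal(ccc_exact, 1)
  for (c_ in c(0.5, 0.9, 1.3))
    expect_lt(external_metrics(y, c_ * y, ytr)$ccc, 1)
})

test_that("the criteria verdict is monotone in each coefficient", {
  base_tr <- list(r2 = 0.85, q2cv = 0.80, ro2 = 0.82, ro2_prime = 0.80,
                  k = 1.0, rm2 = 0.70, rm2_prime = 0.68, rm2_avg = 0.69,
                  rm2_delta = 0.02)
  base_te <- list(q2 = 0.75, qF1 = 0.74, qF2 = 0.73, qF3 = 0.72,
                  ccc = 0.88, ro2 = 0.72, ro2_prime = 0.70, k = 1.0,
                  rm2 = 0.68, rm2_prime = 0.67, rm2_avg = 0.675,
                  rm2_delta = 0.01)
  expect_equal(attr(check_criteria(base_tr, base_te), "overall"), "pass")
  for (f in c("r2", "q2cv", "rm2", "rm2_avg")) {
    up <- base_tr; up[[f]] <- min(1, up[[f]] + 0.05)
    # improving a coefficient can perturb gap criteria, but r2 increases
    # paired with matching ro2 increases must never flip pass to fail
    if (f == "r2") { up$ro2 <- up$ro2 + 0.05; up$ro2_prime <- up$ro2_prime + 0.05
                     up$q2cv <- up$q2cv + 0.05 }
    expect_equal(attr(check_criteria(up, base_te), "overall"), "pass",
                 info = f)
  }
  worse <- base_tr; worse$k <- 1.2
  v <- check_criteria(worse, base_te)
  expect_equal(v$training[v$criterion == "origin_r2_and_slope"], "fail")
  expect_equal(attr(v, "overall"), "fail")
})

test_that("Y-scrambling with the identity permutation recovers the true r2", {
  tab <- make_table(n = 30, seed = 6)
  cfg <- svr_config("epsilon", C = 8, gamma = 0.3, epsilon = 0.05)
  m <- train_svr(tab, descriptor_names(tab), cfg)
  r2 <- squared_correlation_coefficient(tab$response,
                                        m$training_predictions)
  sc <- y_scramble(tab, descriptor_names(tab), cfg,
                   permutations = list(seq_len(30)))
  expect_equal(sc$rs2, r2, tolerance = 1e-12)
  expect_equal(sc$rs2_mean, mean(sc$rs2))
})

test_that("scrambling a strong signal collapses the coefficient", {
  tab <- make_table(n = 60, seed = 12)        # smooth signal, low noise
  cfg <- svr_config("epsilon", C = 32, gamma = 0.2, epsilon = 0.01)
  m <- train_svr(tab, descriptor_names(tab), cfg)
  r2 <- squared_correlation_coefficient(tab$response,
                                        m$training_predictions)
  sc <- y_scramble(tab, descriptor_names(tab), cfg, scrambles = 10,
                   seed = 5)
  expect_gt(r2, 0.8)
  expect_lt(sc$rs2_mean, r2 - 0.4)
})

test_that("residual analysis exposes constant bias", {
  set.seed(9)
  yh <- rnorm(12)
  ra <- residual_analysis(yh + 0.3, yh)
  expect_equal(ra$mean_residual, 0.3)
  expect_equal(ra$table$residual, rep(0.3, 12))
  expect_equal(residual_analysis(yh, yh)$table$residual, rep(0, 12))
})
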