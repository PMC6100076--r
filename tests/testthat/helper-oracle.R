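# Independent brute-force oracles, written from the defining formulas with
# explicit loops and stats::lm fits, never sharing code with the package.

oracle_metrics <- function(y, yhat, ytr = NULL) {
  n <- length(y)
  ss <- function(v) { s <- 0; for (vi in v) s <- s + vi^2; s }
  res <- y - yhat
  out <- list(
    r2 = 1 - ss(res) / ss(y - mean(y)),
    rmse = sqrt(ss(res) / n),
    mae = sum(abs(res)) / n,
    s = sqrt(ss(res - mean(res)) / (n - 1)),
    delta_max = max(abs(res)),
    mean_residual = mean(res))

  # through-origin fits via lm with a forced zero intercept
  fit1 <- stats::lm(yhat ~ 0 + y)      # predicted on observed
  fit2 <- stats::lm(y ~ 0 + yhat)      # observed on predicted
  out$k <- unname(stats::coef(fit1))
  out$k_prime <- unname(stats::coef(fit2))
  out$ro2 <- 1 - ss(stats::resid(fit1)) / ss(yhat - mean(yhat))
  out$ro2_prime <- 1 - ss(stats::resid(fit2)) / ss(y - mean(y))

  out$rm2 <- out$r2 * (1 - sqrt(abs(out$r2 - out$ro2)))
  out$rm2_prime <- out$r2 * (1 - sqrt(abs(out$r2 - out$ro2_prime)))
  out$rm2_avg <- (out$rm2 + out$rm2_prime) / 2
  out$rm2_delta <- abs(out$rm2 - out$rm2_prime)

  if (!is.null(ytr)) {
    press <- ss(res)
    out$qF1 <- 1 - press / ss(y - mean(ytr))
    out$qF2 <- 1 - press / ss(y - mean(y))
    out$qF3 <- 1 - (press / n) / (ss(ytr - mean(ytr)) / length(ytr))
    num <- 0
    for (i in seq_len(n))
      num <- num + (y[i] - mean(y)) * (yhat[i] - mean(yhat))
    out$ccc <- 2 * num /
      (ss(y - mean(y)) + ss(yhat - mean(yhat)) +
         n * (mean(y) - mean(yhat))^2)
  }
  out
}

# Max-min greedy reference for the Kennard-Stone design: at each step,
# recompute every remaining candidate's minimum distance to the selected
# set by explicit loops and confirm the pick attains the maximum.
oracle_ks_is_greedy <- function(values, order_ids) {
  ids <- rownames(values)
  ord <- match(order_ids, ids)
  d <- as.matrix(stats::dist(values))
  # the seed pair must attain the global maximum distance
  if (abs(d[ord[1], ord[2]] - max(d)) > 1e-12) return(FALSE)
  for (step in seq(3, length(ord))) {
    sel <- ord[seq_len(step - 1)]
    remaining <- setdiff(seq_len(nrow(values)), sel)
    mind <- vapply(remaining, function(i) min(d[i, sel]), numeric(1))
    picked <- ord[step]
    if (min(d[picked, sel]) < max(mind) - 1e-12) return(FALSE)
  }
  TRUE
}

# Small normalized random regression table for engine tests.
make_table <- function(n = 40, p = 3, seed = 1, noisy = FALSE) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("s%02d", 1:n), paste0("d", 1:p)))
  y <- if (noisy) rnorm(n) else sin(x[, 1]) + 0.5 * x[, 2] + rnorm(n, 0, 0.05)
  descriptor_table(x, y)
}

tiny_grid <- function() grid_spec(C = 2^c(0, 4), gamma = 2^c(-3, -1),
                                  epsilon = 0.1, modes = "epsilon")

# Independent expansion of a grid_spec into svr_config objects.
expand_grid_spec_for_test <- function(g) {
  out <- list()
  for (mode in g$modes) {
    tube <- if (mode == "epsilon") g$epsilon else g$nu
    for (t in tube) for (gam in g$gamma) for (C in g$C)
      out[[length(out) + 1L]] <- svr_config(mode, C = C, gamma = gam,
                                            epsilon = t, nu = t)
  }
  out
}
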