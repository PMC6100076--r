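#' SVR runtime configuration
#'
#' One point in the LIBSVM runtime-parameter space: regression mode
#' (epsilon-SVR or nu-SVR), cost C, RBF kernel width gamma, and the
#' mode-specific tube parameter (epsilon) or support-vector fraction (nu).
#'
#' @param mode "epsilon" or "nu".
#' @param C cost, > 0.
#' @param gamma RBF kernel width, > 0.
#' @param epsilon tube half-width, >= 0 (epsilon mode).
#' @param nu fraction in (0, 1] (nu mode).
#' @return an \code{svr_config}.
#' @export
svr_config <- function(mode = c("epsilon", "nu"), C = 1, gamma = 0.1,
                       epsilon = 0.1, nu = 0.5) {
  mode <- match.arg(mode)
  stopifnot(C > 0, gamma > 0)
  if (mode == "epsilon") stopifnot(epsilon >= 0) else
    stopifnot(nu > 0, nu <= 1)
  structure(list(mode = mode, C = C, gamma = gamma,
                 epsilon = if (mode == "epsilon") epsilon else NULL,
                 nu = if (mode == "nu") nu else NULL),
            class = "svr_config")
}

#' @export
print.svr_config <- function(x, ...) {
  cat("svr_config: ", x$mode, "-SVR  C=", format(x$C),
      "  gamma=", format(x$gamma),
      if (x$mode == "epsilon") paste0("  epsilon=", format(x$epsilon))
      else paste0("  nu=", format(x$nu)), "\n", sep = "")
  invisible(x)
}

# Mid-grid defaults used as the surrogate learner inside feature selection.
default_fitness_config <- function() svr_config("epsilon", C = 2^5,
                                                gamma = 2^-6, epsilon = 0.1)

#' Grid specification for SVR runtime-parameter search
#'
#' Defaults follow the conventional LIBSVM log-spaced grids:
#' C in 2^(-5..15) and gamma in 2^(-15..3), both in steps of 2^2, with
#' epsilon in \{0.001, 0.01, 0.1, 0.5\} and nu in \{0.25, 0.5, 0.75\}.
#'
#' @param C cost values.
#' @param gamma kernel width values.
#' @param epsilon epsilon values (epsilon mode).
#' @param nu nu values (nu mode).
#' @param modes modes to scan, subset of c("epsilon", "nu").
#' @return a \code{grid_spec}.
#' @export
grid_spec <- function(C = 2^seq(-5, 15, by = 2),
                      gamma = 2^seq(-15, 3, by = 2),
                      epsilon = c(0.001, 0.01, 0.1, 0.5),
                      nu = c(0.25, 0.5, 0.75),
                      modes = c("epsilon", "nu")) {
  modes <- match.arg(modes, several.ok = TRUE)
  stopifnot(length(C) > 0, length(gamma) > 0)
  if ("epsilon" %in% modes) stopifnot(length(epsilon) > 0)
  if ("nu" %in% modes) stopifnot(length(nu) > 0)
  structure(list(C = C, gamma = gamma, epsilon = epsilon, nu = nu,
                 modes = modes), class = "grid_spec")
}

# Expand a grid_spec into the full cross product of configs (modes scanned
# independently, per the systematic grid-search design).
expand_grid_spec <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  configs <- list()
  for (mode in grid$modes) {
    tube <- if (mode == "epsilon") grid$epsilon else grid$nu
    for (t in tube) for (g in grid$gamma) for (C in grid$C)
      configs[[length(configs) + 1L]] <-
        svr_config(mode, C = C, gamma = g, epsilon = t, nu = t)
  }
  configs
}

#' Train a single SVR member model
#'
#' Fits an RBF-kernel support vector regression (via the LIBSVM solver) of
#' the response on the named descriptor subset. Descriptors are assumed
#' already autoscaled; no further scaling is applied inside the solver, so
#' predictions are reproducible from the stored state alone.
#'
#' @param table training \code{descriptor_table} (normalized, with
#'   response).
#' @param subset character vector of descriptor names to use.
#' @param config an \code{svr_config}.
#' @param normalization optional \code{normalization_params} to carry in
#'   the model for prediction-time checks.
#' @return an \code{svr_model}: config, descriptor_subset, fit,
#'   training_ids, training_predictions, normalization.
#' @importFrom e1071 svm
#' @export
train_svr <- function(table, subset, config, normalization = NULL) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(config, "svr_config"))
  if (is.null(table$response)) stop("training table has no response")
  missing <- setdiff(subset, colnames(table$values))
  if (length(missing))
    stop("descriptors absent from table: ", paste(missing, collapse = ", "))
  x <- table$values[, subset, drop = FALSE]
  y <- table$response
  if (stats::sd(y) == 0) {
    # all points inside any tube: the solver has no support vectors, so
    # represent the degenerate fit explicitly as the constant
    warning("constant response: model will predict the constant")
    model <- structure(list(config = config, descriptor_subset = subset,
                            fit = NULL, constant = y[1],
                            training_ids = rownames(x),
                            normalization = normalization),
                       class = "svr_model")
    model$training_predictions <- predict_svr(model, table)
    return(model)
  }
  fit <- e1071::svm(x = x, y = y,
                    type = if (config$mode == "epsilon") "eps-regression"
                           else "nu-regression",
                    kernel = "radial", cost = config$C, gamma = config$gamma,
                    epsilon = if (config$mode == "epsilon") config$epsilon
                              else 0.1,
                    nu = if (config$mode == "nu") config$nu else 0.5,
                    scale = FALSE, fitted = TRUE)
  model <- structure(list(config = config, descriptor_subset = subset,
                          fit = fit, training_ids = rownames(x),
                          normalization = normalization),
                     class = "svr_model")
  model$training_predictions <- predict_svr(model, table)
  model
}

#' Predict with a single SVR model
#'
#' Rows are aligned to the model's descriptor subset by name, so column
#' order in the incoming table is irrelevant.
#'
#' @param model an \code{svr_model}.
#' @param table a \code{descriptor_table} containing the model's
#'   descriptors.
#' @return named numeric vector of predictions, one per row, in row order.
#' @export
predict_svr <- function(model, table) {
  stopifnot(inherits(model, "svr_model"),
            inherits(table, "descriptor_table"))
  missing <- setdiff(model$descriptor_subset, colnames(table$values))
  if (length(missing))
    stop("descriptors absent from table: ", paste(missing, collapse = ", "))
  x <- table$values[, model$descriptor_subset, drop = FALSE]
  p <- if (is.null(model$fit)) rep(model$constant, nrow(x))
       else as.numeric(stats::predict(model$fit, x))
  names(p) <- rownames(x)
  p
}

# Seeded fold assignment: shuffle then contiguous blocks; sizes differ by
# at most one; no stratification.
make_folds <- function(n, folds, seed) {
  if (folds > n) stop("more folds (", folds, ") than samples (", n, ")")
  idx <- with_substream(seed, "cv_folds", folds, sample.int(n))
  sizes <- rep(floor(n / folds), folds)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(idx, rep(seq_len(folds), times = sizes))
}

#' k-fold cross-validation of an SVR configuration
#'
#' Each sample is predicted exactly once out-of-fold; the cross-validated
#' squared correlation q2cv is computed on the pooled out-of-fold
#' predictions, and the pooled RMSE is returned as the grid-search
#' objective.
#'
#' @param table training \code{descriptor_table} with response.
#' @param subset descriptor names.
#' @param config an \code{svr_config}.
#' @param folds number of folds (default 10; folds = n gives
#'   leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @return list: q2cv, rmse, predictions (pooled out-of-fold, in row
#'   order), folds (assignment list).
#' @export
cross_validate <- function(table, subset, config, folds = 10, seed = 1L) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$response)) stop("training table has no response")
  n <- nrow(table$values)
  assignment <- make_folds(n, folds, seed)
  pred <- rep(NA_real_, n)
  for (fold in assignment) {
    tr <- subset_table(table, ids = rownames(table$values)[-fold])
    te <- subset_table(table, ids = rownames(table$values)[fold])
    m <- suppressWarnings(train_svr(tr, subset, config))
    pred[fold] <- predict_svr(m, te)
  }
  names(pred) <- rownames(table$values)
  y <- table$response
  list(q2cv = squared_correlation_coefficient(y, pred),
       rmse = sqrt(mean((y - pred)^2)),
       predictions = pred, folds = assignment)
}

#' Exhaustive grid search over SVR runtime parameters
#'
#' Every point of the expanded grid is evaluated by k-fold CV RMSE on the
#' training table; no early stopping. Ties keep first-occurrence order.
#'
#' @param table training \code{descriptor_table} with response.
#' @param subset descriptor names.
#' @param grid a \code{grid_spec}.
#' @param folds CV folds.
#' @param seed integer seed (same folds reused for every grid point).
#' @return data.frame ranked ascending by objective, with list-column
#'   \code{config} and columns mode, C, gamma, tube, objective, q2cv.
#' @export
grid_search <- function(table, subset, grid, folds = 10, seed = 1L) {
  configs <- expand_grid_spec(grid)
  rows <- vector("list", length(configs))
  for (i in seq_along(configs)) {
    cfg <- configs[[i]]
    cv <- cross_validate(table, subset, cfg, folds = folds, seed = seed)
    rows[[i]] <- data.frame(mode = cfg$mode, C = cfg$C, gamma = cfg$gamma,
                            tube = if (cfg$mode == "epsilon") cfg$epsilon
                                   else cfg$nu,
                            objective = cv$rmse, q2cv = cv$q2cv,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$config <- configs
  ord <- order(res$objective)      # stable: ties keep first occurrence
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}
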