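# Hierarchical SVR: an ensemble of member SVR models, each a "local" model
# on its own descriptor subset, whose predictions feed a second-level SVR
# that acts as the "global" regressor.

#' Build a candidate pool of member SVR models
#'
#' For each supplied descriptor subset, grid-searches the SVR runtime
#' parameters by cross-validation on the training table and keeps the best
#' configuration, yielding one fitted member model per subset together
#' with its training metrics.
#'
#' @param table training \code{descriptor_table} (normalized, with
#'   response).
#' @param subsets list of descriptor-name vectors (one member per subset).
#' @param grid a \code{grid_spec}.
#' @param folds CV folds for the grid search.
#' @param seed integer seed.
#' @param normalization optional \code{normalization_params} carried into
#'   each member.
#' @return list of \code{svr_model}s, each with fields \code{cv}
#'   (q2cv, rmse) and \code{train_metrics} (a training
#'   \code{metric_report}) attached.
#' @export
build_candidate_pool <- function(table, subsets, grid = grid_spec(),
                                 folds = 10, seed = 1L,
                                 normalization = NULL) {
  stopifnot(inherits(table, "descriptor_table"), length(subsets) >= 1)
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), "")
  if (anyDuplicated(keys))
    message("duplicate descriptor subsets supplied: ",
            paste(unique(keys[duplicated(keys)]), collapse = "; "))
  lapply(seq_along(subsets), function(i) {
    s <- subsets[[i]]
    ranked <- grid_search(table, s, grid, folds = folds,
                          seed = substream_seed(seed, "pool", i))
    best <- ranked$config[[1]]
    m <- train_svr(table, s, best, normalization = normalization)
    m$cv <- list(q2cv = ranked$q2cv[1], rmse = ranked$objective[1])
    m$train_metrics <- metric_report(table$response,
                                     m$training_predictions,
                                     context = "training",
                                     q2cv = ranked$q2cv[1])
    m
  })
}

# Member-prediction matrix: one column per member, rows aligned to table.
member_prediction_matrix <- function(members, table) {
  preds <- lapply(seq_along(members), function(i) {
    tryCatch(predict_svr(members[[i]], table), error = function(e)
      stop("member ", i, ": ", conditionMessage(e), call. = FALSE))
  })
  mat <- do.call(cbind, preds)
  colnames(mat) <- paste0("member", seq_along(members))
  rownames(mat) <- rownames(table$values)
  mat
}

#' Fit the second-level SVR of a hierarchical ensemble
#'
#' Regresses the observed response on the member models' predictions
#' (one input dimension per member, no raw descriptors), grid-searching
#' the second-level runtime parameters like any member model.
#'
#' @param members list of fitted \code{svr_model}s (>= 2), trained on the
#'   same training samples.
#' @param table the training \code{descriptor_table}.
#' @param grid a \code{grid_spec} for the second-level search.
#' @param folds CV folds.
#' @param seed integer seed.
#' @return an \code{hsvr_model}: members, meta (\code{svr_model} on the
#'   member-prediction space), cv (second-level CV summary),
#'   training_predictions.
#' @export
fit_meta <- function(members, table, grid = grid_spec(), folds = 10,
                     seed = 1L) {
  stopifnot(length(members) >= 2, inherits(table, "descriptor_table"))
  if (is.null(table$response)) stop("training table has no response")
  pm <- member_prediction_matrix(members, table)
  if (all(apply(pm, 2, stats::sd) == 0))
    warning("all member predictions constant: degenerate second-level input")
  meta_table <- descriptor_table(pm, table$response)
  ranked <- grid_search(meta_table, colnames(pm), grid, folds = folds,
                        seed = substream_seed(seed, "meta"))
  meta <- train_svr(meta_table, colnames(pm), ranked$config[[1]])
  model <- structure(list(members = members, meta = meta,
                          cv = list(q2cv = ranked$q2cv[1],
                                    rmse = ranked$objective[1])),
                     class = "hsvr_model")
  model$training_predictions <- predict_hsvr(model, table)
  model
}

#' Predict with a hierarchical SVR model
#'
#' Each member predicts from its own descriptor subset; the second-level
#' SVR maps the member-prediction vector to the final prediction.
#'
#' @param model an \code{hsvr_model}.
#' @param table a \code{descriptor_table} containing every member's
#'   descriptors.
#' @return named numeric vector of predictions in row order.
#' @export
predict_hsvr <- function(model, table) {
  stopifnot(inherits(model, "hsvr_model"))
  pm <- member_prediction_matrix(model$members, table)
  predict_svr(model$meta, descriptor_table(pm))
}

#' @export
print.hsvr_model <- function(x, ...) {
  cat("hsvr_model: ", length(x$members), " members (",
      paste(vapply(x$members, function(m) length(m$descriptor_subset),
                   integer(1)), collapse = ", "),
      " descriptors), union ",
      length(unique(unlist(lapply(x$members,
                                  function(m) m$descriptor_subset)))),
      "\n", sep = "")
  invisible(x)
}

# Distinct descriptors used across an ensemble.
ensemble_descriptor_union <- function(members)
  unique(unlist(lapply(members, function(m) m$descriptor_subset)))

#' Grow an ensemble and select the smallest passing combination
#'
#' Evaluates every 2-member combination from the candidate pool first,
#' then 3-member, then up to \code{max_members}: for each combination the
#' second-level SVR is fitted and the stringent validation criteria are
#' checked. The first (smallest) ensemble size containing a passing
#' combination wins; within that size the passer using the fewest
#' distinct descriptors is chosen (ties broken by the validation
#' objective). If nothing passes, the best-objective combination overall
#' is returned with \code{criteria_met = FALSE}.
#'
#' By default the verdict is computed from training-internal statistics
#' (training fit plus cross-validation); supplying \code{test_table} with
#' \code{test_guided_selection = TRUE} additionally consults the
#' external-set statistics during selection, which leaks test information
#' into model choice and is provided for fidelity to common (but
#' leakage-prone) QSAR practice.
#'
#' @param table training \code{descriptor_table}.
#' @param pool list of fitted \code{svr_model}s (>= 2).
#' @param test_table optional external \code{descriptor_table} with
#'   response.
#' @param criteria thresholds list (see \code{\link{default_criteria}}).
#' @param max_members largest ensemble size to try (default 4, >= 2).
#' @param grid second-level \code{grid_spec}.
#' @param folds CV folds.
#' @param seed integer seed.
#' @param test_guided_selection use external statistics in the verdict.
#' @return the selected \code{hsvr_model} with fields \code{criteria_met},
#'   \code{verdict}, \code{member_indices}, \code{objective} attached.
#' @export
grow_and_select <- function(table, pool, test_table = NULL,
                            criteria = default_criteria(), max_members = 4,
                            grid = grid_spec(), folds = 10, seed = 1L,
                            test_guided_selection = FALSE) {
  if (max_members < 2) stop("max_members must be at least 2")
  if (length(pool) < 2) stop("candidate pool must hold at least 2 models")
  if (test_guided_selection && is.null(test_table))
    stop("test_guided_selection requires a test_table")

  evaluate <- function(idx) {
    model <- fit_meta(pool[idx], table, grid = grid, folds = folds,
                      seed = substream_seed(seed, "combo",
                                            sum(2^(idx - 1))))
    train_rep <- metric_report(table$response, model$training_predictions,
                               context = "training", q2cv = model$cv$q2cv)
    test_rep <- NULL
    if (!is.null(test_table) && test_guided_selection)
      test_rep <- metric_report(test_table$response,
                                predict_hsvr(model, test_table),
                                context = "external",
                                observed_train = table$response)
    verdict <- check_criteria(train_rep, test_rep, criteria)
    model$member_indices <- idx
    model$train_metrics <- train_rep
    model$verdict <- verdict
    model$objective <- model$cv$rmse
    model$n_descriptors <- length(ensemble_descriptor_union(pool[idx]))
    model
  }

  best_overall <- NULL
  for (size in 2:min(max_members, length(pool))) {
    combos <- utils::combn(length(pool), size, simplify = FALSE)
    fitted <- lapply(combos, evaluate)
    passed <- Filter(function(m) attr(m$verdict, "overall") == "pass",
                     fitted)
    for (m in fitted)
      if (is.null(best_overall) || m$objective < best_overall$objective)
        best_overall <- m
    if (length(passed)) {
      nd <- vapply(passed, function(m) m$n_descriptors, numeric(1))
      obj <- vapply(passed, function(m) m$objective, numeric(1))
      pick <- passed[[order(nd, obj)[1]]]
      pick$criteria_met <- TRUE
      return(pick)
    }
  }
  best_overall$criteria_met <- FALSE
  best_overall
}

#' Tabulate an ensemble's statistics
#'
#' One column per member plus the hierarchical model, mirroring the
#' conventional member-vs-ensemble report: training rows r2, delta_max,
#' MAE, s, RMSE, q2cv and, when an external set is supplied, q2, qF1,
#' qF2, qF3, CCC, delta_max, MAE, s, RMSE.
#'
#' @param model an \code{hsvr_model}.
#' @param train_table training \code{descriptor_table}.
#' @param test_table optional external \code{descriptor_table}.
#' @return list: member_sizes, descriptor_union, training (data.frame),
#'   test (data.frame or NULL).
#' @export
ensemble_report <- function(model, train_table, test_table = NULL) {
  stopifnot(inherits(model, "hsvr_model"))
  members <- model$members
  cols <- c(paste0("SVR_", LETTERS[seq_along(members)]), "HSVR")
  tr_preds <- c(lapply(members, function(m) predict_svr(m, train_table)),
                list(predict_hsvr(model, train_table)))
  y_tr <- train_table$response
  tr_rows <- c("r2", "delta_max", "mae", "s", "rmse", "q2cv")
  tr <- sapply(seq_along(tr_preds), function(j) {
    rep_ <- basic_metrics(y_tr, tr_preds[[j]], "training")
    q2cv <- if (j <= length(members)) members[[j]]$cv$q2cv %||% NA_real_
            else model$cv$q2cv %||% NA_real_
    c(rep_$r2, rep_$delta_max, rep_$mae, rep_$s, rep_$rmse, q2cv)
  })
  dimnames(tr) <- list(tr_rows, cols)

  te <- NULL
  if (!is.null(test_table)) {
    te_preds <- c(lapply(members, function(m) predict_svr(m, test_table)),
                  list(predict_hsvr(model, test_table)))
    y_te <- test_table$response
    te_rows <- c("q2", "qF1", "qF2", "qF3", "ccc", "delta_max", "mae",
                 "s", "rmse")
    te <- sapply(te_preds, function(p) {
      rep_ <- basic_metrics(y_te, p, "external")
      ext <- external_metrics(y_te, p, y_tr)
      c(rep_$q2, ext$qF1, ext$qF2, ext$qF3, ext$ccc, rep_$delta_max,
        rep_$mae, rep_$s, rep_$rmse)
    })
    dimnames(te) <- list(te_rows, cols)
  }
  list(member_sizes = vapply(members,
                             function(m) length(m$descriptor_subset),
                             integer(1)),
       descriptor_union = ensemble_descriptor_union(members),
       training = as.data.frame(tr),
       test = if (is.null(te)) NULL else as.data.frame(te))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
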