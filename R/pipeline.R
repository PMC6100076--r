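# End-to-end orchestration: filter -> autoscale -> Kennard-Stone split ->
# descriptor-subset search -> member grid search -> hierarchical assembly
# -> full statistical validation. Every randomized stage derives its own
# substream from the single run seed.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run. Defaults are desk-scale:
#' reduced LIBSVM-style grids and a small genetic-algorithm budget sized
#' so a complete run on a ~200-sample table finishes in seconds.
#'
#' @param seed master integer seed.
#' @param train_fraction training fraction of the partition (default 0.8,
#'   the conventional 4:1 split).
#' @param split "kennard_stone" (deterministic) or "random" (seeded).
#' @param r2_threshold intercorrelation filter threshold (default 0.8).
#' @param normalize_policy "train_only" (fit autoscaling on the training
#'   set, apply to test; default) or "all" (fit on every sample before the
#'   split).
#' @param ga_population,ga_generations genetic-algorithm budget.
#' @param subset_size_range GA subset-size bounds.
#' @param pool_members number of candidate member models (default 3). The
#'   j-th candidate uses the genetic-algorithm subset minus its j-th most
#'   important descriptor (by elimination ranking), so each member is a
#'   deliberately partial local model and the second level must combine
#'   complementary information.
#' @param member_grid,meta_grid \code{grid_spec}s for member and
#'   second-level searches.
#' @param folds CV folds for the reported q2cv of the selected model
#'   (default 10).
#' @param search_folds CV folds inside member/second-level grid searches
#'   (default 5; cheaper than the reported CV).
#' @param select_folds CV folds inside subset-search fitness.
#' @param max_members largest ensemble size tried (default 4).
#' @param scramble_count Y-scrambling permutations (default 25).
#' @param criteria thresholds list (see \code{\link{default_criteria}}).
#' @param rm2_variant "sqrt" (default) or "nosqrt".
#' @param test_guided_selection consult test-set statistics during
#'   ensemble selection (leakage-prone; off by default).
#' @return a \code{run_config} list.
#' @export
run_config <- function(seed = 1L, train_fraction = 0.8,
                       split = c("kennard_stone", "random"),
                       r2_threshold = 0.8,
                       normalize_policy = c("train_only", "all"),
                       ga_population = 16, ga_generations = 8,
                       subset_size_range = c(2, 7),
                       pool_members = 3,
                       member_grid = grid_spec(C = 2^seq(-1, 7, 2),
                                               gamma = 2^seq(-7, 1, 2),
                                               epsilon = c(0.01, 0.1),
                                               modes = "epsilon"),
                       meta_grid = grid_spec(C = 2^seq(-1, 7, 2),
                                             gamma = 2^seq(-5, 3, 2),
                                             epsilon = c(0.001, 0.01,
                                                         0.1),
                                             modes = "epsilon"),
                       folds = 10, search_folds = 5, select_folds = 5,
                       max_members = 4,
                       scramble_count = 25, criteria = default_criteria(),
                       rm2_variant = c("sqrt", "nosqrt"),
                       test_guided_selection = FALSE) {
  stopifnot(train_fraction > 0, train_fraction <= 1, scramble_count >= 1)
  structure(list(seed = as.integer(seed), train_fraction = train_fraction,
                 split = match.arg(split), r2_threshold = r2_threshold,
                 normalize_policy = match.arg(normalize_policy),
                 ga_population = ga_population,
                 ga_generations = ga_generations,
                 subset_size_range = subset_size_range,
                 pool_members = pool_members,
                 member_grid = member_grid, meta_grid = meta_grid,
                 folds = folds, search_folds = search_folds,
                 select_folds = select_folds,
                 max_members = max_members,
                 scramble_count = scramble_count, criteria = criteria,
                 rm2_variant = match.arg(rm2_variant),
                 test_guided_selection = test_guided_selection),
            class = "run_config")
}

#' Run the full modeling pipeline
#'
#' Filters the descriptor pool, autoscales, partitions by the
#' Kennard-Stone design, searches descriptor subsets (genetic algorithm
#' plus recursive elimination), grid-searches member SVRs, grows the
#' hierarchical ensemble until the stringent validation criteria pass,
#' and assembles the complete statistical report including Y-scrambling.
#'
#' @param table a \code{descriptor_table} with response (raw scale).
#' @param config a \code{run_config}.
#' @param verbose print one structured line per stage.
#' @return a \code{pipeline_result}: filter report, partition,
#'   normalization, selection results, candidate pool, fitted
#'   \code{hsvr_model}, training/test \code{metric_report}s, criteria
#'   verdict, scramble report, chemical-space diagnostics, similarity
#'   table.
#' @export
run_pipeline <- function(table, config = run_config(), verbose = FALSE) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$response)) stop("pipeline requires a response")
  seed <- config$seed
  say <- function(...) if (verbose) message("[hsvr] ", sprintf(...))

  filt <- filter_descriptors(table, r2_threshold = config$r2_threshold)
  say("filter: %d -> %d descriptors", ncol(table$values),
      length(filt$report$surviving))

  # Partition distances live in the all-sample autoscaled space (a distance
  # -metric choice, unsupervised); the model's own normalization follows
  # normalize_policy.
  norm_all <- fit_normalization(filt$table)
  scaled_all <- apply_normalization(filt$table, norm_all)
  part <- if (config$split == "kennard_stone")
    kennard_stone_split(scaled_all, config$train_fraction)
  else random_split(scaled_all, config$train_fraction, seed)
  say("split (%s): %d train / %d test", config$split,
      length(part$train_ids), length(part$test_ids))

  train_raw <- subset_table(filt$table, ids = part$train_ids)
  test_raw <- subset_table(filt$table, ids = part$test_ids)
  norm <- if (config$normalize_policy == "train_only")
    fit_normalization(train_raw) else norm_all
  train <- apply_normalization(train_raw, norm)
  test <- apply_normalization(test_raw, norm)

  space <- chemical_space_stats(scaled_all)
  sim <- similarity_check(train, test)

  ga <- ga_subset_search(train, population = config$ga_population,
                         generations = config$ga_generations,
                         subset_size_range = config$subset_size_range,
                         seed = seed, folds = config$select_folds)
  say("ga: chose %d descriptors (fitness %.4f)", length(ga$chosen),
      ga$fitness)
  # full elimination ranking of the GA subset: most important descriptor
  # first (the last survivor), least important last
  rfe_res <- rfe(train, ga$chosen, floor_size = 1, seed = seed,
                 folds = config$select_folds)
  ranked <- c(rfe_res$chosen, rev(rfe_res$elimination_order$name))
  # candidate members: leave the j-th most important descriptor out, so
  # every member is partial and the members carry complementary signal
  m <- max(2L, min(config$pool_members, length(ranked)))
  subsets <- lapply(seq_len(m),
                    function(j) sort(setdiff(ga$chosen, ranked[j])))
  subsets <- unique(Filter(length, subsets))
  say("pool: %d candidate subsets (sizes %s)", length(subsets),
      paste(vapply(subsets, length, integer(1)), collapse = ","))

  pool <- build_candidate_pool(train, subsets, grid = config$member_grid,
                               folds = config$search_folds, seed = seed,
                               normalization = norm)
  model <- grow_and_select(train, pool, test_table = test,
                           criteria = config$criteria,
                           max_members = config$max_members,
                           grid = config$meta_grid,
                           folds = config$search_folds, seed = seed,
                           test_guided_selection =
                             config$test_guided_selection)
  say("ensemble: %d members, criteria %s", length(model$members),
      if (isTRUE(model$criteria_met)) "met" else "not met")

  # reported q2cv: k-fold CV of the second-level regression of the chosen
  # ensemble at the full fold count
  meta_tbl <- descriptor_table(
    member_prediction_matrix(model$members, train), train$response)
  model$cv$q2cv <- cross_validate(meta_tbl, descriptor_names(meta_tbl),
                                  model$meta$config, folds = config$folds,
                                  seed = substream_seed(seed,
                                                        "final_cv"))$q2cv

  train_pred <- predict_hsvr(model, train)
  test_pred <- predict_hsvr(model, test)
  train_report <- metric_report(train$response, train_pred, "training",
                                q2cv = model$cv$q2cv,
                                rm2_variant = config$rm2_variant)
  test_report <- metric_report(test$response, test_pred, "external",
                               observed_train = train$response,
                               rm2_variant = config$rm2_variant)
  verdict <- check_criteria(train_report, test_report, config$criteria)

  # challenge the final-model members with response randomization
  scramble <- y_scramble(train, model$members[[1]]$descriptor_subset,
                         model$members[[1]]$config,
                         scrambles = config$scramble_count, seed = seed)
  say("y-scramble: <rs2> = %.3f over %d permutations", scramble$rs2_mean,
      scramble$scrambles)

  structure(list(config = config, filter = filt$report, partition = part,
                 normalization = norm, ga = ga, rfe = rfe_res,
                 subsets = subsets, pool = pool, model = model,
                 train_table = train, test_table = test,
                 train_predictions = train_pred,
                 test_predictions = test_pred,
                 train_report = train_report, test_report = test_report,
                 verdict = verdict, scramble = scramble,
                 chemical_space = space, similarity = sim),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  cat("  train/test: ", length(x$partition$train_ids), "/",
      length(x$partition$test_ids), "\n", sep = "")
  cat("  members: ", length(x$model$members), " (",
      paste(vapply(x$model$members,
                   function(m) length(m$descriptor_subset), integer(1)),
            collapse = ", "), " descriptors)\n", sep = "")
  cat("  training r2 = ", formatC(x$train_report$r2, digits = 3,
                                  format = "fg"),
      ", q2cv = ", formatC(x$train_report$q2cv %||% NA_real_, digits = 3,
                           format = "fg"), "\n", sep = "")
  cat("  test q2 = ", formatC(x$test_report$q2, digits = 3, format = "fg"),
      ", CCC = ", formatC(x$test_report$ccc, digits = 3, format = "fg"),
      "\n", sep = "")
  cat("  criteria: ", attr(x$verdict, "overall"), "\n", sep = "")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' Serializes the headline numbers of a run — partition sizes, surviving
#' descriptors, member subset sizes, training and external statistics,
#' criteria verdict and Y-scrambling summary — to a JSON file for the
#' command-line \code{report} step.
#'
#' @param result a \code{pipeline_result}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_pipeline_report <- function(result, path) {
  stopifnot(inherits(result, "pipeline_result"))
  strip <- function(rep_) {
    rep_ <- unclass(rep_)
    rep_$residuals <- NULL
    rep_[vapply(rep_, function(v) is.numeric(v) && length(v) == 1,
                logical(1))]
  }
  out <- list(
    n_train = length(result$partition$train_ids),
    n_test = length(result$partition$test_ids),
    surviving_descriptors = result$filter$surviving,
    member_sizes = vapply(result$model$members,
                          function(m) length(m$descriptor_subset),
                          integer(1)),
    descriptor_union = ensemble_descriptor_union(result$model$members),
    criteria_met = isTRUE(result$model$criteria_met),
    training = strip(result$train_report),
    test = strip(result$test_report),
    verdict = as.data.frame(result$verdict),
    overall = attr(result$verdict, "overall"),
    y_scramble = list(rs2_mean = result$scramble$rs2_mean,
                      scrambles = result$scramble$scrambles),
    chemical_space = result$chemical_space)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
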