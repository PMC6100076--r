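# Two-stage descriptor-subset search: a genetic-algorithm stage over
# membership bitmasks followed by recursive feature elimination. The
# fitness of a candidate subset is the k-fold cross-validated RMSE of an
# eps-SVR at mid-grid runtime parameters — a declared surrogate for the
# proprietary genetic-function-approximation fitness the original
# descriptor search used.

# Cached, pure fitness: same subset + folds + seed -> identical value.
make_fitness <- function(table, config, folds, seed) {
  cache <- new.env(parent = emptyenv())
  function(subset) {
    if (length(subset) == 0) return(Inf)
    key <- paste(sort(subset), collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
    v <- cross_validate(table, subset, config, folds = folds,
                        seed = seed)$rmse
    cache[[key]] <- v
    v
  }
}

repair_mask <- function(mask, size_min, size_max) {
  k <- sum(mask)
  while (k < size_min) {
    off <- which(!mask)
    mask[off[sample.int(length(off), 1)]] <- TRUE
    k <- k + 1
  }
  while (k > size_max) {
    on <- which(mask)
    mask[on[sample.int(length(on), 1)]] <- FALSE
    k <- k - 1
  }
  mask
}

#' Genetic-algorithm descriptor-subset search
#'
#' Evolves subsets of the descriptor pool as membership bitmasks:
#' tournament selection (size 2), uniform crossover, per-bit mutation at
#' rate 1/p, elitism of one, and random add/drop repair to keep subset
#' sizes inside \code{subset_size_range}. Fitness (minimized) is the
#' cross-validated RMSE of the downstream SVR learner on the candidate
#' subset.
#'
#' @param table training \code{descriptor_table} (normalized, with
#'   response).
#' @param population population size (>= 2; default 30).
#' @param generations number of generations (default 50; 0 scores the
#'   random initial population only).
#' @param subset_size_range integer c(min, max) subset sizes.
#' @param seed integer seed.
#' @param folds CV folds inside the fitness (default 10).
#' @param fitness_config \code{svr_config} of the surrogate learner.
#' @param mutation_rate per-bit mutation probability (default 1/p).
#' @return a \code{selection_result}: chosen (names), fitness (of chosen),
#'   fitness_trace (per-generation best/mean, best non-increasing).
#' @export
ga_subset_search <- function(table, population = 30, generations = 50,
                             subset_size_range = c(2, 8), seed = 1L,
                             folds = 10,
                             fitness_config = default_fitness_config(),
                             mutation_rate = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$response)) stop("response required for subset search")
  if (population < 2) stop("population must be at least 2")
  nms <- colnames(table$values)
  p <- length(nms)
  size_min <- max(1L, subset_size_range[1])
  size_max <- min(p, subset_size_range[2])
  if (size_min > size_max) stop("invalid subset_size_range")
  if (is.null(mutation_rate)) mutation_rate <- 1 / p
  fitness <- make_fitness(table, fitness_config, folds,
                          substream_seed(seed, "ga_fitness"))

  with_substream(seed, "ga", 0L, {
    pop <- lapply(seq_len(population), function(i) {
      k <- sample(seq(size_min, size_max), 1)
      mask <- rep(FALSE, p)
      mask[sample.int(p, k)] <- TRUE
      mask
    })
    fit <- vapply(pop, function(m) fitness(nms[m]), numeric(1))
    trace <- data.frame(generation = 0L, best = min(fit), mean = mean(fit))

    gen <- 0L
    while (gen < generations) {
      gen <- gen + 1L
      elite <- pop[[which.min(fit)]]
      children <- list(elite)
      while (length(children) < population) {
        pick <- function() {
          cand <- sample.int(population, 2)
          pop[[cand[which.min(fit[cand])]]]
        }
        pa <- pick(); pb <- pick()
        cross <- stats::runif(p) < 0.5
        child <- ifelse(cross, pa, pb)
        flip <- stats::runif(p) < mutation_rate
        child <- xor(child, flip)
        child <- repair_mask(child, size_min, size_max)
        children[[length(children) + 1L]] <- child
      }
      pop <- children
      fit <- vapply(pop, function(m) fitness(nms[m]), numeric(1))
      trace <- rbind(trace, data.frame(generation = gen,
                                       best = min(c(trace$best, fit)),
                                       mean = mean(fit)))
    }
    best_i <- which.min(fit)
    structure(list(chosen = nms[pop[[best_i]]],
                   fitness = fit[best_i],
                   fitness_trace = trace,
                   elimination_order = data.frame(
                     name = character(0), delta = numeric(0),
                     stringsAsFactors = FALSE)),
              class = "selection_result")
  })
}

#' Recursive feature elimination
#'
#' Starting from \code{start_subset}, repeatedly refits the surrogate
#' learner on every leave-one-descriptor-out subset and discards the
#' descriptor whose removal least degrades (or most improves) the
#' cross-validated fitness — i.e. the descriptor with the smallest
#' contribution — until \code{floor_size} descriptors remain.
#'
#' @param table training \code{descriptor_table} (normalized, with
#'   response).
#' @param start_subset descriptor names to start from.
#' @param floor_size stop when this many descriptors remain (>= 1).
#' @param seed integer seed (CV folds inside the fitness).
#' @param folds CV folds (default 10).
#' @param fitness_config \code{svr_config} of the surrogate learner.
#' @return a \code{selection_result}: chosen, fitness, elimination_order
#'   (data.frame name, delta = fitness change caused by the removal; a
#'   negative delta means removal improved the fitness).
#' @export
rfe <- function(table, start_subset, floor_size, seed = 1L, folds = 10,
                fitness_config = default_fitness_config()) {
  stopifnot(inherits(table, "descriptor_table"))
  if (floor_size < 1) stop("floor_size must be at least 1")
  missing <- setdiff(start_subset, colnames(table$values))
  if (length(missing))
    stop("descriptors absent from table: ", paste(missing, collapse = ", "))
  fitness <- make_fitness(table, fitness_config, folds,
                          substream_seed(seed, "rfe_fitness"))
  current <- start_subset
  base <- fitness(current)
  elim <- data.frame(name = character(0), delta = numeric(0),
                     stringsAsFactors = FALSE)
  trace <- data.frame(generation = 0L, best = base, mean = base)
  while (length(current) > floor_size) {
    cand_fit <- vapply(current, function(nm)
      fitness(setdiff(current, nm)), numeric(1))
    # remove the descriptor whose absence yields the best (lowest) fitness;
    # ties resolve to the earliest name in current order
    drop_i <- which.min(cand_fit)
    delta <- cand_fit[drop_i] - base
    elim <- rbind(elim, data.frame(name = current[drop_i], delta = delta,
                                   stringsAsFactors = FALSE))
    current <- current[-drop_i]
    base <- cand_fit[drop_i]
    trace <- rbind(trace, data.frame(generation = nrow(elim), best = base,
                                     mean = base))
  }
  structure(list(chosen = current, fitness = base,
                 fitness_trace = trace, elimination_order = elim),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result: {", paste(x$chosen, collapse = ", "),
      "}  fitness = ", formatC(x$fitness, digits = 4, format = "fg"),
      "\n", sep = "")
  invisible(x)
}
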