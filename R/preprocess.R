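#' Filter a descriptor pool
#'
#' Applies the standard QSAR descriptor-pool reduction: descriptors with a
#' missing value for any sample are dropped; descriptors with little or no
#' discrimination (variance below \code{variance_floor} on the autoscaled
#' scale, or fewer than two distinct values) are dropped; then, among any
#' pair with squared Pearson intercorrelation above \code{r2_threshold},
#' only one is kept. When a response is present the member with the larger
#' absolute correlation to the response survives, otherwise the earlier
#' column.
#'
#' @param table a \code{descriptor_table}.
#' @param r2_threshold pairwise r-squared above which one of a pair is
#'   dropped (default 0.8).
#' @param variance_floor minimum variance relative to the column scale
#'   (default 1e-8).
#' @return list with elements \code{table} (filtered) and \code{report}
#'   (a \code{filter_report}: dropped_missing, dropped_low_variance,
#'   dropped_intercorrelated with (kept, dropped, r2) rows, surviving).
#' @export
filter_descriptors <- function(table, r2_threshold = 0.8,
                               variance_floor = 1e-8) {
  stopifnot(inherits(table, "descriptor_table"))
  mat <- table$values
  if (ncol(mat) == 0) stop("empty feature space: no descriptors to filter")
  nms <- colnames(mat)

  miss <- nms[colSums(is.na(mat)) > 0]
  keep <- setdiff(nms, miss)

  lowvar <- character(0)
  for (nm in keep) {
    x <- mat[, nm]
    # variance judged on the autoscaled (unit-mean-square) scale so that
    # the floor is insensitive to descriptor units
    scale2 <- mean(x^2)
    v <- stats::var(x)
    if (length(unique(x)) < 2 ||
        (scale2 > 0 && v / scale2 < variance_floor) ||
        (scale2 == 0))
      lowvar <- c(lowvar, nm)
  }
  keep <- setdiff(keep, lowvar)
  if (length(keep) == 0) stop("empty feature space: all descriptors removed")

  # greedy intercorrelation sweep in column order; survivor of a clashing
  # pair chosen by |cor with response|, else earlier column
  resp <- table$response
  dropped_ic <- data.frame(kept = character(0), dropped = character(0),
                           r2 = numeric(0), stringsAsFactors = FALSE)
  surv <- character(0)
  pending <- keep
  while (length(pending)) {
    a <- pending[1]
    pending <- pending[-1]
    clash <- FALSE
    for (b in surv) {
      r2 <- suppressWarnings(stats::cor(mat[, a], mat[, b]))^2
      if (!is.na(r2) && r2 > r2_threshold) {
        # a clashes with an already-kept descriptor; decide which stays
        winner <- b; loser <- a
        if (!is.null(resp)) {
          ca <- abs(suppressWarnings(stats::cor(mat[, a], resp)))
          cb <- abs(suppressWarnings(stats::cor(mat[, b], resp)))
          if (!is.na(ca) && !is.na(cb) && ca > cb) { winner <- a; loser <- b }
        }
        dropped_ic <- rbind(dropped_ic,
                            data.frame(kept = winner, dropped = loser,
                                       r2 = r2, stringsAsFactors = FALSE))
        if (identical(winner, a)) {
          surv <- setdiff(surv, b)
          # re-examine a against remaining survivors
          pending <- c(a, pending)
        }
        clash <- TRUE
        break
      }
    }
    if (!clash) surv <- c(surv, a)
  }
  if (length(surv) == 0) stop("empty feature space: all descriptors removed")
  surv <- nms[nms %in% surv]   # original column order

  report <- structure(list(dropped_missing = miss,
                           dropped_low_variance = lowvar,
                           dropped_intercorrelated = dropped_ic,
                           surviving = surv,
                           r2_threshold = r2_threshold),
                      class = "filter_report")
  list(table = subset_table(table, descriptors = surv), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report: ", length(x$surviving), " surviving; dropped ",
      length(x$dropped_missing), " missing, ",
      length(x$dropped_low_variance), " low-variance, ",
      nrow(x$dropped_intercorrelated), " intercorrelated (r2 > ",
      x$r2_threshold, ")\n", sep = "")
  invisible(x)
}

#' Fit autoscaling parameters
#'
#' Computes per-descriptor means and sample standard deviations (n-1
#' denominator) on a training table, for centring-and-scaling each
#' descriptor to zero mean and unit variance.
#'
#' @param train a \code{descriptor_table} (training set, already filtered).
#' @return a \code{normalization_params} object (means, sds, names).
#' @export
fit_normalization <- function(train) {
  stopifnot(inherits(train, "descriptor_table"))
  mu <- colMeans(train$values)
  sd_ <- apply(train$values, 2, stats::sd)
  if (any(sd_ <= 0))
    stop("zero-variance descriptors must be filtered before normalization: ",
         paste(names(sd_)[sd_ <= 0], collapse = ", "))
  structure(list(mean = mu, sd = sd_, names = colnames(train$values)),
            class = "normalization_params")
}

#' Apply autoscaling
#'
#' Transforms each descriptor x to (x - mean)/sd using parameters fitted on
#' the training set, so test samples are expressed in the training scale.
#'
#' @param table a \code{descriptor_table}.
#' @param params a \code{normalization_params} from
#'   \code{\link{fit_normalization}}.
#' @return the transformed \code{descriptor_table}.
#' @export
apply_normalization <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(params, "normalization_params"))
  missing <- setdiff(params$names, colnames(table$values))
  if (length(missing))
    stop("descriptors absent from table: ", paste(missing, collapse = ", "))
  mat <- table$values[, params$names, drop = FALSE]
  mat <- sweep(sweep(mat, 2, params$mean, "-"), 2, params$sd, "/")
  descriptor_table(mat, table$response)
}

#' Invert autoscaling
#'
#' @param table a normalized \code{descriptor_table}.
#' @param params the \code{normalization_params} used to normalize it.
#' @return the table on the original scale.
#' @export
invert_normalization <- function(table, params) {
  stopifnot(inherits(table, "descriptor_table"),
            inherits(params, "normalization_params"))
  mat <- table$values[, params$names, drop = FALSE]
  mat <- sweep(sweep(mat, 2, params$sd, "*"), 2, params$mean, "+")
  descriptor_table(mat, table$response)
}

#' Kennard-Stone train/test partition
#'
#' Deterministic max-min design: the first two training picks are the
#' globally most distant pair (Euclidean distance in the supplied, normally
#' autoscaled, descriptor space); each subsequent pick maximizes its minimum
#' distance to the already-selected set. Ties resolve to the lowest row
#' index. The training-set size is round-half-up(train_fraction * n), so 63
#' samples at the conventional 4:1 ratio give 50 training and 13 test
#' molecules.
#'
#' @param table a \code{descriptor_table} (normalized descriptors).
#' @param train_fraction fraction of samples assigned to training
#'   (default 0.8).
#' @return a \code{partition_result}: train_ids, test_ids, selection_order,
#'   distance_metric.
#' @export
kennard_stone_split <- function(table, train_fraction = 0.8) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values)
  if (n < 2) stop("need at least 2 samples to partition")
  if (train_fraction <= 0 || train_fraction > 1)
    stop("train_fraction must be in (0, 1]")
  n_train <- floor(train_fraction * n + 0.5)   # round half up
  n_train <- max(2L, min(n, n_train))
  ids <- rownames(table$values)
  d <- as.matrix(stats::dist(table$values))

  # seed pair: maximal distance, ties to lowest (i, j)
  best <- c(1L, 2L); bestd <- -Inf
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    if (d[i, j] > bestd) { bestd <- d[i, j]; best <- c(i, j) }
  }
  sel <- best
  repeat {
    if (length(sel) >= n_train) break
    remaining <- setdiff(seq_len(n), sel)
    mind <- apply(d[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(mind)]   # which.max -> first (lowest index)
    sel <- c(sel, pick)
  }
  structure(list(train_ids = ids[sel], test_ids = ids[setdiff(seq_len(n), sel)],
                 selection_order = ids[sel], distance_metric = "euclidean"),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("partition_result: ", length(x$train_ids), " train / ",
      length(x$test_ids), " test (", x$distance_metric, ")\n", sep = "")
  invisible(x)
}

#' Seeded random train/test partition
#'
#' Alternative to the deterministic Kennard-Stone design: a uniform random
#' assignment at the same rounding rule.
#'
#' @param table a \code{descriptor_table}.
#' @param train_fraction fraction assigned to training.
#' @param seed integer seed.
#' @return a \code{partition_result}.
#' @export
random_split <- function(table, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values)
  n_train <- max(2L, min(n, floor(train_fraction * n + 0.5)))
  ids <- rownames(table$values)
  sel <- with_substream(seed, "random_split", 0L, sample.int(n, n_train))
  structure(list(train_ids = ids[sel],
                 test_ids = ids[setdiff(seq_len(n), sel)],
                 selection_order = ids[sel], distance_metric = "random"),
            class = "partition_result")
}

#' Chemical-space diagnostics
#'
#' Summarizes the spread of samples in descriptor space: variance explained
#' by the leading principal components, the mean and standard deviation of
#' each sample's nearest-neighbor distance, and the maximum pairwise
#' distance. These are the structural-diversity numbers a QSAR study
#' reports alongside its data partition.
#'
#' @param table a \code{descriptor_table}.
#' @param n_components number of leading PCs to report (default 3).
#' @return list: pc_variance_explained (fractions), nn_mean, nn_sd,
#'   max_distance, n_samples.
#' @export
chemical_space_stats <- function(table, n_components = 3) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- nrow(table$values)
  if (n < 3) stop("need at least 3 samples for chemical-space diagnostics")
  k_max <- min(n - 1, ncol(table$values))
  if (n_components > k_max) {
    warning("requested ", n_components, " components, only ", k_max,
            " available; truncating")
    n_components <- k_max
  }
  pca <- stats::prcomp(table$values, center = TRUE, scale. = FALSE)
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  d <- as.matrix(stats::dist(table$values))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  diag(d) <- 0
  list(pc_variance_explained = ve[seq_len(n_components)],
       nn_mean = mean(nn), nn_sd = stats::sd(nn),
       max_distance = max(d), n_samples = n)
}

#' Train/test distributional similarity check
#'
#' Purely descriptive comparison of the two partitions: per-feature range
#' overlap (interval-intersection length over interval-union length) and
#' two-sample means and standard deviations, for the response and every
#' shared descriptor. No pass/fail is attached.
#'
#' @param train,test \code{descriptor_table}s sharing a descriptor space.
#' @return data.frame with one row per feature: feature, overlap,
#'   train_mean, train_sd, test_mean, test_sd.
#' @export
similarity_check <- function(train, test) {
  stopifnot(inherits(train, "descriptor_table"),
            inherits(test, "descriptor_table"))
  shared <- intersect(colnames(train$values), colnames(test$values))
  feats <- lapply(shared, function(nm)
    list(name = nm, a = train$values[, nm], b = test$values[, nm]))
  if (!is.null(train$response) && !is.null(test$response))
    feats <- c(list(list(name = "response", a = train$response,
                         b = test$response)), feats)
  rows <- lapply(feats, function(f) {
    lo <- max(min(f$a), min(f$b)); hi <- min(max(f$a), max(f$b))
    span <- max(max(f$a), max(f$b)) - min(min(f$a), min(f$b))
    overlap <- if (span == 0) 1 else max(0, hi - lo) / span
    data.frame(feature = f$name, overlap = overlap,
               train_mean = mean(f$a), train_sd = stats::sd(f$a),
               test_mean = mean(f$b), test_sd = stats::sd(f$b),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
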