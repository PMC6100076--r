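# Statistical-validation battery for QSAR regression models: determination
# coefficients, Roy rm2 family, external-validation qF coefficients, Lin's
# concordance correlation, Y-scrambling, and the collected Golbraikh /
# Ojha / Roy / Chirico-Gramatica pass criteria.

# Undefined-denominator results propagate as NA (never coerced to 0).

#' Squared correlation coefficient of determination (r2 / q2)
#'
#' 1 - sum((y - yhat)^2) / sum((y - center)^2). The default centers the
#' denominator on the observed mean (the standard convention, consistent
#' with the external qF2 coefficient); \code{center_on_predicted = TRUE} centers it
#' on the mean predicted value instead.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param center_on_predicted center denominator on mean(predicted).
#' @return scalar in (-Inf, 1]; NA when the denominator is 0.
#' @export
squared_correlation_coefficient <- function(observed, predicted,
                                            center_on_predicted = FALSE) {
  stopifnot(length(observed) == length(predicted))
  center <- if (center_on_predicted) mean(predicted) else mean(observed)
  den <- sum((observed - center)^2)
  if (den == 0) return(NA_real_)
  1 - sum((observed - predicted)^2) / den
}

#' Core error statistics for one (observed, predicted) pairing
#'
#' Residuals are observed minus predicted. Returns the determination
#' coefficient (named r2 in the training context, q2 externally), RMSE
#' (n denominator), MAE, the sample standard deviation of the residuals
#' (n-1), the maximum absolute residual and the signed mean residual.
#'
#' @param observed,predicted numeric vectors, length >= 2.
#' @param context "training" or "external" (controls the coefficient
#'   name only).
#' @param center_on_predicted see \code{\link{squared_correlation_coefficient}}.
#' @return a \code{metric_report} (partial; extend with
#'   \code{\link{origin_stats}}, \code{\link{roy_metrics}},
#'   \code{\link{external_metrics}} or use \code{\link{metric_report}}).
#' @export
basic_metrics <- function(observed, predicted,
                          context = c("training", "external"),
                          center_on_predicted = FALSE) {
  context <- match.arg(context)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  res <- observed - predicted
  out <- list(n = length(observed), context = context,
              residuals = res,
              rmse = sqrt(mean(res^2)),
              mae = mean(abs(res)),
              s = stats::sd(res),
              delta_max = max(abs(res)),
              mean_residual = mean(res))
  coef <- squared_correlation_coefficient(observed, predicted, center_on_predicted)
  if (context == "training") out$r2 <- coef else out$q2 <- coef
  structure(out, class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  nm <- setdiff(names(x), c("residuals", "context"))
  vals <- vapply(nm, function(k)
    if (is.numeric(x[[k]]) && length(x[[k]]) == 1)
      formatC(x[[k]], digits = 4, format = "fg") else "", "")
  cat("metric_report (", x$context, "):\n", sep = "")
  for (k in nm) if (nzchar(vals[[k]]))
    cat("  ", format(k, width = 14), vals[[k]], "\n", sep = "")
  invisible(x)
}

#' Through-origin regression statistics (Golbraikh-Tropsha)
#'
#' k is the least-squares slope of the through-origin regression of
#' predicted on observed (predicted ~ 0 + observed). ro2 is the
#' determination coefficient of the predicted values about that
#' through-origin line, centered on the mean of the dependent axis:
#'   ro2  = 1 - sum((yhat - k*y)^2)  / sum((yhat - mean(yhat))^2).
#' ro2' swaps the roles (observed regressed on predicted through the
#' origin, slope k'), so exchanging the two vectors exchanges ro2 and
#' ro2'. Several through-origin conventions circulate in the QSAR
#' literature; this symmetric one is used throughout the package.
#'
#' @param observed,predicted numeric vectors, length >= 2.
#' @return list: k, k_prime, ro2, ro2_prime; NA where a denominator is 0.
#' @export
origin_stats <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  through_origin <- function(x, yv) {
    # regression yv ~ 0 + x; coefficient about the line, centered on yv
    if (sum(x^2) == 0) return(list(k = NA_real_, r2 = NA_real_))
    k <- sum(x * yv) / sum(x^2)
    den <- sum((yv - mean(yv))^2)
    r2 <- if (den == 0) NA_real_ else 1 - sum((yv - k * x)^2) / den
    list(k = k, r2 = r2)
  }
  a <- through_origin(observed, predicted)   # predicted vs observed
  b <- through_origin(predicted, observed)   # observed vs predicted
  list(k = a$k, k_prime = b$k, ro2 = a$r2, ro2_prime = b$r2)
}

#' Roy/Ojha modified determination coefficients (rm2 family)
#'
#' The standard form is rm2 = r2 * (1 - sqrt(|r2 - ro2|)) (variant
#' "sqrt", the default); variant "nosqrt" omits the square root,
#' rm2 = r2 * (1 - |r2 - ro2|). Both keep the multiplier in [0, 1] so
#' rm2 <= r2 either way. The average and absolute difference of the pair
#' are variant-independent summaries.
#'
#' @param r2 ordinary determination coefficient.
#' @param ro2,ro2_prime through-origin coefficients from
#'   \code{\link{origin_stats}}.
#' @param variant "sqrt" or "nosqrt".
#' @return list: rm2, rm2_prime, rm2_avg, rm2_delta.
#' @export
roy_metrics <- function(r2, ro2, ro2_prime, variant = c("sqrt", "nosqrt")) {
  variant <- match.arg(variant)
  one <- function(ro) {
    if (is.na(r2) || is.na(ro)) return(NA_real_)
    gap <- abs(r2 - ro)
    if (variant == "sqrt") gap <- sqrt(gap)
    r2 * (1 - gap)
  }
  rm2 <- one(ro2)
  rm2p <- one(ro2_prime)
  c(list(rm2 = rm2, rm2_prime = rm2p), roy_combine(rm2, rm2p))
}

#' Average and spread of an rm2 pair
#'
#' rm2_avg = (rm2 + rm2')/2 and rm2_delta = |rm2 - rm2'|: the two
#' variant-independent summaries of the modified-determination pair that
#' the stringent validation criteria bound.
#'
#' @param rm2,rm2_prime the two modified coefficients.
#' @return list: rm2_avg, rm2_delta.
#' @export
roy_combine <- function(rm2, rm2_prime) {
  list(rm2_avg = (rm2 + rm2_prime) / 2,
       rm2_delta = abs(rm2 - rm2_prime))
}

#' External-validation coefficients qF1, qF2, qF3 and concordance (CCC)
#'
#' qF1 normalizes the external prediction error by the external spread
#' about the training-set mean response; qF2 by the spread about the
#' external mean; qF3 compares per-sample error variances between the
#' external and training sets. CCC is Lin's concordance correlation,
#' which reaches 1 only at exact agreement.
#'
#' @param observed_ext,predicted_ext external-set vectors, length >= 2.
#' @param observed_train training-set observed responses (for qF1/qF3).
#' @param predicted_train optional training-set predictions; used for the
#'   qF1 centering only when \code{use_predicted_train_mean = TRUE}.
#' @param use_predicted_train_mean center qF1 on the mean predicted (not
#'   observed) training value.
#' @return list: qF1, qF2, qF3, ccc (NA on zero denominators).
#' @export
external_metrics <- function(observed_ext, predicted_ext, observed_train,
                             predicted_train = NULL,
                             use_predicted_train_mean = FALSE) {
  stopifnot(length(observed_ext) == length(predicted_ext),
            length(observed_ext) >= 2)
  y <- observed_ext; yh <- predicted_ext
  n_ext <- length(y); n_tr <- length(observed_train)
  press <- sum((y - yh)^2)

  tr_center <- if (use_predicted_train_mean) {
    if (is.null(predicted_train))
      stop("predicted_train required when use_predicted_train_mean = TRUE")
    mean(predicted_train)
  } else mean(observed_train)

  safe_q <- function(num, den) if (den == 0) NA_real_ else 1 - num / den
  qF1 <- safe_q(press, sum((y - tr_center)^2))
  qF2 <- safe_q(press, sum((y - mean(y))^2))
  qF3 <- safe_q(press / n_ext,
                sum((observed_train - mean(observed_train))^2) / n_tr)

  my <- mean(y); myh <- mean(yh)
  den <- sum((y - my)^2) + sum((yh - myh)^2) + n_ext * (my - myh)^2
  ccc <- if (den == 0) NA_real_ else
    2 * sum((y - my) * (yh - myh)) / den

  list(qF1 = qF1, qF2 = qF2, qF3 = qF3, ccc = ccc)
}

#' Complete metric report for one (observed, predicted) pairing
#'
#' Convenience assembly of \code{\link{basic_metrics}},
#' \code{\link{origin_stats}}, \code{\link{roy_metrics}} and, in the
#' external context, \code{\link{external_metrics}}.
#'
#' @param observed,predicted vectors for the context being scored.
#' @param context "training" or "external".
#' @param observed_train training observations (external context).
#' @param q2cv optional cross-validated coefficient to attach (training).
#' @param rm2_variant passed to \code{\link{roy_metrics}}.
#' @param center_on_predicted see \code{\link{squared_correlation_coefficient}}.
#' @return a \code{metric_report} with every applicable field filled.
#' @export
metric_report <- function(observed, predicted,
                          context = c("training", "external"),
                          observed_train = NULL, q2cv = NULL,
                          rm2_variant = "sqrt", center_on_predicted = FALSE) {
  context <- match.arg(context)
  rep_ <- basic_metrics(observed, predicted, context, center_on_predicted)
  coef <- if (context == "training") rep_$r2 else rep_$q2
  os <- origin_stats(observed, predicted)
  rep_[names(os)] <- os
  rm_ <- roy_metrics(coef, os$ro2, os$ro2_prime, rm2_variant)
  rep_[names(rm_)] <- rm_
  if (context == "external") {
    if (is.null(observed_train))
      stop("observed_train required for external metrics")
    ext <- external_metrics(observed, predicted, observed_train)
    rep_[names(ext)] <- ext
    rep_$n_train <- length(observed_train)
    rep_$mean_observed_train <- mean(observed_train)
  }
  if (!is.null(q2cv)) rep_$q2cv <- q2cv
  rep_$mean_observed <- mean(observed)
  rep_$mean_predicted <- mean(predicted)
  rep_
}

#' Y-scrambling (response-randomization) test
#'
#' Randomly permutes the response, refits the model with unchanged
#' descriptors and runtime parameters, and records the squared
#' correlation rs2 of the refit's training predictions against the
#' permuted response. A genuine structure-activity model shows a large
#' gap between its real r2 and the near-zero mean scrambled coefficient.
#'
#' @param table training \code{descriptor_table} with response.
#' @param subset descriptor names of the model being challenged.
#' @param config the model's \code{svr_config} (held fixed).
#' @param scrambles number of permutations (default 25).
#' @param seed integer seed.
#' @param permutations optional list of explicit permutations (test hook);
#'   overrides \code{scrambles}.
#' @return a \code{scramble_report}: rs2 (vector), rs2_mean, scrambles,
#'   seed.
#' @export
y_scramble <- function(table, subset, config, scrambles = 25, seed = 1L,
                       permutations = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  if (is.null(table$response)) stop("training table has no response")
  if (is.null(permutations)) {
    stopifnot(scrambles >= 1)
    n <- nrow(table$values)
    permutations <- lapply(seq_len(scrambles), function(i)
      with_substream(seed, "y_scramble", i, sample.int(n)))
  }
  rs2 <- vapply(permutations, function(p) {
    scrambled <- descriptor_table(table$values, table$response[p])
    m <- suppressWarnings(train_svr(scrambled, subset, config))
    squared_correlation_coefficient(scrambled$response,
                                    m$training_predictions)
  }, numeric(1))
  structure(list(rs2 = rs2, rs2_mean = mean(rs2),
                 scrambles = length(permutations), seed = seed),
            class = "scramble_report")
}

#' @export
print.scramble_report <- function(x, ...) {
  cat("scramble_report: ", x$scrambles, " permutations, <rs2> = ",
      formatC(x$rs2_mean, digits = 3, format = "fg"), "\n", sep = "")
  invisible(x)
}

#' Default validation-criteria thresholds
#'
#' The collected stringent criteria: every determination coefficient
#' (r2, q2cv, q2, qFn) at least 0.70; |r2 - q2cv| < 0.10 (training);
#' (r2 - ro2)/r2 < 0.10 with slope k in [0.85, 1.15]; |ro2 - ro2'| < 0.30;
#' rm2 >= 0.65; rm2 average >= 0.65 with spread < 0.20; CCC >= 0.85
#' (external).
#'
#' @return named list of thresholds.
#' @export
default_criteria <- function() {
  list(coef_min = 0.70, r2_q2cv_gap = 0.10, origin_rel_gap = 0.10,
       k_low = 0.85, k_high = 1.15, origin_abs_gap = 0.30,
       rm2_min = 0.65, rm2_avg_min = 0.65, rm2_delta_max = 0.20,
       ccc_min = 0.85)
}

# Evaluate one criterion; any NA input -> "not_applicable".
.crit <- function(...) {
  vals <- c(...)
  if (any(is.na(vals))) return("not_applicable")
  if (all(as.logical(vals))) "pass" else "fail"
}

#' Check the stringent validation criteria
#'
#' Evaluates the collected pass/fail battery on a training-set and a
#' test-set \code{metric_report} (or any lists carrying the same fields).
#' The CV-gap criterion applies to the training context only and the
#' concordance criterion to the external context only; those cells are
#' reported "not_applicable", as is any criterion whose inputs are
#' undefined.
#'
#' @param train_report training-context report (fields r2, q2cv, ro2,
#'   ro2_prime, k, rm2, rm2_prime, rm2_avg, rm2_delta).
#' @param test_report external-context report (q2, qF1, qF2, qF3, ccc plus
#'   the origin/rm2 fields); may be NULL, in which case every external
#'   cell reads "not_applicable".
#' @param thresholds list as from \code{\link{default_criteria}}.
#' @return a \code{criteria_verdict}: data.frame (criterion, training,
#'   test) with attribute \code{overall} ("pass" iff nothing failed).
#' @export
check_criteria <- function(train_report, test_report,
                           thresholds = default_criteria()) {
  th <- utils::modifyList(default_criteria(), thresholds)
  g <- function(rep_, field) {
    if (is.null(rep_)) return(NA_real_)
    v <- rep_[[field]]
    if (is.null(v)) NA_real_ else v
  }
  tr <- train_report; te <- test_report

  rows <- list()
  add <- function(criterion, training, test)
    rows[[length(rows) + 1L]] <<- data.frame(criterion = criterion,
                                             training = training, test = test,
                                             stringsAsFactors = FALSE)

  add("coefficients_ge_min",
      .crit(g(tr, "r2") >= th$coef_min, g(tr, "q2cv") >= th$coef_min),
      .crit(g(te, "q2") >= th$coef_min, g(te, "qF1") >= th$coef_min,
            g(te, "qF2") >= th$coef_min, g(te, "qF3") >= th$coef_min))
  add("cv_gap_lt_max",
      .crit(abs(g(tr, "r2") - g(tr, "q2cv")) < th$r2_q2cv_gap),
      "not_applicable")
  origin_crit <- function(rep_, coef_field) {
    r2 <- g(rep_, coef_field)
    .crit((r2 - g(rep_, "ro2")) / r2 < th$origin_rel_gap,
          g(rep_, "k") >= th$k_low, g(rep_, "k") <= th$k_high)
  }
  add("origin_r2_and_slope", origin_crit(tr, "r2"), origin_crit(te, "q2"))
  add("origin_pair_gap_lt_max",
      .crit(abs(g(tr, "ro2") - g(tr, "ro2_prime")) < th$origin_abs_gap),
      .crit(abs(g(te, "ro2") - g(te, "ro2_prime")) < th$origin_abs_gap))
  add("rm2_ge_min",
      .crit(g(tr, "rm2") >= th$rm2_min),
      .crit(g(te, "rm2") >= th$rm2_min))
  add("rm2_avg_and_delta",
      .crit(g(tr, "rm2_avg") >= th$rm2_avg_min,
            g(tr, "rm2_delta") < th$rm2_delta_max),
      .crit(g(te, "rm2_avg") >= th$rm2_avg_min,
            g(te, "rm2_delta") < th$rm2_delta_max))
  add("ccc_ge_min",
      "not_applicable",
      .crit(g(te, "ccc") >= th$ccc_min))

  verdict <- do.call(rbind, rows)
  overall <- if (any(verdict$training == "fail" | verdict$test == "fail"))
    "fail" else "pass"
  structure(verdict, overall = overall, class = c("criteria_verdict",
                                                  "data.frame"))
}

#' @export
print.criteria_verdict <- function(x, ...) {
  print.data.frame(x)
  cat("overall:", attr(x, "overall"), "\n")
  invisible(x)
}

#' Residual-versus-predicted table
#'
#' The systematic-error diagnostic: residuals (observed - predicted)
#' tabulated against the predictions, plus their signed mean. An unbiased
#' model scatters residuals evenly about zero across the predicted range.
#'
#' @param observed,predicted numeric vectors.
#' @return list: table (data.frame predicted, residual), mean_residual.
#' @export
residual_analysis <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  res <- observed - predicted
  list(table = data.frame(predicted = predicted, residual = res),
       mean_residual = mean(res))
}
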