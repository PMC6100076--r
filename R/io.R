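#' Read a molecule table
#'
#' Reads a delimited text file of compounds with columns \code{id},
#' optionally \code{smiles} and \code{cas}, and at least one of \code{er}
#' (efflux ratio, the B->A over A->B apparent-permeability ratio) or
#' \code{log_er} (its base-10 logarithm, the modeling response). When only
#' \code{er} is given, \code{log_er} is derived as \code{log10(er)}.
#' Rows sharing an id are averaged on the log scale (replicate measurements).
#'
#' @param path file path.
#' @param sep field separator; \code{","} (default) or \code{"\t"}.
#' @param average_duplicates average rows sharing an id instead of erroring.
#' @return a data.frame with columns id, smiles, cas, er, log_er,
#'   in file order.
#' @export
read_molecule_table <- function(path, sep = ",", average_duplicates = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE, quote = "\"",
                          comment.char = "")
  if (!"id" %in% names(df)) stop("molecule table must have an 'id' column")
  if (!any(c("er", "log_er") %in% names(df)))
    stop("molecule table must have an 'er' or 'log_er' column")
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    dups <- unique(df$id[duplicated(df$id)])
    if (!average_duplicates)
      stop("duplicate molecule ids: ", paste(dups, collapse = ", "))
  }
  if (!"smiles" %in% names(df)) df$smiles <- NA_character_
  if (!"cas" %in% names(df)) df$cas <- NA_character_
  if (!"er" %in% names(df)) df$er <- NA_real_
  if (!"log_er" %in% names(df)) df$log_er <- NA_real_
  df$er <- as.numeric(df$er)
  df$log_er <- as.numeric(df$log_er)

  bad <- which(!is.na(df$er) & df$er <= 0)
  if (length(bad))
    stop("efflux ratio must be positive; offending rows: ",
         paste(df$id[bad], collapse = ", "))
  derive <- is.na(df$log_er) & !is.na(df$er)
  df$log_er[derive] <- log10(df$er[derive])
  incons <- which(!is.na(df$er) & !is.na(df$log_er) &
                    abs(df$log_er - log10(df$er)) > 1e-9)
  if (length(incons))
    stop("log_er inconsistent with log10(er) for: ",
         paste(df$id[incons], collapse = ", "))
  if (anyNA(df$log_er))
    stop("missing response for rows: ",
         paste(df$id[is.na(df$log_er)], collapse = ", "))

  if (average_duplicates && anyDuplicated(df$id)) {
    keep <- !duplicated(df$id)
    agg <- tapply(df$log_er, df$id, mean)
    df <- df[keep, , drop = FALSE]
    df$log_er <- as.numeric(agg[df$id])
    df$er <- 10^df$log_er
  }
  rownames(df) <- NULL
  df[, c("id", "smiles", "cas", "er", "log_er")]
}

#' Read a descriptor table
#'
#' Reads a delimited text file whose header names the descriptors, whose
#' first column holds sample ids, and whose remaining cells are numeric.
#' The marker \code{NA} (or an empty cell) denotes a missing value and is
#' preserved for downstream filtering; any other non-numeric cell is a
#' parse error located by row and column.
#'
#' @param path file path.
#' @param sep field separator.
#' @param response optional name of a column to extract as the response.
#' @return a \code{descriptor_table}.
#' @export
read_descriptor_table <- function(path, sep = ",", response = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           check.names = FALSE, quote = "\"",
                           comment.char = "")
  if (ncol(raw) < 2) stop("descriptor table needs an id column plus data")
  ids <- raw[[1]]
  cols <- names(raw)[-1]
  if (anyDuplicated(cols))
    stop("duplicate descriptor names in header: ",
         paste(unique(cols[duplicated(cols)]), collapse = ", "))
  mat <- matrix(NA_real_, nrow(raw), length(cols),
                dimnames = list(ids, cols))
  for (j in seq_along(cols)) {
    cell <- raw[[j + 1]]
    missing <- is.na(cell) | cell == "NA" | cell == ""
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!missing & is.na(num))
    if (length(bad))
      stop("non-numeric value '", cell[bad[1]], "' at row ", bad[1],
           ", column '", cols[j], "'")
    mat[, j] <- num
  }
  resp <- NULL
  if (!is.null(response)) {
    if (!response %in% cols) stop("response column '", response, "' not found")
    resp <- mat[, response]
    mat <- mat[, setdiff(cols, response), drop = FALSE]
  }
  descriptor_table(mat, resp)
}

#' Write a descriptor table to delimited text
#'
#' @param table a \code{descriptor_table}.
#' @param path output file path.
#' @param sep field separator.
#' @param digits significant digits to print (default full precision).
#' @export
write_descriptor_table <- function(table, path, sep = ",", digits = 17) {
  stopifnot(inherits(table, "descriptor_table"))
  mat <- table$values
  df <- data.frame(id = rownames(mat),
                   apply(mat, 2, function(x) format(x, digits = digits,
                                                    trim = TRUE)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$response))
    df$log_er <- format(table$response, digits = digits, trim = TRUE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
}

#' Write a molecule table to delimited text
#'
#' @param molecules data.frame with columns id and log_er (er, smiles, cas
#'   optional).
#' @param path output file path.
#' @param sep field separator.
#' @export
write_molecule_table <- function(molecules, path, sep = ",") {
  utils::write.table(molecules, path, sep = sep, quote = FALSE,
                     row.names = FALSE)
}

# Persistence schema version; bumped on incompatible layout changes.
.persist_version <- "1.0"

#' Persist a fitted model to disk
#'
#' Stores the complete fitted state (member models with their descriptor
#' subsets, hyperparameters and normalization reference, plus the
#' second-level model for hierarchical ensembles) so that a reloaded model
#' reproduces predictions exactly on any descriptor table, independent of
#' column order.
#'
#' @param model an \code{svr_model} or \code{hsvr_model}.
#' @param path output file path.
#' @export
persist_model <- function(model, path) {
  stopifnot(inherits(model, c("svr_model", "hsvr_model")))
  saveRDS(list(schema = .persist_version, class = class(model)[1],
               model = model), path)
  invisible(path)
}

#' Load a persisted model
#'
#' @param path file path written by \code{\link{persist_model}}.
#' @return the model object.
#' @export
load_model <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt model archive: ", conditionMessage(e), call. = FALSE))
  if (!is.list(bundle) || is.null(bundle$schema))
    stop("corrupt model archive: no schema marker")
  if (!identical(bundle$schema, .persist_version))
    stop("persisted model schema ", bundle$schema,
         " does not match supported version ", .persist_version)
  bundle$model
}

#' Write a prediction table
#'
#' @param ids sample ids.
#' @param predicted predicted log ER.
#' @param observed optional observed log ER (residuals are added when given).
#' @param path output file path.
#' @param sep field separator.
#' @export
write_predictions <- function(ids, predicted, observed = NULL, path,
                              sep = ",") {
  df <- data.frame(id = ids, stringsAsFactors = FALSE)
  if (!is.null(observed)) df$observed_log_er <- observed
  df$predicted_log_er <- predicted
  if (!is.null(observed)) df$residual <- observed - predicted
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(df)
}
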