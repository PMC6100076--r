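#' Descriptor table
#'
#' A sample-by-descriptor numeric matrix with unique sample ids (rownames),
#' unique descriptor names (colnames) and an optional response vector of
#' log efflux ratios aligned to the rows. This is the container every
#' pipeline stage consumes and returns.
#'
#' @param values numeric matrix, rows = samples, columns = descriptors;
#'   rownames are sample ids, colnames are descriptor names.
#' @param response optional numeric vector of log ER values, one per row.
#' @return an object of class \code{descriptor_table}.
#' @export
descriptor_table <- function(values, response = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    rownames(values) <- paste0("s", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("d", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate descriptor names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (!is.null(response)) {
    if (length(response) != nrow(values))
      stop("response length (", length(response),
           ") does not match sample count (", nrow(values), ")")
    response <- as.numeric(response)
  }
  structure(list(values = values, response = response),
            class = "descriptor_table")
}

#' @export
print.descriptor_table <- function(x, ...) {
  cat("descriptor_table: ", nrow(x$values), " samples x ",
      ncol(x$values), " descriptors",
      if (!is.null(x$response)) " (+ response)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.descriptor_table <- function(x) dim(x$values)

#' Sample ids of a descriptor table
#' @param table a \code{descriptor_table}.
#' @return character vector of row ids.
#' @export
sample_ids <- function(table) rownames(table$values)

#' Descriptor names of a descriptor table
#' @param table a \code{descriptor_table}.
#' @return character vector of descriptor names.
#' @export
descriptor_names <- function(table) colnames(table$values)

#' Subset a descriptor table by sample ids and/or descriptor names
#'
#' @param table a \code{descriptor_table}.
#' @param ids sample ids to keep (default all, in table order).
#' @param descriptors descriptor names to keep (default all).
#' @return a \code{descriptor_table}.
#' @export
subset_table <- function(table, ids = NULL, descriptors = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  ri <- if (is.null(ids)) seq_len(nrow(table$values)) else {
    m <- match(ids, rownames(table$values))
    if (anyNA(m)) stop("unknown sample ids: ",
                       paste(ids[is.na(m)], collapse = ", "))
    m
  }
  ci <- if (is.null(descriptors)) seq_len(ncol(table$values)) else {
    m <- match(descriptors, colnames(table$values))
    if (anyNA(m)) stop("unknown descriptors: ",
                       paste(descriptors[is.na(m)], collapse = ", "))
    m
  }
  descriptor_table(table$values[ri, ci, drop = FALSE],
                   if (!is.null(table$response)) table$response[ri])
}
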