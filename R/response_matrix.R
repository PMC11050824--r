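#' Construct a binary response matrix
#'
#' Container for a persons-by-items matrix of binary (0/1) responses with an
#' explicit missingness mask.  Rows are persons, columns are items.  `NA`
#' cells are treated as unobserved and contribute nothing to the likelihood.
#'
#' @param values numeric or integer matrix (or data frame) of 0/1 responses;
#'   `NA` marks an unobserved cell.
#' @param person_ids character vector of person identifiers; defaults to the
#'   row names of `values` or `p1..pP`.
#' @param item_ids character vector of item identifiers; defaults to column
#'   names or `i1..iI`.
#' @return An object of class `response_matrix` with components `values`
#'   (integer matrix with `NA` for missing), `observed` (logical mask),
#'   `person_ids` and `item_ids`.
#' @examples
#' y <- matrix(rbinom(20, 1, 0.5), 4, 5)
#' rm <- response_matrix(y)
#' dim(rm)
#' @export
response_matrix <- function(values, person_ids = NULL, item_ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  storage.mode(values) <- "double"
  P <- nrow(values); I <- ncol(values)
  if (P < 2L || I < 2L)
    stop("response matrix needs at least 2 persons and 2 items")
  obs <- !is.na(values)
  bad <- obs & !(values %in% c(0, 1))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-binary response value %s at row %d, column %d",
                 format(values[bad][1L]), idx[1L], idx[2L]))
  }
  if (any(rowSums(obs) == 0L)) stop("some persons have no observed responses")
  if (any(colSums(obs) == 0L)) stop("some items have no observed responses")

  person_ids <- person_ids %||% rownames(values) %||% paste0("p", seq_len(P))
  item_ids <- item_ids %||% colnames(values) %||% paste0("i", seq_len(I))
  person_ids <- as.character(person_ids)
  item_ids <- as.character(item_ids)
  if (length(person_ids) != P) stop("person_ids length mismatch")
  if (length(item_ids) != I) stop("item_ids length mismatch")
  if (anyDuplicated(person_ids)) stop("duplicate person ids")
  if (anyDuplicated(item_ids)) stop("duplicate item ids")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(person_ids, item_ids)
  structure(
    list(values = values, observed = obs,
         person_ids = person_ids, item_ids = item_ids),
    class = "response_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
dim.response_matrix <- function(x) dim(x$values)

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %d missing cells\n",
              nrow(x$values), ncol(x$values), sum(!x$observed)))
  invisible(x)
}

#' @export
summary.response_matrix <- function(object, ...) {
  v <- object$values
  list(P = nrow(v), I = ncol(v),
       missing = sum(!object$observed),
       person_accuracy = rowMeans(v, na.rm = TRUE),
       item_accuracy = colMeans(v, na.rm = TRUE))
}

as_response_matrix <- function(x) {
  if (inherits(x, "response_matrix")) return(x)
  response_matrix(x)
}
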