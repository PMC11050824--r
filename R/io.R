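#' Read a response matrix from CSV
#'
#' Wide dialect: first column person id, remaining columns one per item,
#' cells 0/1/empty (empty = missing).  Long dialect: columns
#' `person,item,response`.  Row and column order of first appearance is
#' preserved.
#'
#' @param path CSV file path.
#' @param format `"wide"` (default) or `"long"`.
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c("character"), na.strings = "")
  if (format == "wide") {
    ids <- df[[1L]]
    vals <- as.matrix(df[, -1L, drop = FALSE])
    num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
    bad <- !is.na(vals) & (is.na(num) | !(num %in% c(0, 1)))
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop(sprintf(
        "non-binary value '%s' for person '%s', item '%s'",
        vals[bad][1L], ids[idx[1L]], colnames(vals)[idx[2L]]))
    }
    return(response_matrix(num, person_ids = ids,
                           item_ids = colnames(vals)))
  }
  need <- c("person", "item", "response")
  if (!all(need %in% names(df)))
    stop("long format needs columns person, item, response")
  if (anyDuplicated(df[c("person", "item")]))
    stop("duplicate person-item pairs in long file")
  persons <- unique(df$person); items <- unique(df$item)
  num <- suppressWarnings(as.numeric(df$response))
  bad <- !is.na(df$response) & (is.na(num) | !(num %in% c(0, 1)))
  if (any(bad)) {
    j <- which(bad)[1L]
    stop(sprintf("non-binary value '%s' for person '%s', item '%s'",
                 df$response[j], df$person[j], df$item[j]))
  }
  m <- matrix(NA_real_, length(persons), length(items),
              dimnames = list(persons, items))
  m[cbind(match(df$person, persons), match(df$item, items))] <- num
  response_matrix(m, person_ids = persons, item_ids = items)
}

#' Write a response matrix to CSV
#'
#' @param Y a [response_matrix()].
#' @param path output CSV path.
#' @param format `"wide"` (default) or `"long"`; wide files leave missing
#'   cells empty, long files omit them.
#' @export
write_responses <- function(Y, path, format = c("wide", "long")) {
  format <- match.arg(format)
  Y <- as_response_matrix(Y)
  if (format == "wide") {
    df <- data.frame(person = Y$person_ids, Y$values,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, na = "")
  } else {
    obs <- which(Y$observed, arr.ind = TRUE)
    df <- data.frame(person = Y$person_ids[obs[, 1L]],
                     item = Y$item_ids[obs[, 2L]],
                     response = Y$values[obs])
    df <- df[order(match(df$person, Y$person_ids),
                   match(df$item, Y$item_ids)), ]
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Flatten posterior draws to a data frame / CSV
#'
#' One row per retained draw with `chain`, `iter`, all scalar parameters and
#' flattened position coordinates, plus per-draw log-likelihood and joint
#' log-posterior.
#'
#' @param fit an `lsirt_fit`.
#' @param path optional CSV path; when given the frame is also written.
#' @return the data frame, invisibly when `path` is given.
#' @export
draws_frame <- function(fit, path = NULL) {
  pieces <- lapply(seq_along(fit$chains), function(ci) {
    ch <- fit$chains[[ci]]
    n <- nrow(ch$theta)
    df <- data.frame(chain = ci, iter = seq_len(n))
    th <- ch$theta; colnames(th) <- paste0("theta.", colnames(th))
    bb <- ch$b; colnames(bb) <- paste0("b.", colnames(bb))
    df <- cbind(df, th, bb,
                sigma2 = ch$sigma2, log_lambda = ch$log_lambda)
    if (fit$model == "lsirm") {
      K <- dim(ch$xi)[2]
      for (k in seq_len(K)) {
        xi_k <- matrix(t(ch$xi[, k, ]), nrow = n)
        colnames(xi_k) <- paste0("xi.", fit$response$person_ids, ".", k)
        zt_k <- matrix(t(ch$zeta[, k, ]), nrow = n)
        colnames(zt_k) <- paste0("zeta.", fit$response$item_ids, ".", k)
        df <- cbind(df, xi_k, zt_k)
      }
    }
    cbind(df, log_lik = ch$log_lik, log_post = ch$log_post)
  })
  out <- do.call(rbind, pieces)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Write aligned positions as CSV
#'
#' Rows: persons then items; columns `id`, `role`, `dim1..dimK`.
#'
#' @param aligned an [align_posterior()] result.
#' @param path output CSV path.
#' @export
write_positions <- function(aligned, path) {
  K <- ncol(aligned$xi)
  pos <- rbind(aligned$xi, aligned$zeta)
  df <- data.frame(id = c(aligned$person_ids, aligned$item_ids),
                   role = rep(c("person", "item"),
                              c(nrow(aligned$xi), nrow(aligned$zeta))),
                   pos, row.names = NULL)
  names(df)[-(1:2)] <- paste0("dim", seq_len(K))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read aligned positions written by [write_positions()]
#' @param path CSV path.
#' @return list with `xi` and `zeta` matrices (row names = ids).
#' @export
read_positions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(id = "character"))
  dims <- grep("^dim", names(df), value = TRUE)
  m <- as.matrix(df[, dims, drop = FALSE])
  rownames(m) <- df$id
  list(xi = m[df$role == "person", , drop = FALSE],
       zeta = m[df$role == "item", , drop = FALSE])
}

#' Run manifest: provenance needed to reproduce a run
#'
#' @param fit an `lsirt_fit`.
#' @param inputs named list of input file paths.
#' @param conv optional [convergence()] result.
#' @return a list serializable to JSON.
#' @export
run_manifest <- function(fit, inputs = list(), conv = NULL) {
  list(package = "lsirt",
       version = as.character(utils::packageVersion("lsirt")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       model = fit$model,
       inputs = inputs,
       dimensions = list(P = length(fit$response$person_ids),
                         I = length(fit$response$item_ids),
                         K = fit$config$K),
       model_config = unclass(fit$config),
       run_config = unclass(fit$run),
       chain_seeds = fit$chain_seeds,
       converged = if (!is.null(conv)) conv$converged else NA,
       max_rhat = if (!is.null(conv)) max(conv$rhat$rhat) else NA,
       elapsed_sec = fit$elapsed)
}

#' Write a list as pretty JSON
#' @param x list.
#' @param path output path.
#' @export
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
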