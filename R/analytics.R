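#' Person-item distance matrix
#'
#' @param xi P x K person positions.
#' @param zeta I x K item positions.
#' @return P x I matrix with entry (p, i) the Euclidean distance between
#'   person p and item i.
#' @export
person_item_distances <- function(xi, zeta) {
  xi <- as.matrix(xi); zeta <- as.matrix(zeta)
  if (ncol(xi) != ncol(zeta)) stop("positions must share the same dimension")
  d2 <- outer(rowSums(xi^2), rowSums(zeta^2), "+") - 2 * tcrossprod(xi, zeta)
  out <- sqrt(pmax(d2, 0))
  dimnames(out) <- list(rownames(xi), rownames(zeta))
  out
}

#' Inter-item distance matrix
#'
#' Symmetric, zero-diagonal I x I matrix of distances between estimated item
#' positions; its block structure reveals item clusters driven by residual
#' dependence.
#'
#' @param zeta I x K item positions.
#' @export
item_distance_matrix <- function(zeta) {
  zeta <- as.matrix(zeta)
  if (nrow(zeta) < 2L) stop("need at least 2 items")
  out <- as.matrix(stats::dist(zeta))
  dimnames(out) <- list(rownames(zeta), rownames(zeta))
  out
}

#' Cluster centers of item positions
#'
#' A cluster center is simply the arithmetic mean of the member items'
#' latent positions.
#'
#' @param zeta I x K item positions.
#' @param labels length-I vector of cluster labels.
#' @return C x K matrix of centers, rows named by cluster (sorted by label).
#' @export
cluster_centers <- function(zeta, labels) {
  zeta <- as.matrix(zeta)
  if (length(labels) != nrow(zeta)) stop("one label per item required")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  centers <- t(vapply(lev, function(l)
    colMeans(zeta[labels == l, , drop = FALSE]), numeric(ncol(zeta))))
  rownames(centers) <- lev
  centers
}

#' Inter-cluster distance table
#'
#' Pairwise Euclidean distances among cluster centers, plus each cluster's
#' mean distance to the other clusters.
#'
#' @param centers C x K matrix of cluster centers (e.g. from
#'   [cluster_centers()]).
#' @return An object of class `cluster_summary`: `centers`, symmetric
#'   `distances` (C x C) and `mean_to_others` (length C).
#' @export
inter_cluster_distance_table <- function(centers) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("need at least 2 clusters")
  D <- as.matrix(stats::dist(centers))
  dimnames(D) <- list(rownames(centers), rownames(centers))
  m <- rowSums(D) / (nrow(D) - 1)
  structure(list(centers = centers, distances = D, mean_to_others = m),
            class = "cluster_summary")
}

#' Item cluster summary from positions and labels
#'
#' Convenience wrapper: [cluster_centers()] followed by
#' [inter_cluster_distance_table()].
#'
#' @inheritParams cluster_centers
#' @export
item_cluster_summary <- function(zeta, labels) {
  inter_cluster_distance_table(cluster_centers(zeta, labels))
}

#' @export
print.cluster_summary <- function(x, ...) {
  cat(sprintf("<cluster_summary> %d clusters in %d dims\n",
              nrow(x$centers), ncol(x$centers)))
  df <- data.frame(x$centers, round(x$distances, 3),
                   mean = round(x$mean_to_others, 3), check.names = FALSE)
  print(df)
  invisible(x)
}

#' Person-to-cluster distances and farthest-cluster assignment
#'
#' For each person, distances to each item cluster, either as the mean of
#' the distances to the cluster's member items (`"per-item-mean"`, the
#' averaged-across-items definition) or as the distance to the cluster
#' center (`"centroid"`).  The farthest cluster per person flags the item
#' type with the most residual underperformance; ties go to the lowest
#' cluster index.
#'
#' @param xi P x K person positions.
#' @param zeta I x K item positions.
#' @param labels length-I cluster labels.
#' @param method `"per-item-mean"` (default) or `"centroid"`.
#' @return An object of class `person_cluster_distances`: `distances`
#'   (P x C), `method`, `farthest` (cluster label per person).
#' @export
person_cluster_distances <- function(xi, zeta, labels,
                                     method = c("per-item-mean", "centroid")) {
  method <- match.arg(method)
  xi <- as.matrix(xi); zeta <- as.matrix(zeta)
  if (length(labels) != nrow(zeta)) stop("one label per item required")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (method == "per-item-mean") {
    D <- person_item_distances(xi, zeta)
    out <- vapply(lev, function(l)
      rowMeans(D[, labels == l, drop = FALSE]), numeric(nrow(xi)))
  } else {
    out <- person_item_distances(xi, cluster_centers(zeta, labels))
  }
  out <- matrix(out, nrow = nrow(xi),
                dimnames = list(rownames(xi), lev))
  farthest <- lev[apply(out, 1, which.max)]  # which.max: first = lowest index
  structure(list(distances = out, method = method, farthest = farthest),
            class = "person_cluster_distances")
}

#' Person-wise mean distance to the items
#'
#' @param D P x I person-item distance matrix.
#' @return length-P vector of row means.
#' @export
person_mean_distance <- function(D) rowMeans(as.matrix(D))

#' Perceived item difficulty across persons
#'
#' For each item the Rasch-comparable mean effect
#' \eqn{\hat b_i - \hat\lambda \cdot \frac{1}{P}\sum_p d(\hat\xi_p,
#' \hat\zeta_i)} plus the full per-person interval of raw effects
#' \eqn{\hat b_i - \hat\lambda\, d(\hat\xi_p, \hat\zeta_i)}, quantifying how
#' much the effective difficulty of an item varies between persons.  With
#' `lambda_hat = 0` every interval collapses to \eqn{\hat b_i}.
#'
#' @param b_hat length-I vector of item intercept estimates.
#' @param lambda_hat nonnegative distance-weight estimate.
#' @param D P x I person-item distance matrix (from estimated positions).
#' @return An object of class `perceived_difficulty`: `table` (data frame
#'   with `item`, `mean_effect`, `min`, `max`) and `effects` (P x I matrix
#'   of per-person effects).
#' @export
perceived_difficulty <- function(b_hat, lambda_hat, D) {
  if (lambda_hat < 0) stop("lambda_hat must be nonnegative")
  D <- as.matrix(D)
  if (length(b_hat) != ncol(D)) stop("one intercept per item required")
  eff <- sweep(-lambda_hat * D, 2, b_hat, "+")
  tab <- data.frame(
    item = colnames(D) %||% paste0("i", seq_along(b_hat)),
    mean_effect = colMeans(eff),
    min = apply(eff, 2, min),
    max = apply(eff, 2, max),
    row.names = NULL)
  structure(list(table = tab, effects = eff), class = "perceived_difficulty")
}

#' Overlay a person covariate on the latent space
#'
#' Joins an external covariate table to the estimated person positions and
#' summarizes person-wise mean distances by the covariate: grouped mean/SD
#' for categorical variables, correlation for continuous ones.  Persons
#' without a covariate record are dropped (and counted).
#'
#' @param xi P x K person positions with row names = person ids.
#' @param zeta I x K item positions.
#' @param covariates data frame whose first column holds person ids.
#' @param variable name of the covariate column.
#' @return An object of class `covariate_overlay`: `records` (person id,
#'   position columns, covariate value, mean distance), `summary`, `n_dropped`.
#' @export
covariate_overlay <- function(xi, zeta, covariates, variable) {
  xi <- as.matrix(xi)
  if (!variable %in% names(covariates))
    stop(sprintf("covariate '%s' not found", variable))
  ids <- rownames(xi) %||% as.character(seq_len(nrow(xi)))
  cov_ids <- as.character(covariates[[1L]])
  hit <- match(ids, cov_ids)
  dropped <- ids[is.na(hit)]
  if (length(dropped))
    message(sprintf("%d person(s) without covariate records dropped",
                    length(dropped)))
  keep <- !is.na(hit)
  md <- person_mean_distance(person_item_distances(xi, zeta))
  rec <- data.frame(person_id = ids[keep],
                    xi[keep, , drop = FALSE],
                    value = covariates[[variable]][hit[keep]],
                    mean_distance = md[keep], row.names = NULL)
  val <- rec$value
  if (is.numeric(val) && length(unique(val)) > 8L) {
    smry <- list(type = "continuous",
                 correlation = stats::cor(val, rec$mean_distance))
  } else {
    agg <- do.call(rbind, lapply(split(rec$mean_distance, val), function(x)
      data.frame(mean = mean(x), sd = stats::sd(x), n = length(x))))
    smry <- list(type = "categorical",
                 groups = data.frame(value = rownames(agg), agg,
                                     row.names = NULL))
  }
  structure(list(records = rec, summary = smry, n_dropped = length(dropped)),
            class = "covariate_overlay")
}

#' Agglomerative item clustering from the distance matrix
#'
#' Convenience grouping of items by hierarchical clustering of the
#' inter-item distance matrix (Ward linkage by default, which favors the
#' compact blob-like groups latent-space maps produce).  The model itself
#' defines no clustering; this is an exploratory device for maps without
#' prior labels.
#'
#' @param zeta I x K item positions (or a precomputed I x I distance matrix).
#' @param C number of clusters.
#' @param method linkage passed to [stats::hclust()] (default `"ward.D2"`).
#' @return integer cluster labels, one per item.
#' @export
item_clusters <- function(zeta, C, method = "ward.D2") {
  D <- if (is.matrix(zeta) && nrow(zeta) == ncol(zeta) &&
           isTRUE(all.equal(unname(zeta), unname(t(zeta)))))
    zeta else item_distance_matrix(zeta)
  hc <- stats::hclust(stats::as.dist(D), method = method)
  stats::cutree(hc, k = C)
}

#' Personalized feedback record for one person
#'
#' Bundles what the interaction map says about a single respondent: ability
#' estimate, latent position, observed accuracy, and the items (plus item
#' clusters, when labels are given) ranked by distance, farthest first.
#' Large distances mark item types the person did worse on than the main
#' effects predict.
#'
#' @param fit an `lsirt_fit`.
#' @param aligned the matching [align_posterior()] output.
#' @param person_id person identifier.
#' @param labels optional item cluster labels.
#' @param method passed to [person_cluster_distances()].
#' @return An object of class `feedback_report` (a named list, JSON-ready).
#' @export
feedback_report <- function(fit, aligned, person_id, labels = NULL,
                            method = "per-item-mean") {
  p <- match(as.character(person_id), aligned$person_ids)
  if (is.na(p)) stop(sprintf("unknown person id '%s'", person_id))
  D <- person_item_distances(aligned$xi, aligned$zeta)
  drow <- D[p, ]
  ord <- order(drow, decreasing = TRUE)
  items <- data.frame(item_id = aligned$item_ids[ord],
                      distance = unname(drow[ord]),
                      rank = seq_along(ord), row.names = NULL)
  y <- fit$response$values[p, ]
  rec <- list(person_id = as.character(person_id),
              theta_hat = unname(theta_hat(fit)[p]),
              position = unname(aligned$xi[p, ]),
              accuracy = mean(y, na.rm = TRUE),
              items = items)
  if (!is.null(labels)) {
    pcd <- person_cluster_distances(aligned$xi, aligned$zeta, labels, method)
    crow <- pcd$distances[p, ]
    cord <- order(crow, decreasing = TRUE)
    rec$clusters <- data.frame(cluster = colnames(pcd$distances)[cord],
                               distance = unname(crow[cord]),
                               rank = seq_along(cord), row.names = NULL)
    rec$farthest_cluster <- pcd$farthest[p]
  }
  structure(rec, class = "feedback_report")
}

#' @export
print.feedback_report <- function(x, ...) {
  cat(sprintf("<feedback_report> person %s: theta_hat=%.3f, accuracy=%.3f\n",
              x$person_id, x$theta_hat, x$accuracy))
  if (!is.null(x$farthest_cluster))
    cat(sprintf("  farthest item cluster: %s\n", x$farthest_cluster))
  cat(sprintf("  farthest item: %s (d=%.3f)\n",
              x$items$item_id[1], x$items$distance[1]))
  invisible(x)
}
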