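#' Simulate data from the latent space item response model
#'
#' Draws abilities, item intercepts and latent positions, then Bernoulli
#' responses with success probability
#' `plogis(theta_p + b_i - gamma * d(xi_p, zeta_i))`.  Item positions can be
#' plain Gaussian or clustered into well-separated blobs, the configuration
#' that makes residual item structure detectable at small scale.
#'
#' @param P,I numbers of persons and items.
#' @param K latent space dimension (default 2).
#' @param gamma true nonnegative distance weight (default 2).
#' @param sigma_theta SD of the ability distribution (default 1).
#' @param b_sd SD of the item intercepts (default 1).
#' @param positions `"clustered"` (default) or `"gaussian"` item positions;
#'   person positions are always standard normal.
#' @param n_blobs,blob_sd,blob_radius clustered layout: number of blobs
#'   (default 3), within-blob SD (default 0.3) and the radius of the circle
#'   the blob centers sit on (default 2).
#' @param missing proportion of cells masked uniformly at random (default 0).
#' @param center if `TRUE` (default) the item intercepts are shifted by
#'   `gamma` times the average person-item distance, so the overall accuracy
#'   stays near 50% as in a calibrated test; without this, a sizable distance
#'   weight drives most responses to 0 and produces degenerate all-incorrect
#'   persons.
#' @param seed integer seed.
#' @return An object of class `lsirt_sim`: `responses` (a
#'   [response_matrix()]) plus the generating truth (`theta`, `b`, `xi`,
#'   `zeta`, `gamma`, `blob_labels`, `seed`, `regime`).
#' @export
simulate_lsirm <- function(P, I, K = 2L, gamma = 2, sigma_theta = 1,
                           b_sd = 1, positions = c("clustered", "gaussian"),
                           n_blobs = 3L, blob_sd = 0.3, blob_radius = 2,
                           missing = 0, center = TRUE, seed = 1L) {
  positions <- match.arg(positions)
  stopifnot(P >= 2, I >= 2, K >= 1, gamma >= 0, missing >= 0, missing < 1)
  set.seed(as.integer(seed))
  theta <- stats::rnorm(P, 0, sigma_theta)
  b <- stats::rnorm(I, 0, b_sd)
  xi <- matrix(stats::rnorm(P * K), P, K)
  blob_labels <- NULL
  if (positions == "clustered") {
    blob_labels <- rep_len(seq_len(n_blobs), I)
    ang <- 2 * pi * (seq_len(n_blobs) - 1) / n_blobs
    centers <- blob_radius * cbind(cos(ang), sin(ang))
    if (K > 2) centers <- cbind(centers, matrix(0, n_blobs, K - 2))
    if (K == 1) centers <- matrix(blob_radius * cos(ang), n_blobs, 1)
    zeta <- centers[blob_labels, , drop = FALSE] +
      matrix(stats::rnorm(I * K, 0, blob_sd), I, K)
  } else {
    zeta <- matrix(stats::rnorm(I * K), I, K)
  }
  D <- person_item_distances(xi, zeta)
  if (center && gamma > 0) b <- b + gamma * mean(D)
  eta <- outer(theta, b, "+") - gamma * D
  y <- matrix(stats::rbinom(P * I, 1L, stats::plogis(eta)), P, I)
  if (missing > 0)
    y[stats::runif(P * I) < missing] <- NA_integer_
  structure(
    list(responses = response_matrix(y), theta = theta, b = b,
         xi = xi, zeta = zeta, gamma = gamma,
         blob_labels = blob_labels, factor_labels = NULL,
         seed = as.integer(seed), regime = "lsirm"),
    class = "lsirt_sim")
}

#' Simulate Rasch-only data (no distance effect)
#'
#' Equivalent to [simulate_lsirm()] with `gamma = 0` and no positions:
#' responses satisfy conditional independence given `theta` and `b`.
#'
#' @inheritParams simulate_lsirm
#' @export
simulate_rasch <- function(P, I, sigma_theta = 1, b_sd = 1,
                           missing = 0, seed = 1L) {
  stopifnot(P >= 2, I >= 2, missing >= 0, missing < 1)
  set.seed(as.integer(seed))
  theta <- stats::rnorm(P, 0, sigma_theta)
  b <- stats::rnorm(I, 0, b_sd)
  eta <- outer(theta, b, "+")
  y <- matrix(stats::rbinom(P * I, 1L, stats::plogis(eta)), P, I)
  if (missing > 0)
    y[stats::runif(P * I) < missing] <- NA_integer_
  structure(
    list(responses = response_matrix(y), theta = theta, b = b,
         xi = NULL, zeta = NULL, gamma = 0,
         blob_labels = NULL, factor_labels = NULL,
         seed = as.integer(seed), regime = "rasch"),
    class = "lsirt_sim")
}

#' Simulate multidimensional simple-structure factor data
#'
#' Each item loads on exactly one of `n_factors` correlated factors:
#' `logit P(Y_pi = 1) = loading * theta_{p, f(i)} + b_i` with the per-person
#' factor vector drawn from a multivariate normal with unit variances and
#' compound-symmetric correlation `factor_cor`.  Fitting a unidimensional
#' model to such data leaves the factor structure as residual dependence,
#' which should surface as item clusters in the latent space.
#'
#' @param P number of persons.
#' @param n_factors number of factors (default 7).
#' @param items_per_factor items loading on each factor (default 8).
#' @param factor_cor common inter-factor correlation (default 0.5).
#' @param loading common loading (default 1.5).
#' @inheritParams simulate_lsirm
#' @return An `lsirt_sim` whose `factor_labels` store the generating item
#'   partition.
#' @export
simulate_multifactor <- function(P, n_factors = 7L, items_per_factor = 8L,
                                 factor_cor = 0.5, loading = 1.5,
                                 b_sd = 1, missing = 0, seed = 1L) {
  stopifnot(P >= 2, n_factors >= 1, items_per_factor >= 1,
            factor_cor >= 0, factor_cor <= 1, missing >= 0, missing < 1)
  I <- n_factors * items_per_factor
  set.seed(as.integer(seed))
  Sigma <- matrix(factor_cor, n_factors, n_factors)
  diag(Sigma) <- 1
  Theta <- MASS::mvrnorm(P, mu = rep(0, n_factors), Sigma = Sigma)
  Theta <- matrix(Theta, P, n_factors)
  b <- stats::rnorm(I, 0, b_sd)
  labels <- rep(seq_len(n_factors), each = items_per_factor)
  eta <- loading * Theta[, labels, drop = FALSE] +
    matrix(b, P, I, byrow = TRUE)
  y <- matrix(stats::rbinom(P * I, 1L, stats::plogis(eta)), P, I)
  if (missing > 0)
    y[stats::runif(P * I) < missing] <- NA_integer_
  structure(
    list(responses = response_matrix(y), theta = Theta, b = b,
         xi = NULL, zeta = NULL, gamma = 0,
         blob_labels = NULL, factor_labels = labels,
         loading = loading, factor_cor = factor_cor,
         seed = as.integer(seed), regime = "multifactor"),
    class = "lsirt_sim")
}

#' @export
print.lsirt_sim <- function(x, ...) {
  d <- dim(x$responses)
  cat(sprintf("<lsirt_sim> regime=%s, %d persons x %d items, seed=%d\n",
              x$regime, d[1], d[2], x$seed))
  invisible(x)
}

#' Score parameter recovery of a fit against simulation truth
#'
#' Positions are scored only through rigid-transform-invariant quantities:
#' the correlation between the true and estimated person-item distance
#' matrices (raw coordinates are identified only up to rotation,
#' reflection and translation).  When the truth carries an item partition
#' (factor or blob labels), items are re-clustered from the fitted item
#' distance matrix and scored by adjusted Rand index.
#'
#' @param truth an `lsirt_sim`.
#' @param fit the matching `lsirt_fit`.
#' @param aligned optional [align_posterior()] output (computed if missing
#'   and the fit has positions).
#' @return list with `theta_cor`, `theta_rmse`, `b_cor`, `b_rmse`, and when
#'   applicable `distance_cor` and `ari`.
#' @export
recovery_metrics <- function(truth, fit, aligned = NULL) {
  th <- theta_hat(fit)
  th_true <- if (is.matrix(truth$theta)) rowMeans(truth$theta) else truth$theta
  if (length(th) != length(th_true)) stop("person dimension mismatch")
  bh <- b_hat(fit)
  if (length(bh) != length(truth$b)) stop("item dimension mismatch")
  out <- list(theta_cor = stats::cor(th, th_true),
              theta_rmse = sqrt(mean((th - th_true)^2)),
              b_cor = stats::cor(bh, truth$b),
              b_rmse = sqrt(mean((bh - truth$b)^2)))
  if (fit$model == "lsirm") {
    if (is.null(aligned)) aligned <- align_posterior(fit)
    if (!is.null(truth$xi)) {
      Dt <- person_item_distances(truth$xi, truth$zeta)
      De <- person_item_distances(aligned$xi, aligned$zeta)
      out$distance_cor <- stats::cor(as.vector(Dt), as.vector(De))
    }
    lab <- truth$factor_labels %||% truth$blob_labels
    if (!is.null(lab)) {
      est <- item_clusters(aligned$zeta, C = length(unique(lab)))
      out$ari <- mclust::adjustedRandIndex(est, lab)
    }
  }
  out
}
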