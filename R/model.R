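#' Model configuration: latent dimension and prior hyperparameters
#'
#' The latent space item response model extends the Rasch model
#' \eqn{\mathrm{logit}\,P(Y_{pi}=1) = \theta_p + b_i} with a distance effect
#' \eqn{-\lambda\, d(\xi_p, \zeta_i)} between person and item positions in a
#' shared K-dimensional Euclidean space.  Priors:
#' \eqn{\theta_p \sim N(0,\sigma^2)}, \eqn{b_i \sim N(0,\sigma_b^2)},
#' \eqn{\sigma^2 \sim} Half-Cauchy, positions standard normal per coordinate,
#' and a spike-and-slab normal mixture on \eqn{\log\lambda} whose spike
#' component shrinks the distance effect to zero when the data carry no
#' conditional dependence.
#'
#' @param K latent space dimension (default 2, convenient for maps).
#' @param sigma_b prior SD of the item intercepts (default 5).
#' @param sigma_cauchy_scale half-Cauchy scale for the ability variance
#'   (default 25).
#' @param mu_spike,mu_slab means of the spike and slab components of the
#'   normal mixture prior on \eqn{\log\lambda} (defaults -5 and 0.5).
#' @param sd_spike,sd_slab SDs of the two mixture components (defaults 1).
#' @param slab_prior_weight prior probability of the slab component,
#'   \eqn{P(\delta = 1)} (default 0.5).
#' @param cauchy_on whether the half-Cauchy prior is placed on the ability
#'   variance `"variance"` (default) or its square root `"sd"`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(K = 2L, sigma_b = 5, sigma_cauchy_scale = 25,
                         mu_spike = -5, mu_slab = 0.5,
                         sd_spike = 1, sd_slab = 1,
                         slab_prior_weight = 0.5,
                         cauchy_on = c("variance", "sd")) {
  cauchy_on <- match.arg(cauchy_on)
  K <- as.integer(K)
  stopifnot(K >= 1L, sigma_b > 0, sigma_cauchy_scale > 0,
            sd_spike > 0, sd_slab > 0,
            slab_prior_weight > 0, slab_prior_weight < 1)
  structure(
    list(K = K, sigma_b = sigma_b, sigma_cauchy_scale = sigma_cauchy_scale,
         mu_spike = mu_spike, mu_slab = mu_slab,
         sd_spike = sd_spike, sd_slab = sd_slab,
         slab_prior_weight = slab_prior_weight, cauchy_on = cauchy_on),
    class = "model_config")
}

#' Parameter state of the latent space item response model
#'
#' Bundles one full parameter configuration: abilities `theta` (length P),
#' item intercepts `b` (length I, easiness parameterization
#' \eqn{\theta_p + b_i}), ability variance `sigma2`, the log distance weight
#' `log_lambda`, and position matrices `xi` (P x K) and `zeta` (I x K).
#' The spike/slab indicator is marginalized out and never stored; its
#' posterior is recovered from [slab_responsibility()].
#'
#' @param theta numeric vector of person abilities.
#' @param b numeric vector of item intercepts.
#' @param sigma2 positive ability variance.
#' @param log_lambda log of the nonnegative distance weight; `-Inf` encodes
#'   a pure Rasch state.
#' @param xi,zeta person and item position matrices with `K` columns.
#' @return An object of class `param_state`.
#' @export
param_state <- function(theta, b, sigma2, log_lambda, xi, zeta) {
  xi <- as.matrix(xi); zeta <- as.matrix(zeta)
  stopifnot(sigma2 > 0, is.finite(sigma2),
            length(theta) == nrow(xi), length(b) == nrow(zeta),
            ncol(xi) == ncol(zeta), length(log_lambda) == 1L)
  if (!is.finite(log_lambda) && log_lambda > 0) stop("log_lambda must be < Inf")
  structure(
    list(theta = as.numeric(theta), b = as.numeric(b), sigma2 = sigma2,
         log_lambda = log_lambda, xi = xi, zeta = zeta),
    class = "param_state")
}

#' Euclidean distance between two latent positions
#'
#' @param a,b numeric vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(a, b) {
  if (length(a) != length(b)) stop("positions must have equal dimension")
  sqrt(sum((a - b)^2))
}

#' Cell-level linear predictor
#'
#' Computes \eqn{\theta_p + b_i - \lambda\, d(\xi_p, \zeta_i)}: the logit of
#' the success probability for one person-item pair.
#'
#' @param theta_p person ability.
#' @param b_i item intercept.
#' @param lambda nonnegative distance weight.
#' @param xi_p,zeta_i position vectors.
#' @export
linear_predictor <- function(theta_p, b_i, lambda, xi_p, zeta_i) {
  if (lambda < 0) stop("lambda must be nonnegative")
  theta_p + b_i - lambda * euclidean_distance(xi_p, zeta_i)
}

# P x I matrix of linear predictors for a full state
.predictor_matrix <- function(state) {
  lam <- if (is.finite(state$log_lambda)) exp(state$log_lambda) else 0
  eta <- outer(state$theta, state$b, "+")
  if (lam > 0) eta <- eta - lam * person_item_distances(state$xi, state$zeta)
  eta
}

#' Log-likelihood of a response matrix under a parameter state
#'
#' Sum over observed cells of the Bernoulli log-probability with success
#' probability `plogis(linear_predictor)`; unobserved cells contribute
#' nothing.  Computed through `plogis(log.p = TRUE)` for numerical stability
#' at extreme predictors.
#'
#' @param Y a [response_matrix()] (or plain 0/1 matrix).
#' @param state a [param_state()].
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(Y, state) {
  Y <- as_response_matrix(Y)
  if (nrow(Y$values) != length(state$theta) ||
      ncol(Y$values) != length(state$b))
    stop("state dimensions do not match the response matrix")
  eta <- .predictor_matrix(state)
  ll <- ifelse(Y$values == 1L,
               stats::plogis(eta, log.p = TRUE),
               stats::plogis(-eta, log.p = TRUE))
  sum(ll[Y$observed])
}

.log_half_cauchy <- function(x, scale) {
  ifelse(x > 0, log(2) - log(pi * scale * (1 + (x / scale)^2)), -Inf)
}

# log prior density of sigma2 (w.r.t. the variance)
.log_sigma2_prior <- function(sigma2, config) {
  if (config$cauchy_on == "sd") {
    s <- sqrt(sigma2)
    .log_half_cauchy(s, config$sigma_cauchy_scale) - log(2 * s)
  } else {
    .log_half_cauchy(sigma2, config$sigma_cauchy_scale)
  }
}

# marginal mixture log-density of log(lambda), spike/slab indicator summed out
.log_mix_lambda <- function(log_lambda, config) {
  a0 <- log1p(-config$slab_prior_weight) +
    stats::dnorm(log_lambda, config$mu_spike, config$sd_spike, log = TRUE)
  a1 <- log(config$slab_prior_weight) +
    stats::dnorm(log_lambda, config$mu_slab, config$sd_slab, log = TRUE)
  m <- pmax(a0, a1)
  m + log(exp(a0 - m) + exp(a1 - m))
}

#' Joint log-prior of a parameter state
#'
#' Adds the Normal(0, sigma2) ability terms, Normal(0, sigma_b^2) item terms,
#' the half-Cauchy term for the ability variance, standard-normal terms for
#' every position coordinate, and the marginal spike-and-slab mixture density
#' of `log_lambda` (log-sum-exp, indicator marginalized out).
#'
#' @inheritParams log_likelihood
#' @param config a [model_config()].
#' @export
log_prior <- function(state, config = model_config()) {
  if (state$sigma2 <= 0) stop("sigma2 must be positive")
  lp <- sum(stats::dnorm(state$theta, 0, sqrt(state$sigma2), log = TRUE)) +
    sum(stats::dnorm(state$b, 0, config$sigma_b, log = TRUE)) +
    .log_sigma2_prior(state$sigma2, config)
  if (is.finite(state$log_lambda)) {
    lp <- lp + .log_mix_lambda(state$log_lambda, config) +
      sum(stats::dnorm(state$xi, 0, 1, log = TRUE)) +
      sum(stats::dnorm(state$zeta, 0, 1, log = TRUE))
  }
  lp
}

#' Posterior responsibility of the slab component
#'
#' Probability that the spike/slab indicator equals 1 given the value of
#' `log_lambda`:
#' \eqn{w N_{slab} / [(1-w) N_{spike} + w N_{slab}]}.  Vectorized.
#'
#' @param log_lambda numeric vector of log distance weights.
#' @param config a [model_config()].
#' @return probabilities in `[0, 1]`, increasing in `log_lambda` when the
#'   slab mean exceeds the spike mean.
#' @export
slab_responsibility <- function(log_lambda, config = model_config()) {
  a0 <- log1p(-config$slab_prior_weight) +
    stats::dnorm(log_lambda, config$mu_spike, config$sd_spike, log = TRUE)
  a1 <- log(config$slab_prior_weight) +
    stats::dnorm(log_lambda, config$mu_slab, config$sd_slab, log = TRUE)
  stats::plogis(a1 - a0)
}

#' Moments of a lognormal distribution
#'
#' Closed-form mean, mode and SD of `exp(X)` for `X ~ N(mu, sigma^2)`.  Used
#' to characterize the implied prior on the distance weight `lambda` under
#' each mixture component.
#'
#' @param mu,sigma mean and SD of the underlying normal.
#' @return list with `mean`, `mode`, `sd`.
#' @export
lognormal_moments <- function(mu, sigma) {
  list(mean = exp(mu + sigma^2 / 2),
       mode = exp(mu - sigma^2),
       sd = sqrt((exp(sigma^2) - 1) * exp(2 * mu + sigma^2)))
}

#' Implied prior moments of the distance weight
#'
#' @param config a [model_config()].
#' @return data frame with one row per mixture component (`spike`, `slab`)
#'   and columns `mean`, `mode`, `sd` of the lognormal prior on `lambda`.
#' @export
slab_prior_moments <- function(config = model_config()) {
  sp <- lognormal_moments(config$mu_spike, config$sd_spike)
  sl <- lognormal_moments(config$mu_slab, config$sd_slab)
  data.frame(component = c("spike", "slab"),
             mean = c(sp$mean, sl$mean),
             mode = c(sp$mode, sl$mode),
             sd = c(sp$sd, sl$sd))
}
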