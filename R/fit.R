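#' Sampler run configuration
#'
#' @param n_chains number of independent chains (default 3; at least 2 are
#'   needed for split R-hat).
#' @param n_iter total iterations per chain (default 1500).
#' @param n_burnin iterations discarded from the front of each chain
#'   (default 500); proposal-scale adaptation happens only here.
#' @param seed master seed; chain-level seeds are derived from it.
#' @param adapt_batch adaptation batch length in iterations (default 50).
#' @param temper_floor starting inverse temperature of the likelihood-tempered
#'   burn-in ramp (default 0.7; `1` disables tempering).  During the first
#'   half of burn-in the likelihood is raised to a power that ramps from this
#'   floor to 1; the untempered prior then dissolves latent-position
#'   structure whose likelihood payoff is weak (noise fits) while strongly
#'   supported structure survives, so chains settle into spike/slab basins
#'   by posterior mass rather than by initialization.  Retained draws always
#'   use power 1.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_chains = 3L, n_iter = 1500L, n_burnin = 500L,
                       seed = 1L, adapt_batch = 50L, temper_floor = 0.7) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin)
  stopifnot(n_chains >= 1L, n_burnin >= 0L, n_burnin < n_iter,
            adapt_batch >= 1L, temper_floor > 0, temper_floor <= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 seed = as.integer(seed), adapt_batch = as.integer(adapt_batch),
                 temper_floor = temper_floor),
            class = "run_config")
}

# starting values: centered/standardized logit margins for theta and b,
# residual-MDS positions, log lambda at the mixture midpoint.
#
# Positions are seeded from the data rather than pure noise: with a
# near-zero starting distance weight the likelihood barely informs the
# positions, so a chain whose configuration starts as noise can stall in the
# spike basin even when the data carry strong conditional dependence.
# Classical MDS of the residual item correlations (and residual-weighted
# placement of persons) starts the configuration near any real structure;
# per-chain jitter keeps chains distinct.
.init_state <- function(Y, config, chain = 1L) {
  v <- Y$values; obs <- Y$observed
  P <- nrow(v); I <- ncol(v)
  pp <- rowSums(v == 1L & obs) / rowSums(obs)
  pi_ <- colSums(v == 1L & obs) / colSums(obs)
  clip <- function(x, n) pmin(pmax(x, 1 / (2 * n)), 1 - 1 / (2 * n))
  lt <- stats::qlogis(clip(pp, I))
  theta0 <- lt - mean(lt)
  if (stats::sd(theta0) > 0) theta0 <- theta0 / stats::sd(theta0)
  b0 <- stats::qlogis(clip(pi_, P))
  K <- config$K
  pos <- tryCatch(.residual_mds(v, obs, theta0, b0, K),
                  error = function(e) NULL)
  if (is.null(pos))
    pos <- list(xi = matrix(0, P, K), zeta = matrix(0, I, K))
  list(theta = theta0 + stats::rnorm(P, 0, 0.1),
       b = b0 + stats::rnorm(I, 0, 0.1),
       sigma2 = 1,
       log_lambda = (1 / 2) * (-5 + 0.5),
       xi = pos$xi + matrix(stats::rnorm(P * K, 0, 0.1), P, K),
       zeta = pos$zeta + matrix(stats::rnorm(I * K, 0, 0.1), I, K))
}

.residual_mds <- function(v, obs, theta0, b0, K) {
  R <- v - stats::plogis(outer(theta0, b0, "+"))
  R[!obs] <- 0
  S <- suppressWarnings(stats::cor(R))
  S[!is.finite(S)] <- 0
  dd <- sqrt(pmax(2 * (1 - S), 0))
  zeta <- suppressWarnings(stats::cmdscale(dd, k = K))
  if (!is.matrix(zeta) || ncol(zeta) < K) {
    zeta <- cbind(zeta, matrix(0, nrow(dd), K - ncol(zeta)))
  }
  rescale <- function(m, sd_target = 0.5) {
    s <- apply(m, 2, stats::sd)
    s[s < 1e-8] <- 1
    sweep(sweep(m, 2, colMeans(m)), 2, s / sd_target, "/")
  }
  zeta <- rescale(zeta)
  xi <- R %*% zeta / ncol(v)   # attracted to positive-residual items
  xi <- rescale(xi)
  list(xi = xi, zeta = zeta)
}

.fit_mcmc <- function(Y, config, run, use_distance, updates, verbose) {
  Y <- as_response_matrix(Y)
  v <- Y$values
  deg_row <- rowSums(v == 1L & Y$observed) %in%
    c(0L, rowSums(Y$observed))
  deg_col <- colSums(v == 1L & Y$observed) %in%
    c(0L, colSums(Y$observed))
  if (any(deg_row)) warning(sprintf(
    "%d person(s) with all-0 or all-1 responses; their abilities are weakly identified",
    sum(deg_row)))
  if (any(deg_col)) warning(sprintf(
    "%d item(s) with all-0 or all-1 responses; their intercepts are weakly identified",
    sum(deg_col)))

  Ymat <- v; Ymat[!Y$observed] <- 0L
  storage.mode(Ymat) <- "double"
  Mmat <- matrix(as.double(Y$observed), nrow(v), ncol(v))

  prior <- list(sigma_b = config$sigma_b,
                sigma_cauchy_scale = config$sigma_cauchy_scale,
                cauchy_on_sd = config$cauchy_on == "sd",
                mu_spike = config$mu_spike, mu_slab = config$mu_slab,
                sd_spike = config$sd_spike, sd_slab = config$sd_slab,
                slab_prior_weight = config$slab_prior_weight)
  ctrl <- c(updates, list(adapt_batch = run$adapt_batch,
                          temper_floor = run$temper_floor %||% 0.7))

  set.seed(run$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, run$n_chains)
  t0 <- proc.time()[["elapsed"]]
  chains <- vector("list", run$n_chains)
  for (ch in seq_len(run$n_chains)) {
    set.seed(chain_seeds[ch])
    init <- .init_state(Y, config, ch)
    out <- lsirm_mcmc_cpp(Ymat, Mmat, config$K,
                          init$theta, init$b, init$sigma2, init$log_lambda,
                          init$xi, init$zeta,
                          run$n_iter, run$n_burnin, use_distance,
                          prior, ctrl)
    colnames(out$theta) <- Y$person_ids
    colnames(out$b) <- Y$item_ids
    for (nm in c("sigma2", "log_lambda", "log_lik", "log_post"))
      out[[nm]] <- as.numeric(out[[nm]])
    chains[[ch]] <- out
    if (verbose) message(sprintf("chain %d/%d done", ch, run$n_chains))
  }
  structure(
    list(chains = chains, config = config, run = run, response = Y,
         model = if (use_distance) "lsirm" else "rasch",
         chain_seeds = chain_seeds,
         elapsed = proc.time()[["elapsed"]] - t0),
    class = "lsirt_fit")
}

.all_updates <- function(...) {
  u <- list(update_theta = TRUE, update_b = TRUE, update_sigma2 = TRUE,
            update_lambda = TRUE, update_xi = TRUE, update_zeta = TRUE)
  mod <- list(...)
  u[names(mod)] <- mod
  u
}

#' Fit the latent space item response model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs targeting the joint posterior of
#' abilities, item intercepts, ability variance, log distance weight and
#' latent positions, with the spike/slab indicator marginalized out.  The
#' `log_lambda` block alternates a random-walk proposal with an independence
#' proposal drawn from the mixture prior so the chain can hop between the
#' spike (Rasch) and slab (latent space) basins.
#'
#' Non-convergence is never an error: inspect [convergence()] afterwards.
#'
#' @param Y a [response_matrix()] or plain 0/1 matrix (NA = missing).
#' @param config a [model_config()].
#' @param run a [run_config()].
#' @param updates named list overriding which parameter blocks are sampled
#'   (e.g. `list(update_sigma2 = FALSE)` keeps `sigma2` fixed at its starting
#'   value); mainly for validation studies.
#' @param verbose print per-chain progress.
#' @return An object of class `lsirt_fit` holding per-chain retained draws
#'   (`theta`, `b`, `sigma2`, `log_lambda`, position arrays `xi`, `zeta`,
#'   per-draw `log_lik` and joint `log_post`), the configurations and the
#'   response data.
#' @seealso [fit_rasch()], [align_posterior()], [slab_probability()],
#'   [convergence()]
#' @export
fit_lsirm <- function(Y, config = model_config(), run = run_config(),
                      updates = list(), verbose = FALSE) {
  .fit_mcmc(Y, config, run, use_distance = TRUE,
            updates = do.call(.all_updates, updates), verbose = verbose)
}

#' Fit the Rasch baseline model by MCMC
#'
#' Same machinery as [fit_lsirm()] with the distance term removed: no latent
#' positions, no distance weight.
#'
#' @inheritParams fit_lsirm
#' @export
fit_rasch <- function(Y, config = model_config(), run = run_config(),
                      updates = list(), verbose = FALSE) {
  .fit_mcmc(Y, config, run, use_distance = FALSE,
            updates = do.call(.all_updates, updates), verbose = verbose)
}

#' @export
print.lsirt_fit <- function(x, ...) {
  P <- length(x$response$person_ids); I <- length(x$response$item_ids)
  cat(sprintf("<lsirt_fit> %s model, %d persons x %d items\n",
              x$model, P, I))
  cat(sprintf("  %d chain(s) x %d retained draws (%.1fs)\n",
              x$run$n_chains, x$run$n_iter - x$run$n_burnin, x$elapsed))
  if (x$model == "lsirm")
    cat(sprintf("  posterior P(slab) = %.3f, lambda_hat = %.3f\n",
                slab_probability(x), lambda_hat(x)))
  invisible(x)
}

# pooled draws of a scalar/vector parameter across chains
.pooled <- function(fit, what) {
  do.call(rbind, lapply(fit$chains, function(ch) {
    x <- ch[[what]]
    if (is.matrix(x)) x else matrix(x, ncol = 1)
  }))
}

#' Posterior probability of the slab component
#'
#' Monte Carlo estimate of \eqn{P(\delta = 1 \mid Y)}: the average, over
#' pooled retained draws, of the slab responsibility evaluated at each
#' sampled `log_lambda`.  Values near 1 indicate substantial conditional
#' dependence; values near 0 say the Rasch model suffices.
#'
#' @param fit an `lsirt_fit` from [fit_lsirm()].
#' @param config optional [model_config()]; defaults to the one used to fit.
#' @export
slab_probability <- function(fit, config = fit$config) {
  if (fit$model != "lsirm") stop("slab probability is defined for LSIRM fits")
  ll <- as.numeric(.pooled(fit, "log_lambda"))
  mean(slab_responsibility(ll, config))
}

#' Posterior mean of the distance weight on the natural scale
#' @param fit an `lsirt_fit`.
#' @export
lambda_hat <- function(fit) {
  if (fit$model != "lsirm") return(0)
  mean(exp(as.numeric(.pooled(fit, "log_lambda"))))
}

#' Split R-hat (potential scale reduction factor)
#'
#' Each chain is split in half, then the usual between/within variance ratio
#' \eqn{\sqrt{((n-1)/n\,W + B/n) / W}} is computed over the 2m half-chains.
#' Values near 1 indicate the chains agree.
#'
#' @param draws a matrix with one column per chain, or a list of equal-length
#'   numeric vectors (one per chain).
#' @return scalar R-hat.
#' @export
split_rhat <- function(draws) {
  if (is.list(draws) && !is.data.frame(draws))
    draws <- do.call(cbind, draws)
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("split R-hat needs at least 2 chains")
  n <- nrow(draws)
  half <- floor(n / 2)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(half), j], draws[(n - half + 1):n, j])))
  m <- ncol(halves); nn <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Convergence summary over identified scalar parameters
#'
#' Computes split R-hat for every ability, every item intercept, the ability
#' variance and (for LSIRM fits) `log_lambda`.  Raw position coordinates are
#' excluded: they are identified only up to a rigid transform, so chains may
#' legitimately disagree about them before Procrustes alignment.
#'
#' @param fit an `lsirt_fit`.
#' @param cutoff R-hat threshold (default 1.1).
#' @return An object of class `lsirt_convergence`: data frame `rhat`
#'   (parameter, value), the cutoff, and logical `converged`.
#' @export
convergence <- function(fit, cutoff = 1.1) {
  if (fit$run$n_chains < 2L) stop("convergence assessment needs >= 2 chains")
  per_chain <- function(what) lapply(fit$chains, function(ch) ch[[what]])
  rh <- c()
  th <- per_chain("theta")
  for (j in seq_len(ncol(th[[1]])))
    rh[paste0("theta[", fit$response$person_ids[j], "]")] <-
      split_rhat(lapply(th, function(m) m[, j]))
  bb <- per_chain("b")
  for (j in seq_len(ncol(bb[[1]])))
    rh[paste0("b[", fit$response$item_ids[j], "]")] <-
      split_rhat(lapply(bb, function(m) m[, j]))
  rh["sigma2"] <- split_rhat(per_chain("sigma2"))
  if (fit$model == "lsirm")
    rh["log_lambda"] <- split_rhat(per_chain("log_lambda"))
  out <- data.frame(parameter = names(rh), rhat = unname(rh),
                    row.names = NULL)
  structure(list(rhat = out, cutoff = cutoff,
                 converged = all(out$rhat < cutoff)),
            class = "lsirt_convergence")
}

#' @export
print.lsirt_convergence <- function(x, ...) {
  cat(sprintf("<lsirt_convergence> max R-hat = %.4f (cutoff %.2f): %s\n",
              max(x$rhat$rhat), x$cutoff,
              if (x$converged) "all converged" else "NOT all converged"))
  invisible(x)
}

#' Posterior summaries of the scalar parameters
#'
#' Posterior means and central 95% credible intervals for every ability,
#' item intercept, the ability variance and the distance weight.  The
#' distance weight is summarized on the natural scale, i.e. draws are
#' exponentiated before averaging.
#'
#' @param object an `lsirt_fit`.
#' @param prob interval mass (default 0.95).
#' @param ... unused.
#' @return data frame with columns `parameter`, `mean`, `sd`, `lower`,
#'   `upper`.
#' @export
summary.lsirt_fit <- function(object, prob = 0.95, ...) {
  a <- (1 - prob) / 2
  smry <- function(x, name) data.frame(
    parameter = name, mean = mean(x), sd = stats::sd(x),
    lower = unname(stats::quantile(x, a)),
    upper = unname(stats::quantile(x, 1 - a)))
  th <- .pooled(object, "theta"); bb <- .pooled(object, "b")
  out <- rbind(
    do.call(rbind, lapply(seq_len(ncol(th)), function(j)
      smry(th[, j], paste0("theta[", object$response$person_ids[j], "]")))),
    do.call(rbind, lapply(seq_len(ncol(bb)), function(j)
      smry(bb[, j], paste0("b[", object$response$item_ids[j], "]")))),
    smry(as.numeric(.pooled(object, "sigma2")), "sigma2"))
  if (object$model == "lsirm")
    out <- rbind(out,
                 smry(exp(as.numeric(.pooled(object, "log_lambda"))), "lambda"))
  rownames(out) <- NULL
  out
}

#' Posterior mean abilities
#' @param fit an `lsirt_fit`.
#' @return named numeric vector, one entry per person.
#' @export
theta_hat <- function(fit) colMeans(.pooled(fit, "theta"))

#' Posterior mean item intercepts (easiness parameterization)
#' @param fit an `lsirt_fit`.
#' @param difficulty if `TRUE`, return `-b` (difficulty) instead.
#' @export
b_hat <- function(fit, difficulty = FALSE) {
  out <- colMeans(.pooled(fit, "b"))
  if (difficulty) -out else out
}
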