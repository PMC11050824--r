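# Shared oracles and reference values for the test suite.

# Published interaction-map worked example: seven item-cluster centers in a
# two-dimensional latent space.
ref_centers <- rbind(
  c1 = c(0.168, -0.174),
  c2 = c(-0.207, -0.733),
  c3 = c(-0.685, 0.120),
  c4 = c(-1.828, 0.529),
  c5 = c(0.758, 2.065),
  c6 = c(1.613, -0.471),
  c7 = c(1.570, -1.840))

# Printed pairwise inter-cluster distances (upper triangle, 21 values) and
# each cluster's printed mean distance to the others.
ref_cluster_dist <- rbind(
  c(NA, 0.673, 0.902, 2.116, 2.316, 1.476, 2.178),
  c(NA, NA,    0.977, 2.054, 2.960, 1.840, 2.094),
  c(NA, NA,    NA,    1.214, 2.422, 2.373, 2.988),
  c(NA, NA,    NA,    NA,    3.008, 3.584, 4.143),
  c(NA, NA,    NA,    NA,    NA,    2.677, 3.989),
  c(NA, NA,    NA,    NA,    NA,    NA,    1.370),
  c(NA, NA,    NA,    NA,    NA,    NA,    NA))
ref_cluster_mean <- c(1.601, 1.766, 1.813, 2.686, 2.895, 2.220, 2.794)

# Printed per-person worked example: person id, ability, position, the seven
# person-to-cluster-center distances and observed accuracy.
ref_persons <- data.frame(
  id = c("64", "1359", "1653", "1655"),
  theta = c(1.043, 1.155, 1.227, 1.060),
  x1 = c(-1.227, -1.285, 1.015, 1.424),
  x2 = c(0.656, 1.016, -1.775, -0.976))
ref_person_cluster <- rbind(
  c(1.622, 1.723, 0.762, 0.615, 2.434, 3.055, 3.749),
  c(1.877, 2.054, 1.078, 0.730, 2.296, 3.257, 4.038),
  c(1.812, 1.607, 2.546, 3.660, 3.849, 1.435, 0.559),
  c(1.491, 1.650, 2.377, 3.584, 3.113, 0.539, 0.877))

# Independent Rasch log-likelihood oracle (no distance machinery).
rasch_ll_oracle <- function(y, obs, theta, b) {
  eta <- outer(theta, b, "+")
  sum(stats::dbinom(y[obs], 1, stats::plogis(eta)[obs], log = TRUE))
}

# Tetrachoric correlation of two binary vectors by maximum likelihood on the
# 2x2 table, using a one-dimensional integral for the bivariate normal
# orthant probability (no extra dependencies).
tetrachoric_cor <- function(x, y) {
  h <- stats::qnorm(1 - mean(x)); k <- stats::qnorm(1 - mean(y))
  p11 <- mean(x == 1 & y == 1)
  orthant <- function(rho) {
    f <- function(z) stats::dnorm(z) *
      stats::pnorm((rho * z - k) / sqrt(1 - rho^2), lower.tail = FALSE)
    stats::integrate(f, h, Inf, rel.tol = 1e-8)$value
  }
  stats::optimize(function(r) (orthant(r) - p11)^2,
                  interval = c(-0.99, 0.99))$minimum
}

# Minimal hand-built lsirt_fit (single chain of supplied draws) for testing
# summary operations without running the sampler.
fake_fit <- function(theta, b, sigma2, log_lambda, xi = NULL, zeta = NULL,
                     log_post = NULL, model = "lsirm") {
  n <- nrow(theta)
  pid <- paste0("p", seq_len(ncol(theta)))
  iid <- paste0("i", seq_len(ncol(b)))
  colnames(theta) <- pid; colnames(b) <- iid
  ch <- list(theta = theta, b = b, sigma2 = sigma2, log_lambda = log_lambda,
             xi = xi, zeta = zeta, log_lik = rep(0, n),
             log_post = log_post %||% rep(0, n))
  structure(
    list(chains = list(ch), config = model_config(),
         run = run_config(n_chains = 1L, n_iter = n + 1L, n_burnin = 1L),
         response = list(person_ids = pid, item_ids = iid),
         model = model, chain_seeds = 1L, elapsed = 0),
    class = "lsirt_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
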