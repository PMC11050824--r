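test_that("response_matrix validates its input", {
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  Y <- response_matrix(y)
  expect_equal(dim(Y), c(2L, 2L))
  expect_error(response_matrix(matrix(2, 2, 2)), "non-binary")
  expect_error(response_matrix(matrix(1, 1, 2)))
  expect_error(response_matrix(matrix(NA_real_, 2, 2)))
  m <- y; m[1, ] <- NA
  expect_error(response_matrix(m))
  expect_error(response_matrix(y, person_ids = c("a", "a")), "duplicate")
})

test_that("euclidean_distance matches hand values", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1.3, -2), c(1.3, -2)), 0)
  expect_error(euclidean_distance(c(0, 0), c(1, 2, 3)))
})

test_that("linear_predictor matches hand values", {
  expect_equal(linear_predictor(1, -0.5, 2, c(0, 0), c(0, 0.25)), 0)
  expect_equal(linear_predictor(0, 0, 1, c(0, 0), c(3, 4)), -5)
  expect_equal(linear_predictor(0, 0, 0, c(1, 1), c(9, 9)), 0)
  expect_error(linear_predictor(0, 0, -1, c(0, 0), c(0, 0)))
})

test_that("log_likelihood: closed-form cases", {
  P <- 4L; I <- 3L
  y <- matrix(rep(c(0, 1), length.out = P * I), P, I)
  st <- param_state(rep(0, P), rep(0, I), 1, -Inf,
                    matrix(0, P, 2), matrix(0, I, 2))
  expect_equal(log_likelihood(y, st), P * I * log(0.5))

  # scalar oracle on a grid of predictors (all-ones 2x2, b = 0, theta = eta)
  for (eta in seq(-4, 4, by = 0.5)) {
    st2 <- param_state(c(eta, eta), c(0, 0), 1, -Inf,
                       matrix(0, 2, 2), matrix(0, 2, 2))
    expect_equal(log_likelihood(matrix(1, 2, 2), st2),
                 4 * log(1 / (1 + exp(-eta))), tolerance = 1e-12)
  }
})

test_that("log_likelihood ignores unobserved cells", {
  y <- matrix(c(1, 0, NA, 1), 2, 2)
  st <- param_state(c(0.3, -0.2), c(0.1, 0.4), 1, -Inf,
                    matrix(0, 2, 2), matrix(0, 2, 2))
  eta <- outer(st$theta, st$b, "+")
  obs <- !is.na(y)
  manual <- sum(ifelse(y == 1, log(plogis(eta)), log(plogis(-eta)))[obs])
  expect_equal(log_likelihood(y, st), manual)
})

test_that("Rasch reduction: lambda = 0 equals an independent Rasch oracle", {
  set.seed(101)
  for (r in 1:20) {
    P <- sample(3:12, 1); I <- sample(3:10, 1)
    y <- matrix(rbinom(P * I, 1, 0.5), P, I)
    y[1, 1] <- 1L; y[2, 1] <- 0L  # keep rows/cols non-degenerate enough
    theta <- rnorm(P); b <- rnorm(I)
    st <- param_state(theta, b, 1, -Inf,
                      matrix(rnorm(P * 2), P, 2), matrix(rnorm(I * 2), I, 2))
    expect_equal(log_likelihood(y, st),
                 rasch_ll_oracle(y, !is.na(y), theta, b), tolerance = 1e-10)
  }
})

test_that("log_likelihood is invariant under rigid transforms of positions", {
  set.seed(7)
  P <- 6L; I <- 5L
  y <- matrix(rbinom(P * I, 1, 0.5), P, I); y[1, 1] <- 1L; y[2, 1] <- 0L
  xi <- matrix(rnorm(P * 2), P, 2); zeta <- matrix(rnorm(I * 2), I, 2)
  st <- param_state(rnorm(P), rnorm(I), 1, 0.3, xi, zeta)
  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  shift <- c(2, -3)
  mv <- function(m) sweep(m %*% R, 2, shift, "+")
  st2 <- param_state(st$theta, st$b, 1, 0.3, mv(xi), mv(zeta))
  expect_equal(log_likelihood(y, st), log_likelihood(y, st2),
               tolerance = 1e-12)
})

test_that("mixture midpoint: equal component densities, responsibility 1/2", {
  cfg <- model_config()
  mid <- (cfg$mu_spike + cfg$mu_slab) / 2  # -2.25
  expect_equal(dnorm(mid, cfg$mu_spike, 1), dnorm(mid, cfg$mu_slab, 1))
  expect_equal(slab_responsibility(mid, cfg), 0.5)
  expect_gt(slab_responsibility(0.5, cfg), 0.99)
  expect_lt(slab_responsibility(-5, cfg), 0.01)
  # monotone increasing
  g <- seq(-6, 2, by = 0.25)
  expect_true(all(diff(slab_responsibility(g, cfg)) > 0))
})

test_that("log_prior is finite and responds to each block", {
  cfg <- model_config()
  st <- param_state(c(0.1, -0.2), c(0, 0.3), 1.5, 0.2,
                    matrix(0.1, 2, 2), matrix(-0.1, 2, 2))
  lp <- log_prior(st, cfg)
  expect_true(is.finite(lp))
  # mixture term matches a direct log-sum-exp computation
  direct <- log(0.5 * dnorm(0.2, -5, 1) + 0.5 * dnorm(0.2, 0.5, 1))
  st_rasch <- st; st_rasch$log_lambda <- -Inf
  pos_terms <- sum(dnorm(st$xi, log = TRUE)) + sum(dnorm(st$zeta, log = TRUE))
  expect_equal(lp - log_prior(st_rasch, cfg), direct + pos_terms)
  # half-Cauchy on the SD differs from half-Cauchy on the variance
  expect_false(isTRUE(all.equal(
    log_prior(st, model_config(cauchy_on = "sd")), lp)))
})

test_that("slab prior moments match the published closed forms", {
  m <- slab_prior_moments()
  slab <- m[m$component == "slab", ]
  spike <- m[m$component == "spike", ]
  # printed values are 3-d.p. roundings of the closed forms
  expect_lt(abs(slab$mean - 2.718), 0.005)
  expect_lt(abs(slab$mode - 0.607), 0.005)
  expect_lt(abs(slab$sd - 3.565), 0.005)
  expect_lt(abs(spike$mean - 0.011), 0.0005)
  expect_lt(abs(spike$mode - 0.002), 0.0005)
  expect_lt(abs(spike$sd - 0.015), 0.0005)
  # against the generic lognormal formulas
  lm <- lognormal_moments(0.5, 1)
  expect_equal(slab$mean, lm$mean)
})
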