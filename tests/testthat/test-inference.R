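small_run <- function(seed = 1L, n_iter = 300L, n_burnin = 100L,
                      n_chains = 2L)
  run_config(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
             seed = seed)

test_that("fits are deterministic in the master seed", {
  sim <- simulate_lsirm(25, 8, seed = 41)
  f1 <- suppressWarnings(fit_lsirm(sim$responses, run = small_run(7)))
  f2 <- suppressWarnings(fit_lsirm(sim$responses, run = small_run(7)))
  expect_identical(f1$chains[[1]]$theta, f2$chains[[1]]$theta)
  expect_identical(f1$chains[[2]]$log_lambda, f2$chains[[2]]$log_lambda)
  f3 <- suppressWarnings(fit_lsirm(sim$responses, run = small_run(8)))
  expect_false(identical(f1$chains[[1]]$theta, f3$chains[[1]]$theta))
})

test_that("draw containers have the documented shapes", {
  sim <- simulate_lsirm(12, 6, seed = 42)
  fit <- suppressWarnings(fit_lsirm(sim$responses, run = small_run()))
  ch <- fit$chains[[1]]
  expect_equal(dim(ch$theta), c(200L, 12L))
  expect_equal(dim(ch$b), c(200L, 6L))
  expect_equal(length(ch$sigma2), 200L)
  expect_equal(dim(ch$xi), c(12L, 2L, 200L))
  expect_equal(dim(ch$zeta), c(6L, 2L, 200L))
  expect_equal(colnames(ch$theta), sim$responses$person_ids)
  expect_true(all(is.finite(ch$log_post)))
  # stored log_post equals log_likelihood + log_prior recomputed in R
  j <- 50L
  st <- param_state(ch$theta[j, ], ch$b[j, ], ch$sigma2[j],
                    ch$log_lambda[j], ch$xi[, , j], ch$zeta[, , j])
  expect_equal(ch$log_post[j],
               log_likelihood(sim$responses, st) + log_prior(st, fit$config),
               tolerance = 1e-8)
  expect_equal(ch$log_lik[j], log_likelihood(sim$responses, st),
               tolerance = 1e-8)
})

test_that("an all-correct person sits above an all-incorrect person", {
  set.seed(43)
  y <- matrix(rbinom(20 * 8, 1, 0.5), 20, 8)
  y[1, ] <- 1L
  y[2, ] <- 0L
  fit <- suppressWarnings(fit_rasch(y, run = small_run(seed = 44)))
  th <- theta_hat(fit)
  expect_gt(th[1], th[2])
})

test_that("degenerate rows and columns warn but do not fail", {
  y <- matrix(rbinom(10 * 6, 1, 0.5), 10, 6)
  y[1, ] <- 1L
  expect_warning(fit_rasch(y, run = small_run(seed = 45)), "all-0 or all-1")
})

test_that("split_rhat oracles", {
  set.seed(46)
  expect_true(abs(split_rhat(list(rnorm(5000), rnorm(5000))) - 1) < 0.02)
  expect_gt(split_rhat(list(rnorm(500, 0), rnorm(500, 10))), 5)
  # identical copies: between-chain variance only reflects within-series
  # sampling noise across the two halves
  x <- rnorm(400)
  expect_lt(split_rhat(list(x, x)), 1.02)
  expect_error(split_rhat(matrix(1:10, ncol = 1)), "2 chains")
})

test_that("convergence() covers the identified scalars only", {
  sim <- simulate_lsirm(10, 5, seed = 47)
  fit <- suppressWarnings(fit_lsirm(sim$responses, run = small_run()))
  cv <- convergence(fit)
  expect_setequal(
    cv$rhat$parameter,
    c(paste0("theta[", sim$responses$person_ids, "]"),
      paste0("b[", sim$responses$item_ids, "]"), "sigma2", "log_lambda"))
  expect_true(all(cv$rhat$rhat >= 1 - 1e-8))
  expect_equal(cv$converged, all(cv$rhat$rhat < 1.1))
  one <- suppressWarnings(fit_lsirm(sim$responses,
                                    run = small_run(n_chains = 1L)))
  expect_error(convergence(one), "2 chains")
})

test_that("slab_probability oracles on constructed draws", {
  n <- 10L
  mk <- function(ll) fake_fit(matrix(0, n, 2), matrix(0, n, 2),
                              rep(1, n), ll,
                              xi = array(0, c(2, 2, n)),
                              zeta = array(0, c(2, 2, n)))
  expect_equal(slab_probability(mk(rep(-2.25, n))), 0.5)
  expect_gt(slab_probability(mk(rep(0.5, n))), 0.99)
  r <- slab_responsibility(c(-5, 0.5))
  expect_equal(slab_probability(mk(rep(c(-5, 0.5), n / 2))),
               mean(r))
  # lambda_hat is the mean of exponentiated draws
  expect_equal(lambda_hat(mk(rep(log(2), n))), 2)
})

test_that("posterior summaries: means and interval edge cases", {
  n <- 100L
  fit <- fake_fit(matrix(1:100, n, 1), matrix(5, n, 1),
                  rep(1, n), rep(0, n),
                  xi = array(0, c(1, 2, n)), zeta = array(0, c(1, 2, n)))
  s <- summary(fit)
  expect_equal(s$mean[s$parameter == "theta[p1]"], 50.5)
  # constant draws give a zero-width interval
  brow <- s[s$parameter == "b[i1]", ]
  expect_equal(brow$mean, 5)
  expect_equal(brow$lower, brow$upper)
  expect_true("lambda" %in% s$parameter)
})

test_that("rasch fits have no distance machinery", {
  sim <- simulate_rasch(15, 6, seed = 48)
  fit <- suppressWarnings(fit_rasch(sim$responses, run = small_run()))
  expect_equal(fit$model, "rasch")
  expect_equal(lambda_hat(fit), 0)
  expect_error(slab_probability(fit), "LSIRM")
  expect_error(select_reference(fit), "positions")
  expect_false("lambda" %in% summary(fit)$parameter)
})

test_that("update overrides freeze the requested blocks", {
  sim <- simulate_lsirm(10, 5, seed = 49)
  fit <- suppressWarnings(fit_lsirm(
    sim$responses, run = small_run(n_chains = 1L),
    updates = list(update_b = FALSE, update_sigma2 = FALSE)))
  ch <- fit$chains[[1]]
  expect_equal(max(apply(ch$b, 2, sd)), 0)
  expect_equal(sd(ch$sigma2), 0)
  expect_gt(max(apply(ch$theta, 2, sd)), 0)
})

test_that("item intercepts are recovered on Rasch data at P = 500", {
  sim <- simulate_rasch(500, 20, seed = 50)
  fit <- suppressWarnings(fit_rasch(sim$responses,
                                    run = run_config(seed = 51)))
  expect_gt(cor(b_hat(fit), sim$b), 0.95)
  expect_equal(b_hat(fit, difficulty = TRUE), -b_hat(fit))
})
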