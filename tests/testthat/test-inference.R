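test_that("fitting from the truth with exact data converges immediately", {
  spec <- bd_surrogate_spec(order = 2)
  fit <- fit_parameters(spec, c(0.3, 0.4), list(truth = c(0.3, 0.4)))
  expect_lt(fit$cost, 1e-10)
  expect_lte(fit$n_iterations, 2)
  expect_true(all(fit$rel_errors < 1e-6))
})

test_that("fitting is deterministic and the cost trace is non-increasing", {
  spec <- dim_surrogate_spec(order = 2)
  c_init <- c(3e-3, 0.1)
  f1 <- fit_parameters(spec, c_init)
  f2 <- fit_parameters(spec, c_init)
  expect_identical(f1$c_hat, f2$c_hat)
  expect_identical(f1$cost_trace, f2$cost_trace)
  expect_true(all(diff(f1$cost_trace) <= 1e-12))
  expect_true(all(f1$c_hat > 0))
})

test_that("log-scale fitting recovers the same optimum as linear scale", {
  spec <- dim_surrogate_spec(order = 2)
  c_init <- c(3e-3, 0.1)
  lin <- fit_parameters(spec, c_init)
  lg <- fit_parameters(spec, c_init, list(scale = "log"))
  expect_equal(lg$c_hat, lin$c_hat, tolerance = 1e-4)
})

test_that("prior-only Metropolis chains reproduce the Gamma prior", {
  shape <- c(2, 3); rate <- c(4, 2)
  chain <- mcmc_metropolis(NULL, priors = list(shape = shape, rate = rate),
                           c_init = shape / rate, n_steps = 20000,
                           proposal_sd = 0.5 * shape / rate,
                           burn_in = 4000, seed = 5)
  sm <- chain_summary(chain)
  for (i in 1:2) {
    st <- sm$stats[[i]]
    expect_lt(abs(st$mean - shape[i] / rate[i]), 3 * st$mcse_mean)
    expect_lt(abs(st$sd^2 - shape[i] / rate[i]^2), 3 * st$mcse_var)
  }
})

test_that("Metropolis sampling is reproducible and degenerates gracefully", {
  priors <- list(shape = 2, rate = 4)
  c1 <- mcmc_metropolis(NULL, priors, c_init = 0.5, n_steps = 2000,
                        burn_in = 100, seed = 9)
  c2 <- mcmc_metropolis(NULL, priors, c_init = 0.5, n_steps = 2000,
                        burn_in = 100, seed = 9)
  expect_identical(c1$samples, c2$samples)
  expect_true(all(c1$samples > 0))
  expect_true(c1$acceptance_rate >= 0 && c1$acceptance_rate <= 1)

  # vanishing proposal scale: every proposal is accepted, chain barely moves
  c3 <- mcmc_metropolis(NULL, priors, c_init = 0.5, n_steps = 1000,
                        proposal_sd = 1e-12, burn_in = 0, seed = 2)
  expect_gt(c3$acceptance_rate, 0.999)
  expect_lt(diff(range(c3$samples)), 1e-9)
})

test_that("chain summaries handle degenerate chains and linear combinations", {
  chain <- structure(list(
    samples = matrix(rep(c(0.3, 0.4), each = 500), 500, 2,
                     dimnames = list(NULL, c("c1", "c2"))),
    log_target_trace = rep(0, 500), acceptance_rate = 0, burn_in = 100,
    seed = 1, priors = list(shape = 2, rate = 2), proposal_sd = c(1, 1)),
    class = "chain")
  sm <- chain_summary(chain, combos = list("c1-c2" = c(1, -1)))
  expect_equal(sm$stats$c1$sd, 0)
  expect_equal(sum(sm$stats$c1$hist_counts > 0), 1)
  expect_equal(sm$stats[["c1-c2"]]$mean, -0.1)
})

test_that("failing likelihood evaluations are treated as rejections", {
  bad_target <- function(cc) if (cc[1] > 0.6) stop("boom") else 0
  expect_warning(
    chain <- mcmc_metropolis(bad_target, list(shape = 2, rate = 4),
                             c_init = 0.5, n_steps = 500, proposal_sd = 0.2,
                             burn_in = 0, seed = 3),
    "rejected")
  expect_true(all(chain$samples[, 1] <= 0.6))
})
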