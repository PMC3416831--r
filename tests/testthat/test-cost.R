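test_that("cost vanishes at the generating parameters and equals the residual norm", {
  spec <- bd_surrogate_spec(order = 2)
  expect_lt(moment_cost(c(0.3, 0.4), spec), 1e-12)
  c0 <- c(0.5, 0.45)
  r <- moment_residuals(c0, spec)
  expect_equal(length(r), 20 + 20) # K mean entries + K variance entries
  expect_equal(moment_cost(c0, spec), sum(r^2))
})

test_that("mean-only cost is constant along the (1,1) ridge", {
  spec <- bd_surrogate_spec(order = 1, kind = "bd_analytic")
  ref <- moment_cost(c(0.45, 0.3), spec) # off-ridge reference scale
  for (s in c(-0.2, 0.3, 1.5)) {
    expect_lt(moment_cost(c(0.3, 0.4) + s, spec), 1e-10 * ref)
  }
  # the order-2 cost breaks the degeneracy
  spec2 <- bd_surrogate_spec(order = 2, kind = "bd_analytic")
  for (s in c(-0.2, 0.3, 1.5)) {
    expect_gt(moment_cost(c(0.3, 0.4) + s, spec2), 1e-3)
  }
})

test_that("weights act linearly on their residual blocks", {
  net <- builtin_model("birth_death")
  obs <- observation_operator(T = 10, K = 10, observed = 1L)
  ms <- exact_moment_system(net)
  pred <- predict_observed_moments(ms, c(0.3, 0.4), 30, obs)
  dat <- stokinfit:::as_moment_series(obs$times, pred$mean, pred$cov)
  c0 <- c(0.45, 0.35)
  sp11 <- cost_spec(net, ms, obs, dat, order = 2, weights = c(1, 1))
  sp12 <- cost_spec(net, ms, obs, dat, order = 2, weights = c(1, 2))
  sp10 <- cost_spec(net, ms, obs, dat, order = 1, weights = 1)
  cov_block <- moment_cost(c0, sp11) - moment_cost(c0, sp10)
  expect_equal(moment_cost(c0, sp12), moment_cost(c0, sp10) + 2 * cov_block,
               tolerance = 1e-10)
})

test_that("observed-moment predictions respect the splitting operator", {
  net <- builtin_model("p53")
  ms <- lna_system(net)
  c <- net$default_params
  obs_all <- observation_operator(T = 10, K = 5, observed = 1:3)
  obs_one <- observation_operator(T = 10, K = 5, observed = 3L)
  full <- predict_observed_moments(ms, c, net$x0, obs_all)
  one <- predict_observed_moments(ms, c, net$x0, obs_one)
  expect_equal(dim(one$mean), c(5, 1))
  expect_equal(dim(one$cov), c(5, 1, 1))
  # selecting after solving equals the selected block of the full solve
  expect_equal(one$mean[, 1], full$mean[, 3])
  expect_equal(one$cov[, 1, 1], full$cov[, 3, 3])
})

test_that("cost specifications are validated", {
  net <- builtin_model("birth_death")
  obs <- observation_operator(T = 10, K = 5, observed = 1L)
  ms <- exact_moment_system(net)
  pred <- predict_observed_moments(ms, c(0.3, 0.4), 30, obs)
  dat1 <- stokinfit:::as_moment_series(obs$times, pred$mean) # no covariance
  expect_error(cost_spec(net, ms, obs, dat1, order = 2), "covariance")
  expect_error(cost_spec(net, ms, obs, dat1, order = 1, weights = 0),
               "not all be zero")
  obs_bad <- observation_operator(T = 8, K = 5, observed = 1L)
  expect_error(cost_spec(net, ms, obs_bad, dat1, order = 1), "times")
})

test_that("the mean-only likelihood ignores the sample variance and prefers small model variance", {
  net <- builtin_model("birth_death")
  obs <- observation_operator(T = 10, K = 20, observed = 1L)
  ms <- moment_system(net, "bd_analytic")
  truth <- c(0.3, 0.4)
  N <- 1000
  an <- birth_death_analytic(truth, 30, obs$times)
  dat <- stokinfit:::as_moment_series(obs$times, matrix(an$mean, ncol = 1),
                                      N = N)

  # data mean == model mean: only the normalization term remains
  ll <- log_likelihood_mean_only(truth, dat, ms, obs, x0 = 30)
  expect_equal(ll, sum(-0.5 * log(2 * pi * an$variance / N)), tolerance = 1e-10)

  # along the ridge the mean is unchanged and the variance grows with c1 + c2,
  # so the likelihood increases monotonically towards the positivity boundary
  lls <- sapply(c(-0.25, 0, 0.5, 1), function(s)
    log_likelihood_mean_only(truth + s, dat, ms, obs, x0 = 30))
  expect_true(all(diff(lls) < 0))

  # more replicates sharpen the quadratic term proportionally
  datN <- stokinfit:::as_moment_series(obs$times,
                                       matrix(an$mean * 1.01, ncol = 1), N = N)
  quad <- function(NN) {
    raw <- log_likelihood_mean_only(truth, datN, ms, obs, x0 = 30, N = NN)
    raw - sum(-0.5 * log(2 * pi * an$variance / NN))
  }
  expect_equal(quad(4000) / quad(1000), 4, tolerance = 1e-8)
})
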