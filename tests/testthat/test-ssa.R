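test_that("simulation is deterministic given a seed and stops in absorbing states", {
  net <- builtin_model("birth_death")
  set.seed(99); t1 <- simulate_ssa(net, c(0.3, 0.4), 30, 10)
  set.seed(99); t2 <- simulate_ssa(net, c(0.3, 0.4), 30, 10)
  expect_identical(t1, t2)
  expect_true(all(t1$states >= 0))
  expect_equal(t1$states[, -1] - t1$states[, -ncol(t1$states)],
               matrix(net$stoich[, t1$reaction_ids], nrow = 1),
               ignore_attr = TRUE)

  # x = 0 is absorbing: no reaction can fire, the state is held to t_max
  set.seed(1)
  t0 <- simulate_ssa(net, c(0.3, 0.4), 0, 5)
  expect_true(t0$absorbed)
  expect_equal(ncol(t0$states), 1)
  expect_equal(sample_at_times(t0, c(0, 2.5, 5)), matrix(0, 3, 1))
})

test_that("trajectory sampling is right-continuous at jump times", {
  traj <- structure(list(jump_times = c(0, 1, 2), states = matrix(c(5, 6, 5), 1),
                         reaction_ids = c(1L, 2L), t_max = 3, absorbed = FALSE),
                    class = "trajectory")
  expect_equal(sample_at_times(traj, 0)[1, 1], 5)       # initial condition
  expect_equal(sample_at_times(traj, 1)[1, 1], 6)       # post-jump state
  expect_equal(sample_at_times(traj, 1.5)[1, 1], 6)
  expect_equal(sample_at_times(traj, 2)[1, 1], 5)
  expect_error(sample_at_times(traj, 4), "within")
})

test_that("pure-death extinction times follow the exponential law", {
  net <- make_network(list(
    species = "X",
    reactions = list(list(reactants = c(X = 1), products = c(X = 0),
                          law = "mass_action", rate_param = "c2")),
    params = "c2", x0 = 1))
  c2 <- 0.7
  set.seed(314)
  times <- replicate(10000, {
    tr <- simulate_ssa(net, c2, 1, 1000)
    tr$jump_times[2]
  })
  # extinction time from x0 = 1 is Exp(c2): mean 1/c2, sd 1/c2
  se <- 1 / c2 / sqrt(10000)
  expect_lt(abs(mean(times) - 1 / c2), 5 * se)
})

test_that("ensembles are reproducible and replicate substreams are stable", {
  net <- builtin_model("birth_death")
  obs <- observation_operator(T = 5, K = 5, observed = 1L)
  d1 <- simulate_ensemble(net, c(0.3, 0.4), 30, obs, N = 8, seed = 7)
  d2 <- simulate_ensemble(net, c(0.3, 0.4), 30, obs, N = 8, seed = 7)
  expect_identical(d1$values, d2$values)
  expect_equal(dim(d1$values), c(8, 5, 1))
  # per-replicate substreams: a smaller ensemble is a prefix of a larger one
  d3 <- simulate_ensemble(net, c(0.3, 0.4), 30, obs, N = 3, seed = 7)
  expect_identical(d3$values, d1$values[1:3, , , drop = FALSE])
})

test_that("dimerisation paths conserve parity and stay within [0, M]", {
  net <- builtin_model("dimerisation")
  M <- net$constants$M
  set.seed(5)
  tr <- simulate_ssa(net, net$default_params, M, 10)
  expect_true(all(tr$states >= 0 & tr$states <= M))
  expect_true(all(tr$states %% 2 == M %% 2))
})

test_that("ensemble sample means track the analytic mean (CLT band)", {
  net <- builtin_model("birth_death")
  obs <- observation_operator(T = 6, K = 3, observed = 1L)
  N <- 4000
  data <- simulate_ensemble(net, c(0.3, 0.4), 30, obs, N = N, seed = 21)
  an <- birth_death_analytic(c(0.3, 0.4), 30, obs$times)
  sm <- compute_sample_moments(data, order = 2)
  se <- sqrt(an$variance / N)
  expect_true(all(abs(sm$mean[, 1] - an$mean) < 5 * se))
})
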