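test_that("exact affine system reproduces the birth-death moment ODEs", {
  net <- builtin_model("birth_death")
  ms <- exact_moment_system(net)
  # dm/dt = (c1 - c2) m ; dv/dt = 2 (c1 - c2) v + (c1 + c2) m
  c <- c(0.3, 0.4); y <- c(12, 3.5)
  expect_equal(ms$rhs(0, y, c),
               c((c[1] - c[2]) * y[1],
                 2 * (c[1] - c[2]) * y[2] + (c[1] + c[2]) * y[1]))
  # equal rates: mean stays at x0
  tr <- solve_moment_system(ms, c(0.4, 0.4), 30, c(1, 5, 10))
  expect_equal(tr$mean[, 1], rep(30, 3), tolerance = 1e-8)
})

test_that("the exact system refuses non-affine propensities", {
  expect_error(exact_moment_system(builtin_model("dimerisation")),
               "affine propensities")
})

test_that("closure and LNA coincide with the exact system for affine networks", {
  net <- builtin_model("birth_death")
  exact <- exact_moment_system(net)
  lna <- lna_system(net)
  ncl <- normal_closure_1d(net)
  set.seed(2)
  for (i in 1:10) {
    y <- c(runif(1, 1, 60), runif(1, 0, 80))
    c <- runif(2, 0.05, 2)
    expect_equal(exact$rhs(0, y, c), lna$rhs(0, y, c), tolerance = 1e-13)
    expect_equal(exact$rhs(0, y, c), ncl$rhs(0, y, c), tolerance = 1e-13)
  }
})

test_that("normal closure is restricted to one-dimensional networks", {
  expect_error(normal_closure_1d(builtin_model("p53")), "one-dimensional")
})

test_that("pure diffusion gives linearly growing variance", {
  # +1 / -1 jumps at equal constant rate b: drift 0, diffusion 2b
  b <- 1.3
  net <- make_network(list(
    species = "X",
    reactions = list(
      list(reactants = c(X = 0), products = c(X = 1),
           law = function(x, c) c[1], kind = "affine"),
      list(reactants = c(X = 1), products = c(X = 0),
           law = function(x, c) c[1], kind = "affine")),
    params = "b", x0 = 50))
  ncl <- normal_closure_1d(net)
  tr <- solve_moment_system(ncl, b, 50, c(1, 2, 4))
  expect_equal(tr$mean[, 1], rep(50, 3), tolerance = 1e-7)
  expect_equal(tr$cov[, 1, 1], 2 * b * c(1, 2, 4), tolerance = 1e-6)
})

test_that("dimerisation closure lowers the mean relative to the macroscopic solution", {
  net <- builtin_model("dimerisation")
  ncl <- normal_closure_1d(net)
  c <- net$default_params
  # closure correction in dm/dt is -c1 * v (negative for positive variance)
  y <- c(150, 40)
  macro_drift <- sum(net$stoich[1, ] * net$propensity(150, c))
  expect_equal(ncl$rhs(0, y, c)[1], unname(macro_drift - c[1] * 40),
               tolerance = 1e-12)
  times <- c(2, 5, 10)
  closed <- solve_moment_system(ncl, c, net$x0, times)
  macro <- macroscopic_solve(net, c, net$x0, times)
  expect_true(all(closed$mean[, 1] < macro$mean[, 1]))
})

test_that("closure moments approach the exact finite CME with growing system size", {
  # closure error shrinks as the total molecule number M grows
  times <- c(2, 6)
  gaps <- sapply(c(30, 120), function(M) {
    net <- stokinfit:::.model_dimerisation(M = M)
    c <- c(1.66e-3 * 300 / M, 0.2) # keep comparable equilibrium occupancy
    cl <- solve_moment_system(normal_closure_1d(net), c, M, times)
    or <- cme_truncated_moments(net, c, M, times, M)
    max(abs(cl$mean[, 1] - or$mean[, 1]) / or$mean[, 1])
  })
  expect_lt(gaps[2], gaps[1])
})

test_that("LNA covariances stay symmetric and positive semidefinite (p53)", {
  net <- builtin_model("p53")
  ms <- lna_system(net)
  expect_equal(ms$dim, 3 + 6)
  tr <- solve_moment_system(ms, net$default_params, net$x0, seq(2, 24, by = 2))
  for (k in seq_along(tr$times)) {
    V <- tr$cov[k, , ]
    expect_equal(V, t(V))
    expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-8))
  }
  # zero fluctuation source: V stays at 0 when no reaction fires
  h0 <- propensities(net, c(0, 0, 0), net$default_params)
  expect_true(all(h0[-1] == 0)) # only constitutive production is state-free
})

test_that("moment solves are consistent across horizons and degenerate time grids", {
  net <- builtin_model("birth_death")
  ms <- exact_moment_system(net)
  full <- solve_moment_system(ms, c(0.3, 0.4), 30, c(1, 2, 3, 4))
  half <- solve_moment_system(ms, c(0.3, 0.4), 30, c(1, 2))
  expect_equal(full$mean[1:2, , drop = FALSE], half$mean, tolerance = 1e-8)
  expect_equal(full$cov[1:2, , , drop = FALSE], half$cov, tolerance = 1e-7)

  at0 <- solve_moment_system(ms, c(0.3, 0.4), 30, 1e-12)
  expect_equal(at0$mean[1, 1], 30, tolerance = 1e-9)
  expect_equal(at0$cov[1, 1, 1], 0, tolerance = 1e-9)
})

test_that("macroscopic solve matches the exact mean for affine nets and finds equilibria", {
  net <- builtin_model("birth_death")
  times <- c(1, 4, 8)
  macro <- macroscopic_solve(net, c(0.3, 0.4), 30, times)
  expect_equal(macro$mean[, 1], birth_death_analytic(c(0.3, 0.4), 30, times)$mean,
               tolerance = 1e-7)

  dnet <- builtin_model("dimerisation")
  eq <- macroscopic_solve(dnet, dnet$default_params, dnet$x0, c(50, 200))
  xstar <- eq$mean[2, 1]
  drift <- sum(dnet$stoich[1, ] * dnet$propensity(xstar, dnet$default_params))
  expect_lt(abs(drift), 1e-6)
  expect_equal(eq$mean[1, 1], xstar, tolerance = 1e-5) # already equilibrated
})

test_that("the truncated CME oracle conserves probability on closed state spaces", {
  net <- builtin_model("dimerisation")
  M <- 40
  small <- stokinfit:::.model_dimerisation(M = M)
  or <- cme_truncated_moments(small, c(0.02, 0.2), M, c(1, 3), M)
  expect_true(all(abs(or$leak) < 1e-9))
  expect_error(cme_truncated_moments(builtin_model("p53"),
                                     builtin_model("p53")$default_params,
                                     c(5, 2, 2), 1, 200),
               "states")
})

test_that("analytic birth-death moments behave correctly in the limits", {
  # t = 0 and the critical case c1 = c2
  an0 <- birth_death_analytic(c(0.5, 0.2), 17, 0)
  expect_equal(an0$mean, 17)
  expect_equal(an0$variance, 0)
  anc <- birth_death_analytic(c(0.4, 0.4), 17, c(1, 2))
  expect_equal(anc$mean, c(17, 17))
  expect_equal(anc$variance, 2 * 0.4 * 17 * c(1, 2))
  # the mean depends on c1 - c2 only; the variance does not
  s <- 0.7
  a1 <- birth_death_analytic(c(0.3, 0.4), 30, c(1, 5))
  a2 <- birth_death_analytic(c(0.3 + s, 0.4 + s), 30, c(1, 5))
  expect_equal(a1$mean, a2$mean)
  expect_true(all(a2$variance > a1$variance))
})
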