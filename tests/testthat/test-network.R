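test_that("mass-action networks are assembled with correct stoichiometry and rates", {
  bd <- make_network(list(
    species = "X",
    reactions = list(
      list(reactants = c(X = 1), products = c(X = 2),
           law = "mass_action", rate_param = "c1"),
      list(reactants = c(X = 1), products = c(X = 0),
           law = "mass_action", rate_param = "c2")),
    params = c("c1", "c2"), x0 = 30))
  expect_equal(unname(bd$stoich), matrix(c(1, -1), 1, 2))
  expect_equal(bd$prop_kinds, c("affine", "affine"))
  expect_equal(propensities(bd, 10, c(2, 1)), c(20, 10))
})

test_that("invalid network descriptions are rejected with informative errors", {
  base <- list(species = "X",
               reactions = list(list(reactants = c(X = 1), products = c(X = -1),
                                     law = "mass_action", rate_param = "c1")),
               params = "c1")
  expect_error(make_network(base), "negative reactant or product")
  base$reactions[[1]]$products <- c(X = 0)
  base$reactions[[1]]$law <- "michaelis"
  expect_error(make_network(base), "unknown propensity law")
  base$reactions[[1]]$law <- "mass_action"
  base$reactions[[1]]$rate_param <- "zzz"
  expect_error(make_network(base), "unknown rate parameter")
  base$reactions[[1]]$reactants <- c(Y = 1)
  expect_error(make_network(base), "unknown species")
})

test_that("built-in models match their published structure", {
  bd <- builtin_model("birth_death")
  expect_equal(bd$n_species, 1)
  expect_equal(bd$n_reactions, 2)
  expect_true(all(bd$prop_kinds == "affine"))

  dm <- builtin_model("dimerisation")
  expect_equal(unname(dm$stoich), matrix(c(-2, 2), 1, 2))
  expect_true("polynomial" %in% dm$prop_kinds)
  # no pair available at x = 1, dissociation rate from (M - x)/2 dimers
  M <- dm$constants$M
  expect_equal(propensities(dm, 1, c(2, 3)), c(0, 3 * (M - 1) / 2))

  p <- builtin_model("p53")
  expect_equal(p$n_species, 3)
  expect_equal(p$n_reactions, 6)
  expect_equal(sum(p$prop_kinds == "rational"), 1)
  expect_error(builtin_model("lotka"))
})

test_that("propensities are non-negative and vanish without reactants", {
  set.seed(42)
  for (name in c("birth_death", "dimerisation", "p53")) {
    net <- builtin_model(name)
    for (rep in 1:20) {
      x <- sample(0:30, net$n_species, replace = TRUE)
      c <- net$default_params * stats::runif(net$n_params, 0.2, 5)
      h <- propensities(net, x, c)
      expect_true(all(h >= 0))
    }
    # empty state: only zeroth-order reactions can fire
    h0 <- propensities(net, rep(0, net$n_species), net$default_params)
    consuming <- apply(net$stoich, 2, function(s) any(s < 0))
    expect_true(all(h0[consuming] == 0))
  }
})

test_that("mass-action propensities are homogeneous of degree one in c", {
  dm <- builtin_model("dimerisation")
  c <- dm$default_params
  expect_equal(propensities(dm, 17, 3 * c), 3 * propensities(dm, 17, c))
})

test_that("hand-coded propensity derivatives agree with finite differences", {
  set.seed(11)
  for (name in c("birth_death", "dimerisation", "p53")) {
    net <- builtin_model(name)
    for (rep in 1:5) {
      x <- stats::runif(net$n_species, 1, 40)
      c <- net$default_params * stats::runif(net$n_params, 0.5, 2)
      # d h / d x
      for (i in seq_len(net$n_species)) {
        h <- 1e-6 * max(1, x[i])
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        fd <- (net$propensity(xp, c) - net$propensity(xm, c)) / (2 * h)
        expect_equal(net$derivs$dx(x, c)[, i], unname(fd), tolerance = 1e-5)
      }
      # d h / d c
      for (p in seq_len(net$n_params)) {
        h <- 1e-6 * c[p]
        cp <- c; cp[p] <- c[p] + h
        cm <- c; cm[p] <- c[p] - h
        fd <- (net$propensity(x, cp) - net$propensity(x, cm)) / (2 * h)
        expect_equal(net$derivs$dc(x, c)[, p], unname(fd), tolerance = 1e-5)
      }
      # mixed d2 h / dx dc
      for (p in seq_len(net$n_params)) {
        h <- 1e-6 * c[p]
        cp <- c; cp[p] <- c[p] + h
        cm <- c; cm[p] <- c[p] - h
        fd <- (net$derivs$dx(x, cp) - net$derivs$dx(x, cm)) / (2 * h)
        expect_equal(net$derivs$dxdc(x, c)[, , p],
                     fd, tolerance = 1e-5, ignore_attr = TRUE)
      }
    }
  }
})

test_that("domain violations raise errors", {
  bd <- builtin_model("birth_death")
  expect_error(propensities(bd, -1, c(1, 1)), "negative state")
  expect_error(propensities(bd, 5, c(1, 0)), "strictly positive")
  expect_error(propensities(bd, c(1, 2), c(1, 1)), "length")
})
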