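#' Reaction network objects
#'
#' A `reaction_network` bundles everything the rest of the package needs to
#' know about a well-mixed stochastic reaction system: species names, the
#' stoichiometric matrix `S` (one column per reaction, entries are the net
#' change in each species' copy number when the reaction fires), a propensity
#' (hazard) function `h(x, c)` returning one non-negative rate per reaction,
#' the rate-parameter names, and a default initial state.
#'
#' Networks also carry analytic derivative functions of the propensities
#' (with respect to state and parameters) when available; these power the
#' moment-system Jacobians and the adjoint gradient. For mass-action networks
#' built with [make_network()] they are generated automatically.
#'
#' @name reaction_network
NULL

new_reaction_network <- function(species, stoich, propensity, prop_kinds,
                                 param_names, x0, derivs = NULL,
                                 constants = list(), name = "custom",
                                 default_params = NULL, sim_defaults = NULL,
                                 compiled = NULL) {
  stoich <- as.matrix(stoich)
  u <- length(species)
  v <- ncol(stoich)
  stopifnot(nrow(stoich) == u, length(prop_kinds) == v, length(x0) == u)
  structure(list(
    name = name,
    species = species,
    n_species = u,
    n_reactions = v,
    stoich = stoich,
    propensity = propensity,
    prop_kinds = prop_kinds,
    param_names = param_names,
    n_params = length(param_names),
    x0 = x0,
    derivs = derivs,
    constants = constants,
    default_params = default_params,
    sim_defaults = sim_defaults,
    compiled = compiled
  ), class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network '%s': %d species, %d reactions, %d parameters>\n",
              x$name, x$n_species, x$n_reactions, x$n_params))
  cat("  species:   ", paste(x$species, collapse = ", "), "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  cat("  propensity kinds:", paste(x$prop_kinds, collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate reaction propensities
#'
#' Evaluates the hazard functions `h_j(x, c)` of a network at a state vector
#' and a parameter vector. States must be non-negative and parameters
#' strictly positive; the returned rates are finite and non-negative, and a
#' reaction whose reactants exceed the available copies has propensity zero.
#'
#' @param net a [reaction_network].
#' @param x numeric state vector (non-negative).
#' @param c numeric parameter vector (strictly positive).
#' @return numeric vector of length `net$n_reactions`.
#' @export
propensities <- function(net, x, c) {
  stopifnot(inherits(net, "reaction_network"))
  if (length(x) != net$n_species)
    stop("state vector has length ", length(x), ", expected ", net$n_species)
  if (length(c) != net$n_params)
    stop("parameter vector has length ", length(c), ", expected ", net$n_params)
  if (any(x < 0)) stop("negative state is outside the domain of the propensities")
  if (any(c <= 0)) stop("rate parameters must be strictly positive")
  h <- net$propensity(x, c)
  if (any(!is.finite(h))) stop("non-finite propensity encountered")
  h
}

# polynomial extension of binomial counting factors used by stochastic
# mass-action kinetics: r molecules of one species give choose(x, r) pairs
.ma_factor <- function(x, r) {
  switch(as.character(r),
         "0" = 1,
         "1" = x,
         "2" = x * (x - 1) / 2,
         stop("mass-action reactant multiplicity > 2 is not supported"))
}
.ma_factor_d1 <- function(x, r) {
  switch(as.character(r), "0" = 0, "1" = 1, "2" = x - 0.5)
}
.ma_factor_d2 <- function(x, r) {
  switch(as.character(r), "0" = 0, "1" = 0, "2" = 1)
}

#' Build a reaction network from a structured description
#'
#' Constructs a validated [reaction_network] from a list describing species,
#' reactions and parameters. Each reaction gives integer reactant and product
#' counts (named by species), a propensity law (`"mass_action"`, or a custom
#' function `h(x, c)`), and for mass-action the name of its rate parameter.
#' The stoichiometric matrix is derived as products minus reactants.
#'
#' Stochastic mass-action uses the combinatorial convention: a reaction
#' consuming two copies of a species with count `x` has hazard
#' `c * x * (x - 1) / 2`.
#'
#' @param spec a list with elements `species` (character), `reactions`
#'   (list of lists with `reactants`, `products`, `law`, and `rate_param`),
#'   `params` (character vector of parameter names), and optionally `x0`.
#' @return a [reaction_network].
#' @examples
#' bd <- make_network(list(
#'   species = "X",
#'   reactions = list(
#'     list(reactants = c(X = 1), products = c(X = 2),
#'          law = "mass_action", rate_param = "c1"),
#'     list(reactants = c(X = 1), products = c(X = 0),
#'          law = "mass_action", rate_param = "c2")),
#'   params = c("c1", "c2"), x0 = 30))
#' propensities(bd, 10, c(2, 1))
#' @export
make_network <- function(spec) {
  species <- spec$species
  params <- spec$params
  u <- length(species)
  v <- length(spec$reactions)
  if (u < 1 || v < 1) stop("need at least one species and one reaction")
  stoich <- matrix(0L, u, v, dimnames = list(species, NULL))
  reac_counts <- matrix(0L, u, v)
  rate_idx <- integer(v)
  kinds <- character(v)
  custom <- vector("list", v)

  for (j in seq_len(v)) {
    rx <- spec$reactions[[j]]
    r <- p <- stats::setNames(rep(0L, u), species)
    fill <- function(target, counts) {
      for (nm in names(counts)) {
        if (!nm %in% species)
          stop("reaction ", j, " references unknown species '", nm, "'")
        target[nm] <- target[nm] + as.integer(counts[[nm]])
      }
      target
    }
    if (!is.null(rx$reactants)) r <- fill(r, rx$reactants)
    if (!is.null(rx$products)) p <- fill(p, rx$products)
    if (any(r < 0) || any(p < 0))
      stop("reaction ", j, " has a negative reactant or product count")
    stoich[, j] <- p - r
    reac_counts[, j] <- r
    if (is.function(rx$law)) {
      kinds[j] <- if (is.null(rx$kind)) "polynomial" else rx$kind
      custom[[j]] <- rx$law
    } else if (identical(rx$law, "mass_action")) {
      if (!rx$rate_param %in% params)
        stop("reaction ", j, " names unknown rate parameter '", rx$rate_param, "'")
      rate_idx[j] <- match(rx$rate_param, params)
      kinds[j] <- if (sum(r) <= 1) "affine" else "polynomial"
    } else {
      stop("reaction ", j, " has unknown propensity law '",
           as.character(rx$law), "'")
    }
  }

  has_custom <- any(!vapply(custom, is.null, logical(1)))
  propensity <- function(x, c) {
    h <- numeric(v)
    for (j in seq_len(v)) {
      if (!is.null(custom[[j]])) {
        h[j] <- custom[[j]](x, c)
      } else {
        g <- 1
        for (i in seq_len(u)) g <- g * .ma_factor(x[i], reac_counts[i, j])
        h[j] <- c[rate_idx[j]] * g
      }
    }
    h
  }

  derivs <- NULL
  if (!has_custom) {
    # analytic derivatives for pure mass-action networks
    gfun <- function(x, j) {
      g <- 1
      for (i in seq_len(u)) g <- g * .ma_factor(x[i], reac_counts[i, j])
      g
    }
    gfun_d1 <- function(x, j, i) {
      g <- .ma_factor_d1(x[i], reac_counts[i, j])
      for (l in seq_len(u)[-i]) g <- g * .ma_factor(x[l], reac_counts[l, j])
      g
    }
    gfun_d2 <- function(x, j, i, l) {
      if (i == l) {
        g <- .ma_factor_d2(x[i], reac_counts[i, j])
        for (m in seq_len(u)[-i]) g <- g * .ma_factor(x[m], reac_counts[m, j])
      } else {
        g <- .ma_factor_d1(x[i], reac_counts[i, j]) *
          .ma_factor_d1(x[l], reac_counts[l, j])
        for (m in setdiff(seq_len(u), c(i, l)))
          g <- g * .ma_factor(x[m], reac_counts[m, j])
      }
      g
    }
    np <- length(params)
    derivs <- list(
      dx = function(x, c) {
        out <- matrix(0, v, u)
        for (j in seq_len(v)) for (i in seq_len(u))
          out[j, i] <- c[rate_idx[j]] * gfun_d1(x, j, i)
        out
      },
      dc = function(x, c) {
        out <- matrix(0, v, np)
        for (j in seq_len(v)) out[j, rate_idx[j]] <- gfun(x, j)
        out
      },
      dxdx = function(x, c) {
        out <- array(0, c(v, u, u))
        for (j in seq_len(v)) for (i in seq_len(u)) for (l in seq_len(u))
          out[j, i, l] <- c[rate_idx[j]] * gfun_d2(x, j, i, l)
        out
      },
      dxdc = function(x, c) {
        out <- array(0, c(v, u, np))
        for (j in seq_len(v)) for (i in seq_len(u))
          out[j, i, rate_idx[j]] <- gfun_d1(x, j, i)
        out
      },
      dxdxdc = function(x, c) {
        out <- array(0, c(v, u, u, np))
        for (j in seq_len(v)) for (i in seq_len(u)) for (l in seq_len(u))
          out[j, i, l, rate_idx[j]] <- gfun_d2(x, j, i, l)
        out
      })
  }

  x0 <- if (is.null(spec$x0)) rep(0, u) else spec$x0
  if (length(x0) != u) stop("x0 has length ", length(x0), ", expected ", u)
  if (any(x0 < 0)) stop("x0 must be non-negative")

  compiled <- NULL
  if (!has_custom) {
    compiled <- lapply(seq_len(v), function(j)
      list(type = 0L, rate = rate_idx[j], counts = as.integer(reac_counts[, j])))
  }

  new_reaction_network(species, stoich, propensity, kinds, params, x0,
                       derivs = derivs, compiled = compiled,
                       name = if (is.null(spec$name)) "custom" else spec$name)
}

#' Built-in test models
#'
#' Returns one of three classic stochastic kinetics models, each with default
#' rate parameters, initial state and observation settings used throughout
#' the package's examples and case studies.
#'
#' \describe{
#' \item{`birth_death`}{Linear birth-death process for one species `X`:
#'   `X -> 2X` at rate `c1 * x` and `X -> 0` at rate `c2 * x`. Both
#'   propensities are affine, so the mean/variance moment equations are exact
#'   and admit a closed-form solution ([birth_death_analytic()]).}
#' \item{`dimerisation`}{Reversible dimerisation `2X -> X2`, `X2 -> 2X`.
#'   Conservation of the total monomer count `M` (monomers plus twice the
#'   dimers) reduces the state to the monomer count `x` with stoichiometry
#'   `(-2, +2)` and hazards `c1 * x * (x - 1) / 2` and `c2 * (M - x) / 2`.
#'   The forward hazard is quadratic, so moment equations need closure.}
#' \item{`p53`}{A three-species negative feedback loop between the tumor
#'   suppressor p53, the precursor transcript of its inhibitor Mdm2, and
#'   mature Mdm2: constitutive p53 production, linear p53 degradation,
#'   Mdm2-mediated p53 degradation with a saturating (rational) hazard
#'   `a_k * y * x / (x + k)`, p53-driven precursor production, precursor
#'   maturation, and linear Mdm2 degradation. The default parameter vector is
#'   a fixed synthetic choice giving the damped oscillation characteristic of
#'   this feedback loop (period about 6 time units) at copy numbers around a
#'   hundred molecules -- comfortably inside the validity regime of the
#'   linear noise approximation used for inference on this model; all
#'   inference experiments with this model are self-consistent (simulate,
#'   then recover).}
#' }
#'
#' @param name one of `"birth_death"`, `"dimerisation"`, `"p53"`.
#' @return a [reaction_network] with elements `default_params`, `x0` and
#'   `sim_defaults` (observation horizon `T`, number of observation times `K`,
#'   replicate count `N`, observed species indices).
#' @export
builtin_model <- function(name = c("birth_death", "dimerisation", "p53")) {
  name <- match.arg(name)
  switch(name,
         birth_death = .model_birth_death(),
         dimerisation = .model_dimerisation(),
         p53 = .model_p53())
}

.model_birth_death <- function() {
  derivs <- list(
    dx = function(x, c) matrix(c(c[1], c[2]), 2, 1),
    dc = function(x, c) matrix(c(x[1], 0, 0, x[1]), 2, 2),
    dxdx = function(x, c) array(0, c(2, 1, 1)),
    dxdc = function(x, c) {
      out <- array(0, c(2, 1, 2)); out[1, 1, 1] <- 1; out[2, 1, 2] <- 1; out
    },
    dxdxdc = function(x, c) array(0, c(2, 1, 1, 2)))
  new_reaction_network(
    species = "X",
    stoich = matrix(c(1, -1), 1, 2),
    propensity = function(x, c) c(c[1] * x[1], c[2] * x[1]),
    prop_kinds = c("affine", "affine"),
    param_names = c("c1", "c2"),
    x0 = 30,
    derivs = derivs,
    name = "birth_death",
    compiled = list(list(type = 0L, rate = 1L, counts = 1L),
                    list(type = 0L, rate = 2L, counts = 1L)),
    default_params = c(c1 = 0.3, c2 = 0.4),
    sim_defaults = list(T = 10, K = 20, N = 10000, observed = 1L))
}

.model_dimerisation <- function(M = 301) {
  derivs <- list(
    dx = function(x, c) matrix(c(c[1] * (x[1] - 0.5), -c[2] / 2), 2, 1),
    dc = function(x, c)
      matrix(c(x[1] * (x[1] - 1) / 2, 0, 0, (M - x[1]) / 2), 2, 2),
    dxdx = function(x, c) array(c(c[1], 0), c(2, 1, 1)),
    dxdc = function(x, c) {
      out <- array(0, c(2, 1, 2))
      out[1, 1, 1] <- x[1] - 0.5; out[2, 1, 2] <- -0.5
      out
    },
    dxdxdc = function(x, c) {
      out <- array(0, c(2, 1, 1, 2)); out[1, 1, 1, 1] <- 1; out
    })
  new_reaction_network(
    species = "X",
    stoich = matrix(c(-2, 2), 1, 2),
    propensity = function(x, c)
      c(c[1] * x[1] * (x[1] - 1) / 2, c[2] * (M - x[1]) / 2),
    prop_kinds = c("polynomial", "affine"),
    param_names = c("c1", "c2"),
    x0 = M,
    derivs = derivs,
    constants = list(M = M),
    name = "dimerisation",
    compiled = list(list(type = 0L, rate = 1L, counts = 2L),
                    list(type = 1L, rate = 2L, a0 = M / 2, a = -0.5)),
    default_params = c(c1 = 1.66e-3, c2 = 0.2),
    sim_defaults = list(T = 10, K = 20, N = 10000, observed = 1L))
}

.model_p53 <- function() {
  # parameters: b_x (p53 production), a_x (p53 degradation), a_k (maximal
  # Mdm2-mediated p53 degradation), k (saturation constant), b_y (precursor
  # production per p53), a_0 (maturation), a_y (Mdm2 degradation)
  prop <- function(x, c) {
    c(c[1],
      c[2] * x[1],
      c[3] * x[3] * x[1] / (x[1] + c[4]),
      c[5] * x[1],
      c[6] * x[2],
      c[7] * x[3])
  }
  derivs <- list(
    dx = function(x, c) {
      out <- matrix(0, 6, 3)
      out[2, 1] <- c[2]
      out[3, 1] <- c[3] * x[3] * c[4] / (x[1] + c[4])^2
      out[3, 3] <- c[3] * x[1] / (x[1] + c[4])
      out[4, 1] <- c[5]
      out[5, 2] <- c[6]
      out[6, 3] <- c[7]
      out
    },
    dc = function(x, c) {
      out <- matrix(0, 6, 7)
      out[1, 1] <- 1
      out[2, 2] <- x[1]
      out[3, 3] <- x[3] * x[1] / (x[1] + c[4])
      out[3, 4] <- -c[3] * x[3] * x[1] / (x[1] + c[4])^2
      out[4, 5] <- x[1]
      out[5, 6] <- x[2]
      out[6, 7] <- x[3]
      out
    },
    dxdx = function(x, c) {
      out <- array(0, c(6, 3, 3))
      out[3, 1, 1] <- -2 * c[3] * x[3] * c[4] / (x[1] + c[4])^3
      out[3, 1, 3] <- out[3, 3, 1] <- c[3] * c[4] / (x[1] + c[4])^2
      out
    },
    dxdc = function(x, c) {
      out <- array(0, c(6, 3, 7))
      out[2, 1, 2] <- 1
      out[3, 1, 3] <- x[3] * c[4] / (x[1] + c[4])^2
      out[3, 1, 4] <- c[3] * x[3] * (x[1] - c[4]) / (x[1] + c[4])^3
      out[3, 3, 3] <- x[1] / (x[1] + c[4])
      out[3, 3, 4] <- -c[3] * x[1] / (x[1] + c[4])^2
      out[4, 1, 5] <- 1
      out[5, 2, 6] <- 1
      out[6, 3, 7] <- 1
      out
    },
    dxdxdc = NULL)
  new_reaction_network(
    species = c("p53", "premdm2", "mdm2"),
    stoich = matrix(c(1, 0, 0,
                      -1, 0, 0,
                      -1, 0, 0,
                      0, 1, 0,
                      0, -1, 1,
                      0, 0, -1), 3, 6),
    propensity = prop,
    prop_kinds = c("affine", "affine", "rational", "affine", "affine", "affine"),
    param_names = c("b_x", "a_x", "a_k", "k", "b_y", "a_0", "a_y"),
    x0 = c(80, 32, 32),
    derivs = derivs,
    name = "p53",
    compiled = list(
      list(type = 0L, rate = 1L, counts = c(0L, 0L, 0L)),
      list(type = 0L, rate = 2L, counts = c(1L, 0L, 0L)),
      list(type = 2L, rate = 3L, ksat = 4L, ix = 1L, iy = 3L),
      list(type = 0L, rate = 5L, counts = c(1L, 0L, 0L)),
      list(type = 0L, rate = 6L, counts = c(0L, 1L, 0L)),
      list(type = 0L, rate = 7L, counts = c(0L, 0L, 1L))),
    default_params = c(b_x = 720, a_x = 0.05, a_k = 2, k = 80,
                       b_y = 1, a_0 = 0.8, a_y = 0.8),
    sim_defaults = list(T = 25, K = 25, N = 1000, observed = 1L))
}

#' Observation operators
#'
#' Describes which state components are observed and at which discrete times.
#' The default time grid is equidistant on `(0, T]`: `t_k = k * T / K`.
#'
#' @param times strictly increasing observation times, or `NULL` to build an
#'   equidistant grid from `T` and `K`.
#' @param observed integer indices of observed species.
#' @param T,K horizon and number of equidistant observation times (used when
#'   `times` is `NULL`).
#' @return an `observation_operator` (list with `times`, `observed`, `K`).
#' @export
observation_operator <- function(times = NULL, observed = 1L, T = NULL, K = NULL) {
  if (is.null(times)) {
    stopifnot(!is.null(T), !is.null(K), T > 0, K >= 1)
    times <- seq_len(K) * (T / K)
  }
  if (any(diff(times) <= 0)) stop("observation times must be strictly increasing")
  if (any(times < 0)) stop("observation times must be non-negative")
  observed <- as.integer(observed)
  if (anyDuplicated(observed)) stop("observed indices must be distinct")
  structure(list(times = times, observed = observed, K = length(times)),
            class = "observation_operator")
}
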