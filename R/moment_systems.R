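#' Closed moment ODE systems
#'
#' A `moment_system` is a closed, parameter-dependent ODE system whose state
#' stacks approximate moments of a reaction network up to order 2: first the
#' mean entries `m_1..m_u`, then the covariance entries packed row-major over
#' the upper triangle (`V_11, V_12, ..., V_1u, V_22, ...`). Three closures are
#' provided:
#'
#' * `exact_affine` - exact (closure-free) mean/covariance equations, valid
#'   when every propensity is affine in the state;
#' * `normal_closure_1d` - normal moment closure (third central moment set to
#'   zero) of the Fokker-Planck drift/diffusion for one-dimensional networks
#'   with polynomial propensities;
#' * `lna` - the linear noise approximation: the mean solves the macroscopic
#'   rate equation and the covariance a Lyapunov-type ODE driven by the
#'   Jacobian of the macroscopic right-hand side;
#' * `macroscopic` - mean-only deterministic rate equation (no covariance);
#' * `bd_analytic` - the closed-form mean/variance solution available for the
#'   linear birth-death model, usable wherever a solved system is needed.
#'
#' @name moment_system
NULL

sym_pack_index <- function(u) {
  idx <- which(upper.tri(matrix(0, u, u), diag = TRUE), arr.ind = TRUE)
  idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
}

pack_sym <- function(M) {
  u <- nrow(M)
  M[sym_pack_index(u)]
}

unpack_sym <- function(v, u) {
  M <- matrix(0, u, u)
  idx <- sym_pack_index(u)
  M[idx] <- v
  M[idx[, c(2, 1), drop = FALSE]] <- v
  M
}

new_moment_system <- function(kind, net, rhs, jac_y = NULL, jac_c = NULL,
                              order = 2) {
  u <- net$n_species
  dim <- if (kind == "macroscopic") u else u + u * (u + 1) / 2
  init_state <- if (kind == "macroscopic") {
    function(x0) as.numeric(x0)
  } else {
    function(x0) c(as.numeric(x0), rep(0, u * (u + 1) / 2))
  }
  structure(list(kind = kind, net = net, order = order, dim = dim,
                 rhs = rhs, jac_y = jac_y, jac_c = jac_c,
                 init_state = init_state),
            class = "moment_system")
}

#' @export
print.moment_system <- function(x, ...) {
  cat(sprintf("<moment_system '%s' for '%s': state dimension %d>\n",
              x$kind, x$net$name, x$dim), sep = "")
  invisible(x)
}

# affine decomposition h(x, c) = W x + w0, exact when propensities are affine
.affine_parts <- function(fun, u) {
  w0 <- fun(rep(0, u))
  W <- matrix(0, length(w0), u)
  for (i in seq_len(u)) {
    e <- rep(0, u); e[i] <- 1
    W[, i] <- fun(e) - w0
  }
  list(W = W, w0 = w0)
}

.lyap <- function(J, V, Q) J %*% V + V %*% t(J) + Q

#' Exact moment equations for affine-propensity networks
#'
#' Builds the exact mean/covariance ODE system derived from the chemical
#' master equation: `dm/dt = S E[h]`, and covariance dynamics combining the
#' drift coupling `A V + V A'` (with `A = S W`, `h(x) = W x + w0`) and the
#' fluctuation source `S diag(h(m)) S'`. Requires every propensity to be
#' affine in the state; otherwise the moment hierarchy does not close and an
#' error names the offending reaction.
#'
#' @param net a [reaction_network] with all `prop_kinds == "affine"`.
#' @return a [moment_system] of kind `"exact_affine"`.
#' @export
exact_moment_system <- function(net) {
  bad <- which(net$prop_kinds != "affine")
  if (length(bad))
    stop("exact moment equations need affine propensities; reaction(s) ",
         paste(bad, collapse = ", "), " are ", net$prop_kinds[bad][1])
  u <- net$n_species
  S <- net$stoich
  pidx <- sym_pack_index(u)

  rhs <- function(t, y, c) {
    ap <- .affine_parts(function(x) net$propensity(x, c), u)
    m <- y[seq_len(u)]
    V <- unpack_sym(y[-seq_len(u)], u)
    h <- as.numeric(ap$W %*% m + ap$w0)
    A <- S %*% ap$W
    dM <- as.numeric(S %*% h)
    dV <- .lyap(A, V, S %*% diag(h, nrow = length(h)) %*% t(S))
    c(dM, dV[pidx])
  }

  jac_y <- function(t, y, c) {
    n <- length(y)
    f0 <- rhs(t, rep(0, n), c)
    J <- matrix(0, n, n)
    for (i in seq_len(n)) {
      e <- rep(0, n); e[i] <- 1
      J[, i] <- rhs(t, e, c) - f0
    }
    J
  }

  jac_c <- NULL
  if (!is.null(net$derivs$dc)) {
    jac_c <- function(t, y, c) {
      m <- y[seq_len(u)]
      V <- unpack_sym(y[-seq_len(u)], u)
      np <- net$n_params
      out <- matrix(0, length(y), np)
      dc0 <- net$derivs$dc(rep(0, u), c)
      dcs <- lapply(seq_len(u), function(i) {
        e <- rep(0, u); e[i] <- 1
        net$derivs$dc(e, c) - dc0
      })
      for (p in seq_len(np)) {
        Wp <- vapply(dcs, function(D) D[, p], numeric(net$n_reactions))
        Wp <- matrix(Wp, net$n_reactions, u)
        w0p <- dc0[, p]
        hp <- as.numeric(Wp %*% m + w0p)
        Ap <- S %*% Wp
        dMp <- as.numeric(S %*% hp)
        dVp <- .lyap(Ap, V, S %*% diag(hp, nrow = length(hp)) %*% t(S))
        out[, p] <- c(dMp, dVp[pidx])
      }
      out
    }
  }
  new_moment_system("exact_affine", net, rhs, jac_y, jac_c)
}

#' Linear noise approximation moment system
#'
#' The mean block solves the macroscopic rate equation
#' `dPhi/dt = S h(Phi, c)` and the covariance block the Lyapunov-type ODE
#' `dV/dt = J V + V J' + S diag(h(Phi)) S'` with `J = S (dh/dx)(Phi)`.
#' Propensity Jacobians are taken from the network's analytic derivative
#' functions when present, otherwise by central finite differences.
#'
#' @param net a [reaction_network] with propensities differentiable in the
#'   state.
#' @return a [moment_system] of kind `"lna"`.
#' @export
lna_system <- function(net) {
  u <- net$n_species
  S <- net$stoich
  pidx <- sym_pack_index(u)
  dx_fun <- net$derivs$dx
  if (is.null(dx_fun)) dx_fun <- function(x, c) .fd_jac_x(net, x, c)

  rhs <- function(t, y, c) {
    m <- y[seq_len(u)]
    V <- unpack_sym(y[-seq_len(u)], u)
    h <- net$propensity(m, c)
    J <- S %*% dx_fun(m, c)
    dM <- as.numeric(S %*% h)
    dV <- .lyap(J, V, S %*% diag(h, nrow = length(h)) %*% t(S))
    c(dM, dV[pidx])
  }

  jac_y <- NULL
  if (!is.null(net$derivs$dxdx)) {
    jac_y <- function(t, y, c) {
      m <- y[seq_len(u)]
      V <- unpack_sym(y[-seq_len(u)], u)
      h <- net$propensity(m, c)
      H <- dx_fun(m, c)
      HH <- net$derivs$dxdx(m, c)
      J <- S %*% H
      n <- length(y)
      npack <- u * (u + 1) / 2
      out <- matrix(0, n, n)
      out[seq_len(u), seq_len(u)] <- J
      for (i in seq_len(u)) {
        dJ <- S %*% matrix(HH[, , i], net$n_reactions, u)
        dV <- .lyap(dJ, V, S %*% diag(H[, i], nrow = net$n_reactions) %*% t(S))
        out[u + seq_len(npack), i] <- dV[pidx]
      }
      for (q in seq_len(npack)) {
        E <- unpack_sym(replace(rep(0, npack), q, 1), u)
        dV <- J %*% E + E %*% t(J)
        out[u + seq_len(npack), u + q] <- dV[pidx]
      }
      out
    }
  }

  jac_c <- NULL
  if (!is.null(net$derivs$dc) && !is.null(net$derivs$dxdc)) {
    jac_c <- function(t, y, c) {
      m <- y[seq_len(u)]
      V <- unpack_sym(y[-seq_len(u)], u)
      DC <- net$derivs$dc(m, c)
      DXDC <- net$derivs$dxdc(m, c)
      np <- net$n_params
      out <- matrix(0, length(y), np)
      for (p in seq_len(np)) {
        hp <- DC[, p]
        dJ <- S %*% matrix(DXDC[, , p], net$n_reactions, u)
        dMp <- as.numeric(S %*% hp)
        dVp <- .lyap(dJ, V, S %*% diag(hp, nrow = length(hp)) %*% t(S))
        out[, p] <- c(dMp, dVp[pidx])
      }
      out
    }
  }
  new_moment_system("lna", net, rhs, jac_y, jac_c)
}

#' Normal moment closure for one-dimensional networks
#'
#' For a scalar state with drift `A(x) = sum_j s_j h_j(x)` and diffusion
#' `B(x) = sum_j s_j^2 h_j(x)` (the Fokker-Planck coefficients), Taylor
#' expansion about the mean with the third central moment set to zero yields
#'
#' \deqn{dm/dt = A(m) + A''(m) v / 2, \quad
#'       dv/dt = 2 A'(m) v + B(m) + B''(m) v / 2.}
#'
#' For affine propensities the closure terms vanish and the system coincides
#' with [exact_moment_system()]. State Jacobians assume propensities of
#' polynomial degree at most two (third state derivatives zero), which holds
#' for all built-in models.
#'
#' @param net a one-species [reaction_network] with polynomial propensities.
#' @return a [moment_system] of kind `"normal_closure_1d"`.
#' @export
normal_closure_1d <- function(net) {
  if (net$n_species != 1)
    stop("normal closure is implemented for one-dimensional networks only")
  s <- as.numeric(net$stoich[1, ])
  s2 <- s^2
  dx_fun <- net$derivs$dx
  dxdx_fun <- net$derivs$dxdx
  if (is.null(dx_fun)) dx_fun <- function(x, c) .fd_jac_x(net, x, c)
  if (is.null(dxdx_fun)) dxdx_fun <- function(x, c) .fd_hess_x(net, x, c)

  coefs <- function(m, c) {
    h <- net$propensity(m, c)
    h1 <- as.numeric(dx_fun(m, c))
    h2 <- as.numeric(dxdx_fun(m, c))
    list(A = sum(s * h), A1 = sum(s * h1), A2 = sum(s * h2),
         B = sum(s2 * h), B1 = sum(s2 * h1), B2 = sum(s2 * h2))
  }

  rhs <- function(t, y, c) {
    k <- coefs(y[1], c)
    c(k$A + 0.5 * k$A2 * y[2],
      2 * k$A1 * y[2] + k$B + 0.5 * k$B2 * y[2])
  }

  jac_y <- function(t, y, c) {
    k <- coefs(y[1], c)
    matrix(c(k$A1, 2 * k$A2 * y[2] + k$B1,
             0.5 * k$A2, 2 * k$A1 + 0.5 * k$B2), 2, 2)
  }

  jac_c <- NULL
  if (!is.null(net$derivs$dc) && !is.null(net$derivs$dxdc) &&
      !is.null(net$derivs$dxdxdc)) {
    jac_c <- function(t, y, c) {
      m <- y[1]; v <- y[2]
      DC <- net$derivs$dc(m, c)
      DXDC <- net$derivs$dxdc(m, c)
      DXXDC <- net$derivs$dxdxdc(m, c)
      np <- net$n_params
      out <- matrix(0, 2, np)
      for (p in seq_len(np)) {
        hA <- sum(s * DC[, p]); hA1 <- sum(s * DXDC[, 1, p])
        hA2 <- sum(s * DXXDC[, 1, 1, p])
        hB <- sum(s2 * DC[, p]); hB2 <- sum(s2 * DXXDC[, 1, 1, p])
        out[1, p] <- hA + 0.5 * hA2 * v
        out[2, p] <- 2 * hA1 * v + hB + 0.5 * hB2 * v
      }
      out
    }
  }
  new_moment_system("normal_closure_1d", net, rhs, jac_y, jac_c)
}

#' Mean-only macroscopic rate equation system
#'
#' @param net a [reaction_network].
#' @return a [moment_system] of kind `"macroscopic"` (state = means only).
#' @export
macroscopic_system <- function(net) {
  S <- net$stoich
  rhs <- function(t, y, c) as.numeric(S %*% net$propensity(y, c))
  jac_y <- NULL
  if (!is.null(net$derivs$dx))
    jac_y <- function(t, y, c) S %*% net$derivs$dx(y, c)
  jac_c <- NULL
  if (!is.null(net$derivs$dc))
    jac_c <- function(t, y, c) S %*% net$derivs$dc(y, c)
  new_moment_system("macroscopic", net, rhs, jac_y, jac_c, order = 1)
}

#' Construct a moment system by kind
#'
#' @param net a [reaction_network].
#' @param kind one of `"exact_affine"`, `"normal_closure_1d"`, `"lna"`,
#'   `"macroscopic"`, `"bd_analytic"` (closed form; birth-death model only).
#' @return a [moment_system].
#' @export
moment_system <- function(net, kind = c("exact_affine", "normal_closure_1d",
                                        "lna", "macroscopic", "bd_analytic")) {
  kind <- match.arg(kind)
  switch(kind,
         exact_affine = exact_moment_system(net),
         normal_closure_1d = normal_closure_1d(net),
         lna = lna_system(net),
         macroscopic = macroscopic_system(net),
         bd_analytic = {
           if (net$name != "birth_death")
             stop("the closed-form system is available for the birth-death model only")
           ms <- new_moment_system("bd_analytic", net, rhs = NULL)
           ms
         })
}

# central-difference fallbacks for networks without analytic derivatives
.fd_jac_x <- function(net, x, c, rel = 1e-5) {
  u <- net$n_species
  out <- matrix(0, net$n_reactions, u)
  for (i in seq_len(u)) {
    h <- rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- max(x[i] - h, 0) # keep within domain
    out[, i] <- (net$propensity(xp, c) - net$propensity(xm, c)) / (xp[i] - xm[i])
  }
  out
}

.fd_hess_x <- function(net, x, c, rel = 1e-4) {
  u <- net$n_species
  out <- array(0, c(net$n_reactions, u, u))
  for (i in seq_len(u)) {
    h <- rel * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + h
    xm <- x; xm[i] <- x[i] + h # one-sided second difference keeps x >= 0
    xm[i] <- max(x[i] - h, 0)
    f0 <- net$propensity(x, c)
    out[, i, i] <- (net$propensity(xp, c) - 2 * f0 + net$propensity(xm, c)) /
      (((xp[i] - xm[i]) / 2)^2)
  }
  out
}

#' Solve a moment system
#'
#' Integrates the stacked moment ODEs from a deterministic initial state
#' (mean = `x0`, covariance = 0) and returns moments at the requested times.
#' A stiff-capable integrator (`deSolve::lsoda`) is used with tight default
#' tolerances so that integration error stays well below fitting error.
#'
#' @param ms a [moment_system].
#' @param c positive parameter vector.
#' @param x0 initial state (defaults to the network's `x0`).
#' @param times increasing observation times (0 is prepended internally).
#' @param rtol,atol integration tolerances.
#' @return a `moment_trajectory`: list with `times`, `mean` (`K x u`), `cov`
#'   (`K x u x u`, `NULL` for macroscopic systems), `params`.
#' @export
solve_moment_system <- function(ms, c, x0 = ms$net$x0, times,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(ms, "moment_system"))
  if (any(c <= 0)) stop("rate parameters must be strictly positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  u <- ms$net$n_species

  if (ms$kind == "bd_analytic") {
    an <- birth_death_analytic(c, x0, times)
    cov <- array(an$variance, c(length(times), 1, 1))
    return(structure(list(times = times, mean = matrix(an$mean, ncol = 1),
                          cov = cov, params = c, kind = ms$kind),
                     class = "moment_trajectory"))
  }

  y0 <- ms$init_state(x0)
  tt <- if (times[1] > 0) c(0, times) else times
  func <- function(t, y, parms) list(ms$rhs(t, y, parms))
  args <- list(y = y0, times = tt, func = func, parms = c,
               rtol = rtol, atol = atol)
  if (!is.null(ms$jac_y)) {
    args$jacfunc <- function(t, y, parms) ms$jac_y(t, y, parms)
    args$jactype <- "fullusr"
  }
  sol <- try(suppressWarnings(do.call(deSolve::lsoda, args)), silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) < length(tt) ||
      anyNA(sol[, -1]))
    stop("moment ODE integration failed at c = (",
         paste(signif(c, 6), collapse = ", "), ")")
  keep <- match(times, sol[, 1])
  Y <- matrix(sol[keep, -1, drop = FALSE], nrow = length(times))

  mean <- Y[, seq_len(u), drop = FALSE]
  cov <- NULL
  if (ms$kind != "macroscopic") {
    K <- length(times)
    cov <- array(0, c(K, u, u))
    for (k in seq_len(K)) cov[k, , ] <- unpack_sym(Y[k, -seq_len(u)], u)
  }
  structure(list(times = times, mean = mean, cov = cov, params = c,
                 kind = ms$kind),
            class = "moment_trajectory")
}

#' @export
print.moment_trajectory <- function(x, ...) {
  cat(sprintf("<moment_trajectory ('%s'): %d times, %d species%s>\n",
              x$kind, length(x$times), ncol(x$mean),
              if (is.null(x$cov)) ", mean only" else ""))
  invisible(x)
}

#' Closed-form moments of the linear birth-death process
#'
#' For birth rate `c1 * x`, death rate `c2 * x` and deterministic initial
#' count `x0`, the exact mean and variance are
#' \deqn{m(t) = x_0 e^{(c_1 - c_2) t}, \quad
#'  v(t) = x_0 \frac{c_1 + c_2}{c_1 - c_2} e^{(c_1-c_2)t}(e^{(c_1-c_2)t} - 1)}
#' with the continuous limit `v(t) = 2 c1 x0 t` when `c1 = c2`. The mean
#' depends on the parameters only through the difference `c1 - c2`; this is
#' the source of the ridge non-identifiability of mean-only fitting.
#'
#' @param c parameter vector `(c1, c2)`, both positive.
#' @param x0 initial molecule count.
#' @param times numeric vector of times.
#' @return list with components `mean` and `variance`.
#' @export
birth_death_analytic <- function(c, x0, times) {
  a <- c[1] - c[2]
  m <- x0 * exp(a * times)
  if (a == 0) {
    v <- 2 * c[1] * x0 * times
  } else {
    # expm1 keeps the near-critical case c1 ~ c2 numerically stable
    v <- x0 * (c[1] + c[2]) * exp(a * times) * expm1(a * times) / a
  }
  list(mean = m, variance = v)
}

#' Solve the macroscopic rate equation
#'
#' Convenience wrapper integrating `dx/dt = S h(x, c)` and returning the
#' mean-only trajectory; used for deterministic-limit checks and as the mean
#' block of the linear noise approximation.
#'
#' @inheritParams solve_moment_system
#' @param net a [reaction_network].
#' @return a `moment_trajectory` with `cov = NULL`.
#' @export
macroscopic_solve <- function(net, c, x0 = net$x0, times,
                              rtol = 1e-8, atol = 1e-10) {
  solve_moment_system(macroscopic_system(net), c, x0, times, rtol, atol)
}

#' Truncated chemical master equation moments (test oracle)
#'
#' Integrates the full probability-vector ODE of the chemical master equation
#' on a truncated lattice (each species capped at `state_cap`) and reports
#' the exact mean and covariance of the truncated distribution together with
#' the probability mass that leaked over the cap. Intended as an independent
#' oracle for small networks; refuses state spaces above `max_states`.
#'
#' @param net a [reaction_network].
#' @param c positive parameter vector.
#' @param x0 initial state.
#' @param times increasing times.
#' @param state_cap per-species cap (scalar or vector).
#' @param max_states refusal threshold for the truncated lattice size.
#' @param rtol,atol integration tolerances.
#' @return a `moment_trajectory` with extra element `leak` (per-time leaked
#'   probability mass).
#' @export
cme_truncated_moments <- function(net, c, x0, times, state_cap,
                                  max_states = 4000, rtol = 1e-10,
                                  atol = 1e-12) {
  u <- net$n_species
  cap <- rep(state_cap, length.out = u)
  nstates <- prod(cap + 1)
  if (nstates > max_states)
    stop("truncated state space has ", nstates, " states (limit ", max_states, ")")
  grids <- lapply(cap, function(m) 0:m)
  states <- as.matrix(expand.grid(grids))
  idx_of <- function(x) {
    # mixed-radix index into expand.grid order
    i <- 0
    mult <- 1
    for (s in seq_len(u)) {
      i <- i + x[s] * mult
      mult <- mult * (cap[s] + 1)
    }
    i + 1
  }

  A <- matrix(0, nstates, nstates)
  for (r in seq_len(nstates)) {
    x <- states[r, ]
    h <- net$propensity(as.numeric(x), c)
    for (j in seq_len(net$n_reactions)) {
      if (h[j] <= 0) next
      xp <- x + net$stoich[, j]
      A[r, r] <- A[r, r] - h[j]
      if (all(xp >= 0) && all(xp <= cap)) {
        A[idx_of(xp), r] <- A[idx_of(xp), r] + h[j]
      } # else: probability mass leaks out of the truncated lattice
    }
  }

  p0 <- rep(0, nstates)
  p0[idx_of(round(x0))] <- 1
  tt <- if (times[1] > 0) c(0, times) else times
  sol <- deSolve::lsoda(p0, tt, function(t, y, parms) list(as.numeric(A %*% y)),
                        parms = NULL, rtol = rtol, atol = atol,
                        jacfunc = function(t, y, parms) A, jactype = "fullusr")
  keep <- match(times, sol[, 1])
  K <- length(times)
  mean <- matrix(0, K, u)
  cov <- array(0, c(K, u, u))
  leak <- numeric(K)
  for (k in seq_len(K)) {
    p <- pmax(sol[keep[k], -1], 0)
    mass <- sum(p)
    leak[k] <- 1 - mass
    pn <- p / mass
    mu <- as.numeric(t(states) %*% pn)
    ctr <- sweep(states, 2, mu)
    cov[k, , ] <- t(ctr) %*% (ctr * pn)
    mean[k, ] <- mu
  }
  structure(list(times = times, mean = mean, cov = cov, params = c,
                 kind = "cme_truncated", leak = leak),
            class = "moment_trajectory")
}
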