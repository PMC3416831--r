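#' Exact stochastic simulation (Gillespie direct method)
#'
#' Generates a single exact realization of the jump process defined by a
#' reaction network: waiting times are exponential with rate equal to the
#' total propensity, and the firing reaction is chosen with probability
#' proportional to its propensity. Simulation stops at `t_max` or as soon as
#' the total propensity reaches zero (absorbing state, e.g. extinction in the
#' birth-death process).
#'
#' @param net a [reaction_network].
#' @param c positive parameter vector (defaults to the model's built-in
#'   values when available).
#' @param x0 initial state (defaults to `net$x0`).
#' @param t_max simulation horizon (> 0).
#' @return a `trajectory`: list with `jump_times` (starting at 0), `states`
#'   (`n_species x n_jumps` matrix of states, right-continuous piecewise
#'   constant), `reaction_ids`, `t_max`, and `absorbed` flag.
#' @export
simulate_ssa <- function(net, c = net$default_params, x0 = net$x0, t_max) {
  stopifnot(inherits(net, "reaction_network"), t_max > 0)
  if (any(c <= 0)) stop("rate parameters must be strictly positive")
  u <- net$n_species
  S <- net$stoich
  prop <- net$propensity

  if (!is.null(net$compiled)) {
    res <- .ssa_direct_cpp(matrix(as.integer(S), u), net$compiled,
                           as.numeric(c), as.numeric(x0), t_max)
    return(structure(list(jump_times = res$jump_times,
                          states = res$states,
                          reaction_ids = res$reaction_ids,
                          t_max = t_max,
                          absorbed = res$absorbed),
                     class = "trajectory"))
  }

  cap <- 256L
  times <- numeric(cap)
  states <- matrix(0, u, cap)
  rids <- integer(cap)
  times[1] <- 0
  states[, 1] <- x0
  n <- 1L
  x <- as.numeric(x0)
  t <- 0
  absorbed <- FALSE

  repeat {
    h <- prop(x, c)
    H <- sum(h)
    if (H <= 0) { absorbed <- TRUE; break }
    t <- t + stats::rexp(1L, H)
    if (t > t_max) break
    j <- findInterval(stats::runif(1L) * H, cumsum(h),
                      rightmost.closed = FALSE) + 1L
    x <- x + S[, j]
    n <- n + 1L
    if (n > cap) {
      cap <- cap * 2L
      length(times) <- cap
      length(rids) <- cap
      states <- cbind(states, matrix(0, u, cap / 2L))
    }
    times[n] <- t
    states[, n] <- x
    rids[n] <- j
  }

  structure(list(jump_times = times[seq_len(n)],
                 states = states[, seq_len(n), drop = FALSE],
                 reaction_ids = rids[seq_len(n)][-1L],
                 t_max = t_max,
                 absorbed = absorbed),
            class = "trajectory")
}

#' Sample a trajectory at discrete times
#'
#' Evaluates a piecewise-constant, right-continuous SSA path at the requested
#' times: the state at time `t` is the state after the last jump at or before
#' `t`. Queries after an absorbing state return the absorbing state.
#'
#' @param traj a `trajectory` from [simulate_ssa()].
#' @param times numeric vector within `[0, t_max]`.
#' @return `length(times) x n_species` matrix of states.
#' @export
sample_at_times <- function(traj, times) {
  if (any(times < 0) || (!traj$absorbed && any(times > traj$t_max)))
    stop("query times must lie within [0, t_max]")
  idx <- findInterval(times, traj$jump_times)
  t(traj$states[, idx, drop = FALSE])
}

# deterministic per-replicate substream seed below 2^31, mixing the master
# seed with the replicate index so single replicates are reproducible alone
.substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 + i * 104729) %% 2147483629L + 1L
}

#' Simulate an ensemble of observed trajectories
#'
#' Runs `N` independent SSA realizations, samples each at the observation
#' times, and keeps the observed components, yielding the
#' replicate-by-time-by-component data tensor used for sample moments. Each
#' replicate uses its own RNG substream derived deterministically from
#' `seed`, so any replicate can be regenerated in isolation and results do
#' not depend on evaluation order.
#'
#' @param net a [reaction_network].
#' @param c positive parameter vector.
#' @param x0 initial state.
#' @param obs an [observation_operator()].
#' @param N number of replicates (>= 1).
#' @param seed integer master seed.
#' @return a `data_tensor`: list with `values` (`N x K x d` array), `times`,
#'   `observed`, `N`, and provenance attributes (`seed`, `params`, `model`).
#' @export
simulate_ensemble <- function(net, c = net$default_params, x0 = net$x0,
                              obs, N, seed = 1L) {
  stopifnot(inherits(obs, "observation_operator"), N >= 1)
  d <- length(obs$observed)
  K <- obs$K
  t_max <- max(obs$times)
  if (is.null(names(c))) names(c) <- net$param_names
  values <- array(0, dim = c(N, K, d))
  for (i in seq_len(N)) {
    set.seed(.substream_seed(seed, i))
    traj <- simulate_ssa(net, c, x0, t_max)
    xs <- sample_at_times(traj, obs$times)
    values[i, , ] <- xs[, obs$observed, drop = FALSE]
  }
  structure(list(values = values, times = obs$times,
                 observed = obs$observed, N = N,
                 seed = seed, params = c, model = net$name),
            class = "data_tensor")
}

#' @export
print.data_tensor <- function(x, ...) {
  cat(sprintf("<data_tensor: %d replicates x %d times x %d components (model '%s', seed %s)>\n",
              x$N, length(x$times), length(x$observed), x$model,
              format(x$seed)))
  invisible(x)
}
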