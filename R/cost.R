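#' Cost specification for moment fitting
#'
#' Bundles everything needed to evaluate a weighted moment-residual cost: the
#' network, the moment system used for predictions, the observation operator,
#' the sample moment data, the moment order `n` (1 = mean only, 2 = mean and
#' covariance) and the block weights `w_1..w_n`.
#'
#' The associated residual vector concatenates, over observation times,
#' `sqrt(w1) * (sample mean - model mean)` for the observed components,
#' followed (for `n = 2`) by `sqrt(w2) * (sample cov - model cov)` over the
#' packed upper triangle of the observed block. The cost is the sum of
#' squared residual entries.
#'
#' @param net a [reaction_network].
#' @param ms a [moment_system] (or a kind string passed to [moment_system()]).
#' @param obs an [observation_operator()]; `obs$times` must equal the data's
#'   times.
#' @param data a `sample_moment_series` for the observed components.
#' @param order moment order `n`, 1 or 2.
#' @param weights non-negative weights, length `order`.
#' @param x0 initial state for the moment system.
#' @param rtol,atol ODE tolerances used when evaluating this cost (tighter
#'   values make the cost surface smoother, e.g. for finite-difference
#'   probing).
#' @return a `cost_spec`.
#' @export
cost_spec <- function(net, ms, obs, data, order = 2, weights = rep(1, order),
                      x0 = net$x0, rtol = 1e-8, atol = 1e-10) {
  if (is.character(ms)) ms <- moment_system(net, ms)
  stopifnot(inherits(net, "reaction_network"), inherits(ms, "moment_system"),
            inherits(obs, "observation_operator"),
            inherits(data, "sample_moment_series"),
            order %in% c(1, 2), length(weights) == order)
  if (!isTRUE(all.equal(data$times, obs$times)))
    stop("data times and observation times differ")
  if (all(weights == 0)) stop("weights must not all be zero")
  if (order == 2 && is.null(data$cov))
    stop("order 2 requires covariance data (compute sample moments with order = 2)")
  if (max(obs$observed) > net$n_species)
    stop("observed indices exceed the number of species")
  if (ncol(data$mean) != length(obs$observed))
    stop("data has ", ncol(data$mean), " components but ",
         length(obs$observed), " species are observed")
  structure(list(net = net, ms = ms, obs = obs, data = data, order = order,
                 weights = weights, x0 = x0, rtol = rtol, atol = atol),
            class = "cost_spec")
}

#' Predicted moments of the observed components
#'
#' Solves the full moment system and applies the (linear) splitting operator
#' that selects the mean entries and covariance sub-block of the observed
#' species at the observation times. Unobserved species still shape the
#' predictions through the coupled dynamics.
#'
#' @param ms a [moment_system].
#' @param c positive parameter vector.
#' @param x0 initial state.
#' @param obs an [observation_operator()].
#' @param rtol,atol ODE tolerances.
#' @return list with `times`, `mean` (`K x d`), `cov` (`K x d x d` or `NULL`).
#' @export
predict_observed_moments <- function(ms, c, x0, obs, rtol = 1e-8,
                                     atol = 1e-10) {
  tr <- solve_moment_system(ms, c, x0, obs$times, rtol = rtol, atol = atol)
  sel <- obs$observed
  K <- length(obs$times)
  d <- length(sel)
  cov <- NULL
  if (!is.null(tr$cov)) {
    cov <- array(0, c(K, d, d))
    for (k in seq_len(K)) cov[k, , ] <- tr$cov[k, sel, sel]
  }
  list(times = obs$times, mean = tr$mean[, sel, drop = FALSE], cov = cov)
}

#' Moment-residual vector and weighted squared-error cost
#'
#' `moment_residuals()` returns the weighted residual vector (sample moments
#' minus model moments, mean block over all times first, then the packed
#' covariance block); `moment_cost()` returns its squared Euclidean norm.
#' Integration failures at a parameter vector propagate as errors so
#' optimizers can treat the step as rejected.
#'
#' @param c positive parameter vector.
#' @param spec a [cost_spec()].
#' @return numeric residual vector / non-negative scalar cost.
#' @export
moment_residuals <- function(c, spec) {
  pred <- predict_observed_moments(spec$ms, c, spec$x0, spec$obs,
                                   rtol = spec$rtol, atol = spec$atol)
  d <- length(spec$obs$observed)
  res <- sqrt(spec$weights[1]) * as.numeric(t(spec$data$mean - pred$mean))
  if (spec$order >= 2) {
    if (is.null(pred$cov))
      stop("moment system '", spec$ms$kind, "' provides no covariance block")
    pidx <- sym_pack_index(d)
    K <- length(spec$obs$times)
    cv <- numeric(K * nrow(pidx))
    for (k in seq_len(K)) {
      diffmat <- matrix(spec$data$cov[k, , ] - pred$cov[k, , ], d, d)
      cv[(k - 1) * nrow(pidx) + seq_len(nrow(pidx))] <- diffmat[pidx]
    }
    res <- c(res, sqrt(spec$weights[2]) * cv)
  }
  res
}

#' @rdname moment_residuals
#' @export
moment_cost <- function(c, spec) {
  r <- moment_residuals(c, spec)
  sum(r * r)
}

#' Mean-only Gaussian log-likelihood
#'
#' The likelihood used to demonstrate the failure of mean-only Bayesian
#' inference: the per-time sample mean of a single observed component is
#' modelled as Normal with the model mean `m(t_k; c)` and the model variance
#' scaled by the replicate count, `v(t_k; c) / N`. The distance between the
#' sample variance and the model variance is deliberately not part of this
#' likelihood.
#'
#' @param c positive parameter vector.
#' @param data a `sample_moment_series` (single observed component) or a
#'   `data_tensor` (moments are computed internally).
#' @param ms a [moment_system] supplying mean and variance of the observed
#'   component.
#' @param obs an [observation_operator()] with one observed index.
#' @param x0 initial state.
#' @param N replicate count; defaults to `data$N`.
#' @return scalar log-likelihood.
#' @export
log_likelihood_mean_only <- function(c, data, ms, obs, x0 = ms$net$x0,
                                     N = NULL) {
  if (inherits(data, "data_tensor")) data <- compute_sample_moments(data, order = 1)
  if (length(obs$observed) != 1)
    stop("the mean-only likelihood is defined for a single observed component")
  if (is.null(N)) N <- data$N
  if (!is.finite(N) || N < 1) stop("a finite replicate count N is required")
  pred <- predict_observed_moments(ms, c, x0, obs)
  if (is.null(pred$cov))
    stop("moment system '", ms$kind, "' provides no variance prediction")
  m <- pred$mean[, 1]
  v <- pred$cov[, 1, 1]
  if (any(v <= 0)) stop("non-positive model variance at c = (",
                        paste(signif(c, 6), collapse = ", "), ")")
  sum(stats::dnorm(data$mean[, 1], mean = m, sd = sqrt(v / N), log = TRUE))
}
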