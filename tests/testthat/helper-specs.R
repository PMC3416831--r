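# shared fixtures: surrogate (infinite-N) cost specs built from model
# predictions, so costs vanish at the generating parameters

bd_surrogate_spec <- function(order = 2, kind = "exact_affine",
                              truth = c(0.3, 0.4), x0 = 30, T = 10, K = 20) {
  net <- builtin_model("birth_death")
  obs <- observation_operator(T = T, K = K, observed = 1L)
  ms <- moment_system(net, kind)
  if (kind == "bd_analytic") {
    an <- birth_death_analytic(truth, x0, obs$times)
    dat <- stokinfit:::as_moment_series(obs$times, matrix(an$mean, ncol = 1),
                                        array(an$variance, c(K, 1, 1)))
  } else {
    pred <- predict_observed_moments(ms, truth, x0, obs)
    dat <- stokinfit:::as_moment_series(obs$times, pred$mean, pred$cov)
  }
  cost_spec(net, ms, obs, dat, order = order, x0 = x0)
}

dim_surrogate_spec <- function(order = 2, truth = NULL) {
  net <- builtin_model("dimerisation")
  if (is.null(truth)) truth <- net$default_params
  obs <- observation_operator(T = 10, K = 20, observed = 1L)
  ms <- normal_closure_1d(net)
  pred <- predict_observed_moments(ms, truth, net$x0, obs)
  dat <- stokinfit:::as_moment_series(obs$times, pred$mean, pred$cov)
  cost_spec(net, ms, obs, dat, order = order)
}

p53_surrogate_spec <- function(order = 2, observed = 1L, truth = NULL,
                               K = 25, T = 25, x0 = NULL, rtol = 1e-8,
                               atol = 1e-10) {
  net <- builtin_model("p53")
  if (is.null(truth)) truth <- net$default_params
  if (is.null(x0)) x0 <- round(net$x0 * truth[["b_x"]] / net$default_params[["b_x"]])
  obs_full <- observation_operator(T = T, K = K, observed = seq_len(3))
  ms <- lna_system(net)
  pred <- predict_observed_moments(ms, truth, x0, obs_full)
  obs <- observation_operator(times = obs_full$times, observed = observed)
  d <- length(observed)
  cov <- array(0, c(K, d, d))
  for (k in seq_len(K)) cov[k, , ] <- pred$cov[k, observed, observed]
  dat <- stokinfit:::as_moment_series(obs$times,
                                      pred$mean[, observed, drop = FALSE], cov)
  cost_spec(net, ms, obs, dat, order = order, x0 = x0, rtol = rtol,
            atol = atol)
}
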