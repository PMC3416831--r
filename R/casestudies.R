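# End-to-end case studies tying simulation, sample moments, moment systems
# and inference together. These are the experiments the CLI `casestudy`
# subcommand runs and the acceptance script reports on.

# keep a subset of observed components of a tensor
tensor_select <- function(data, comps) {
  structure(list(values = data$values[, , comps, drop = FALSE],
                 times = data$times, observed = data$observed[comps],
                 N = data$N, seed = data$seed, params = data$params,
                 model = data$model),
            class = "data_tensor")
}

#' Birth-death case study: mean-only vs moment fitting
#'
#' Simulates an ensemble of the linear birth-death process at the default
#' parameters, then fits the two rate constants from a deliberately distant
#' initial guess twice: once from the sample means alone (`n = 1`) and once
#' from means plus variances (`n = 2`). The mean depends on the parameters
#' only through `c1 - c2`, so the mean-only fit lands somewhere on the
#' `(1, 1)` ridge while the moment fit recovers both parameters. Gauss-Newton
#' Hessians at the two minimizers quantify the difference in identifiability.
#'
#' @param seed master seed for data generation.
#' @param N number of replicates.
#' @param c_init initial parameter guess for both fits.
#' @param outdir optional output directory for JSON/CSV artifacts.
#' @return list with the data moments, both `fit_result`s, relative errors,
#'   and `sloppiness_report`s.
#' @export
casestudy_birth_death <- function(seed = 1L, N = 10000,
                                  c_init = c(2.0, 2.1), outdir = NULL) {
  net <- builtin_model("birth_death")
  sim <- net$sim_defaults
  truth <- net$default_params
  obs <- observation_operator(T = sim$T, K = sim$K, observed = sim$observed)
  data <- simulate_ensemble(net, truth, net$x0, obs, N = N, seed = seed)
  sms <- compute_sample_moments(data, order = 2)
  ms <- exact_moment_system(net)

  spec1 <- cost_spec(net, ms, obs, sms, order = 1)
  spec2 <- cost_spec(net, ms, obs, sms, order = 2)
  fit1 <- fit_parameters(spec1, c_init, list(truth = truth))
  fit2 <- fit_parameters(spec2, c_init, list(truth = truth))

  rep1 <- sloppiness_report(cost_hessian(spec1, fit1$c_hat, "gauss_newton"))
  rep2 <- sloppiness_report(cost_hessian(spec2, fit2$c_hat, "gauss_newton"))

  out <- list(seed = seed, N = N, truth = truth, c_init = c_init,
              moments = sms, fit_mean_only = fit1, fit_moments = fit2,
              diff_rel_error = abs((fit1$c_hat[1] - fit1$c_hat[2]) -
                                     (truth[1] - truth[2])) /
                abs(truth[1] - truth[2]),
              report_mean_only = rep1, report_moments = rep2)
  if (!is.null(outdir)) .write_casestudy(out, outdir, "birth_death", data)
  out
}

#' Dimerisation case study: convergence speed of moment fitting
#'
#' Simulates the conservation-reduced dimerisation process, then minimizes
#' the mean-only and the mean-plus-variance cost (normal moment closure
#' predictions) from the same initial guess and data, recording outer
#' iteration counts and Hessian condition numbers at the minimizers. The
#' better-conditioned `n = 2` landscape is expected to converge in fewer
#' iterations.
#'
#' @inheritParams casestudy_birth_death
#' @export
casestudy_dimerisation <- function(seed = 1L, N = 10000,
                                   c_init = c(3e-3, 0.1), outdir = NULL) {
  net <- builtin_model("dimerisation")
  sim <- net$sim_defaults
  truth <- net$default_params
  obs <- observation_operator(T = sim$T, K = sim$K, observed = sim$observed)
  data <- simulate_ensemble(net, truth, net$x0, obs, N = N, seed = seed)
  sms <- compute_sample_moments(data, order = 2)
  ms <- normal_closure_1d(net)

  spec1 <- cost_spec(net, ms, obs, sms, order = 1)
  spec2 <- cost_spec(net, ms, obs, sms, order = 2)
  fit1 <- fit_parameters(spec1, c_init, list(truth = truth))
  fit2 <- fit_parameters(spec2, c_init, list(truth = truth))

  rep1 <- sloppiness_report(cost_hessian(spec1, fit1$c_hat, "gauss_newton"))
  rep2 <- sloppiness_report(cost_hessian(spec2, fit2$c_hat, "gauss_newton"))

  out <- list(seed = seed, N = N, truth = truth, c_init = c_init,
              moments = sms, fit_mean_only = fit1, fit_moments = fit2,
              iterations = c(mean_only = fit1$n_iterations,
                             moments = fit2$n_iterations),
              condition_numbers = c(mean_only = rep1$condition_number,
                                    moments = rep2$condition_number),
              report_mean_only = rep1, report_moments = rep2)
  if (!is.null(outdir)) .write_casestudy(out, outdir, "dimerisation", data)
  out
}

#' p53 case study: partial observation with the LNA
#'
#' Simulates the three-species p53-Mdm2 feedback model and compares two
#' partial-observation inference setups on the same ensemble: fitting all
#' seven rate parameters from the sample means of two observed components
#' (p53 and Mdm2, `n = 1`) versus from the sample mean and variance of the
#' single p53 component (`n = 2`). Both fits start from a deliberately
#' distant common initial guess (alternating factors 2 and 1/2 of the
#' truth), so that practically non-identifiable directions show up as large
#' errors instead of lingering near a lucky start. Predictions come from the
#' linear noise approximation, and the least-squares iteration runs on the
#' log-parameter scale because the rate constants span four orders of
#' magnitude.
#'
#' @inheritParams casestudy_birth_death
#' @param init_factors fixed multiplicative perturbation of the true
#'   parameters used as the common initial guess.
#' @export
casestudy_p53 <- function(seed = 1L, N = 1000,
                          init_factors = c(2, 0.5, 2, 0.5, 2, 0.5, 2),
                          outdir = NULL) {
  net <- builtin_model("p53")
  sim <- net$sim_defaults
  truth <- net$default_params
  obs_all <- observation_operator(T = sim$T, K = sim$K, observed = 1:3)
  data <- simulate_ensemble(net, truth, net$x0, obs_all, N = N, seed = seed)
  ms <- lna_system(net)
  c_init <- truth * init_factors

  # strict tolerances: linear-scale LM stalls on `ptol` in this sloppy valley
  fit_opts <- list(truth = truth, scale = "log", max_iter = 150,
                   ftol = 1e-12, ptol = 0)

  # two observed components (p53 + Mdm2), means only
  obs_two <- observation_operator(times = obs_all$times, observed = c(1L, 3L))
  sms_two <- compute_sample_moments(tensor_select(data, c(1, 3)), order = 1)
  spec_two <- cost_spec(net, ms, obs_two, sms_two, order = 1)
  fit_two <- fit_parameters(spec_two, c_init, fit_opts)

  # single observed component (p53), mean + variance
  obs_one <- observation_operator(times = obs_all$times, observed = 1L)
  sms_one <- compute_sample_moments(tensor_select(data, 1), order = 2)
  spec_one <- cost_spec(net, ms, obs_one, sms_one, order = 2)
  fit_one <- fit_parameters(spec_one, c_init, fit_opts)

  out <- list(seed = seed, N = N, truth = truth, c_init = c_init,
              fit_two_means = fit_two, fit_one_meanvar = fit_one,
              max_rel_error = c(two_means = max(fit_two$rel_errors),
                                one_meanvar = max(fit_one$rel_errors)))
  if (!is.null(outdir)) .write_casestudy(out, outdir, "p53", data)
  out
}

.write_casestudy <- function(out, outdir, name, data) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_data_tensor(data, file.path(outdir, paste0(name, "_data.csv")))
  for (f in c("fit_mean_only", "fit_moments", "fit_two_means",
              "fit_one_meanvar")) {
    if (!is.null(out[[f]]))
      write_fit_result(out[[f]], file.path(outdir, paste0(name, "_", f)))
  }
  summary <- list(seed = out$seed, N = out$N, truth = as.list(out$truth),
                  c_init = as.list(out$c_init))
  for (f in c("diff_rel_error", "iterations", "condition_numbers",
              "max_rel_error"))
    if (!is.null(out[[f]])) summary[[f]] <- as.list(out[[f]])
  jsonlite::write_json(summary, file.path(outdir, paste0(name, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
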