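#' Fit rate parameters by moment fitting
#'
#' Minimizes the weighted moment-residual cost with a trust-region-style
#' nonlinear least-squares driver (Levenberg-Marquardt on the residual
#' vector, with positivity enforced through box bounds at a small epsilon).
#' The residual Jacobian is taken by finite differences on the residuals;
#' alternatively, `method = "bfgs_adjoint"` runs BFGS on the log-parameter
#' scale with the adjoint gradient.
#'
#' @param spec a [cost_spec()].
#' @param c_init positive initial parameter guess.
#' @param options list of options: `method` (`"lm"` default or
#'   `"bfgs_adjoint"`), `scale` (`"linear"` default, or `"log"` to run the
#'   least-squares iteration in `log(c)` — recommended when parameters span
#'   several orders of magnitude), `max_iter` (default 200), `ftol`, `ptol`,
#'   `gtol` (default 1e-10), `lower` (default 1e-12), `truth` (optional known
#'   truth for relative-error reporting).
#' @return a `fit_result`: list with `c_hat`, `cost`, `cost_trace`
#'   (non-increasing over accepted iterations), `n_iterations`,
#'   `termination`, `iterates` (accepted parameter vectors when
#'   reconstructable), `rel_errors` (if `truth` supplied), `n_evals`.
#' @export
fit_parameters <- function(spec, c_init, options = list()) {
  stopifnot(inherits(spec, "cost_spec"), all(c_init > 0))
  opt <- utils::modifyList(list(method = "lm", scale = "linear",
                                max_iter = 200, ftol = 1e-10,
                                ptol = 1e-10, gtol = 1e-10, lower = 1e-12,
                                truth = NULL), options)
  np <- length(c_init)
  evals <- new.env(parent = emptyenv())
  evals$par <- list()
  evals$cost <- numeric(0)
  nres <- length(moment_residuals(pmax(c_init, opt$lower), spec))

  if (opt$method == "lm") {
    logscale <- identical(opt$scale, "log")
    fn <- function(par) {
      cc <- if (logscale) exp(par) else par
      r <- tryCatch(moment_residuals(cc, spec), error = function(e) {
        rep(1e8, nres) # failed solve: huge residual, step gets rejected
      })
      evals$par[[length(evals$par) + 1L]] <- cc
      evals$cost <- c(evals$cost, sum(r * r))
      r
    }
    res <- minpack.lm::nls.lm(
      par = if (logscale) log(c_init) else c_init,
      lower = if (logscale) NULL else rep(opt$lower, np), fn = fn,
      control = minpack.lm::nls.lm.control(
        maxiter = opt$max_iter, ftol = opt$ftol, ptol = opt$ptol,
        gtol = opt$gtol, maxfev = 100 * (np + 1) * opt$max_iter))
    c_hat <- if (logscale) exp(res$par) else res$par
    trace <- res$rsstrace
    niter <- res$niter
    term <- res$message
  } else if (opt$method == "bfgs_adjoint") {
    fn <- function(theta) {
      par <- exp(theta)
      val <- tryCatch(moment_cost(par, spec), error = function(e) 1e16)
      evals$par[[length(evals$par) + 1L]] <- par
      evals$cost <- c(evals$cost, val)
      val
    }
    gr <- function(theta) {
      par <- exp(theta)
      g <- tryCatch(cost_gradient_adjoint(par, spec)$gradient,
                    error = function(e) rep(0, np))
      g * par # chain rule for theta = log c
    }
    res <- stats::optim(log(c_init), fn, gr, method = "BFGS",
                        control = list(maxit = opt$max_iter, reltol = opt$ftol))
    c_hat <- exp(res$par)
    trace <- cummin(evals$cost)
    niter <- res$counts[["function"]]
    term <- if (res$convergence == 0) "converged" else
      paste("optim convergence code", res$convergence)
  } else {
    stop("unknown fit method '", opt$method, "'")
  }

  # accepted iterates: first evaluation matching each accepted cost value
  iterates <- NULL
  if (length(trace)) {
    rows <- match(trace, evals$cost)
    ok <- !is.na(rows)
    if (any(ok))
      iterates <- do.call(rbind, evals$par[rows[ok]])
  }

  rel_errors <- NULL
  if (!is.null(opt$truth))
    rel_errors <- abs(c_hat - opt$truth) / abs(opt$truth)

  structure(list(c_hat = stats::setNames(c_hat, spec$net$param_names),
                 cost = sum(moment_residuals(c_hat, spec)^2),
                 cost_trace = trace,
                 n_iterations = niter,
                 termination = term,
                 iterates = iterates,
                 rel_errors = rel_errors,
                 n_evals = length(evals$cost)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  c_hat: ", paste(signif(x$c_hat, 5), collapse = ", "),
      "\n  cost: ", signif(x$cost, 6),
      "\n  iterations: ", x$n_iterations,
      "\n  termination: ", x$termination, "\n", sep = "")
  invisible(x)
}

#' Metropolis random-walk MCMC over rate parameters
#'
#' Samples the posterior of the rate parameters under independent Gamma
#' priors using symmetric Gaussian random-walk proposals
#' `c' = c + eps, eps ~ N(0, diag(proposal_sd^2))`, accepting with
#' probability `min(1, exp(delta log posterior))`. Proposals leaving the
#' positive orthant are rejected (zero prior support); a failing likelihood
#' evaluation at a proposal is treated as a rejection with a warning.
#'
#' @param log_target log-likelihood function of the parameter vector, or
#'   `NULL` for prior-only sampling.
#' @param priors list with numeric vectors `shape` and `rate` (independent
#'   Gamma prior per parameter).
#' @param c_init positive starting point.
#' @param n_steps total number of steps (> `burn_in`).
#' @param proposal_sd per-parameter proposal standard deviations (default 5%
#'   of `c_init`).
#' @param burn_in steps discarded by [chain_summary()] (stored in the chain).
#' @param seed integer RNG seed; chains are bit-reproducible given the seed.
#' @return a `chain`: list with `samples` (`n_steps x n_params`),
#'   `log_target_trace`, `acceptance_rate`, `burn_in`, `seed`, `priors`,
#'   `proposal_sd`.
#' @export
mcmc_metropolis <- function(log_target = NULL, priors, c_init, n_steps = 50000,
                            proposal_sd = 0.05 * c_init, burn_in = 10000,
                            seed = 1L) {
  np <- length(c_init)
  stopifnot(all(c_init > 0), all(proposal_sd > 0), n_steps > burn_in,
            burn_in >= 0, length(priors$shape) %in% c(1, np),
            length(priors$rate) %in% c(1, np))
  shape <- rep(priors$shape, length.out = np)
  rate <- rep(priors$rate, length.out = np)
  n_fail <- 0L

  log_post <- function(cc) {
    if (any(cc <= 0)) return(-Inf)
    lp <- sum(stats::dgamma(cc, shape = shape, rate = rate, log = TRUE))
    if (!is.null(log_target)) {
      ll <- tryCatch(log_target(cc), error = function(e) {
        n_fail <<- n_fail + 1L
        -Inf
      })
      lp <- lp + ll
    }
    lp
  }

  set.seed(as.integer(seed))
  samples <- matrix(0, n_steps, np,
                    dimnames = list(NULL, names(c_init)))
  lt <- numeric(n_steps)
  cur <- c_init
  cur_lp <- log_post(cur)
  if (!is.finite(cur_lp)) stop("log posterior is not finite at c_init")
  acc <- 0L
  for (s in seq_len(n_steps)) {
    prop <- cur + stats::rnorm(np, 0, proposal_sd)
    prop_lp <- log_post(prop)
    if (is.finite(prop_lp) && log(stats::runif(1)) < prop_lp - cur_lp) {
      cur <- prop
      cur_lp <- prop_lp
      acc <- acc + 1L
    }
    samples[s, ] <- cur
    lt[s] <- cur_lp
  }
  if (n_fail > 0)
    warning(n_fail, " proposal(s) failed target evaluation and were rejected")
  structure(list(samples = samples, log_target_trace = lt,
                 acceptance_rate = acc / n_steps, burn_in = burn_in,
                 seed = seed, priors = list(shape = shape, rate = rate),
                 proposal_sd = proposal_sd),
            class = "chain")
}

#' @export
print.chain <- function(x, ...) {
  cat(sprintf("<chain: %d steps (%d burn-in), %d parameters, acceptance %.3f>\n",
              nrow(x$samples), x$burn_in, ncol(x$samples), x$acceptance_rate))
  invisible(x)
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) scalar chain
mcse_batch <- function(x, n_batches = 50) {
  n <- length(x)
  b <- max(2, floor(n / n_batches))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * b + 1):(i * b)]),
               numeric(1))
  stats::sd(bm) / sqrt(nb)
}

#' Summarize an MCMC chain
#'
#' Post-burn-in marginal statistics per parameter and per requested linear
#' combination of parameters: mean, standard deviation, quantiles,
#' batch-means Monte-Carlo standard errors (for the mean and for the second
#' central moment), and fixed-bin histogram counts.
#'
#' @param chain a `chain` from [mcmc_metropolis()].
#' @param combos optional named list of coefficient vectors, e.g.
#'   `list("c1-c2" = c(1, -1), "c1+c2" = c(1, 1))`.
#' @param bins number of histogram bins.
#' @return a `chain_summary`: list of per-quantity statistics.
#' @export
chain_summary <- function(chain, combos = NULL, bins = 30) {
  keep <- seq(chain$burn_in + 1, nrow(chain$samples))
  if (length(keep) < 1) stop("chain is empty after burn-in")
  S <- chain$samples[keep, , drop = FALSE]
  cols <- as.list(as.data.frame(S))
  nm <- colnames(S)
  if (is.null(nm)) nm <- paste0("c", seq_len(ncol(S)))
  names(cols) <- nm
  for (cn in names(combos)) cols[[cn]] <- as.numeric(S %*% combos[[cn]])

  out <- lapply(cols, function(x) {
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
    list(mean = mean(x), sd = stats::sd(x),
         quantiles = stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975)),
         mcse_mean = mcse_batch(x),
         mcse_var = mcse_batch((x - mean(x))^2),
         hist_breaks = h$breaks, hist_counts = h$counts)
  })
  structure(list(stats = out, n_kept = length(keep),
                 acceptance_rate = chain$acceptance_rate),
            class = "chain_summary")
}

#' @export
print.chain_summary <- function(x, ...) {
  cat(sprintf("<chain_summary: %d kept samples, acceptance %.3f>\n",
              x$n_kept, x$acceptance_rate))
  for (nm in names(x$stats))
    cat(sprintf("  %-10s mean %.5g sd %.5g\n", nm, x$stats[[nm]]$mean,
                x$stats[[nm]]$sd))
  invisible(x)
}
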