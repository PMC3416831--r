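# stokinfit

Moment fitting for parameter inference in stochastic biochemical reaction
networks.

## The problem

Intracellular reaction networks at low copy numbers are stochastic: a
well-mixed system of `u` species and `v` reactions is a Markov jump process
whose state `x` (molecule counts) advances by the stoichiometric column
`S[, j]` whenever reaction `j` fires at its propensity rate `h_j(x, c)`.
The rate constants `c` must usually be inferred from data. Modern
experiments can observe some species repeatedly over `N` independent
replicates at discrete times `t_1 < ... < t_K`, which makes per-time
**sample moments** available — the sample mean and the sample covariance of
the observed counts — not just a single mean trace.

Classical fitting compares data only with the model **mean**. That can be
fatally degenerate: for the linear birth–death process
(`X -> 2X` at rate `c1*x`, `X -> 0` at rate `c2*x`) the mean is
`m(t) = x0 * exp((c1 - c2) * t)`, so every parameter pair with the same
difference `c1 - c2` explains the mean data equally well — a perfectly flat
ridge in the cost landscape, i.e. extreme parameter sloppiness.

`stokinfit` implements **moment fitting**: solve a closed ODE system for
the theoretical moments up to order `n` and minimize

    Delta_n(c) = sum_i w_i * sum_k || nu_hat_i(t_k) - nu_tilde_i(t_k; c) ||^2

over the rate constants, where `nu_hat_1, nu_hat_2` are the per-time sample
mean/covariance of the observed components and `nu_tilde_i(t; c)` the
matching blocks of the moment-ODE solution. Fitting the second moment
restores curvature along mean-invariant directions, repairs
identifiability, and — through better Hessian conditioning — speeds up
gradient-based optimizers.

The package provides, for the whole pipeline:

- **Networks** — `make_network()` for mass-action systems,
  `builtin_model()` for three classics: linear birth–death, reversible
  dimerisation (conservation-reduced, quadratic hazard), and a
  p53–Mdm2 negative feedback loop with a saturating (rational) hazard.
- **Synthetic data** — an exact Gillespie direct-method simulator
  (`simulate_ssa`, `simulate_ensemble`) with reproducible per-replicate
  RNG substreams, and `compute_sample_moments()`.
- **Moment systems** — exact equations for affine propensities, normal
  moment closure for one-dimensional networks, the linear noise
  approximation for multivariate nonlinear networks, the macroscopic rate
  equation, a closed-form birth–death solution, and a truncated
  chemical-master-equation oracle for validation.
- **Inference** — weighted moment-residual costs (`cost_spec`,
  `moment_cost`), adjoint-method gradients (`cost_gradient_adjoint`),
  trust-region least-squares fitting (`fit_parameters`), Metropolis
  random-walk MCMC (`mcmc_metropolis`) including the mean-only likelihood
  that reproduces the classic ridge failure mode, and Hessian-based
  sloppiness analysis (`cost_hessian`, `sloppiness_report`,
  `levelset_scan`).
- **I/O and CLI** — CSV/JSON serialization for every artifact and a thin
  `stokinfit` command-line tool (`simulate`, `moments`, `fit`, `mcmc`,
  `sloppy`, `casestudy`).

## Worked example

Simulate birth–death data at the true rates `(0.3, 0.4)` and fit from the
deliberately distant initial guess `(2.0, 2.1)`, once from means alone and
once from means plus variances:

```r
library(stokinfit)
cs <- casestudy_birth_death(seed = 1, N = 10000)

round(cs$fit_mean_only$c_hat, 4)
#>      c1      c2
#> 10.5961 10.6963
round(cs$diff_rel_error, 4)
#> 0.0024
round(cs$fit_moments$c_hat, 4)
#>     c1     c2
#> 0.3032 0.4030
cs$report_moments$condition_number
#> [1] 329.3708
```

The mean-only fit wanders far along the ridge — the individual rates are
off by a factor of 30, yet their difference is recovered to 0.2%, exactly
the degeneracy the flat direction predicts (the mean-only Gauss–Newton
Hessian has eigenvalue ratio at numerical zero with sloppy direction
`(1,1)/sqrt(2)`). The mean+variance fit recovers both rates to about 1%
with a regular Hessian.

The same comparison from the shell:

```sh
stokinfit casestudy birth_death --seed 1 --outdir results/bd
```

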