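# lfpce

Gradient-based Bayesian optimal experimental design (BOED) for
simulation-based inference (SBI), in pure R.

## The problem

A stochastic simulator `y = g(theta, xi, z)` defines an *implicit*
likelihood: you can draw responses but not evaluate `p(y | theta, xi)`.
Designing a good experiment under such a model means maximizing the
expected information gain

    I(xi) = MI_xi(theta; y),

the mutual information between parameters and responses — and every
classical estimator of it needs the likelihood you do not have.

This package implements the **likelihood-free prior-contrastive
estimation (LF-PCE)** lower bound: the intractable likelihood inside the
PCE bound

    I_PCE(xi, L) = E[ log p(y|theta_0, xi)
                      - log( (1/(L+1)) * sum_{l=0..L} p(y|theta_l, xi) ) ]

is replaced by an amortized conditional normalizing-flow density
`p_phi(y | theta, xi)`. Because the flow is exactly normalized the bound
structure survives, and because it is differentiable in everything, a
single stochastic-gradient loop can optimize the design `xi` and the
flow weights `phi` *simultaneously*. The loss adds an optional
likelihood regularizer:

    L(phi, xi) = -( I_LFPCE + lambda * mean(log p_phi(y | theta_0, xi)) ).

The same trained flow is then the likelihood for MCMC posterior
inference at the optimized design: `p(theta | y_obs, xi*) proportional to
p_phi(y_obs | theta, xi*) p(theta)`.

There is no autodiff framework in this stack: the conditional neural
spline flow (rational-quadratic spline bijectors with residual-MLP
conditioners) and its full reverse-mode gradient — including gradients
in the designs, the parameters and the responses, and pathwise gradients
of its sampler via implicit differentiation — are implemented by hand
and verified against finite differences in the test suite.

Audience: statisticians and modelers doing BOED/SBI on black-box
simulators, and anyone needing an exact-density conditional flow in R.

## Worked example

Optimize a 2-coordinate design for the noisy linear simulator
`y_i = theta0 + theta1 * xi_i + eps_i + nu_i` (Gaussian + Gamma noise),
then infer `theta` from a synthetic observation at the optimized design:

```r
library(lfpce)

prior <- normal_prior(mean = c(0, 0), scale = c(3, 3))
sim   <- noisy_linear_model()          # eps ~ N(0,1), nu ~ Gamma(2,2)
set.seed(99)
flow  <- conditional_flow(theta_dim = 2, design_dim = 2)

fit <- train_joint(sim, prior, flow,
                   train_config(n_steps = 1000, lambda_reg = 1, seed = 1))
fit$xi
#> <design D=2 in [-10, 10]>
#> [1]  -9.952744 -10.000000

evaluate_eig(fit$flow, sim, prior, fit$xi,
             n_outer = 100, n_contrastive = 500)
#> <lfpce bound: 2.4293 nats (N=100, L=500, ceiling log(L+1)=6.2166)>

set.seed(1)
y_obs <- simulate_noisy_linear(sim, c(2, 5), fit$xi)   # truth: (2, 5)
obs   <- observation(as.numeric(y_obs), fit$xi, theta_true = c(2, 5))
post  <- summarize_posterior(run_mcmc(obs, fit$flow, prior))
post
#> theta0: -0.594 +/- 2.471
#> theta1: 4.944 +/- 0.301
```

Reading the output: the loop pushes both design coordinates to the
`[-10, 10]` box boundary, where a measurement is most informative about
the slope; the evaluated bound (~2.4 nats, necessarily below the
`log(501)` ceiling) is the certified information gain of the learned
design under the learned likelihood; and the MCMC posterior from the
amortized flow covers the generating parameters `(2, 5)`, with the
slope pinned an order of magnitude more tightly than the offset (the
offset is weakly identified and confounded with the Gamma noise mean).

The full reproduction sweep (design dimensions x lambda x seeds, traces,
design snapshots and the posterior table as CSV/JSON/YAML artifacts) is
`run_linear_study(study_config(...))`, also reachable from the command
line via `inst/cli/lfpce`.

## Validation oracles

The fully Gaussian variant `gaussian_linear_model()` has a closed-form
EIG (`analytic_eig_gaussian()`, `0.5 * log det(I + s^-2 Sp X'X)`), an
exact likelihood, and a nested Monte-Carlo estimator (`nmc_eig()`).
These anchor the test suite: exact-likelihood PCE converges to the
analytic EIG from below, LF-PCE with a "perfect flow" equals PCE, the
trained flow approaches the exact likelihood, and MCMC recovers the
conjugate posterior.

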