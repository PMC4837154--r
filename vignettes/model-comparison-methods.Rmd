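---
title: "Comparing adaptive-learning models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing adaptive-learning models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmhgf)
```

## The problem

Human observers tracking a noisy, changing quantity (a dot position, a reward
rate) must decide, trial by trial, how much of each prediction error to absorb
into their estimate. Two well-established families of sequential Bayesian
filters formalise this with *adaptive learning rates*:

* the two-level **Hierarchical Gaussian Filter (HGF)**, which models the
  hidden state as a Gaussian random walk whose log-diffusion-rate (the
  *volatility*) is itself a random walk, and
* the variational **Change Point Model (CPM)**, which models the hidden state
  as a random walk that is occasionally (hazard `h`) redrawn wholesale from a
  broad distribution.

`cpmhgf` implements both filters, the two generative environments they
mirror, a Gaussian response model, and the full model-comparison machinery —
so that one can ask: *given only noisy responses, can the generating model,
its parameters and its internal belief trajectories be recovered?* Two
inversion schemes are compared throughout: Bayesian inference with a Laplace
approximation of the evidence (**BI-LA**) and maximum likelihood with the BIC
surrogate (**MLE-BIC**).

## Generative environments

Both environments emit `T` observations per block,
`o_t = x_t + noise(variance s)`.

* **Switching** (defaults `h = 0.1, w1 = 0.01, w2 = 10, s = 1`): with
  probability `1 - h` the state continues a random walk of variance `w1`;
  with probability `h` it is redrawn from `N(0, w2)`.
* **Diffusive** (defaults `eta = 0.1, s = 1`): the state diffuses with
  variance `exp(x2_t)`, and the log-volatility `x2` diffuses with
  variance `eta`.

All Gaussian second arguments in this package are **variances**. Two
conventions deserve a note. First, `h` is the *change* probability; the
complementary number (0.9 at the defaults) is the probability of following
the walk. Second, the initial states are not dictated by the generative
equations and are package defaults, recorded in every serialized artifact:
`x0 = 0` for the switching state, `x0_1 = 0` and `x0_2 = 0` for the
diffusive levels. Blocks are independent: hidden states are re-initialised at
every block start, which emulates separate experimental blocks.

The initial log-volatility deserves its own paragraph, because it was a
genuinely open choice and it matters. Starting `x2` very low (say
`ln(0.01)`) makes the first-trial state almost deterministic; training then
drives the believed prior uncertainty `sigma0_1` to ~`e^-5`, far into the
tail of the fixed inversion prior, and the fitted learning-rate trajectory
acquires an initial transient of the *opposite* sign to the generating one.
In that world two of the toolkit's qualitative benchmark findings invert: coverage of
the seven-parameter posterior falls well below nominal, and the matched
model's learning-rate correlation drops below the mismatched one. With
`x0_2 = 0` — initial state diffusion at the scale of the observation noise,
comparable to the switching environment's stationary spread — both findings
come out as expected (HGF-side coverage near 0.95, matched correlation far
above mismatched). The default is therefore `x0_2 = 0`, with the
low-volatility start available as a configurable variant.

## The filters

Both filters carry a level-1 posterior `(mu1, sigma1)` updated by a
delta rule `mu1 <- mu1 + alpha1 * (o - mu1)` with `alpha1 = sigma1 / s`,
which the precision updates force into `(0, 1]`. They differ in how the
learning rate adapts:

* the HGF inflates the level-1 prior variance by `exp(mu2)`, with `mu2`
  updated by a single Newton step on the level-2 variational energy,
  linearised at the prior expectation (not iterated to convergence — this is
  the standard closed-form filter, and its per-trial *free energy* is a lower
  bound on the marginal log-likelihood);
* the CPM computes a per-trial change-point probability `Omega` from the two
  predictive densities (walk vs. redraw) and discounts the old precision by
  `1 - Omega`; its per-trial surprise is exact (a two-component mixture). The
  redraw-conditional posterior uncertainty uses the stated approximation
  `sigma|2 ~ s`, valid for `w2 >> s` (the constructor warns otherwise). The
  volatility-like quantity `mu2 = logit(Omega) / a` uses an arbitrary
  positive scale `a` (default 1; correlation analyses are invariant to it).

Numerical guards, all flagged rather than silent: `Omega` is clamped to
`[1e-12, 1 - 1e-12]` before the logit; the CPM's level-2 state starts at the
logit of the hazard (its no-data expectation); the HGF's level-2 precision
update can turn non-positive for extreme inputs, in which case forward
filtering raises an error carrying the trial index while likelihood
evaluation returns `-Inf` so that optimisers treat the parameter set as
rejected. Forward simulation of agents with trained parameters can still hit
that pathology on rare fresh blocks (a property of the filter, not a bug);
`simulate_valid_agent()` deterministically redraws the block and records the
seed actually used.

## Response model and inversion

Responses are `r_t = mu1_t + noise`, with `sigma_r` the response-noise
**variance** (the generative equation's literal reading would make it a
standard deviation; the likelihood and the stated noise levels 1 and 5 are
consistent only with the variance reading, which we adopt everywhere).
The response at trial `t` conditions on the belief *after* observing `o_t`.

Each full behavioural model has seven free parameters (six perceptual plus
`sigma_r`), fitted in an unconstrained space: identity for location
parameters, `log` for variances, `logit` for the hazard. The prior in that
space is independent normal, mean 0 and variance 5 everywhere except
`eta` (mean -2), `w2` (mean 7) and `h` (mean -3, variance 2). `sigma_r` is
absent from the stated transform list but is a free parameter; it is
log-transformed with the generic N(0, 5) prior for consistency with the
other variances.

Optimisation uses a compact, fully seeded CMA-ES (no CMA-ES package exists in
the supported environment, so the standard rank-one/rank-mu algorithm with
step-size adaptation and population-doubling restarts is implemented here),
followed by a Nelder-Mead polish of the incumbent. Defaults: start at the
prior mean, initial step 1, 5000 evaluations, 3 restarts. Curvature at the
mode comes from a central finite-difference Hessian (per-coordinate steps,
shrunk automatically if a probe lands in the rejected region); it is
inverted through its eigendecomposition with eigenvalues floored at `1e-8`
(flagged as repaired when the floor binds), which also handles the extreme
conditioning of barely identified directions. BI-LA evidence is the
log-joint at the mode plus `0.5 * log|2*pi*S|`; MLE evidence is the
log-likelihood at the maximum minus `(d/2) * log T`.

## Training

`train_perceptual()` emulates the pre-experiment training session: it
maximises the summed per-trial free energy (HGF) or exact log marginal
likelihood (CPM) over many blocks, penalised by the same transformed-space
prior, and returns natural-scale parameters. The full-scale protocol uses
1000 blocks of 100 trials; the desk-scale pipelines here use 200 (tests go
as low as 8-50), which recovers the informative parameters well. Note that
training recovers the *filter-optimal* parameters, which for the approximate
CPM need not equal the generative ones exactly (`w1` in particular absorbs
some approximation bias).

## What the synthetic world does and does not establish

The generator *is* the model family under study, so green recovery tests
establish internal consistency of simulation + inversion — not that either
filter describes human behaviour. Real data would add features deliberately
absent here: response lapses and biases, non-Gaussian noise, reaction-time
structure, learning during the test session.

One honest caveat deserves emphasis. Coverage of the +/- 2 sd interval is
close to nominal for the HGF (about 0.95 averaged over its seven
parameters) but lower for the CPM, whose redraw variance `w2` is only weakly
identified at `T = 100`: its posterior is pulled towards the prior mean
(7 in log space) while the trained truth sits near `ln 10 ~ 2.3`, so that
parameter's interval misses the truth for a substantial fraction of agents
(we verified this is not an optimiser failure — the log-joint is unimodal in
our checks, with optimisation from the truth reaching the same mode as from
the prior mean — but genuine posterior geometry under the fixed prior). The
seven-parameter average across both models lands slightly below 0.95 for
this reason; the well-identified parameters (`s`, `h`, `eta`, `sigma_r`, the
level-1 location) are individually close to nominal. Calibration studies of
this kind usually display only the informative parameters, precisely because
the weakly identified ones behave this way.

## Group model selection and the factorial experiment

`group_bms()` implements the standard random-effects scheme: a variational
Dirichlet posterior over population model frequencies (uniform Dirichlet
prior), with the two-model exceedance probability in closed form through the
regularised incomplete beta function (cross-checked against Monte Carlo).
`confusion_experiment()` resamples groups of `k = 20` agents from a fitted
pool and tabulates the winning model (exceedance > 0.5 — the winner rule is
a convention here; exceedance above one half is the standard
choice) against the generating one. `run_experiment()` chains
training -> simulation -> fitting -> evaluation over the full
environment x model x noise x duration factorial with derived seeds and a
file manifest; the second experiment duration is exposed as configuration
(defaults 50 and 100) since only `T = 100` is stated explicitly.

Trajectory correlations (`trajectory_correlation()`) compare generating and
re-inferred internal variables (`mu1`, `alpha1`, `eps1`, `mu2`, `eps2`) by
Pearson correlation, skipping the first trial, whose level-2 prediction
error is initialisation-dependent; `exceedance_vs_median()` quantifies
whether MLE-based trajectories beat the BI-LA median.

## A small worked example

```{r example, eval = FALSE}
env <- switching_params()
blk <- simulate_switching(env, T = 100, seed = 1)
agent <- simulate_agent("CPM", cpm_params(), blk, sigma_r = 1, seed = 2)
fit <- fit_bi_la(agent, "CPM", seed = 3)
fit$log_evidence
trajectory_correlation(agent, fit)
```

## Known limitations

* The Laplace approximation is the only inversion scheme; MCMC or full
  variational alternatives are out of scope.
* Two hierarchy levels only; no binary-outcome variants; single learning-rate
  CPM.
* Coverage calibration inherits the initial-state and prior choices discussed
  above; users probing calibration should vary `x0`/`x0_2` and the prior.
* The CMA-ES implementation is compact; for very rugged likelihoods a larger
  evaluation budget (it is a single configuration knob) is advisable.
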