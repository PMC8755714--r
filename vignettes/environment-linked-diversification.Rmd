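---
title: "Episodic birth-death models of environmentally linked diversification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Episodic birth-death models of environmentally linked diversification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epochdiv)
```

# The model

`epochdiv` estimates how speciation and extinction rates of a clade changed
through time from a single time-calibrated, ultrametric phylogeny, and tests
whether those changes track a paleoenvironmental variable such as atmospheric
CO2. The process model is the *episodic birth-death process*: every lineage
speciates at rate $\lambda_i$ and goes extinct at rate $\mu_i$, where the
rates are constant within an epoch (an age interval) and shift instantly at
epoch boundaries. Rates are homogeneous across contemporaneous lineages —
there are no lineage-specific shifts, which is also what keeps the model
identifiable.

Writing $t$ for forward time (0 at the root, $T$ at the present),
$r(t,T)=\int_t^T(\mu(s)-\lambda(s))\,ds$, and $P(t)$ for the probability that
a lineage alive at $t$ leaves at least one *sampled* descendant at the
present (sampling fraction $\rho$), the probability density of a
reconstructed tree with $n$ sampled tips, conditioned on the two root
lineages both surviving, is

$$
f(\Psi) \;=\; \frac{2^{n-1}}{n!}\;
\left[\frac{p_1(t_1)}{P(t_1)}\right]^2
\prod_{i}\lambda(t_i)\,p_1(t_i),
\qquad p_1(t) = \frac{P(t)^2 e^{r(t,T)}}{\rho},
$$

the product running over the $n-2$ non-root internal nodes. $p_1(t)$ is the
probability that a lineage at $t$ leaves exactly one sampled descendant. For
piecewise-constant rates, $1/P(t)$ has a closed form as a sum of positive
per-epoch terms, which the package accumulates entirely in log space by
log-sum-exp; the $\lambda_j=\mu_j$ degeneracy is handled by a second-order
series expansion below $|\mu-\lambda| < 10^{-10}$, so no parameter
combination produces `NaN`.

Because the density is a function of the *rate functions* and not of the
epoch partition, refining epochs with equal rates leaves it unchanged; the
test suite checks this identity to $10^{-10}$ and checks the constant-rate
special case against an independent implementation of the classical
reconstructed-process density, the pure-birth closed form, and an exact
integration identity (for 3-tip trees the density integrates, over topology
and node time, to the analytic geometric tip-number probability of the
conditioned process).

## Empirical (clade-informed) taxon sampling

Hyper-diverse groups are never completely sampled, and the missing species
are not spread uniformly: they concentrate in particular named clades. The
empirical sampling model takes, for each named clade $i$, the count $k_i$ of
known-but-unsampled extant species. The tree factor is then evaluated at
$\rho=1$ (combining a global $\rho<1$ with clade terms would double-count
missing species, and the package refuses to), and each missing speciation
event is integrated over the interval in which it must have occurred — from
the clade age $c_i$ to the present — via the speciation-time distribution
function

$$
F(t) = 1-\frac{1-P(t)\,e^{r(t,T)}}{1-P(t_1)\,e^{r(t_1,T)}},
$$

giving the joint density
$f(\Psi)\times\frac{(m-1)!}{(n-1)!}\prod_i \frac{(1-F(c_i))^{k_i}}{k_i!}$,
with $m$ the total species count. All factorials are log-gamma differences.

Two conventions for $c_i$ exist because the clade's earliest missing
speciation could be placed from its crown or its stem: the package defaults
to the crown age of the sampled members and exposes `clade_age = "stem"` as
an option. The crown default matches the one-surviving-lineage conditioning
of $F$; the stem window is wider, so the density under it is never smaller.

A caveat worth stating: the $(1-F(c_i))^{k_i}$ term treats each missing
speciation time as an independent event on a single surviving lineage. Exact
marginalization of a complete tree in which a clade holds many missing
species would also track how many clade lineages were available at each
time. For small $k_i$ the two agree (the package's quadrature tests show
exact agreement for the one-clade, few-missing cases); for clades carrying
hundreds of missing species the single-lineage form is an approximation, and
in simulation it can surface as mild spurious rate variation concentrated
near the clade ages. This is a property of the model form itself, not of the
implementation.

## Priors on epoch rates

Log rates get one of three prior families, identically and independently
structured for $\lambda$ and $\mu$:

* **UCLN** — iid $\ln\lambda_i \sim \mathrm{Normal}(m_0,\sigma)$;
  uncorrelated epochs. $m_0$ gets a Uniform(-10, 5) prior on the log scale
  (about $4.5\times10^{-5}$ to 148 events/lineage/Myr).
* **GMRF** — a discretized Brownian motion,
  $\ln\lambda_i \sim \mathrm{Normal}(\ln\lambda_{i-1},\sigma)$, anchored at a
  present-day rate $\lambda_0 \sim \mathrm{Uniform}(0,100)$.
* **HSMRF** — the horseshoe variant, with a local scale per increment,
  $\gamma_i \sim \mathrm{halfCauchy}(0,1)$ and increment scale
  $\sigma\gamma_i$: abrupt jumps are possible while constant stretches are
  smoothed harder.

The global scale $\sigma$ gets a half-Cauchy hyperprior whose scale
`mrf_global_scale()` calibrates so that, at the hyperprior median, the prior
expects about $\ln 2$ "effective shifts" (adjacent epochs differing by more
than two-fold) across the grid — the convention of the Markov-random-field
literature this construction comes from. Epoch counts of 4-200 equal-width
age intervals are the intended range; other counts work but warn.

## Environmentally dependent diversification

The environmental series (age-value pairs) is binned onto the same epoch
grid by arithmetic means — the per-epoch mean of raw observations, epochs
half-open so a boundary observation belongs to the younger epoch, empty
epochs interpolated with a warning. Interval widths of 1, 2, and 5 Myr are
the usual choices. Only the per-epoch *differences* $\Delta E_i$ enter the
models, so adding a constant to the series changes nothing.

Four link models connect rates to the series through a correlation factor
$\beta$ (separately $\beta_\lambda$, $\beta_\mu$):

* **fixed** — $\ln\lambda_i = \ln\lambda_{i-1} + \beta\,\Delta E_i$:
  deterministic linkage, no independent rate variation.
* **UCLN-env** — iid lognormal deviations around that trajectory.
* **GMRF-env** — Brownian motion with the environmental trend as drift.
* **HSMRF-env** — the horseshoe field with the same trend.

Only this exponential dependency is implemented; a linear dependency can
produce negative rates and is excluded. At $\beta=0$ each model collapses
exactly (to the log-density) to its environment-free counterpart, which is
what makes "no correlation" a well-defined nested hypothesis. $\beta$ is not
a correlation coefficient in $[-1,1]$: it is the factor converting
environmental change into log-rate change.

The prior on $\beta$ is Normal$(0,\sigma_\beta)$ — symmetric and zero-centred
so the prior odds $P(\beta<0)/P(\beta>0)$ equal 1 exactly. By default
$\sigma_\beta$ is set so that $\beta$ times the observed range of the series
spans $\pm 3$ log-rate units; for a CO2 series spanning ~600 ppm this gives
$\sigma_\beta \approx 0.005$, on the scale of the effects the method is
meant to detect.

## Inference

`div_model()` assembles tree, priors, link, and sampling scheme into a
model object; `run_mcmc()` samples it with adaptive random-walk Metropolis
moves on scalars (Robbins-Monro adaptation toward 0.35 acceptance, frozen
after burn-in) and elliptical slice sampling on the non-centered
standard-normal increment fields of the MRF priors. Default burn-in is 10%
with no thinning; effective sample sizes use the standard
autocorrelation-time estimator. The engine is generic: a conjugate
normal-mean model plugged into the same machinery reproduces its closed-form
posterior and marginal likelihood, which is the package's primary validity
check for the sampler, and simulation-based calibration on the fixed-link
model yields uniform rank statistics for $\beta$.

Marginal likelihoods for model selection come from stepping-stone sampling:
power posteriors at exponents placed on Beta(0.3, 1) quantiles (dense near
the prior), each stone its own warm-started chain, 128 stones in full
analyses (tests use fewer with more error tolerance). Support for a
negative correlation is read directly from the posterior: since the prior
odds are 1, BF$(\beta<0)$ is the posterior odds, computed with add-one
smoothing $(N_{<0}+1)/(N_{>0}+1)$ so an all-negative trace of 37,500
samples yields the finite, sample-size-bound value 37,501; the raw ratio is
available by flag.

## Simulation and validation

`simulate_tree()` runs the process forward from two root lineages by a
Gillespie algorithm with piecewise-constant rates, prunes extinct and
unsampled lineages, and conditions by rejection on both root lineages
leaving a sampled descendant — the same conditioning the likelihood uses.
`simulate_env_tree()` draws a rate trajectory from a chosen link model
first. `simulate_empirical_sampling()` emulates clade-informed incomplete
sampling: missing species are attached uniformly at random within their
named clade, all divergence times are redrawn from the generating process
conditional on the topology (iid draws from the speciation-time distribution
assigned along a uniformly random ranked history; the next node is chosen
with probability proportional to its subtree size, which is what makes the
ranking uniform), and the added species are pruned away again.

The synthetic environmental curve (`synthetic_cenozoic_co2()`) is a smooth
deterministic stand-in for a Cenozoic CO2 record — high Eocene values, a
steep Oligocene-like logistic decline centered near 31 Ma, near-modern
Neogene values, a mild oscillation. It emulates the *shape* that matters for
the method (a large monotone step concentrated in a few epochs); it does not
emulate measurement noise, proxy disagreement, or uneven age coverage of
real compilations, so passing tests say nothing about proxy uncertainty.
Simulated trees likewise carry no dating error: divergence times are exact,
whereas real chronograms carry calibration uncertainty the model does not
propagate.

## Numerical choices and problem sizes

All likelihood work is in log space; survival probabilities are accumulated
by log-sum-exp over positive terms, so under- and overflow cannot produce
`NaN`. Inside `div_model()` the log rates are additionally restricted to
$|\ln \text{rate}| \le 20$: beyond that the log-space sums reach magnitudes
at which double precision loses all additive accuracy (and rates of
$e^{20}$ per Myr are biologically meaningless anyway).

The shipped validation suite uses deliberately modest problem sizes chosen
to exercise every code path at high statistical power per CPU-second: toy
trees of 3-5 tips for exact oracles, simulated trees of roughly 100-400
tips with 10 epochs for recovery studies (ten replicates per condition,
chains of a few thousand sweeps), $10^5$ forward simulations for the
distribution-function cross-check, and 32-stone ladders for the evidence
checks. Full-scale analyses (hundreds of epochs, 128 stones, multi-thousand
tip supertrees) use the same code paths and simply take longer.

## Known limitations

* The single-lineage missing-species term is approximate for clades with
  very many missing species (see above).
* $\rho$ is a fixed datum, not a parameter; lineage-specific rate shifts and
  fossilized birth-death processes are out of scope.
* The environmental series and the epochs must share one grid; time-lagged
  or multivariate environmental dependencies are not modeled.
* Iteration counts are full sweeps over all update blocks and are not
  comparable to single-move-per-iteration samplers.
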