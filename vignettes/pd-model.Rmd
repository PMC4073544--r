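---
title: "The perceptual-detection model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The perceptual-detection model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdetect)
```

## The model

The perceptual-detection (PD) model is a multinomial processing tree for
two-condition detection experiments with four ordered confidence
categories. Its central claim is that responses are a *stochastic
mixture* of discrete states rather than readings of a single continuous
strength axis. On a target-present trial the observer reaches a state of
certain detection with probability $\theta_d$, in which case the
response is always "definitely yes". Otherwise (probability
$1-\theta_d$) the observer guesses: "yes" with probability $\theta_g$,
"no" with probability $1-\theta_g$, and a guess is voiced with the
high-confidence rating with probability $\theta_h$. Target-absent trials
mirror this with the certain non-target identification rate
$\theta_{nt}$ and the "no"-guess rate $\theta_g'$. The same $\theta_h$
applies to guesses in both conditions; it is a nuisance correction for
over-confident guessing.

The five parameters therefore map to eight category probabilities with
six free data proportions, leaving one degree of freedom for goodness of
fit ($G^2$ with one degree of freedom).

Assumptions worth keeping in mind:

* certain detection always produces the extreme rating — there is no
  "certain but cautious" state;
* the two conditions share a single over-confidence rate $\theta_h$;
* trials are i.i.d. within a condition, so the likelihood is a product
  of two multinomials.

## Estimation

**Maximum likelihood** (`fit_mle()`). The likelihood has a closed-form
interior maximum. The shared $\theta_h$ is identified by two independent
binomial splits — the definitely/probably split among present-condition
"no" guesses ($x_1 : x_2$) and among absent-condition "yes" guesses
($y_4 : y_3$) — and its profile MLE pools them with count weights,
$\hat\theta_h = (x_1+y_4)/(x_1+x_2+y_3+y_4)$. The remaining four
parameters follow by inverting the tree. At small samples the
closed-form values regularly leave $[0,1]$; the fit then switches to
multi-start box-constrained optimisation (L-BFGS-B from five fixed
starts) and records which parameters triggered the fallback, rather
than clamping — a clamped closed form is not in general the constrained
optimum. The test suite checks the fit against a brute-force grid
oracle and an independent optimiser on hundreds of random tables.

**Population parameter mapping** (`fit_ppm()`). Each condition's cell
proportions get an independent Dirichlet posterior; joint draws are
mapped through the inverse tree equations, and draws whose mapped
parameters leave the unit hypercube are discarded as *incoherent*. The
retained fraction is the model's coherence probability. Because
$\theta_h$ is over-determined, the inverse map must choose how to
combine the two splits; we use the count-weighted pooled ratio, which
coincides with the profile MLE when evaluated at observed proportions.
The default prior adds $1/2$ to each cell (a Jeffreys-style choice).
We examined both the uniform ($+1$) and Jeffreys priors against the
published worked example this package reproduces: the Jeffreys prior
recovers the published posterior means for $\theta_d$, $\theta_{nt}$
and $\theta_h$ to within 0.01, while the uniform prior shrinks
$\theta_d$ about 0.025 too far toward the centre of the simplex at this
sample size; the `prior` argument exposes the choice. The published
analysis used a proprietary mapping whose exact form is not stated;
with our mapping the posterior means of the guessing parameters differ
from the published ones by up to about 0.03.

**MCMC** (`fit_mcmc()`). Independent uniform priors on all five
parameters with single-site random-walk Metropolis on the logit scale
(normal proposals, scale 0.5; defaults 20000 iterations, 5000 burn-in,
no thinning). The posterior is five-dimensional, unimodal and cheap to
evaluate, so nothing fancier is warranted. On the worked example the
posterior means agree with the published MCMC analysis to within 0.003.
The logit transform needs a proposal scale comment: 0.5 mixes well for
data-informed posteriors; for a pure prior (empty tables) a larger
scale is advisable.

## ROC geometry and area measures

The model's ROC is polygonal: two linear limbs meeting at the any-yes
operating point, with slopes
$s_{13} = (1-\theta_d)\theta_g/[(1-\theta_{nt})(1-\theta_g')]$ and
$s_{35} = (1-\theta_d)(1-\theta_g)/[(1-\theta_{nt})\theta_g']$, whose
ratio reduces to $(1-\theta_g)(1-\theta_g')/(\theta_g\theta_g')$. Twice
the area between the ROC and the chance diagonal splits into a
certain-detection part $D_c = \theta_d + \theta_{nt} -
\theta_d\theta_{nt}$ and an effective-guessing part
$D_g = (1-\theta_d)(1-\theta_{nt})[\theta_g - (1-\theta_g')]$. When
guessing is worse than pure response bias, $D_g$ is negative; we return
the signed value (with a warning) so that $D = D_c + D_g$ remains an
exact identity — tested against a shoelace-formula polygon oracle.

## The SDT baseline

`fit_sdt()` is the standard unequal-variance Gaussian rating model:
noise strength $N(0,1)$, signal strength $N(d', \sigma^2)$, three
ordered criteria. $d'$ is reported in noise-SD units. Optimisation
works on an unconstrained parameterisation ($\log\sigma$, first
criterion plus log-spacings) from five deterministic starts with a
simplex polish; the likelihood optimum was verified against an
independent implementation. Note a data-vintage subtlety: the published
figures for this radiologist ($d' = 2.332$, $\sigma_S/\sigma_N =
1.409$) sit about 0.8% away from the exact maximum-likelihood optimum
of the four-category table analysed here ($2.315$, $1.398$); they match
a least-squares fit on z-transformed ROC coordinates instead, which
this package deliberately does not implement. Similarly the package
reports the directly computed $G^2$ statistics; they are validated by
the exact-fit ($G^2 = 0$) and count-doubling properties rather than by
any printed value.

## Simulation experiments

`run_estimator_accuracy()` draws true parameters i.i.d. uniform on
$[0,1]$ (the minimal reading where no distribution is stated), simulates
$n$ trials per condition, and scores PPM posterior means against MLEs by
mean absolute error. Defaults use 2000 replicates and 2000 PPM draws per
replicate — enough for a Monte Carlo standard error of about 0.003 on
each MAE while keeping a four-size benchmark under a minute. The
qualitative findings are robust: the Bayesian posterior mean dominates
the MLE at every small-to-moderate $n$, and the two converge at
$n \approx 1000$. Exact MAE magnitudes depend on the truth
distribution, which is why the package pins the ordering and
monotonicity rather than particular decimals.

`run_pooling_vs_averaging()` generates heterogeneous cohorts — each
observer's parameter drawn from a Beta with a replicate-level mean
(uniform) and concentration 32, our reading of "slightly different true
values" — and compares averaging per-observer fits against fitting once
to the summed counts. Only the sign and the decline of the pooling
advantage with trials-per-observer are asserted; the published
advantage magnitudes depend on an unstated heterogeneity level.

`run_shrinkage_experiment()` replicates the 90-observer design: ten
observers per cell of $\theta_d \times \theta_{nt} \in \{0.2, 0.5,
0.8\}^2$, $\theta_h \sim \mathrm{Beta}(2,4)$, $\theta_g, \theta_g' \sim
\mathrm{Beta}(28,14)$, 20 trials per condition. Each observer is
estimated individually (PPM posterior mean by default; MLE by option),
then shifted by the common constant that equates the cohort mean to the
pooled-fit estimate (`adjusted_estimates()`); both sets are scored by
the rms distance to the true $(\theta_d, \theta_{nt})$ point. The mean
identity of the adjustment holds exactly and is tested to $10^{-12}$.
Two design notes. First, the adjustment can only remove error that is
*shared* across the observers being pooled; with our estimator the
shared component at $n = 20$ is small, so the default whole-cohort
adjustment yields a modest rms improvement rather than the dramatic one
an estimator with a large uniform small-sample bias would show. Second,
`group = "cell"` pools within the homogeneous design cells instead, so
the shift corrects cell-specific bias — there the adjustment's value is
clearly visible (double-digit percentage rms reductions with a
uniform-prior PPM estimator). Ten replications are used by default;
the rms values are stable to about $\pm 0.005$ across seeds.

## Degenerate inputs and numerical conventions

* Probability vectors are validated to sum to one within $10^{-12}$;
  the likelihood uses $0\log 0 = 0$ and returns $-\infty$ for a
  positive count on a zero-probability cell.
* An empty condition leaves half the parameters unidentified: the fit
  returns the identified sub-parameters and flags the rest as `NA`.
* PPM with an all-zero table samples the prior; the two $\theta_h$
  splits are then weighted equally.
* Adjusted estimates are returned unclipped by default (the affine
  identity is exact); `clip = TRUE` truncates to $[0,1]$ at the cost of
  that identity.
* All stochastic functions accept an integer `seed` and restore the
  caller's RNG state; experiment replicates consume one sequential RNG
  stream derived from it.

## What the simulations do and do not show

The generators emulate ideal PD observers: multinomial sampling from
the model's own cell probabilities, independence across trials and
observers, and stationary parameters. Real rating data bring
sequential dependencies, criterion drift, and observers whose guessing
need not follow any parametric law — passing the recovery and
benchmark tests therefore validates the estimation machinery, not the
model's adequacy for a given data set; that question belongs to $G^2$
and to comparisons with the SDT baseline. The package also implements
only the five-parameter PD tree: the variant with separate
over-confidence rates for "yes" and "no" guesses is out of scope, as
are hierarchical random-effects extensions beyond the fixed-shift
adjustment.
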