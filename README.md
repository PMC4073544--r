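# pdetect

Multinomial processing-tree analysis of perceptual detection rating data.

## The problem

A detection experiment — a radiologist classifying CT scans, a sonar
operator listening for a threat — produces a 2 × 4 table: target-present
and target-absent trials, each rated on an ordered confidence scale from
"definitely no" to "definitely yes". The classical analysis is signal
detection theory (SDT), which assumes a single continuous strength axis.
The perceptual-detection (PD) model instead treats each trial as a
*mixture* of discrete states: on a target-present trial the observer
either certainly detects the target (probability θ_d) or falls back on
guessing "yes" with probability θ_g; on a target-absent trial the
observer either certainly identifies the non-target (θ_nt) or guesses
"no" with probability θ_g′. A shared nuisance parameter θ_h is the
probability of over-confidently using the high-confidence rating while
guessing. The five parameters generate the eight category probabilities
through a processing tree, e.g. for target-present trials

    P(definitely yes) = θ_d + (1 − θ_d) θ_g θ_h
    P(probably yes)   = (1 − θ_d) θ_g (1 − θ_h)
    P(probably no)    = (1 − θ_d)(1 − θ_g)(1 − θ_h)
    P(definitely no)  = (1 − θ_d)(1 − θ_g) θ_h

The package provides:

* **Estimation** — closed-form maximum likelihood with G² goodness of
  fit (`fit_mle()`), exact Bayesian sampling by population parameter
  mapping with a model-coherence probability (`fit_ppm()`), and MCMC
  under uniform priors (`fit_mcmc()`), plus posterior queries
  (`posterior_probability()`) and the informed-guessing index
  `guessing_assessment()` = θ_g − (1 − θ_g′).
* **ROC geometry** — the model's two-limb polygonal ROC
  (`operating_points()`, `roc_path()`, `roc_slopes()`) and area-based
  detection measures D_c = θ_d + θ_nt − θ_d θ_nt,
  D_g = (1 − θ_d)(1 − θ_nt)[θ_g − (1 − θ_g′)], D = D_c + D_g
  (`area_metrics()`), with `autoplot()` methods.
* **SDT baseline** — the unequal-variance Gaussian rating model for
  comparison (`fit_sdt()`, `sdt_roc_curve()`).
* **Monte Carlo machinery** — estimator-accuracy benchmarks
  (`run_estimator_accuracy()`), pooling-versus-averaging comparisons
  (`run_pooling_vs_averaging()`), and the 90-observer shrinkage
  experiment with the fixed-shift group adjustment
  (`run_shrinkage_experiment()`, `adjusted_estimates()`).

Everything is tibble-first: fits have `tidy()` and `glance()` methods
and count tables are plain data frames with a `condition`, `category`,
`count` schema (`read_counts()` / `write_counts()`).

## Worked example

The bundled data set is a radiologist's ratings of 109 CT scans
(51 abnormal, 58 normal):

```r
library(pdetect)

scans <- radiology_scans()
fit <- fit_mle(scans)
fit
#> <PD maximum-likelihood fit>
#>       theta_d      theta_nt       theta_g theta_g_prime       theta_h
#>         0.578         0.523         0.721         0.421         0.227
#> G^2(1) = 3.208, Pearson X^2 = 3.494
```

More than half of the abnormal scans are certainly detected
(θ_d ≈ 0.58) and half of the normals certainly identified
(θ_nt ≈ 0.52) — the SDT baseline (`fit_sdt(scans)`: d′ = 2.315,
σ_S/σ_N = 1.398) has no way to express these mixture states. Bayesian
uncertainty comes from the posterior samplers:

```r
post <- fit_mcmc(scans, seed = 1)
round(unclass(post$theta), 3)
#>       theta_d      theta_nt       theta_g theta_g_prime       theta_h
#>         0.550         0.505         0.711         0.440         0.265
posterior_probability(post, "theta_d", 0.39)
#> [1] 0.9502
guessing_assessment(post$theta)
#> [1] 0.151
```

so the detection mixture is credibly present (P(θ_d > 0.39) > 0.95) and
guessing is better than pure response bias (θ_g > 1 − θ_g′). The
area-based summary of the published posterior means gives the total
detection measure:

```r
area_metrics(theta_pd(0.552, 0.496, 0.734, 0.405, 0.25))
#>     D_c    D_g     D   A_c    A_g informed
#> 1 0.774 0.0314 0.806 0.387 0.0157 TRUE
autoplot(operating_points(fit$theta), sdt = fit_sdt(scans))
```

## Vignette

`vignettes/pd-model.Rmd` documents the model, the estimation methods and
their numerical choices, the simulation designs behind the Monte Carlo
experiments, and known limitations.
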