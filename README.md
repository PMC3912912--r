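# troposcale

Trophic position (TP) from bulk nitrogen stable isotopes, under a **scaled
diet-tissue discrimination framework** for fish food webs.

Consumer tissue δ15N increases over dietary δ15N by the diet-tissue
discrimination factor Δ15N. The conventional additive TP estimator assumes
Δ15N is a constant 3.4 ‰ per trophic step,

    TP_additive = TL_base + (δ15N_consumer − δ15N_base) / 3.4,

but controlled feeding trials show Δ15N *narrows* linearly as dietary δ15N
rises, Δ15N = β0 + β1·δ15N_diet with β1 < 0. That relationship implies a
saturating (von Bertalanffy-form) enrichment curve with asymptote
δ15N_lim = −β0/β1 and per-step rate k = −log(1 + β1):

    δ15N_TP = δ15N_lim − (δ15N_lim − δ15N_base) · exp(−k (TP − TL_base))

whose closed-form inverse is the scaled TP estimator,

    TP_scaled = TL_base + [log(δ15N_lim − δ15N_base) − log(δ15N_lim − δ15N_TP)] / k.

The package provides:

* **`fit_meta_model()`** — a Bayesian hierarchical measurement-error
  regression of Δ15N on dietary δ15N across feeding studies (latent true
  diet/consumer values, study errors known), with a built-in blocked Gibbs
  sampler, split-R̂/ESS diagnostics, covariate offsets and AIC/WAIC model
  comparison (`compare_covariate_models()`).
* **`derive_scaled_params()`, `delta15N_at_tp()`, `tp_scaled()`,
  `tp_additive()`, `tp_with_posterior()`** — the enrichment curve, both TP
  estimators, and full posterior propagation of TP uncertainty (including
  the fraction of draws with undefined TP near the asymptote).
* **`pool_baseline()`, `build_grid()`, `estimate_foodweb_tp()`,
  `compare_frameworks()`** — specimen tables in, per-individual and
  per-functional-group TP tables and framework comparisons out.
* **`simulate_experiments()`, `simulate_foodweb()`** — seeded synthetic
  feeding-trial tables and food webs with known ground truth.
* a thin command line (`inst/cli/troposcale`): `fit`, `tp`, `grid`,
  `compare`, `simulate-experiments`, `simulate-foodweb`.

Intended users: isotope ecologists estimating TP and food-web structure
from bulk δ15N, and anyone needing a reference implementation of the
scaled framework to compare against the additive convention.

## Worked example

```r
library(troposcale)

# Discrimination line at the meta-analytic coefficient medians
params <- derive_scaled_params(discrimination_line(5.92, -0.27))
params
#> <scaled_params>  delta15N_lim = 21.9259 permil, k = 0.31471 per TL step

# Arctic-like baseline: zooplankton at 10.2 permil, TL2
base <- baseline_spec(10.2, 2)
build_grid("scaled", base, params = params)
#> # A tibble: 6 x 5
#>   framework baseline_tl    tl  d15n  step
#> 1 scaled              2     2  10.2  3.17
#> 2 scaled              2     3  13.4  2.31
#> 3 scaled              2     4  15.7  1.69
#> # ... per-step discrimination narrows towards 0 at the asymptote

# A consumer at 18.8 permil: one full trophic level apart between methods
tp_scaled(params, base, 18.8)$tp    #> 6.20
tp_additive(18.8, base)$tp          #> 4.53
```

The scaled estimator places this consumer at TP 6.2 — the additive
constant-3.4 ‰ convention compresses it to 4.5 because every step above
this high-δ15N baseline actually enriches by much less than 3.4 ‰.

Refitting the meta-regression on a synthetic 59-study table generated at
those coefficients recovers them with honest uncertainty:

```r
obs <- simulate_experiments(n_studies = 59, seed = 1)
fit <- fit_meta_model(obs, mcmc = mcmc_control(6000, 2000, thin = 2,
                                               chains = 2, seed = 2))
posterior_summary(fit)
#>   parameter   median     lo     hi level
#> 1 beta0        6.03   5.67   6.39   0.95
#> 2 beta1       -0.280 -0.311 -0.249  0.95
#> 3 resid_scale  0.522  0.390  0.682  0.95

web <- simulate_foodweb(base = base, seed = 3)   # known true TPs
ts <- estimate_foodweb_tp(web, base, "scaled", params = fit)
ta <- estimate_foodweb_tp(web, base, "additive")
compare_frameworks(ts, ta)
#> <framework_comparison>  62 specimens, max |TP difference| = 2.11 TL
#>   functional_group        n mean_difference max_abs_difference
#> 1 primary_piscivore      20         0.425               0.694
#> 2 secondary_piscivore     8         0.844               1.07
#> 3 tertiary_piscivore      6         1.76                2.11
#> 4 zooplanktivore         12         0.0624              0.110
#> 5 zooplankton            16         0.00842             0.0357
```

The difference between frameworks is negligible at the bottom of the web
and grows to >2 TL for tertiary piscivores — the additive convention
increasingly underestimates TP towards the saturating limit.

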