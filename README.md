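# tutakoke

Hierarchical Bayesian trend models for long-term studies of black brant
(*Branta bernicla nigricans*) brood rearing.

Brant goslings grow up on grazing lawns of *Carex subspathacea*, a short,
nitrogen-rich sedge that is itself maintained by goose grazing. Gosling
mass near fledging predicts first-year survival and adult size, so a
decline in lawn extent can propagate through gosling growth into
population dynamics. This package is for ecologists analysing the three
data streams such studies produce — gosling capture masses, aerial photo
point counts of lawn cover, and scan-sampled behavioral time budgets —
and asking whether their long-term trends move together.

## Models

**Gosling growth** (mass in g, age in days, year *t*):

    mass_i ~ Normal(43.6 + beta_t * age_i, sigma_mass^2)
    beta_t ~ Normal(alpha + beta_growth * (t - t0), sigma_growth^2)

with the intercept fixed at the 43.6 g mean hatch mass, so `beta_t` is the
year-specific daily growth rate and `beta_growth` the long-term trend in
it. "Mass at 30 days" is `43.6 + 30 * beta_t`.

**Grazing-lawn extent** (photo point counts):

    y_it ~ Binomial(K_it, P_t),   logit(P_t) ~ Normal(alpha + beta_extent * (t - t0), sigma^2)

**Behavioral time budgets** (scan counts per bout, per group x behavior):

    n_i ~ Binomial(N_i, theta_t),   logit(theta_t) ~ Normal(alpha + beta * (t - t0), sigma^2)

Every parameter is reported with posterior mean, sd, 2.5–97.5% credible
interval, and *f* — the portion of the posterior on the same side of zero
as the mean, a probability-of-direction measure. Annual estimates from
different models are related by a posterior-resampling regression: 300
times, draw one posterior value per shared year for each variable and
record the OLS slope.

The Gibbs / Metropolis-within-Gibbs sampler is implemented in the package
and validated against conjugate closed forms, least-squares oracles, and
an independent JAGS fit. A synthetic-data generator emulates the study
design (1987–2015 with its missing years), so every stage is checkable by
parameter recovery; see `vignette("trend-models")` for the methods and
design rationale.

## Worked example

```r
library(tutakoke)

records <- simulate_growth_data(growth_sim_params(seed = 11))
photos  <- simulate_lawn_photos(lawn_sim_params(seed = 12))

fit <- fit_growth_model(records, growth_model_spec(year_origin = 1987),
                        mcmc_settings(chains = 4, iterations = 2000,
                                      burnin = 1000, seed = 13))
summary(fit, parameters = c("alpha_growth", "beta_growth",
                            "sigma_mass", "sigma_growth"))
#>    label    parameter        mean         sd    cri_2.5    cri_97.5 f
#> 1 growth alpha_growth 21.20982708 0.16365169 20.8874092 21.53285842 1
#> 2 growth  beta_growth -0.09471342 0.01036844 -0.1154268 -0.07417252 1
#> 3 growth   sigma_mass 60.38368551 0.82007533 58.7863655 62.03616156 1
#> 4 growth sigma_growth  0.40141244 0.07192254  0.2844876  0.56959912 1
```

The generating trend was −0.100 g/day per year; the fit recovers
−0.095 with a credible interval (−0.115, −0.074) covering it, and `f = 1`
says the whole posterior agrees the trend is negative. Mass at 30 days in
a given year is a linear transform of that year's growth rate:

```r
mass_at_30(fit, 2014)$summary
#>       mean      sd  cri_2.5 cri_97.5 f
#> 1 601.1407 4.87257 591.5354 610.8019 1
```

Fit the lawn model and regress the annual mass estimates on annual lawn
cover by posterior resampling:

```r
lawn <- fit_lawn_model(photos, lawn_model_spec(year_origin = 1991),
                       mcmc_settings(chains = 4, iterations = 2000,
                                     burnin = 1000, seed = 14))
cr <- correlate_posteriors(lawn_extent_series(lawn), mass_at_30_series(fit),
                           n_samples = 300, seed = 15)
cr
#> Posterior-resampling regression: mass_at_30 ~ lawn_extent
#>   shared years: 16 (1991-2014), replicates: 300
#>   slope mean 1426  (2.5% 1247, 97.5% 1594)
#>   f = 1.000, proportion of positive slopes = 1.000
```

A positive slope: years with more lawn cover are years with heavier
goslings, in grams per unit proportion of cover. (In this simulation the
two streams were generated independently, each with its own negative year
trend, so the association reflects those shared trends; use
`simulate_joint_scenario()` to generate — and recover — a known causal
coupling.) Convergence diagnostics come from `check_convergence()`
(split R-hat and effective sample size per parameter).

`run_pipeline()` chains all stages — simulate (or read CSVs), fit the
three models, correlate, write summary tables and a JSON manifest — and
`inst/scripts/tutakoke-cli.R` exposes the stages as shell subcommands
(`simulate`, `fit-growth`, `fit-lawn`, `fit-behavior`, `correlate`,
`run-all`).

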