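---
title: "Hierarchical trend models for brant brood rearing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical trend models for brant brood rearing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `tutakoke`, the priors
and numerical choices behind them, what the synthetic-data generator does
and does not emulate, and the design decisions a maintainer should know
about. All empirical statements here are properties the package's test
suite or `scripts/acceptance.R` actually computes.

## The scientific setting

Black brant (*Branta bernicla nigricans*) goslings grow up on brood-rearing
areas dominated by grazing lawns of *Carex subspathacea*, a short,
nitrogen-rich sedge maintained by goose grazing itself. Gosling mass near
fledging predicts first-year survival and adult size, so three long-term
data streams carry the story: gosling capture masses (ages 22--45 days),
aerial photographic point counts of grazing-lawn cover, and scan-sampled
behavioral time budgets of broods. The package fits year-level Bayesian
hierarchical trend models to each stream and then asks how the annual
estimates co-vary.

## Gosling growth model

Individual mass (g) at capture age $a_i$ (days) in year $t(i)$:

$$\mathrm{mass}_i \sim \mathcal{N}(43.6 + \beta_{t(i)}\, a_i,\ \sigma^2_{\mathrm{mass}})$$

The intercept is fixed at 43.6 g, the mean hatch mass of brant, so
$\beta_t$ is the year-specific daily growth rate. Year slopes follow a
linear hyper-trend with a random year effect:

$$\beta_t \sim \mathcal{N}(\alpha_{\mathrm{growth}} + \beta_{\mathrm{growth}} x_t,\ \sigma^2_{\mathrm{growth}}), \qquad x_t = t - t_0.$$

Growth is treated as linear only over the 22--45 day capture window;
no logistic or Gompertz option is offered, deliberately (over that window
linearity is a good approximation and a nonlinear fit would confound
within-season hatch-date variation with growth). Sex is not a covariate.
"Mass at 30 days", the annual quantity used downstream, is the per-draw
transform $43.6 + 30\beta_t$.

Year coding: $x_t = t - t_0$ with $t_0$ the first study year (1987 for
growth and behavior, 1991 for the aerial survey). The intercept
$\alpha_{\mathrm{growth}}$ is therefore the growth rate at the study
start, which puts it on the interpretable ~21 g/day scale. The hyper-trend
is equivariant to this choice: shifting $t_0$ by $k$ changes the intercept
by $-k\,\beta_{\mathrm{growth}}$ and leaves the slope posterior unchanged
(tested).

Although the hyper-trend intercept is sometimes written with a year
subscript in field descriptions of this model family, it enters the mean
as a single scalar; the package implements it as scalar
`alpha_growth`.

## Grazing-lawn extent model

Photo $i$ of year $t$ contributes a binomial point count:

$$y_{i,t} \sim \mathrm{Binomial}(K_{i,t},\ P_t), \qquad
\mathrm{logit}(P_t) \sim \mathcal{N}(\alpha_{\mathrm{extent}} + \beta_{\mathrm{extent}} x_t,\ \sigma^2_{\mathrm{extent}}).$$

The year effect is placed on the log-odds of $P_t$ rather than on the
proportion itself: a normal year effect on $P$ is unbounded, while the
logit keeps $P \in (0,1)$, and an intercept of about $-3.1$ on this scale
corresponds to the plausible ~4% cover at the survey start. Because
photos of a year are conditionally i.i.d. binomials given $P_t$, the
posterior depends on the data only through per-year totals
$(\sum_i y_{i,t}, \sum_i K_{i,t})$; the two historical grid designs
(100-point and 180-point overlays) therefore mix transparently through
`points_total`, with no area re-weighting. Splitting one photo into two
of the same year leaves the posterior unchanged (tested exactly). Spatial
autocorrelation between photos is not modeled; photos are treated as a
random sample of the colony's extent.

## Behavioral time-budget model

Scan sampling records each subject's behavior every minute within a
30--60 minute observation bout; bouts of 30 minutes or less are excluded
at read time. For one group (goslings, adult females, adult males) and
one behavior category (foraging, alert, walking, aggression, resting),
bout $i$ in year $t$ contributes

$$n_{i} \sim \mathrm{Binomial}(N_i,\ \theta_t), \qquad
\mathrm{logit}(\theta_t) \sim \mathcal{N}(\alpha + \beta x_t,\ \sigma^2_\theta).$$

Each group-by-behavior cell is fitted marginally with its own scalar
trend slope $\beta$. The five categories of a group are of course not
independent -- their probabilities must sum to (at most) one -- and the
marginal fits inherit that caveat: the sum of posterior-mean proportions
across categories is checked to land near one but is not constrained to.
A joint multinomial model and within-bout temporal autocorrelation are
explicit non-goals. Scan counts may sum to less than a bout's scan total
(out-of-sight or no-majority minutes are unclassified). Cells whose
behavior almost never occurs (overall proportion below 1%) are flagged
low-information in the trend table, because a logit-scale trend for a
near-absent behavior is weakly identified; the estimates are still
reported.

## Posterior summaries and the f statistic

Every reported parameter row carries the posterior mean, sd, empirical
2.5% and 97.5% quantiles (R's default type-7 rule, linear interpolation
of order statistics), and $f$: the portion of the posterior on the same
side of zero as the posterior mean, a probability-of-direction measure.
Draws exactly at zero count toward neither side (they remain in the
denominator; under continuous posteriors this is a measure-zero
convention), and a posterior mean of exactly zero returns $f = 0.5$ with
a warning. $f$ is invariant to positive rescaling and to flipping the
sign of every draw. Note that $f$ as defined can in principle fall below
0.5 for strongly skewed draws (mean on the minority side); this does not
arise for the unimodal posteriors produced here.

## The sampler

The models are fitted by a Gibbs / Metropolis-within-Gibbs sampler
implemented in the package:

* **Growth**: the year slopes and the hyper-coefficients
  $(\alpha_{\mathrm{growth}}, \beta_{\mathrm{growth}})$ have conjugate
  normal full conditionals (the likelihood enters through per-year
  sufficient statistics, so one sweep is $O(T)$ in the number of years,
  not the number of goslings). The two sds are updated by univariate
  slice sampling (stepping-out with shrinkage, width 0.5) on
  $\log\sigma$.
* **Binomial trends** (lawn, behavior): the year log-odds are updated by
  vectorized random-walk Metropolis with per-year proposal scales adapted
  toward 0.44 acceptance by Robbins--Monro (gain $\min(0.5, 1/\sqrt{k})$)
  **during burn-in only** -- scales are frozen afterwards, so the kept
  draws come from a fixed, valid transition kernel. Hyper-coefficients
  are conjugate; $\sigma$ is slice sampled.

Priors: $\mathcal{N}(0, 100^2)$ on all hyper-intercepts and slopes;
half-normal priors on sds with scale matched to the parameter's units --
100 for the gram-scale residual mass sd (which sits near 60 g under
realistic conditions; a tighter scale would be informative there), 10 for
the g/day year-slope sd, and 5 for logit-scale sds. All are weakly
informative at the scales of these data.

Chains are initialized at moment estimates (per-year least-squares slopes,
empirical logits) with overdispersing jitter, run sequentially under a
single seeded RNG stream, so a fixed seed reproduces every draw; defaults
are 4 chains of 2,000 kept draws after 1,000 burn-in. Convergence is
summarized by split-chain R-hat (warning threshold 1.01) and an
autocorrelation-based effective sample size with Geyer's initial monotone
positive-sequence truncation. A non-finite log-density at the starting
state raises an initialization error rather than sampling garbage.

The sampler's correctness is checked against independent oracles: a
single-proportion model with flat prior whose exact posterior is
Beta$(y+1, K-y+1)$, matched within three Monte-Carlo standard errors over
a grid of $(y, K)$; noise-free growth data, where the year slopes must
reproduce the fixed-intercept least-squares estimator
$\sum a(m - 43.6) / \sum a^2$ to four significant figures; and a JAGS fit
of the identical growth model, used purely as a cross-check in the test
suite.

## Posterior-resampling correlation

To relate two fitted models' annual estimates without collapsing their
posteriors to point estimates, the correlation stage repeats, 300 times
by default: draw one posterior value per shared year for each variable,
fit an ordinary least-squares line of $y$ on $x$, record the slope. The
slope draws are summarized by their mean, quantile interval, $f$, and the
proportion of positive slopes. Slopes are reported on natural scales
(grams of mass-at-30 per unit lawn proportion, proportion per
proportion), i.e. as regression coefficients rather than Pearson
correlations. At least three shared years are required; with point-mass
posteriors the procedure collapses to the deterministic least-squares
slope of the annual means (tested exactly).

Draws are paired independently across years and variables within a
replicate: the models were fitted separately, so there is no joint
posterior structure to preserve. Two consequences are worth knowing.
First, the replicate interval reflects posterior uncertainty only -- it is
not a confidence interval for a population slope over hypothetical
re-runs of the study. Second, when per-year estimates are weakly informed,
hierarchical shrinkage pulls them toward the hyper-mean and attenuates
cross-model slopes, exactly as measurement error attenuates regression
coefficients. The coupling-recovery validation (below) is therefore
designed with strongly informed years, so that it tests the resampling
stage itself rather than that attenuation.

## The synthetic-data generator

The generator produces the three streams under the models above with
known parameters, and is the basis of every recovery test:

* **Growth**: defaults emulate the long-term study -- years 1987--2014
  with 2001 missing, intercept 21.422 g/day, trend $-0.100$ g/day/yr,
  hatch mass 43.6 g, ages discrete-uniform on 22--45 (the age
  distribution within the capture window is not otherwise constrained),
  100 goslings/year, residual sd 60 g and year-slope sd 0.5 g/day as
  realistic scales for ~600--900 g goslings.
* **Lawn**: survey years 1991--2016 with the 1992, 1996, 2000, 2002,
  2003, 2005, 2006 gaps; logit intercept $-3.126$, logit trend $-0.191$,
  year sd 0.5, 250 photos/year of 150 points.
* **Behavior**: years 1987--2015 with the 1989, 2006, 2012 gaps; one
  (group, behavior) trend table whose mean proportions (e.g. gosling
  foraging 0.705, walking 0.109) and logit trends (e.g. walking +0.050,
  resting $-0.024$) mirror the study-scale values, year sd 0.3, 30 bouts
  of 60 scans per year-group.

Within a bout, counts for the simulated categories plus an unclassified
remainder are multinomial with cell probabilities equal to the marginal
$\theta$ values, rescaled only if they sum above one. Each category is
then marginally Binomial$(N, \theta)$ -- the structure the fits assume --
while the scan-total invariant always holds. The rescaling is a soft cap:
in year-draws where the $\theta$ values jointly exceed one it depresses
all categories proportionally, which can leak a small spurious trend into
a large category when another category trends upward. The effect is a few
percent under the defaults and is visible in the acceptance run's
foraging trend; it is the price of enforcing the invariant while keeping
exact marginal binomials elsewhere.

The generator does **not** emulate: spatial structure of lawn patches or
photo autocorrelation, hatch-date phenology or within-season effects,
individual heterogeneity beyond the year level (no gosling random
effects, no observation-level overdispersion), sex differences in
goslings, or brood movement. Passing recovery tests therefore show the
estimation machinery is correct under the assumed generative structure,
not that the structure captures every feature of field data.

The coupled scenario (`simulate_joint_scenario`) simulates lawn
proportions first, then sets year growth slopes so expected mass-at-30
equals a **flat** baseline plus `coupling` $\times (P_t - \bar P)$. The
growth hyper-trend is deliberately dropped there: lawn extent itself
trends in year, so an additional independent baseline trend in mass would
be collinear with it and the regression slope would no longer equal the
generating coupling. In the coupled world, the year trend in gosling size
arises *through* the lawn, which is the causal structure the correlation
stage is meant to detect.

## Problem sizes and numerical choices in the checks

The recovery checks run 20 replicates per setting at reduced sampler
budgets (2 chains, 1,000 kept draws after 500 burn-in), sizes chosen so
the whole suite stays a desk-scale run: growth at 29 years x 100
goslings, lawn at 20 years x 50 photos x 150 points, behavior at 27
years x 30 bouts, and the coupling scenario at 16 shared years with 400
goslings/year and year-slope sd 0.02 (strong per-year information, for
the attenuation reason above). Credible intervals are expected to cover
truth in at least 18 of 20 replicates. The acceptance script runs the
full pipeline at the study design's own sizes with the default 4-chain
budget.

Other numerical conventions: quantiles are type 7; the slice sampler's
stepping-out is capped at 50 widths; RWM proposal scales are initialized
at roughly the inverse square root of the per-year information; duplicate
(label, parameter) rows are refused when writing trend tables; trend
tables are written at full precision so they round-trip losslessly.

## Known limitations

* Behavior categories are modeled marginally; variance estimates inherit
  the sum-to-one dependence caveat.
* The f statistic is reported per parameter; it is a probability of
  direction, not a posterior probability that a trend of a stated
  magnitude exists.
* The correlation stage is bivariate by design; with only ~16 shared
  years, multi-covariate regressions (e.g. adding colony density) are
  deliberately out of scope.
* Cross-model slopes attenuate when per-year posteriors are weakly
  informed (hierarchical shrinkage); interpret slopes from short, noisy
  series accordingly.
* A year with no data is simply absent from a fit; the package does not
  impute gap years from the hyper-distribution.
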