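---
title: "Partitioning grassland overyielding under nitrogen enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning grassland overyielding under nitrogen enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overyieldN)
```

## The question

Mixtures of plant species usually produce more biomass than expected from
their constituent monocultures — they *overyield*. Nitrogen enrichment,
whether experimental fertilisation or chronic atmospheric deposition, can
erode this overyielding, and its impact plausibly depends not on the annual
rate alone but on the *cumulative* amount of N a community has received
over the years. `overyieldN` implements the full analysis chain for
multi-study grassland biodiversity × N-addition data: the additive
partition of net biodiversity effects, cumulative N accounting, a
hierarchy of mixed-effects models, and a synthetic-data generator used to
validate every step.

## The partition

For a mixture plot-year with $n \ge 2$ sown species, observed species
yields $Y_i$ (g/m²/year), monoculture references $M_i$ and sown
proportions $RY_{e,i}$ (summing to 1):

$$RY_i = Y_i / M_i, \qquad \Delta RY_i = RY_i - RY_{e,i}, \qquad
  RYT = \sum_i RY_i$$

$$\mathrm{NBE} = \sum_i Y_i - \sum_i RY_{e,i} M_i, \qquad
  \mathrm{CE} = n\,\overline{M}\,\overline{\Delta RY}, \qquad
  \mathrm{SE} = n\,\mathrm{cov}(M, \Delta RY)$$

The complementarity effect (CE) captures community-wide gains (resource
partitioning, facilitation); the selection effect (SE) captures dominance
by species with high monoculture yields. Two numerical conventions matter:

* **Covariance divisor.** `cov` here is the *population* covariance
  (divisor $n$). This is the only variant under which
  $\mathrm{NBE} = \mathrm{CE} + \mathrm{SE}$ holds as an exact algebraic
  identity ($\sum_i M_i \Delta RY_i = n\overline{M}\,\overline{\Delta RY}
  + n\,\mathrm{cov}_{pop}$); the sample covariance (divisor $n-1$) breaks
  it. The package asserts the identity to 1e-9 relative tolerance on every
  computation. The covariance is taken across sown species between the
  per-species $M_i$ and $\Delta RY_i$ — the only reading with correct
  dimensionality, although the field's notation sometimes writes a barred
  (scalar-looking) $\bar M$ inside the covariance.
* **Monoculture adjustment.** A constant `adjustment_c` (default
  1 g/m²/year) is added to every monoculture mean, because relative yields
  explode as a monoculture yield approaches zero. Increasing the constant
  weakly shrinks all $|RY_i|$; tests assert this monotonicity.

**Monoculture matching.** A mixture's $M_i$ defaults to the mean over
replicate monoculture plots of the same *study × year × N treatment*
(`study_year_treatment`). Two fallbacks are available and recorded in the
output flags when used: `study_treatment` (averaged over years) and
`study_year` (pooled over treatments). The matching rule is genuinely open
in the field's practice; we default to the most specific grouping. For
analyses whose predictor is *time* (the H2 and H3 fits below) we recommend
— and the bundled analyses use — the year-averaged policy: when monoculture
productivity is stationary, a year-varying reference injects year-structured
noise into the response exactly along the axis being modelled, inflating
the temporal variance without adding information.

**Data policy.** Plot-years with a sown species lacking any monoculture
reference are dropped and reported (`missing_monoculture`), never imputed,
because imputation would silently change the statistic. Unsown species
present in a mixture are excluded from the algebra (their $RY_{e}$ is
undefined) and flagged `unsown_invader`. Sown-but-absent species enter
with $Y_i = 0$, i.e. $\Delta RY_i = -RY_{e,i}$. Species with identical
$M$ give $\mathrm{SE} = 0$ by the formula, with no special-casing.

## Nitrogen exposure

The annual N input of a plot is `experimental rate + site deposition`
(kg/ha/year). Deposition is a static per-site constant, so ambient control
plots retain a strictly positive rate — which is what keeps
log-rate models defined for them. Cumulative exposure through year $t$
includes year $t$'s input (year 1 exposure = one year's rate); with a
constant rate it is `rate × years elapsed`. With time-varying schedules
the last observed rate is carried forward across unobserved years.
Deposition accrues from experiment start, not site history, and no loss
terms (leaching, biomass removal) are modelled. Three accounting modes
separate experimental, deposition and total inputs; they are exactly
additive.

A subtlety: the first-year biomass exclusion (below) removes year-1
*observations*, but year-1 *inputs* still count, so exposure is computed
from the pre-exclusion schedule.

## Validation rules

`validate_dataset()` enforces the inclusion rules of multi-study
syntheses on the canonical CSV schema: required columns present (hard
error), numeric fields parseable, biomass non-negative, sown proportions
summing to 1 within each plot-year, monoculture plots present in each
study, and each study's first observed year excluded (biomass is
informative at earliest in the second year after establishment). Every
dropped row carries a reason, and row counts are conserved
(`rows_in = rows_kept + rows_dropped`).

## The model hierarchy

All models are `nlme::lme` fits; model construction, transformations and
inclusion rules are package code.

| Fit | Fixed effects | Random / correlation | Inclusion |
|---|---|---|---|
| `fit_h1a_binary` | treatment × study | plot intercepts + AR1 over years | studies with both arms |
| `fit_h1a_richness` | treatment × log2(richness) | richness in study | studies with ≥ 3 richness levels |
| `fit_h1b_rate` | log(annual rate) | intercept + slope by study | rows with positive rate; ambient toggle |
| `fit_h2_time` | treatment × year | richness intercepts | one long-running study, ≥ 3 years |
| `fit_h3_cumulative` | log(cum N) + log(cum N)² | intercept + slope by study | positive cumulative N; 3 accounting modes |

Notes on the genuinely open choices:

* "Plot ID nested in year" admits two readings. The default is plot-level
  random intercepts with an AR1 residual correlation across years within
  plots (the standard way to express repeated measures); the literal
  nesting (`year/plot` random intercepts, no AR1) is selectable via
  `random_structure = "plot_in_year"`. With single-year data the AR1 term
  is dropped with a logged warning.
* Transformations: natural log for N rates and cumulative N, log2 for
  richness (matching the powers-of-two design ladders).
* Marginal means (ambient vs N) come from `emmeans`, averaging over study
  levels with equal weights; the contrast p-value uses the model's t
  distribution.
* AIC comparisons (`compare_aic`) require identical observation sets and
  responses, and warn on REML fits because REML likelihoods are comparable
  only across identical fixed effects — refit with `method = "ML"`.
  `fit_h3_rate_time` provides the competitor model (log rate + year,
  optionally their interaction).
* Significance labels follow common usage (p < 0.05 significant,
  p < 0.10 marginal) and are never used for filtering.
* `nlme::lme` combines random slopes with AR1 residuals directly, so no
  two-stage approximation is needed; failed default optimisations are
  retried with `optim` and noted in the fit object.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the analysis
assumes, not grassland biology. The defaults mirror the design envelope
of the multi-study setting the package targets: 15 studies; sown richness
1, 2, 4, 8, 16 from a 20-species pool; experimental rates 0, 40, 120,
360 kg/ha/year on top of static site deposition spread over 6–24
kg/ha/year; one 23-year study (the long-running BioCON analogue) and 14
short (2–4 year) studies; monocultures for every species × rate with 2
replicates; 2 mixture replicates per richness × rate cell; half the
studies report two within-year harvests (60/40) that the pipeline must
re-aggregate. This yields ≈ 1,500 mixture plot-years after first-year
exclusion — the scale at which published multi-study syntheses of
grassland N-addition experiments operate.

Key mechanisms:

* **Exact effect injection.** Mixture yields are built by inverting the
  partition: $\Delta RY_i = \mathrm{CE}/(n\overline M) +
  \beta\,(M_i - \overline M)$ with $\beta = \mathrm{SE}/(n\,
  \mathrm{var}_{pop}(M))$, then $Y_i = (RY_{e,i} + \Delta RY_i) M_i$.
  Partitioning noise-free output recovers the targets to 1e-9. A
  mechanistic competition model would make ground truth unknowable; the
  algebraic inversion makes recovery testable.
* **Degenerate compositions.** When sampled species have nearly tied
  monoculture means, $\beta$ diverges; the generator caps the
  selection-term deviation at `max_delta_ry` (default 1.5) and the
  ground-truth table records the *achieved* target. Yields clipped at
  zero are flagged `clipped`; tests exclude flagged plot-years from exact
  recovery checks.
* **Noise.** Plot-level lognormal noise with unit mean
  ($\exp(e - \sigma^2/2)$, $e$ a stationary AR1 series with marginal sd
  `noise_sd` = 0.15 and lag-1 correlation `ar1_rho` = 0.4), shared across
  the species of a plot. Monoculture response to N is multiplicative
  (`1 + 8e-4 × rate` by default). The noise magnitudes are
  order-of-magnitude choices calibrated for test power; the real
  synthesis's noise levels are unknown.
* **Trend surfaces.** `ce_fun`/`se_fun` map `(time, rate[, richness])` to
  target effects, where `rate` is the *total* annual input. The richness
  argument is accepted (functions of two arguments also work) because
  richness-dependent targets are needed to exercise the
  richness-interaction model. Presets: the `"additive"` regime is additive
  in (year, log rate) — literally no time × rate interaction on the scale
  the competitor model fits — while the `"multiplicative"` regime is a
  convex quadratic in log cumulative N for CE and a concave one for SE.

What the generator does *not* emulate: species identities and traits,
mechanistic resource competition or soil-N dynamics, species turnover,
unsown invaders (tests construct those explicitly), N losses, or
correlated deposition trends. Passing recovery tests therefore shows the
*statistical machinery* is correct under the assumed structure, not that
real grasslands behave this way.

## Conceptual curves

`conceptual_trends()` combines a duration trend $f(t)$ and a rate trend
$g(r)$ into a curve against cumulative N ($t \times r$): the *additive*
construction plots the product $f(t)g(r)$; the *multiplicative* one fits
a quadratic in $\log(tr)$ to the pointwise products and evaluates the
trend. A caution from our own numerics: "increasing time trend ×
decreasing rate trend ⇒ convex" is not unconditional. With a steep linear
rate decline (e.g. $(5+2t)(400-0.7r)$) the bilinear $-t\,r$ term dominates
and the curve is *concave* (fitted quadratic ≈ −418). Convexity emerges
when the rate decline is modest enough that the trend stays well above
zero across the design range — the situation conceptual diagrams of this
effect typically depict. The bundled examples use
$f(t) = 5 + 2t$, $g(r) = 1 - 5\times10^{-4} r$ (dense-grid quadratic
coefficient ≈ +0.77).

## Problem sizes and numerical tolerances

The test suite checks the partition identity to 1e-9 relative tolerance
on 1,000+ random communities, round-trips 500 noise-free communities
through the generator inversion, and runs 100-replicate recovery studies
at the default ≈ 1,500-plot-year scale for each headline coefficient
(richness × N interaction, log-rate slope, time × N interaction,
quadratic log-cumulative-N term), asserting recovery within 3 standard
errors in ≥ 90% of replicates, and the AIC preference for the
cumulative-N model under the multiplicative regime (and its reversal
under the additive regime) in ≥ 90% of replicates. The H2 recovery
scenario generates 3 studies (the analysis itself uses only the
long-running one); the richness scenario uses the 5-study subset with
≥ 3 richness levels, mirroring the inclusion rule. Proportion sums are
checked to 1e-6; the AIC identity $\mathrm{AIC} = 2k - 2\ell$ to 1e-6.

## Worked example

```{r example}
cfg <- generator_config(seed = 1, trend_mode = "multiplicative")
sim <- simulate_experiment(cfg)
val <- validate_dataset(sim$data)
ann <- aggregate_annual_yield(val$data)
part <- batch_partition(ann, monoculture_reference(ann))
tab <- add_exposure(part, cumulative_exposure(val$schedule, cfg$deposition))
f <- fit_h3_cumulative(tab, "nbe")
f$quadratic
```

A positive quadratic coefficient means the net biodiversity effect is
convex in log cumulative N: declining through intermediate exposures and
recovering (or degrading less) at the extremes of the design.

## Known limitations

* The mixed models treat monoculture references as known; in truth they
  are estimated from few replicate plots, and their error is shared by
  every mixture in the same matching group. Model standard errors
  therefore understate replicate-to-replicate variability somewhat —
  visible in the recovery studies, and equally a property of analyses of
  this kind on real data.
* Random-effects structures are configurable but default to one reading
  of ambiguous descriptions; fits on designs with few studies and random
  slopes can hit singular convergence (the fit is returned with a note).
* The evenness analysis of community change is not implemented: no
  defensible metric is specified in the source material for it.
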