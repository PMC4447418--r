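---
title: "Variance partitioning in nested three-level models of birthweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance partitioning in nested three-level models of birthweight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nestvpc)
```

## The model

`nestvpc` analyses individual heterogeneity in a continuous outcome —
birthweight in grams is the motivating case — across a three-level nested
hierarchy: babies (level 1) within mothers (level 2) within maternal
countries of birth (level 3). The model is a Gaussian random-intercept
linear mixed model,

$$ y_{ijk} = \mathbf{x}_{ijk}^\top \boldsymbol\beta + v_k + u_{jk} + e_{ijk}, $$

with $v_k \sim N(0, \sigma^2_{mcb})$, $u_{jk} \sim N(0, \sigma^2_m)$ and
$e_{ijk} \sim N(0, \sigma^2_b)$ mutually independent. The scientific
question is not whether country means differ — with hundreds of thousands
of births almost any difference is "significant" — but how much of the
total individual variance sits at each level. The package's core
statistics are

- **VPC** (variance partition coefficient) per level:
  $100\,\sigma^2_\ell / (\sigma^2_{mcb}+\sigma^2_m+\sigma^2_b)$;
- **ICC** (intra-class correlation): the expected correlation between two
  babies sharing a cluster — equal to the VPC at the country level, and
  $100(\sigma^2_{mcb}+\sigma^2_m)/\sigma^2_{total}$ at the mother level,
  because siblings share both the mother and the country effect;
- **PCV** (proportional change in variance):
  $100(\sigma^2_{model}-\sigma^2_{ref})/\sigma^2_{ref}$ per level against
  the 'empty' (covariate-free) reference model.

A low country-level VPC means country membership discriminates poorly
between individual outcomes (a *general contextual influence* close to
nil), even when country averages differ in ways that pass significance
tests. The complementary *specific* view is the league table of shrunken
country effects: posterior deviations of each country from the grand
mean, pulled towards zero in proportion to their imprecision.

```{r partition}
m1 <- variance_components(7699, 111583, 119871)  # an empty-model decomposition
round_half_up(vpc(m1), 1)
round_half_up(icc(m1), 1)
```

## Estimation

`nested_lmm()` fits the model in two stages, mirroring the two-stage
practice of the multilevel-modelling software lineage this package
follows (start values from a deterministic estimator, then MCMC):

1. **`fit_mom()`** — Henderson-type method-of-moments estimates of the
   variance components from OLS residuals, using the classical unbalanced
   nested-ANOVA moment equations, followed by feasible GLS for the fixed
   effects. Negative moment estimates are floored at
   $10^{-8}\,\mathrm{var}(y)$ rather than zero, so the sampler can move
   away from the boundary.
2. **`fit_gibbs()`** — a blocked Gibbs sampler. Fixed effects carry a
   flat prior and are drawn jointly; each variance carries an
   inverse-gamma(0.001, 0.001) prior, the common default of this software
   lineage. Point estimates are posterior means, standard errors are
   posterior SDs, and intervals are equal-tailed 2.5/97.5 percentiles.
   Chain defaults are 500 burn-in and 5,000 monitoring iterations
   (`mcmc_settings()`), again the lineage's defaults.

Two numerical choices deserve emphasis:

- **Blocked variance updates.** The naive scan that draws each variance
  from its inverse-gamma conditional *given the current effects* has a
  well-known absorbing state: once a variance draw lands near zero, the
  effects are shrunk to zero and the variance can take thousands of
  iterations to escape. On weakly identified levels (few clusters, or a
  dominant cluster holding most observations) the chain visibly collapses.
  `fit_gibbs()` therefore updates each `(variance, effects)` pair as one
  block: the variance is drawn first from its conditional with the
  effects integrated out — under which the cluster means of the working
  residual are independent $N(0, \sigma^2_\ell + \sigma^2_b/n_g)$ — by a
  stepping-out slice sampler on the log scale, and the effects are then
  drawn from their closed-form normal conditional. This is an exact
  blocked Gibbs draw (not an approximation) targeting the same posterior,
  and it was verified against an independent MCMC implementation and
  against dense-covariance maximum likelihood on small fixtures.
- **Identifiability sweep.** The intercept and the mean of each effect
  vector are jointly unidentified by the likelihood. After each effects
  draw the effect vector is re-centred, the mean being absorbed by the
  following intercept update.

Per-iteration cost is linear in the number of babies: all level sums are
computed with grouped `rowsum()` on indices sorted once at entry (which
also makes every estimate invariant to input row order). A cohort of
about 28,000 babies runs the default 5,500 scans in well under a minute.

The marginal deviance ($-2\log$ likelihood with the random effects
integrated out) is computed level-wise via the nested Woodbury identity —
no $n \times n$ matrix is ever formed — and feeds the deviance
information criterion: $\mathrm{DIC} = \bar D + p_D$ with
$p_D = \bar D - D(\hat\theta)$ evaluated over the retained draws of the
fixed effects and variances. Smaller DIC is better. `oracle_direct()`
maximises the exact dense-covariance likelihood on fixtures of up to 500
rows and exists purely as a brute-force cross-check.

## The synthetic register

Because national birth-register data cannot be redistributed, the package
generates cohorts with the published study's statistical structure
(`synth_config()` defaults):

- 109 countries, one dominant origin holding 80% of mothers, remaining
  shares from a symmetric Dirichlet(0.5) (heavily skewed, emulating a
  register where one native country dwarfs the rest);
- 1–3 babies per mother with probabilities (0.62, 0.34, 0.04), giving the
  study's 1.42 babies per mother;
- empty-model variance components 7,699 / 111,583 / 119,871 g² at the
  country / mother / baby level;
- covariate category frequencies equal to the published population table
  (e.g. 48.96% girls, 51.65% of mothers 160–169 cm), with mother-level
  covariates constant within mother and the World Bank income class
  constant within country;
- gestational age drawn from $N(39.66, 1.27^2)$ weeks, rounded to
  completed weeks and truncated to 37–42 by resampling (the study reports
  only the mean and SD of the included range);
- fully adjusted fixed-effect sizes (e.g. −123 g for girls, +149 g per
  centered gestational week) injected on top of the latent effects.

Covariates are drawn independently of each other and of the latent
effects: the generator exercises *estimation*, not confounding. A
`covariate_sampler` hook accepts a user-supplied joint sampler for richer
scenarios. The true latent effects are retrievable with
`cohort_truth()`, so tests can compare estimates against the exact
realised structure.

Two scenario details are deliberate choices:

- **Empty-model recovery uses `synth_config_empty()`** (all covariate
  effects zeroed). Injected covariate effects add roughly 10,000 g² of
  mother-level and 36,000 g² of baby-level marginal variance, so an
  empty-model fit of a fully adjusted cohort decomposes a *larger* total;
  the pure-variance configuration is the one whose empty-model
  decomposition equals the configured components, which is what a
  recovery experiment should target.
- **The planted low-birthweight scenario** (`plant_low_countries()`)
  replaces the selected countries' latent effects with a deterministic
  value 250 g below the lowest remaining country, emulating a register
  in which a handful of origins sit markedly below all others. Planting
  is done after the inclusion filters, so planted countries meet the
  ≥100-observations rule; with fewer observations than that, shrinkage
  correctly refuses to rank a country confidently, and exact rank
  recovery is not an appropriate yardstick.

What passing tests on this generator do **not** show: robustness to
covariate–effect confounding, non-Gaussian outcomes, informative cluster
sizes, or calendar-time structure. None of these are modelled.

## The study workflow

`apply_inclusion_filters()` implements the self-contained subset of the
study's selection rules, in a fixed order: missing maternal age or birth
order; birthweight < 500 g; missing country; gestational age outside
37–42 completed weeks; then — once, after all row-level rules — countries
with fewer than 100 remaining observations. Rules requiring external
reference material (malformation codes, growth-implausibility criteria,
multiple-birth detection) are out of scope. `assign_income_tertiles()`
cuts household income at the 1/3 and 2/3 quantiles of the non-missing
values, ties going to the lower category (all-equal input is therefore
all "lowest"), computed over the whole cohort rather than per calendar
year (the study does not say which; overall is the simpler reading).

`run_model_sequence()` fits the cumulative five-model covariate sequence
(1: empty; 2: maternal stature; 3: + maternal age; 4: + sex, gestational
age, household income, marital status, smoking, hypertension, diabetes;
5: + country income class), with dummy coding against the published
reference categories and "missing" kept as an ordinary category rather
than dropping rows. Gestational age is entered grand-mean-centered — the
published intercepts are only coherent under centering, though the source
never states it — and the centering value is stored for prediction.
Model 1 anchors the PCV reference and the league table; the league table
is anchored to the grand mean across countries rather than to a
native-born reference group.

Sensitivity operations mirror the study's checks: dropping the k lowest
shrunken countries (default 9), the two-level model of continuous
maternal stature (24% between-country share by default), dropping the
mother level (its variance is absorbed by the residual; the country share
barely moves), and retaining a random fraction of dominant-country
mothers (whole mothers, never partial sibling sets).

```{r workflow}
cfg <- synth_config(n_countries = 15, n_mothers = 1500,
                    dominant_country_share = 0.4,
                    country_size_concentration = 2)
coh <- sample_cohort(cfg, seed = 42)
filt <- apply_inclusion_filters(coh)
filt$tally

fit <- nested_lmm(filt$cohort, model_spec(1),
                  settings = mcmc_settings(burn_in = 200, n_iter = 800,
                                           seed = 1))
round_half_up(vpc(fit$variances), 1)
head(league_table(country_effects(fit)), 3)
```

## Problem sizes and tolerances

The package's own experiments use these scales, chosen to keep every
component of the estimator well identified:

- *Estimator agreement*: 200-row balanced fixtures (20 countries × 5
  mothers × 2 babies, components 1,500 / 1,000 / 1,000 g²), sized so that
  each level's cluster-mean noise is well below its component; Gibbs
  posterior means then agree with dense-covariance ML within 25% across
  seeds. On much smaller fixtures (a handful of clusters) the posterior
  mean of a variance and its ML estimate are genuinely different
  quantities and no sampler should be expected to reconcile them.
- *Study-structure recovery*: 100 countries × 20,000 mothers (≈28,400
  babies), ten replicate seeds; the country-level VPC is recovered with a
  replicate spread of roughly ±1 percentage point around 3%.
- *Stature clustering*: 100 countries × 200 mothers recovers the 24%
  between-country share within a few points.

Numerical conventions: statistics are computed at full precision and
displayed at one decimal with ties rounded away from zero (matching the
printed tables this package reproduces); two-level fits carry the absent
component as `NA` and the partition statistics treat it as zero rather
than silently dropping it; degenerate chains (all draws equal) yield
`pD = 0` by construction.

## Known limitations

- No random slopes, cross-classification, or non-Gaussian outcomes.
- The moment start can be inefficient under extreme cluster-size skew;
  it is only a starting value, never the reported estimate.
- With very few clusters at a level, the variance posterior under the
  inverse-gamma(0.001, 0.001) prior is heavy-tailed and prior-sensitive;
  reported SEs at such levels should be read with care.
- The generator's independence assumptions (covariates independent of
  each other and of the latent effects) mean association structure in
  real registers — e.g. smoking by income — is not emulated.
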