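---
title: "Hierarchical fecundity modelling and climate trend attribution: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical fecundity modelling and climate trend attribution: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masting)
```

# The model

Seed production of masting trees is volatile, zero-inflated, and observed
only indirectly, which is why this package models it in two latent layers.
A tree $i$ at site $j$ is mature in year $t$ with probability given by a
probit in diameter,

$$\rho_{ijt} = \Phi(\alpha_0 + \alpha_G G_{ijt}),$$

and, conditional on maturity, produces $\psi_{ijt}$ seeds with

$$\log \psi_{ijt} = \mathbf{x}_{ijt}'\boldsymbol\beta + \kappa_{e(j),t} + b_i + \varepsilon_{ijt},
\qquad \varepsilon_{ijt} \sim N(0, \sigma^2),\; b_i \sim N(0, \sigma^2_{re}).$$

The design vector $\mathbf{x}$ (see `design_terms()`) holds an intercept;
diameter $G$ (cm) and $G^2$; ordinal canopy shade class $S$ (1 = fully
exposed, 5 = understory); spring minimum temperature (February--March daily
minima), summer mean temperature (June--August, linear and quadratic), and
moisture deficit (cumulative monthly PET $-$ P over months 1--8), each
split into a site norm and yearly anomalies; and a deficit-by-diameter
interaction.  Summer temperature and deficit anomalies enter with current
and previous years; the spring minimum with the current year only.  For
species dispersing seed in spring, `build_design_vector(lag_only = TRUE)`
replaces current-year anomalies with the previous year's.

Two conventions are worth stating because sources disagree on them.
Moisture deficit is taken as PET $-$ P, so that larger values mean drier
conditions; its units are mm·month throughout.  Year effects
$\kappa_{e,t}$ are fixed effects within an ecoregion and hierarchically
shrunk between ecoregions ($\kappa_{e,t} \sim N(\bar\kappa_t, \tau^2)$),
and are centered to mean zero per ecoregion — the identifiability
convention that separates them from the intercept.

Maturation state $z_{ijt}$ is absorbing: once a tree is mature it stays
mature.  The state probability $\rho$ is a *state* probability, not a
transition hazard, so simulation and inference couple the whole trajectory
to one uniform draw per tree: $z_{ijt} = 1$ iff $\Phi(\mu_{ijt}) \ge u_i$.
Because $G$ is nondecreasing and $\alpha_G \ge 0$, this yields a monotone
trajectory whose marginal matches $\rho$ exactly, and reduces the latent
state to a single maturation changepoint year per tree.

## Observation layers

Two data types inform tree-year fecundity:

* **Crop counts**: a count of reproductive structures with a recorded
  fraction $\theta \in (0,1]$ of the crop observed.  Modelled as
  Poisson$(\theta\,\psi)$.  The source field protocols involve further
  detection structure that is not published in reusable form; the Poisson
  form here is a declared, swappable stand-in.
* **Seed traps**: fixed-area collectors with yearly counts, modelled as
  Poisson$\big(a \sum_i z_i \psi_i K(r_i; u)\big)$ with an isotropic 2D
  Student-t kernel $K(r; u) = u / (\pi (u + r^2)^2)$, which integrates to
  one over the plane.  $u$ (m$^2$) sets the spread; it is fixed by default
  (100 m$^2$) and can be sampled under a log-normal prior
  (`estimate_kernel = TRUE`).

A tree observed bearing seed, now or in the past, is known to be mature
now: positive crop counts and `first_seed_year` bound the maturation
changepoint in every posterior draw.  Failure to observe seed is *not*
evidence of immaturity, because crop failures and detection errors occur;
that asymmetry is exactly what the changepoint likelihood encodes.

# Posterior computation

`fit_fecundity()` uses a Gibbs/Metropolis composition chosen so that every
conditional is either exact or a textbook Metropolis step:

* **Maturation changepoints** are sampled by discrete Gibbs from the
  probit-implied prior (successive differences of $\Phi(\mu_{ijt})$, with a
  running maximum guarding non-monotone diameter records) times the exact
  observation-likelihood profile of "immature before year $m$, mature
  from $m$".  Trap terms are evaluated exactly by removing and re-adding
  one tree's kernel contribution.
* **Trap counts** are then split across mature trees by multinomial
  thinning of each Poisson count (the superposition property), which makes
  the latent $\log\psi$ conditionally independent across tree-years, so the
  **latent fecundities** update as one vectorized log-scale random-walk
  Metropolis sweep with a global step size adapted toward 0.3 acceptance
  during burn-in and frozen afterwards.
* **Coefficients** $\boldsymbol\beta$, year effects, and random effects are
  conjugate Gaussian updates; variances are inverse-gamma
  ($\mathrm{IG}(2,1)$ priors).  Two extra Gibbs moves translate mass along
  the likelihood-invariant directions (intercept vs. year-effect mean,
  intercept vs. random-effect mean); without them those sums mix very
  slowly.
* **The maturation probit** $(\alpha_0, \alpha_G)$ updates by joint
  random-walk Metropolis against the changepoint prior, with
  $\alpha_G \ge 0$ enforced (maturation must increase with size).

Priors, all configurable: $\beta, \bar\kappa \sim N(0, 10^2)$,
$\alpha_0 \sim N(-3, 2^2)$, $\alpha_G \sim N(0.05, 0.05^2)$ truncated at
zero.  Chain defaults are 4000 iterations, 2000 burn-in, thinning 2; a
split-chain potential scale reduction factor is reported per parameter but
deliberately not enforced.

## Size-class weighting

Abundant mid-sized trees would otherwise dominate the diameter response,
so coefficient sampling is a weighted regression: each tree-year's weight
is inversely proportional to the occupancy of its 5-cm diameter bin,
normalized to mean one.  The weights are implemented as observation
precisions in the regression layer — the latent $\log\psi$ regression has
variance $\sigma^2 / w_{ijt}$ — and they enter *every* conditional of that
layer ($\beta$, $\kappa$, $b$, $\sigma^2$, and the latent prior), not only
the $\beta$ draw.  Applying them in a single conditional would leave the
chain with incompatible conditionals and no coherent stationary
distribution; treating them uniformly as precisions keeps the sampler an
exact Gibbs sampler for a well-defined (heteroscedastic) posterior.  With
a single bin the scheme reduces to the unweighted model.

Cells with no observation influence (no crop count, no trap on the plot)
are marginalized out of the regression layer exactly rather than imputed;
this leaves the no-data posterior equal to the prior (a property the test
suite checks) and speeds mixing.

## Prediction

Expected fecundity marginalizes the individual effects:
$E[F] = \Phi(\mu) \exp(\mathbf{x}'\boldsymbol\beta + \kappa +
(\sigma^2 + \sigma^2_{re})/2)$ — the mean, not the median, of the
lognormal; both are available from the draws.  A requested year with no
fitted year effect falls back to the ecoregion mean with a warning.

# Growth and the Tobit

Diameter increments are regressed on the same covariates with
left-censoring at zero: a remeasurement can be smaller than its
predecessor, and the Tobit treats such negative growth as censored rather
than as signal.  `fit_tobit()` maximizes the censored likelihood directly
(BFGS with analytic gradients, then Newton steps until the gradient is
numerically zero), reports standard errors from the observed information,
and drops constant or linearly dependent design columns (few-site designs
leave the site-level norms collinear) rather than failing.  Uncertainty is
propagated through the asymptotic covariance; MCMC would add nothing for a
concave likelihood.

# Trend attribution

On the proportionate (log) scale, yearly change in expected fecundity
decomposes to first order as

$$\Delta f_{ijt} = \beta_{T_{sp}}\Delta T_{sp}
 + (\beta_T + 2\beta_{T^2} T)\,\Delta T
 + (\beta_D + \beta_{GD} G)\,\Delta D
 + \Big(\alpha_G \tfrac{\phi(\mu)}{\Phi(\mu)} + \beta_G + 2\beta_{G^2} G
        + \beta_{GD} D\Big)\Delta G
 + \gamma + \nu,$$

computed per tree-year by `decompose_tree_year()`.  The climate increments
are the OLS slopes of the site series over the analysis window (the trend
estimator is a package choice; the window, 1990--2019 by default, follows
the period of consistent recent warming).  The inverse Mills ratio
$\phi/\Phi$ — the maturation contribution — is evaluated on the log scale
so deeply immature trees give large finite values instead of 0/0.
`total` is the *exact* sum of its components plus $\gamma$; additivity is
asserted at $10^{-12}$, not approximated.  $\nu \sim N(0, 2\sigma^2)$, the
variance of a difference of residuals, is reported as a variance and not
folded into the deterministic total.

Three genuinely open design points were resolved as follows:

* $\gamma$ (trends "neither growth nor climate") is the OLS slope of the
  fitted ecoregion year effects over the analysis years plus the
  anomaly-trend carryover (anomaly slopes weighted by their current + lag
  coefficients), per site — symmetric with the climate-trend estimator.
* The growth term is routed back to climate by expanding
  $\Delta G$ with the growth model's partials:
  routed$(c) = \partial f/\partial G \cdot \partial g/\partial x_c \cdot
  \Delta c$, remainder unexplained.  The routed parts plus the remainder
  reconstruct the growth term exactly (a conservation identity the tests
  assert at $10^{-12}$).  A variable's "full effect" is its direct term
  plus its routed growth share, interaction parts assigned to the same
  variable.
* Growth partials for routing are taken on the latent (uncensored) linear
  predictor, not the censored mean: the decomposition is linear in
  coefficients and the censored-mean derivative would entangle the
  censoring probability with climate attribution.

Shade class is treated as constant per tree, so no $\Delta S$ term
appears.  Aggregation is the unweighted mean of per-tree totals (and of
each component) over a plot — proportionate change is used precisely so
that high- and low-fecundity species contribute comparably — and absolute
stand-level change is recovered as $\Delta F_j = \sum_i F_{ij}
\Delta f_{ij}$.  Species without their own fit inherit the element-wise
mean of fitted congeners (`genus_fallback()`).  Posterior uncertainty for
any tree's terms comes from re-evaluating the decomposition at each
retained draw.

# The synthetic-data generator

`simulate_dataset()` emulates the structure the analysis assumes, with
ground truth saved for recovery testing.  The default configuration — the
package's reference study conditions — is 40 single-plot sites in 4
ecoregions, 25 trees per plot, observation years 2005--2019 inside a
1990--2019 climate window, 2 seed traps per plot (0.5 m$^2$), and crop
counts on every tree-year with observed fractions uniform on (0.5, 1).
Site norms are uniform over realistic mid-latitude ranges (spring minima
$-3$ to $8\,^\circ$C, summer means 16--24 $^\circ$C, deficit 20--120
mm·month), warming trends of 0.01--0.04 $^\circ$C/yr, and iid Gaussian
anomalies (an AR(1) option exists for robustness experiments).
Generating coefficients (`default_truth()`) put 50% maturation near 20 cm,
median conditional fecundity near 100 seeds/yr for a mid-sized tree, a
thermal optimum at 20 $^\circ$C, negative shading and drought responses
with stronger drought sensitivity in large trees, residual sd 0.6, and
individual-effect sd 0.5.

What the generator does *not* emulate — and therefore what passing
recovery tests cannot certify about field data — includes resource-driven
mast synchrony beyond shared year effects, temporally autocorrelated
anomalies (by default), seed misidentification between species,
canopy-class measurement error, unbalanced panels, and observation efforts
that depend on crop size.

# Problem sizes and numerical choices

The validation suite fits the reference configuration (15,000 tree-years)
with 2,500 iterations (1,000 burn-in, thin 3) and checks that posterior
means of all fecundity coefficients fall within 3 posterior SDs of truth;
interval calibration uses 20 replicates of a reduced configuration (10
sites × 10 trees × 10 years, 900 iterations) and checks 90% credible
interval coverage of at least 80%.  These sizes were chosen as the
smallest at which site-level covariates (norms and their quadratics, which
are strongly collinear across sites) are meaningfully identified.  Exact
identities (decomposition additivity, routing conservation) are asserted
at $10^{-12}$; derivative checks against central finite differences at
$10^{-6}$ with step $10^{-5}$; Monte-Carlo identities at 3 standard
errors.  Ties in the changepoint categorical draw are broken by first
index (they occur only when two candidate years have identical posterior
weight); degenerate inputs — all-censored Tobit data, empty plots,
missing trends, fractions outside (0,1] — raise immediate, named errors.

# Limitations

The crop-count and seed-trap likelihoods are simplified stand-ins for
richer field protocols; the dispersal kernel is isotropic; year effects
absorb, but do not explain, masting synchrony; the decomposition is
first-order and its accuracy degrades quadratically with the size of the
yearly change (the test suite measures exactly this rate); and fitting
assumes a balanced tree-year panel per dataset, which real inventories
would need alignment to satisfy.
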