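# masting

Hierarchical fecundity models and climate trend attribution for masting
trees.

## The problem

Interannual seed production ("masting") of trees is volatile,
quasi-synchronous, and observed only indirectly — through binocular crop
counts with partial detection and through seed traps connected to trees by
a dispersal kernel.  Yet whether tree fecundity is rising or falling, and
*why*, is a demographic question that matters for forest regeneration under
climate change.  This package implements, end to end and at desk scale,
the modelling chain needed to answer it:

1. a **hierarchical Bayesian state-space model** of seed production, in
   which a tree's reproductive maturation follows a size-dependent probit
   and its conditional fecundity is log-linear in size, canopy shading,
   and climate;
2. a **Tobit regression** of annual diameter growth (censored at zero) on
   the same covariates; and
3. a first-order **trend-attribution decomposition** that splits the yearly
   proportionate change in expected fecundity into direct climate terms,
   growth-mediated terms (including the maturation contribution), and a
   residual trend.

It is written for quantitative ecologists and biostatisticians who want a
tested, reusable, fully synthetic-data-validated implementation of this
pipeline.

## The model

A tree $i$ at site $j$ in year $t$ is mature with probability
$\rho = \Phi(\alpha_0 + \alpha_G G)$ ($G$ = diameter, cm), and if mature
produces $\psi$ seeds with

$$\log \psi_{ijt} = \mathbf{x}_{ijt}'\boldsymbol\beta + \kappa_{e(j),t} + b_i + \varepsilon_{ijt},$$

where $\mathbf{x}$ holds diameter and its square, shade class, climate
norms and anomalies (spring minimum temperature, summer mean temperature
with a quadratic, moisture deficit with a size interaction — see
`design_terms()`), $\kappa$ are ecoregion year effects (fixed within,
hierarchical between ecoregions), and $b_i$ are individual effects.  Crop
counts are Poisson($\theta\psi$) given the observed fraction $\theta$;
trap counts are Poisson($a\sum_i z_i\psi_i K(r_i;u)$) with a 2D Student-t
dispersal kernel.  Expected fecundity is $F = \rho\,\psi$, and its yearly
proportionate change decomposes as

$$\frac{df}{dt} = \beta_{T_{sp}}\Delta T_{sp}
 + (\beta_T + 2\beta_{T^2}T)\,\Delta T
 + (\beta_D + \beta_{GD}G)\,\Delta D
 + \Big(\alpha_G\tfrac{\phi(\mu)}{\Phi(\mu)} + \beta_G + 2\beta_{G^2}G + \beta_{GD}D\Big)\Delta G
 + \gamma + \nu .$$

The methods vignette (`vignettes/trend-attribution-methods.Rmd`) derives
and discusses every term, the sampler, and all numerical choices.

## Worked example

Simulate a small study (8 sites, 12 trees each, 10 years, crop counts and
seed traps), fit the fecundity and growth models, and decompose trends:

```r
library(masting)
ds  <- simulate_dataset(n_sites = 8, n_trees_per_plot = 12,
                        obs_years = c(2008, 2017), seed = 4)
fit <- fit_fecundity(ds$trees, ds$climate, ds$cropcounts, ds$traps,
                     ds$trapcounts, window = ds$window,
                     n_iter = 1200, n_burn = 600, thin = 2, seed = 4)
print(fit)
#> Hierarchical maturation + fecundity model (MCMC)
#>   96 trees x 10 years; 300 retained draws (of 1200, burn-in 600, thin 2)
#>   acceptance: latent psi 0.30, maturation probit 0.32
#> Posterior means:
#>     intercept             G            G2             S      Tsp_norm
#>       -2.4032        0.1550       -0.0025       -0.2920        0.0974
#> ...
#>   alpha0 = -2.874, alpha_G = 0.1293, sigma2 = 0.312, sigma2_re = 0.310

gd  <- growth_increments(ds$trees, ds$climate, ds$window)
tob <- fit_tobit(gd$increments, gd$designs)
att <- attribute_trees(coef(fit), tob, ds$trees, ds$climate, ds$window)
round(colMeans(att[c("direct_Tsp", "direct_Tsum", "direct_D",
                     "growth_term", "maturation_component",
                     "gamma", "total")]), 5)
#>           direct_Tsp          direct_Tsum             direct_D
#>              0.00186             -0.00177             -0.00452
#>          growth_term maturation_component                gamma
#>              0.08891              0.05757              0.02553
#>                total
#>              0.11001
```

Read: on this simulated landscape, mean proportionate fecundity change is
+0.110/yr per tree-year; most of it comes through growth (+0.089/yr, of
which +0.058/yr is trees crossing into maturity as they grow), warming
springs add +0.002/yr directly, rising moisture deficit subtracts
0.005/yr, and trends in year effects contribute +0.026/yr.  `total` is the
exact sum of the components plus `gamma` for every row.
`aggregate_plot(att)` averages these over the trees of each plot and
converts to absolute stand-level change via $\sum_i F_i\,\Delta f_i$.

The full pipeline (simulate/read → fit → growth → attribute → report) runs
from one YAML config via `run_pipeline()`, or from a shell through the
thin wrapper `inst/scripts/run_pipeline.R`.

## Data schemas

CSV tables (UTF-8, header row), documented in `read_tables()`:

| file | columns |
|---|---|
| `trees.csv` | `tree_id, species, genus, site_id, plot_id, x, y, shade_class, year, diameter_cm` (+ optional `first_seed_year`) |
| `climate.csv` | `site_id, ecoregion, year, tsp_min, tsum_mean, deficit` |
| `cropcounts.csv` | `tree_id, year, count, fraction` |
| `traps.csv` | `trap_id, plot_id, x, y, area_m2` |
| `trapcounts.csv` | `trap_id, year, count` |

Units: diameters cm, coordinates m, temperatures °C, moisture deficit
mm·month as PET − P (positive = drier), trap areas m².
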