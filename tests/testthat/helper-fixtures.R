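# Shared fixture builders (everything generated in code at test time).

# Small two-tree, two-site long tables with hand-set values.
tiny_tables <- function() {
  years <- 2010:2013
  trees <- rbind(
    data.frame(tree_id = "tA", species = "sp1", genus = "g1",
               site_id = "s1", plot_id = "s1_p1", x = 10, y = 10,
               shade_class = 2, year = years,
               diameter_cm = c(20, 20.5, 21, 21.6)),
    data.frame(tree_id = "tB", species = "sp1", genus = "g1",
               site_id = "s2", plot_id = "s2_p1", x = 30, y = 20,
               shade_class = 4, year = years,
               diameter_cm = c(8, 8.2, 8.5, 8.9)))
  climate <- do.call(rbind, lapply(c("s1", "s2"), function(s) {
    yrs <- 2005:2013
    data.frame(site_id = s, ecoregion = if (s == "s1") "e1" else "e2",
               year = yrs,
               tsp_min = 2 + 0.03 * (yrs - 2009) + c(0.2, -0.1, 0, 0.1,
                                                     -0.2, 0.3, -0.3, 0.05,
                                                     -0.05),
               tsum_mean = 20 + 0.02 * (yrs - 2009),
               deficit = 60 - 0.5 * (yrs - 2009))
  }))
  list(trees = trees, climate = climate, window = c(2005, 2013))
}

# A site_climate object with all-zero climate (norms and anomalies 0).
zero_climate_site <- function(years = 2000:2019) {
  climate <- data.frame(site_id = "z1", ecoregion = "e1", year = years,
                        tsp_min = 0, tsum_mean = 0, deficit = 0)
  summarize_climate(climate, c(min(years), max(years)))[["z1"]]
}

# Canonical design vector built directly from underlying variables
# (anomalies fixed), used as the independent route for derivative checks.
design_from_vars <- function(Tsp, Tsum, D, G, S,
                             anoms = c(tsp = 0, tsum = 0, tsum1 = 0,
                                       d = 0, d1 = 0)) {
  x <- c(1, G, G^2, S, Tsp, anoms["tsp"], Tsum, Tsum^2, anoms["tsum"],
         anoms["tsum1"], D, anoms["d"], anoms["d1"], D * G)
  names(x) <- design_terms()
  x
}

# Random-but-reproducible fecundity coefficients for derivative checks.
random_coefficients <- function(seed) {
  set.seed(seed)
  beta <- stats::rnorm(14, 0, 0.1)
  names(beta) <- design_terms()
  fecundity_coefficients(alpha0 = stats::rnorm(1, -2, 1),
                         alpha_G = stats::runif(1, 0.01, 0.2),
                         beta = beta, sigma2_resid = 0.4, sigma2_re = 0.2)
}

# log expected occupancy-and-production surface f = log(rho * psi) as a
# function of the underlying variables; oracle for partial derivatives.
log_rho_psi <- function(cf, Tsp, Tsum, D, G, S, anoms = NULL) {
  x <- if (is.null(anoms)) design_from_vars(Tsp, Tsum, D, G, S)
       else design_from_vars(Tsp, Tsum, D, G, S, anoms)
  stats::pnorm(cf$alpha0 + cf$alpha_G * G, log.p = TRUE) + sum(x * cf$beta)
}

# Small synthetic dataset for fitting tests.
small_dataset <- function(seed = 11, n_sites = 6, n_trees = 8,
                          obs_years = c(2010, 2017)) {
  simulate_dataset(n_sites = n_sites, n_trees_per_plot = n_trees,
                   obs_years = obs_years, seed = seed)
}
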