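#' Fecundity model coefficients
#'
#' Container for the parameters of the maturation + conditional-fecundity
#' model: probit maturation intercept and slope, the fecundity coefficient
#' vector aligned to [design_terms()], ecoregion-by-year effects, residual
#' and random-effect variances, and the dispersal-kernel scale.
#'
#' @param alpha0 Maturation probit intercept.
#' @param alpha_G Maturation probit slope (per cm); must be >= 0.
#' @param beta Named numeric vector in [design_terms()] order.
#' @param kappa Year-effect matrix, ecoregions in rows (named), years in
#'   columns (named); may be `NULL` before fitting.
#' @param sigma2_resid Residual variance of log conditional fecundity.
#' @param sigma2_re Variance of per-tree random effects.
#' @param kernel_u Dispersal-kernel scale, m^2.
#' @return Object of class `fecundity_coefficients`.
#' @export
fecundity_coefficients <- function(alpha0, alpha_G, beta, kappa = NULL,
                                   sigma2_resid, sigma2_re, kernel_u = 100) {
  if (alpha_G < 0) stop("alpha_G must be >= 0: maturation increases with size")
  if (sigma2_resid < 0 || sigma2_re < 0) stop("variances must be non-negative")
  beta <- beta[design_terms()]
  if (anyNA(beta)) stop("beta must be named by design_terms()")
  structure(list(alpha0 = alpha0, alpha_G = alpha_G, beta = beta,
                 kappa = kappa, sigma2_resid = sigma2_resid,
                 sigma2_re = sigma2_re, kernel_u = kernel_u),
            class = "fecundity_coefficients")
}

#' Growth model coefficients
#'
#' @param beta_g Named numeric vector in [design_terms()] order (cm/yr per
#'   unit predictor).
#' @param sigma_g Latent increment noise scale, cm/yr (> 0).
#' @return Object of class `growth_coefficients`.
#' @export
growth_coefficients <- function(beta_g, sigma_g) {
  if (sigma_g < 0) stop("sigma_g must be >= 0")
  beta_g <- beta_g[design_terms()]
  if (anyNA(beta_g)) stop("beta_g must be named by design_terms()")
  structure(list(beta_g = beta_g, sigma_g = sigma_g),
            class = "growth_coefficients")
}

#' Default generating parameters for the synthetic study
#'
#' Values chosen to mimic a temperate masting species: 50% maturation around
#' 20 cm diameter, median conditional fecundity on the order of 100 seeds/yr
#' for a mid-sized canopy tree, strong summer-temperature response with a
#' thermal optimum near 20 degC, negative moisture-deficit and shading
#' responses, greater drought sensitivity in large trees (negative D x G),
#' and lognormal year-to-year volatility (residual sd 0.6) on top of year
#' effects and individual effects.
#'
#' @return List with elements `fec` ([fecundity_coefficients()]) and
#'   `growth` ([growth_coefficients()]).
#' @export
default_truth <- function() {
  beta <- c(intercept = 1.0, G = 0.05, G2 = -4e-4, S = -0.3,
            Tsp_norm = 0.08, Tsp_anom = 0.10,
            Tsum_norm = 0.40, Tsum_norm2 = -0.01,
            Tsum_anom = 0.10, Tsum_anom_lag = 0.05,
            D_norm = -0.005, D_anom = -0.004, D_anom_lag = -0.002,
            DxG = -1e-4)
  beta_g <- c(intercept = 0.55, G = 0.01, G2 = -2e-4, S = -0.05,
              Tsp_norm = 0.005, Tsp_anom = 0.004,
              Tsum_norm = 0.010, Tsum_norm2 = -3e-4,
              Tsum_anom = 0.005, Tsum_anom_lag = 0.002,
              D_norm = -8e-4, D_anom = -5e-4, D_anom_lag = -2e-4,
              DxG = -2e-6)
  list(fec = fecundity_coefficients(alpha0 = -2, alpha_G = 0.1, beta = beta,
                                    sigma2_resid = 0.36, sigma2_re = 0.25,
                                    kernel_u = 100),
       growth = growth_coefficients(beta_g = beta_g, sigma_g = 0.15))
}
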