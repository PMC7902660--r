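#' Partial derivatives of log expected fecundity
#'
#' Responses of `f = log(rho * psi)` to each trend-bearing variable at the
#' current design point.  Main effects are fitted coefficients; predictors
#' in quadratics or interactions combine coefficients with current values;
#' diameter additionally carries the maturation term `alpha_G *
#' phi(mu)/Phi(mu)` (inverse Mills ratio of the maturation probit), which is
#' evaluated on the log scale so deeply immature trees give large finite
#' values rather than NaN.
#'
#' @param coefficients [fecundity_coefficients()].
#' @param design Named design vector from [build_design_vector()].
#' @return Named vector of partials: `Tsp` (1/degC), `Tsum` (1/degC), `D`
#'   (1/(mm month)), `G` (1/cm), `S` (per shade class).
#' @export
response_partials <- function(coefficients, design) {
  p <- linpred_partials(coefficients$beta, design)
  mu <- coefficients$alpha0 + coefficients$alpha_G * unname(design["G"])
  p["G"] <- p["G"] + coefficients$alpha_G * inverse_mills(mu)
  p
}

#' First-order trend decomposition for one tree-year
#'
#' Splits the yearly proportionate fecundity change `df/dt` into direct
#' climate terms (partial response times climate trend), a growth term
#' (diameter response, including its maturation component, times diameter
#' change), and a residual trend `gamma` carrying year-effect and anomaly
#' trends.  `total` is the exact sum of the deterministic terms plus
#' `gamma`; the stochastic residual has variance `nu_var = 2 * sigma2_resid`
#' (the variance of a difference of two independent model residuals) and is
#' reported as a variance, not added to the total.
#'
#' @param coefficients [fecundity_coefficients()].
#' @param design Named design vector.
#' @param climate_trends Named numeric with `tsp`, `tsum`, `d` trends
#'   (degC/yr, degC/yr, mm month/yr).
#' @param dG Diameter change, cm/yr (from the growth model or observed).
#' @param gamma Residual trend term, 1/yr (see [estimate_gamma()]).
#' @param growth Optional [growth_coefficients()] or [fit_tobit()]; when
#'   supplied the growth term is also routed to climate variables via
#'   [route_growth_to_climate()].
#' @return Object of class `ta_terms`: list with `direct_Tsp`,
#'   `direct_Tsum`, `direct_D`, `growth_term`, `maturation_component`,
#'   `routed` (or `NULL`), `unexplained_growth`, `gamma`, `nu_var`, `total`.
#' @export
decompose_tree_year <- function(coefficients, design, climate_trends, dG,
                                gamma = 0, growth = NULL) {
  for (v in c("tsp", "tsum", "d"))
    if (is.na(climate_trends[v]))
      stop("missing climate trend for variable ", v)
  pr <- response_partials(coefficients, design)
  mu <- coefficients$alpha0 + coefficients$alpha_G * unname(design["G"])
  direct_Tsp <- unname(pr["Tsp"] * climate_trends["tsp"])
  direct_Tsum <- unname(pr["Tsum"] * climate_trends["tsum"])
  direct_D <- unname(pr["D"] * climate_trends["d"])
  growth_term <- unname(pr["G"]) * dG
  maturation_component <- coefficients$alpha_G * inverse_mills(mu) * dG
  routed <- NULL; unexplained <- NULL
  if (!is.null(growth)) {
    rt <- route_growth_to_climate(coefficients, growth, design,
                                  climate_trends, dG)
    routed <- rt$routed
    unexplained <- rt$unexplained
  }
  total <- direct_Tsp + direct_Tsum + direct_D + growth_term + gamma
  structure(list(direct_Tsp = direct_Tsp, direct_Tsum = direct_Tsum,
                 direct_D = direct_D, growth_term = growth_term,
                 maturation_component = maturation_component,
                 routed = routed, unexplained_growth = unexplained,
                 gamma = unname(gamma),
                 nu_var = 2 * coefficients$sigma2_resid,
                 total = total),
            class = "ta_terms")
}

#' @export
print.ta_terms <- function(x, ...) {
  cat("Trend-attribution terms (proportionate fecundity change, 1/yr)\n")
  v <- c(direct_Tsp = x$direct_Tsp, direct_Tsum = x$direct_Tsum,
         direct_D = x$direct_D, growth = x$growth_term,
         `  of which maturation` = x$maturation_component,
         gamma = x$gamma, total = x$total)
  print(round(v, 6))
  if (!is.null(x$routed)) {
    cat("growth routed to climate:\n")
    print(round(c(x$routed, unexplained = x$unexplained_growth), 6))
  }
  invisible(x)
}

#' Route the growth term back to climate variables
#'
#' The diameter change `dG` is decomposed into climate-attributable parts
#' (growth partial times climate trend) plus an unexplained remainder;
#' multiplying each part by the fecundity response to diameter reproduces
#' the growth term exactly (conservation).
#'
#' @param fec [fecundity_coefficients()].
#' @param growth [growth_coefficients()] or [fit_tobit()].
#' @param design Named design vector.
#' @param climate_trends Named numeric with `tsp`, `tsum`, `d` (units/yr).
#' @param dG Realized diameter change, cm/yr.
#' @return List: `routed` (named `Tsp`, `Tsum`, `D`, in 1/yr),
#'   `unexplained` (1/yr), `growth_term` (their exact sum).
#' @export
route_growth_to_climate <- function(fec, growth, design, climate_trends, dG) {
  gb <- if (inherits(growth, "tobit_fit")) growth$coefficients
        else growth$beta_g
  if (!all(design_terms() %in% names(gb)))
    stop("growth coefficients are not aligned to the design")
  gp <- growth_partials(growth, design)
  dfdG <- unname(response_partials(fec, design)["G"])
  dG_parts <- c(Tsp = unname(gp["Tsp"] * climate_trends["tsp"]),
                Tsum = unname(gp["Tsum"] * climate_trends["tsum"]),
                D = unname(gp["D"] * climate_trends["d"]))
  routed <- dfdG * dG_parts
  unexplained <- dfdG * (dG - sum(dG_parts))
  list(routed = routed, unexplained = unexplained,
       growth_term = sum(routed) + unexplained)
}

#' Residual trend term from year effects and anomaly trends
#'
#' The decomposition's direct terms use trends in climate norms; trends in
#' the year effects and in the anomalies over the analysis years are not
#' captured there and enter through `gamma`.  Computed per site as the OLS
#' slope of the site's ecoregion year effects plus the anomaly trends
#' weighted by their (current + lag) coefficients.
#'
#' @param coefficients [fecundity_coefficients()] with `kappa` filled.
#' @param clim Site climate list from [summarize_climate()].
#' @param years Integer years over which to evaluate the trends (>= 3).
#' @return Named numeric, gamma (1/yr) per site.
#' @export
estimate_gamma <- function(coefficients, clim, years) {
  if (is.null(coefficients$kappa)) stop("coefficients carry no year effects")
  kap <- coefficients$kappa
  yrs_k <- intersect(as.character(years), colnames(kap))
  if (length(yrs_k) < 3) stop("need >= 3 years of year effects for gamma")
  slope <- function(y, t) {
    tc <- t - mean(t)
    sum(tc * (y - mean(y))) / sum(tc^2)
  }
  kslope <- apply(kap[, yrs_k, drop = FALSE], 1, slope,
                  t = as.integer(yrs_k))
  b <- coefficients$beta
  vapply(clim, function(s) {
    an <- s$anomalies[rownames(s$anomalies) %in% as.character(years), ,
                      drop = FALSE]
    t <- as.integer(rownames(an))
    unname(kslope[s$ecoregion]) +
      unname(b["Tsp_anom"]) * slope(an[, "tsp"], t) +
      unname(b["Tsum_anom"] + b["Tsum_anom_lag"]) * slope(an[, "tsum"], t) +
      unname(b["D_anom"] + b["D_anom_lag"]) * slope(an[, "d"], t)
  }, numeric(1))
}

#' @keywords internal
#' Flatten a ta_terms object into a one-row data frame.
ta_row <- function(terms) {
  r <- data.frame(direct_Tsp = terms$direct_Tsp,
                  direct_Tsum = terms$direct_Tsum,
                  direct_D = terms$direct_D,
                  growth_term = terms$growth_term,
                  maturation_component = terms$maturation_component,
                  gamma = terms$gamma, nu_var = terms$nu_var,
                  total = terms$total)
  if (!is.null(terms$routed)) {
    r$routed_Tsp <- unname(terms$routed["Tsp"])
    r$routed_Tsum <- unname(terms$routed["Tsum"])
    r$routed_D <- unname(terms$routed["D"])
    r$unexplained_growth <- terms$unexplained_growth
  }
  r
}

#' Plot-level aggregation of trend-attribution terms
#'
#' Unweighted arithmetic means of the per-tree totals and of every
#' component across trees of a plot, with a per-species breakdown, plus the
#' absolute stand-level change `sum(F * df)` when expected fecundities are
#' supplied.
#'
#' @param terms Data frame of per-tree(-year) attribution rows, including
#'   columns `plot_id`, `species`, the component columns of [ta_row()], and
#'   optionally `F` (expected seeds/yr).
#' @return List of class `plot_summary` per plot: `plot_id`, `n_trees`
#'   (member rows: trees, or tree-years when all years are decomposed),
#'   `mean_df`, `components` (named means), `by_species`, `dF_stand`.
#' @export
aggregate_plot <- function(terms) {
  if (!nrow(terms)) stop("no trees to aggregate")
  num <- intersect(c("direct_Tsp", "direct_Tsum", "direct_D", "growth_term",
                     "maturation_component", "routed_Tsp", "routed_Tsum",
                     "routed_D", "unexplained_growth", "gamma", "total"),
                   names(terms))
  lapply(split(terms, terms$plot_id), function(tt) {
    comp <- colMeans(tt[num])
    by_sp <- do.call(rbind, lapply(split(tt, tt$species), function(ss)
      data.frame(species = ss$species[1], n = nrow(ss),
                 mean_df = mean(ss$total))))
    rownames(by_sp) <- NULL
    dF <- if ("F" %in% names(tt))
      stand_absolute_change(tt$F, tt$total) else NA_real_
    structure(list(plot_id = tt$plot_id[1], n_trees = nrow(tt),
                   mean_df = unname(comp["total"]), components = comp,
                   by_species = by_sp, dF_stand = dF),
              class = "plot_summary")
  })
}

#' @export
print.plot_summary <- function(x, ...) {
  cat(sprintf("Plot %s: %d members, mean df/dt = %.5f /yr", x$plot_id,
              x$n_trees, x$mean_df))
  if (!is.na(x$dF_stand))
    cat(sprintf(", stand dF = %.1f seeds/yr", x$dF_stand))
  cat("\n")
  invisible(x)
}

#' Absolute stand-level fecundity change
#'
#' `sum_i F_i * df_i`: converts per-tree proportionate changes back to
#' absolute seeds per year and sums over the stand.
#'
#' @param F_values Expected fecundities, seeds/yr.
#' @param df_values Proportionate changes, 1/yr.
#' @return Scalar, seeds/yr.
#' @export
stand_absolute_change <- function(F_values, df_values) {
  if (length(F_values) != length(df_values))
    stop("F_values and df_values must have equal length")
  sum(F_values * df_values)
}

#' Genus-mean fallback for unfitted species
#'
#' A species with its own fit uses its own coefficients; otherwise the
#' element-wise mean over fitted congeners stands in.
#'
#' @param fitted Named list (by species) of [fecundity_coefficients()].
#' @param species Species to look up.
#' @param genus Its genus.
#' @param genus_of Named character mapping fitted species to genera; by
#'   default read from a `genus` field on each element.
#' @return A [fecundity_coefficients()] object.
#' @export
genus_fallback <- function(fitted, species, genus, genus_of = NULL) {
  if (species %in% names(fitted)) return(fitted[[species]])
  if (is.null(genus_of))
    genus_of <- vapply(fitted, function(f)
      if (is.null(f$genus)) NA_character_ else f$genus, "")
  cong <- names(fitted)[!is.na(genus_of) & genus_of == genus]
  if (!length(cong))
    stop("no fitted congener for genus ", genus)
  fl <- fitted[cong]
  avg <- function(get) {
    vals <- lapply(fl, get)
    Reduce(`+`, vals) / length(vals)
  }
  kap <- tryCatch(avg(function(f) f$kappa), error = function(e) NULL)
  out <- fecundity_coefficients(
    alpha0 = avg(function(f) f$alpha0),
    alpha_G = avg(function(f) f$alpha_G),
    beta = avg(function(f) f$beta),
    kappa = kap,
    sigma2_resid = avg(function(f) f$sigma2_resid),
    sigma2_re = avg(function(f) f$sigma2_re),
    kernel_u = avg(function(f) f$kernel_u))
  out$genus <- genus
  out
}

#' Posterior uncertainty for the decomposition terms
#'
#' Re-evaluates [decompose_tree_year()] at each retained posterior draw and
#' returns per-term quantiles.  With `include_nu = TRUE` a draw of the
#' stochastic residual `nu ~ N(0, 2 sigma2)` is added to each draw's total,
#' giving a predictive rather than mean-trend interval.
#'
#' @param fit A `fecundity_fit` (needs >= 100 retained draws).
#' @param design Named design vector.
#' @param climate_trends Named `tsp`, `tsum`, `d` trends (units/yr).
#' @param dG Diameter change, cm/yr.
#' @param gamma Residual trend (scalar, or per-draw vector).
#' @param probs Quantiles to report.
#' @param include_nu Add predictive residual noise to the total.
#' @return Matrix: rows = terms (+ total), columns = quantiles.
#' @export
propagate_uncertainty <- function(fit, design, climate_trends, dG, gamma = 0,
                                  probs = c(0.05, 0.5, 0.95),
                                  include_nu = FALSE) {
  S <- nrow(fit$samples$beta)
  if (is.null(S) || S < 100) stop("need at least 100 retained draws")
  gam <- rep_len(gamma, S)
  rows <- matrix(NA_real_, S, 6,
                 dimnames = list(NULL, c("direct_Tsp", "direct_Tsum",
                                         "direct_D", "growth_term",
                                         "gamma", "total")))
  for (s in seq_len(S)) {
    cf <- fecundity_coefficients(
      alpha0 = fit$samples$alpha[s, 1], alpha_G = fit$samples$alpha[s, 2],
      beta = fit$samples$beta[s, ],
      sigma2_resid = fit$samples$sigma2_resid[s],
      sigma2_re = fit$samples$sigma2_re[s])
    d <- decompose_tree_year(cf, design, climate_trends, dG, gam[s])
    rows[s, ] <- c(d$direct_Tsp, d$direct_Tsum, d$direct_D, d$growth_term,
                   d$gamma, d$total)
  }
  if (include_nu)
    rows[, "total"] <- rows[, "total"] +
      stats::rnorm(S, 0, sqrt(2 * fit$samples$sigma2_resid))
  t(apply(rows, 2, stats::quantile, probs = probs))
}
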