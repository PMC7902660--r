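test_that("response partials reproduce the stated coefficient combinations", {
  beta <- stats::setNames(numeric(14), design_terms())
  beta["D_norm"] <- -0.02; beta["DxG"] <- 0.001
  cf <- fecundity_coefficients(alpha0 = -2, alpha_G = 0.1, beta = beta,
                               sigma2_resid = 0.3, sigma2_re = 0.1)
  x <- design_from_vars(Tsp = 0, Tsum = 0, D = 50, G = 30, S = 1)
  p <- response_partials(cf, x)
  expect_equal(unname(p["D"]), -0.02 + 0.001 * 30)

  # maturation term: inverse Mills at mu = 0 is sqrt(2/pi)
  beta2 <- stats::setNames(numeric(14), design_terms())
  cf2 <- fecundity_coefficients(alpha0 = -5, alpha_G = 0.1, beta = beta2,
                                sigma2_resid = 0.3, sigma2_re = 0.1)
  x2 <- design_from_vars(Tsp = 0, Tsum = 0, D = 0, G = 50, S = 1)
  p2 <- response_partials(cf2, x2)
  expect_equal(unname(p2["G"]), 0.1 * sqrt(2 / pi), tolerance = 1e-6)
  expect_equal(unname(p2["G"]), 0.1 * 0.79788, tolerance = 1e-4)
})

test_that("response partials survive deep-immaturity underflow", {
  cf <- random_coefficients(3)
  x <- design_from_vars(Tsp = 0, Tsum = 0, D = 0, G = 1, S = 1)
  cf$alpha0 <- -60   # Phi underflows to 0 in double precision
  p <- response_partials(cf, x)
  expect_true(all(is.finite(p)))
})

test_that("response partials match finite differences of log(rho * psi)", {
  for (seed in 1:10) {
    cf <- random_coefficients(seed)
    set.seed(seed + 100)
    vars <- list(Tsp = stats::rnorm(1, 3, 2), Tsum = stats::rnorm(1, 20, 2),
                 D = stats::runif(1, 20, 120), G = stats::runif(1, 5, 60),
                 S = sample(1:5, 1))
    x <- do.call(design_from_vars, vars)
    p <- response_partials(cf, x)
    h <- 1e-5
    for (v in c("Tsp", "Tsum", "D", "G")) {
      up <- vars; up[[v]] <- up[[v]] + h
      dn <- vars; dn[[v]] <- dn[[v]] - h
      fd <- (do.call(log_rho_psi, c(list(cf), up)) -
               do.call(log_rho_psi, c(list(cf), dn))) / (2 * h)
      expect_equal(unname(p[v]), fd, tolerance = 1e-6,
                   label = paste(v, "seed", seed))
    }
  }
})

test_that("decomposition terms follow the rate equation and sum exactly", {
  cf <- random_coefficients(11)
  x <- design_from_vars(Tsp = 2, Tsum = 19, D = 60, G = 25, S = 2)
  z0 <- decompose_tree_year(cf, x, c(tsp = 0, tsum = 0, d = 0), dG = 0,
                            gamma = 0.004)
  expect_equal(z0$direct_Tsp, 0)
  expect_equal(z0$growth_term, 0)
  expect_equal(z0$total, 0.004)

  beta <- stats::setNames(numeric(14), design_terms())
  beta["Tsp_norm"] <- 0.1
  cf2 <- fecundity_coefficients(alpha0 = -2, alpha_G = 0.05, beta = beta,
                                sigma2_resid = 0.3, sigma2_re = 0.1)
  z1 <- decompose_tree_year(cf2, x, c(tsp = 0.5, tsum = 0, d = 0), dG = 0)
  expect_equal(z1$direct_Tsp, 0.05)
  expect_equal(z1$total, 0.05)
  expect_equal(z1$nu_var, 2 * 0.3)

  # exact additivity on randomized inputs
  for (seed in 1:20) {
    cfs <- random_coefficients(seed + 40)
    set.seed(seed)
    tr <- c(tsp = stats::rnorm(1, 0, 0.05), tsum = stats::rnorm(1, 0, 0.05),
            d = stats::rnorm(1, 0, 0.5))
    zz <- decompose_tree_year(cfs, x, tr, dG = stats::rnorm(1, 0.3, 0.1),
                              gamma = stats::rnorm(1, 0, 0.01))
    expect_lt(abs(zz$total - (zz$direct_Tsp + zz$direct_Tsum + zz$direct_D +
                                zz$growth_term + zz$gamma)), 1e-15)
  }
  expect_error(decompose_tree_year(cf, x, c(tsp = 0.1, tsum = 0.1), 0),
               "missing climate trend")
})

test_that("maturation component carries the sign of the diameter change", {
  cf <- random_coefficients(50)
  x <- design_from_vars(Tsp = 1, Tsum = 18, D = 40, G = 15, S = 1)
  tr <- c(tsp = 0.02, tsum = 0.02, d = 0.3)
  up <- decompose_tree_year(cf, x, tr, dG = 0.4)
  dn <- decompose_tree_year(cf, x, tr, dG = -0.4)
  expect_gt(up$maturation_component, 0)
  expect_lt(dn$maturation_component, 0)
})

test_that("deterministic total is first-order accurate in the perturbation", {
  cf <- random_coefficients(12)
  vars <- list(Tsp = 3, Tsum = 20, D = 70, G = 30, S = 2)
  x <- do.call(design_from_vars, vars)
  dirn <- c(tsp = 0.4, tsum = 0.3, d = 6, G = 0.8)
  hs <- 2^-(0:6)
  errs <- vapply(hs, function(h) {
    tr <- c(tsp = dirn["tsp"], tsum = dirn["tsum"], d = dirn["d"]) * h
    names(tr) <- c("tsp", "tsum", "d")
    dG <- unname(dirn["G"] * h)
    dt <- decompose_tree_year(cf, x, tr, dG)
    up <- list(Tsp = vars$Tsp + tr["tsp"], Tsum = vars$Tsum + tr["tsum"],
               D = vars$D + tr["d"], G = vars$G + dG, S = vars$S)
    exact <- do.call(log_rho_psi, c(list(cf), up)) -
      do.call(log_rho_psi, c(list(cf), vars))
    abs(exact - dt$total)
  }, numeric(1))
  # halving the step quarters the error (second-order remainder)
  rates <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(rates > 1.6 & rates < 2.4))
})

test_that("growth routing conserves the growth term exactly", {
  cf <- random_coefficients(13)
  bg <- stats::setNames(numeric(14), design_terms())
  bg["D_norm"] <- -0.002; bg["DxG"] <- -1e-5
  gro <- growth_coefficients(bg, 0.1)
  x <- design_from_vars(Tsp = 2, Tsum = 18, D = 80, G = 35, S = 3)
  tr <- c(tsp = 0.03, tsum = 0.02, d = 0.5)
  rt <- route_growth_to_climate(cf, gro, x, tr, dG = 0.5)
  # growth depends only on D: temperature routes are zero
  expect_equal(unname(rt$routed["Tsp"]), 0)
  expect_equal(unname(rt$routed["Tsum"]), 0)
  dfdG <- unname(response_partials(cf, x)["G"])
  gpD <- unname(growth_partials(gro, x)["D"])
  expect_equal(unname(rt$routed["D"]), dfdG * gpD * 0.5)

  # zero trends: everything unexplained
  rt0 <- route_growth_to_climate(cf, gro, x,
                                 c(tsp = 0, tsum = 0, d = 0), dG = 0.5)
  expect_true(all(rt0$routed == 0))
  expect_equal(rt0$unexplained, dfdG * 0.5)

  # conservation on randomized draws
  for (seed in 1:15) {
    set.seed(seed)
    bg2 <- stats::rnorm(14, 0, 0.01); names(bg2) <- design_terms()
    g2 <- growth_coefficients(bg2, 0.2)
    trr <- c(tsp = stats::rnorm(1, 0, 0.1), tsum = stats::rnorm(1, 0, 0.1),
             d = stats::rnorm(1, 0, 1))
    dG <- stats::rnorm(1, 0.3, 0.2)
    rr <- route_growth_to_climate(cf, g2, x, trr, dG)
    gt <- unname(response_partials(cf, x)["G"]) * dG
    expect_lt(abs(sum(rr$routed) + rr$unexplained - gt), 1e-12)
  }
})

test_that("direct terms are positive when response and trend share sign", {
  cf <- random_coefficients(14)
  x <- design_from_vars(Tsp = 2, Tsum = 18, D = 60, G = 20, S = 2)
  p <- response_partials(cf, x)
  tr <- c(tsp = 0.05 * sign(p["Tsp"]), tsum = 0.05 * sign(p["Tsum"]),
          d = 0.5 * sign(p["D"]))
  names(tr) <- c("tsp", "tsum", "d")
  d <- decompose_tree_year(cf, x, tr, dG = 0)
  expect_gt(d$direct_Tsp, 0)
  expect_gt(d$direct_Tsum, 0)
  expect_gt(d$direct_D, 0)
})

test_that("plot aggregation takes unweighted means and stand sums", {
  terms <- data.frame(plot_id = "p1", species = c("a", "b"),
                      direct_Tsp = c(0.01, 0.02),
                      direct_Tsum = c(0, 0), direct_D = c(0, 0),
                      growth_term = c(0.005, -0.02),
                      maturation_component = c(0.001, 0.002),
                      gamma = c(0.005, -0.01),
                      total = c(0.02, -0.01), F = c(100, 50))
  ps <- aggregate_plot(terms)[["p1"]]
  expect_equal(ps$mean_df, 0.005)
  expect_equal(ps$n_trees, 2)
  expect_equal(unname(ps$components["direct_Tsp"]), 0.015)
  # linearity: mean of totals equals sum of mean components
  expect_equal(unname(sum(ps$components[c("direct_Tsp", "direct_Tsum",
                                          "direct_D", "growth_term",
                                          "gamma")])), ps$mean_df)
  expect_equal(ps$dF_stand, 100 * 0.02 + 50 * -0.01)
  expect_equal(nrow(ps$by_species), 2)

  single <- aggregate_plot(terms[1, ])[["p1"]]
  expect_equal(single$mean_df, 0.02)
  expect_error(aggregate_plot(terms[0, ]), "no trees")
})

test_that("stand-level absolute change is the product-sum", {
  expect_equal(stand_absolute_change(c(100, 50), c(0.1, -0.2)), 0)
  expect_equal(stand_absolute_change(c(0, 80), c(0.5, 0.01)), 0.8)
  set.seed(17)
  F <- stats::runif(40, 0, 500); df <- stats::rnorm(40, 0, 0.05)
  expect_equal(stand_absolute_change(F, df), sum(F * df))
  expect_error(stand_absolute_change(1:3, 1:2), "equal length")
})

test_that("genus fallback averages fitted congeners element-wise", {
  mk <- function(seed, genus) {
    cf <- random_coefficients(seed)
    cf$genus <- genus
    cf
  }
  fitted <- list(oakA = mk(1, "Quercus"), oakB = mk(2, "Quercus"),
                 oakC = mk(3, "Quercus"), pineA = mk(4, "Pinus"))
  expect_identical(genus_fallback(fitted, "oakA", "Quercus"),
                   fitted$oakA)
  gb <- genus_fallback(fitted, "oakZ", "Quercus")
  ref <- colMeans(rbind(fitted$oakA$beta, fitted$oakB$beta,
                        fitted$oakC$beta))
  expect_equal(gb$beta, ref)
  expect_equal(gb$alpha0, mean(sapply(fitted[1:3], `[[`, "alpha0")))
  two <- genus_fallback(fitted[c("oakA", "oakB")], "oakZ", "Quercus")
  expect_equal(two$alpha_G, (fitted$oakA$alpha_G + fitted$oakB$alpha_G) / 2)
  expect_error(genus_fallback(fitted, "mapleA", "Acer"), "Acer")
})

test_that("gamma reflects the year-effect trend plus anomaly carryover", {
  tt <- tiny_tables()
  clim <- summarize_climate(tt$climate, tt$window)
  beta <- stats::setNames(numeric(14), design_terms())
  yrs <- 2006:2013
  kap <- matrix(rep(0.01 * (yrs - 2009), each = 2), 2,
                dimnames = list(c("e1", "e2"), yrs))
  cf <- fecundity_coefficients(alpha0 = -2, alpha_G = 0.05, beta = beta,
                               kappa = kap, sigma2_resid = 0.3,
                               sigma2_re = 0.1)
  g <- estimate_gamma(cf, clim, yrs)
  # anomaly coefficients are zero, so gamma is the kappa slope alone
  expect_equal(unname(g["s1"]), 0.01, tolerance = 1e-10)
  expect_equal(unname(g["s2"]), 0.01, tolerance = 1e-10)
})

test_that("uncertainty propagation reduces to empirical quantiles", {
  S <- 200
  beta_draws <- matrix(rep(stats::rnorm(14, 0, 0.05), each = S), S,
                       dimnames = list(NULL, design_terms()))
  fake <- structure(list(samples = list(
    beta = beta_draws,
    alpha = cbind(rep(-2, S), rep(0.1, S)),
    sigma2_resid = rep(0.3, S), sigma2_re = rep(0.2, S))),
    class = "fecundity_fit")
  x <- design_from_vars(Tsp = 2, Tsum = 19, D = 50, G = 25, S = 2)
  tr <- c(tsp = 0.02, tsum = 0.02, d = 0.4)
  q <- propagate_uncertainty(fake, x, tr, dG = 0.3)
  # identical draws: zero-width intervals
  expect_equal(q["total", "5%"], q["total", "95%"])

  set.seed(23)
  beta_draws2 <- beta_draws + matrix(stats::rnorm(S * 14, 0, 0.01), S)
  colnames(beta_draws2) <- design_terms()
  fake2 <- fake
  fake2$samples$beta <- beta_draws2
  q2 <- propagate_uncertainty(fake2, x, tr, dG = 0.3)
  totals <- vapply(seq_len(S), function(s) {
    cf <- fecundity_coefficients(alpha0 = -2, alpha_G = 0.1,
                                 beta = beta_draws2[s, ],
                                 sigma2_resid = 0.3, sigma2_re = 0.2)
    decompose_tree_year(cf, x, tr, dG = 0.3)$total
  }, numeric(1))
  expect_equal(unname(q2["total", ]),
               unname(stats::quantile(totals, c(0.05, 0.5, 0.95))))
  # total is linear in the Gaussian draws, so median tracks the mean
  expect_lt(abs(q2["total", "50%"] - mean(totals)),
            4 * stats::sd(totals) / sqrt(S))

  fake3 <- fake
  fake3$samples <- lapply(fake$samples, function(m)
    if (is.matrix(m)) m[1:50, , drop = FALSE] else m[1:50])
  expect_error(propagate_uncertainty(fake3, x, tr, dG = 0.3), "100")
})
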