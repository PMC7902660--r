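test_that("landscape generator produces complete, reproducible site series", {
  cl <- gen_landscape(3, window = c(2000, 2010), seed = 4)
  expect_equal(length(unique(cl$site_id)), 3)
  # one lead year before the window for lagged anomalies
  expect_true(all(table(cl$site_id) == 12))
  expect_identical(cl, gen_landscape(3, window = c(2000, 2010), seed = 4))
  expect_error(gen_landscape(0), "n_sites")
  expect_error(gen_landscape(2, window = c(2010, 2000)), "window")
})

test_that("noiseless landscape recovers the configured trend exactly", {
  tr <- list(tsp = c(0.05, 0.05), tsum = c(0.02, 0.02), d = c(0.4, 0.4))
  cl <- gen_landscape(2, window = c(1990, 2019), trend_ranges = tr,
                      anomaly_sd = c(tsp = 0, tsum = 0, d = 0), seed = 8)
  for (s in unique(cl$site_id)) {
    cs <- cl[cl$site_id == s, ]
    expect_equal(estimate_climate_trend(
      stats::setNames(cs$tsp_min, cs$year), c(1990, 2019)), 0.05,
      tolerance = 1e-12)
    expect_equal(estimate_climate_trend(
      stats::setNames(cs$deficit, cs$year), c(1990, 2019)), 0.4,
      tolerance = 1e-12)
  }
})

test_that("tree population generator respects layout and shade configuration", {
  cl <- gen_landscape(2, seed = 1)
  pop <- gen_tree_population(cl, n_trees_per_plot = 10, seed = 2)
  expect_equal(nrow(pop), 20)
  expect_equal(length(unique(pop$plot_id)), 2)
  pop1 <- gen_tree_population(cl, n_trees_per_plot = 5,
                              shade_probs = c(1, 0, 0, 0, 0), seed = 3)
  expect_true(all(pop1$shade_class == 1))
  expect_identical(gen_tree_population(cl, seed = 7),
                   gen_tree_population(cl, seed = 7))
  expect_error(gen_tree_population(cl[0, ]), "no sites")
  expect_error(gen_tree_population(cl, shade_probs = c(0.5, 0.5, 0.5, 0, 0)),
               "sum to 1")
})

test_that("noiseless growth gives exact increments with censoring at zero", {
  cl <- gen_landscape(1, seed = 1)
  clim <- summarize_climate(cl, c(1990, 2019))
  pop <- gen_tree_population(cl, n_trees_per_plot = 4, seed = 2)
  bg <- stats::setNames(numeric(14), design_terms())
  bg["intercept"] <- 0.4
  g0 <- growth_coefficients(bg, 0)
  tr <- sim_growth(pop, g0, clim, 2005:2010, seed = 3)
  incr <- unlist(tapply(tr$diameter_cm, tr$tree_id, diff))
  expect_true(all(abs(incr - 0.4) < 1e-12))

  bg["intercept"] <- -1
  g1 <- growth_coefficients(bg, 0)
  tr1 <- sim_growth(pop, g1, clim, 2005:2010, seed = 3)
  incr1 <- unlist(tapply(tr1$diameter_cm, tr1$tree_id, diff))
  expect_true(all(incr1 == 0))
})

test_that("maturation is absorbing and fecundity positive only when mature", {
  ds <- small_dataset(seed = 5)
  z <- ds$truth$z
  expect_true(all(apply(z, 1, function(r) all(diff(r) >= 0))))
  expect_true(all(ds$truth$psi[z == 1] > 0))
  expect_true(all(ds$truth$psi[z == 0] == 0))
})

test_that("reproduction limits behave: no maturation, unit fecundity", {
  cl <- gen_landscape(1, seed = 1)
  clim <- summarize_climate(cl, c(1990, 2019))
  pop <- gen_tree_population(cl, n_trees_per_plot = 6, seed = 2)
  bg <- default_truth()$growth
  trees <- sim_growth(pop, bg, clim, 2005:2010, seed = 3)

  never <- fecundity_coefficients(alpha0 = -50, alpha_G = 0,
                                  beta = stats::setNames(numeric(14),
                                                         design_terms()),
                                  sigma2_resid = 0.1, sigma2_re = 0.1)
  t1 <- sim_reproduction(trees, never, clim, seed = 4)
  expect_true(all(t1$z == 0))
  expect_true(all(t1$psi == 0))

  ecos <- unique(cl$ecoregion)
  kap0 <- matrix(0, length(ecos), 6, dimnames = list(ecos, 2005:2010))
  unit <- fecundity_coefficients(alpha0 = 50, alpha_G = 0,
                                 beta = stats::setNames(numeric(14),
                                                        design_terms()),
                                 kappa = kap0,
                                 sigma2_resid = 0, sigma2_re = 0)
  t2 <- sim_reproduction(trees, unit, clim, seed = 4)
  expect_true(all(t2$z == 1))
  expect_true(all(abs(t2$psi - 1) < 1e-12))
  expect_error(sim_reproduction(trees, unlist, clim), "fecundity_coefficients")
})

test_that("empirical maturation frequency matches the probit", {
  # many single-year trees at a fixed diameter
  cl <- gen_landscape(1, seed = 1)
  clim <- summarize_climate(cl, c(1990, 2019))
  n <- 1e4
  trees <- data.frame(tree_id = sprintf("t%05d", 1:n), species = "sp1",
                      genus = "g1", site_id = cl$site_id[1],
                      plot_id = "p1", x = 1, y = 1, shade_class = 2,
                      year = 2010, diameter_cm = 20)
  cf <- default_truth()$fec
  tr <- sim_reproduction(trees, cf, clim, seed = 99)
  p_true <- maturation_prob(cf$alpha0, cf$alpha_G, 20)
  p_emp <- mean(tr$z)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_emp - p_true), 3 * se)
})

test_that("noiseless log fecundity equals the linear predictor exactly", {
  cl <- gen_landscape(2, seed = 6)
  clim <- summarize_climate(cl, c(1990, 2019))
  pop <- gen_tree_population(cl, n_trees_per_plot = 5, seed = 7)
  trees <- sim_growth(pop, default_truth()$growth, clim, 2005:2012, seed = 8)
  beta <- default_truth()$fec$beta
  ecos <- sort(unique(cl$ecoregion))
  kap0 <- matrix(0, length(ecos), 8, dimnames = list(ecos, 2005:2012))
  cf <- fecundity_coefficients(alpha0 = 50, alpha_G = 0, beta = beta,
                               kappa = kap0, sigma2_resid = 0,
                               sigma2_re = 0)
  tr <- sim_reproduction(trees, cf, clim, seed = 9)
  recs <- tree_records(trees)
  for (id in c(names(recs)[1], names(recs)[8])) {
    for (y in c(2006, 2011)) {
      x <- build_design_vector(recs[[id]], clim[[recs[[id]]$site_id]], y)
      expect_equal(tr$log_psi[id, as.character(y)], sum(x * beta),
                   tolerance = 1e-12)
    }
  }
})

test_that("observation layers respect their expectation identities", {
  # crop counts: mean ~ theta * psi over many trees with identical psi
  cl <- gen_landscape(1, seed = 1)
  clim <- summarize_climate(cl, c(1990, 2019))
  n <- 1e4
  trees <- data.frame(tree_id = sprintf("t%05d", 1:n), species = "sp1",
                      genus = "g1", site_id = cl$site_id[1],
                      plot_id = "p1", x = 30, y = 30, shade_class = 2,
                      year = 2010, diameter_cm = 25)
  beta0 <- stats::setNames(numeric(14), design_terms())
  beta0["intercept"] <- log(80)
  kap0 <- matrix(0, 1, 1, dimnames = list(unique(cl$ecoregion), 2010))
  cf <- fecundity_coefficients(alpha0 = 50, alpha_G = 0, beta = beta0,
                               kappa = kap0, sigma2_resid = 0,
                               sigma2_re = 0, kernel_u = 100)
  tr <- sim_reproduction(trees, cf, clim, seed = 2)
  expect_true(all(abs(tr$psi - 80) < 1e-9))
  obs <- sim_observations(tr, trees, traps = NULL,
                          detection = c(0.7, 0.7), seed = 3)
  lam_crop <- 0.7 * 80
  se_crop <- sqrt(lam_crop / n)
  expect_lt(abs(mean(obs$cropcounts$count) - lam_crop), 3 * se_crop)

  # trap counts: many identical traps at a fixed offset from one tree
  tree1 <- trees[1, ]
  tr1 <- sim_reproduction(tree1, cf, clim, seed = 4)
  traps <- data.frame(trap_id = sprintf("k%05d", 1:n), plot_id = "p1",
                      x = 30, y = 40, area_m2 = 2)
  obs1 <- sim_observations(tr1, tree1, traps, detection = c(1, 1), seed = 5)
  lam_trap <- 2 * 80 * dispersal_kernel(10, 100)
  se_trap <- sqrt(lam_trap / n)
  expect_lt(abs(mean(obs1$trapcounts$count) - lam_trap), 3 * se_trap)

  # immature trees contribute nothing
  cf0 <- fecundity_coefficients(alpha0 = -50, alpha_G = 0, beta = beta0,
                                kappa = kap0, sigma2_resid = 0,
                                sigma2_re = 0)
  tr0 <- sim_reproduction(trees[1:50, ], cf0, clim, seed = 6)
  obs0 <- sim_observations(tr0, trees[1:50, ], traps[1:50, ],
                           detection = c(1, 1), seed = 7)
  expect_true(all(obs0$cropcounts$count == 0))
  expect_true(all(obs0$trapcounts$count == 0))
  expect_error(sim_observations(tr0, trees[1:50, ], detection = c(0, 1)),
               "detection")
})

test_that("fixtures round-trip through disk byte-identically under a seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds <- make_fixture(d1, n_sites = 3, n_trees_per_plot = 4,
                     obs_years = c(2010, 2014), seed = 77)
  make_fixture(d2, n_sites = 3, n_trees_per_plot = 4,
               obs_years = c(2010, 2014), seed = 77)
  for (f in c("trees.csv", "climate.csv", "cropcounts.csv", "traps.csv",
              "trapcounts.csv", "truth.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6), label = f)
  }
  back <- read_tables(d1)
  expect_equal(back$trees$diameter_cm, ds$trees$diameter_cm,
               tolerance = 1e-12)
  expect_identical(nrow(back$trees), nrow(ds$trees))
  expect_identical(back$cropcounts$count, ds$cropcounts$count)
  # row counts follow from the configuration arithmetic
  expect_identical(nrow(back$trees), 3L * 4L * 5L)
  expect_identical(nrow(back$trapcounts), 3L * 2L * 5L)
})
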