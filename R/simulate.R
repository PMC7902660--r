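#' @keywords internal
#' Vectorized design rows for one year across trees.
year_design <- function(G, shade, site_ids, clim, year, lag_only = FALSE) {
  si <- match(site_ids, names(clim))
  if (anyNA(si)) stop("unknown site_id: ",
                      paste(unique(site_ids[is.na(si)]), collapse = ", "))
  pick <- function(y) {
    t(vapply(clim, function(s) {
      r <- match(as.character(y), rownames(s$anomalies))
      if (is.na(r)) stop("site ", s$site_id, " has no climate for year ", y)
      s$anomalies[r, ]
    }, numeric(3)))
  }
  norms <- t(vapply(clim, `[[`, numeric(3), "norms"))
  an <- pick(year); an1 <- pick(year - 1)
  if (lag_only) an[, c("tsum", "d")] <- an1[, c("tsum", "d")]
  X <- cbind(intercept = 1, G = G, G2 = G^2, S = shade,
             Tsp_norm = norms[si, "tsp_norm"], Tsp_anom = an[si, "tsp"],
             Tsum_norm = norms[si, "tsum_norm"],
             Tsum_norm2 = norms[si, "tsum_norm"]^2,
             Tsum_anom = an[si, "tsum"], Tsum_anom_lag = an1[si, "tsum"],
             D_norm = norms[si, "d_norm"], D_anom = an[si, "d"],
             D_anom_lag = an1[si, "d"],
             DxG = norms[si, "d_norm"] * G)
  X
}

#' @keywords internal
#' Stacked design matrix for a balanced tree x year panel.  Rows are ordered
#' tree-major with year varying fastest: row (i-1)*T + k is tree i, year k.
panel_design_matrix <- function(G, shade, site_ids, clim, years,
                                lag_only = FALSE) {
  n <- nrow(G); Ty <- length(years)
  X <- matrix(NA_real_, n * Ty, 14, dimnames = list(NULL, design_terms()))
  for (k in seq_len(Ty))
    X[seq.int(k, by = Ty, length.out = n), ] <-
      year_design(G[, k], shade, site_ids, clim, years[k], lag_only)
  X
}

#' Generate a synthetic climate landscape
#'
#' Each site receives climate norms drawn uniformly from configured ranges
#' and a linear trend; yearly values are norm + trend x (year - window
#' midpoint) + iid Gaussian anomalies.  The series starts one year before
#' the window so previous-year anomalies exist for the first window year.
#'
#' @param n_sites Number of sites (>= 1).
#' @param window Integer `c(start, end)` norm/trend window (default
#'   1990--2019).
#' @param norm_ranges,trend_ranges Named lists (`tsp`, `tsum`, `d`) of
#'   2-vectors giving uniform sampling ranges for site norms (degC, degC,
#'   mm month) and trends (units/yr).
#' @param anomaly_sd Named numeric (`tsp`, `tsum`, `d`) anomaly standard
#'   deviations.
#' @param n_ecoregions Sites are assigned round-robin to this many ecoregions.
#' @param ar1 Optional AR(1) coefficient for temporally correlated anomalies
#'   (default 0, iid).
#' @param seed Integer seed.
#' @return Climate data frame (`site_id`, `ecoregion`, `year`, `tsp_min`,
#'   `tsum_mean`, `deficit`) suitable for [summarize_climate()].
#' @export
gen_landscape <- function(n_sites, window = c(1990, 2019),
                          norm_ranges = list(tsp = c(-3, 8), tsum = c(16, 24),
                                             d = c(20, 120)),
                          trend_ranges = list(tsp = c(0.01, 0.04),
                                              tsum = c(0.01, 0.04),
                                              d = c(-0.3, 0.8)),
                          anomaly_sd = c(tsp = 1.2, tsum = 0.8, d = 15),
                          n_ecoregions = 4, ar1 = 0, seed = 1) {
  if (n_sites < 1) stop("n_sites must be >= 1")
  if (window[1] >= window[2]) stop("window start must precede end")
  for (v in c("tsp", "tsum", "d")) {
    if (diff(norm_ranges[[v]]) < 0 || diff(trend_ranges[[v]]) < 0)
      stop("invalid range for ", v)
  }
  set.seed(seed)
  yrs <- seq.int(window[1] - 1L, window[2])
  mid <- mean(seq.int(window[1], window[2]))
  out <- vector("list", n_sites)
  for (s in seq_len(n_sites)) {
    site_id <- sprintf("s%03d", s)
    eco <- sprintf("eco%d", (s - 1L) %% n_ecoregions + 1L)
    vals <- sapply(c("tsp", "tsum", "d"), function(v) {
      norm <- stats::runif(1, norm_ranges[[v]][1], norm_ranges[[v]][2])
      trend <- stats::runif(1, trend_ranges[[v]][1], trend_ranges[[v]][2])
      e <- stats::rnorm(length(yrs), 0, anomaly_sd[[v]])
      if (ar1 != 0) e <- as.numeric(stats::filter(e, ar1, "recursive"))
      norm + trend * (yrs - mid) + e
    })
    out[[s]] <- data.frame(site_id = site_id, ecoregion = eco, year = yrs,
                           tsp_min = vals[, "tsp"], tsum_mean = vals[, "tsum"],
                           deficit = vals[, "d"])
  }
  do.call(rbind, out)
}

#' Generate a tree population across sites
#'
#' One or more square plots per site; trees receive uniform plot-local
#' coordinates, initial diameters, and ordinal shade classes.
#'
#' @param climate Climate table from [gen_landscape()] (defines the sites).
#' @param n_plots_per_site,n_trees_per_plot Layout counts.
#' @param diameter_init_range Uniform range (cm) of initial diameters.
#' @param shade_probs Probabilities of shade classes 1..5 (sum to 1).
#' @param plot_size Side of the square plot, m.
#' @param species,genus Labels applied to all trees.
#' @param seed Integer seed.
#' @return Data frame, one row per tree: `tree_id`, `species`, `genus`,
#'   `site_id`, `plot_id`, `x`, `y`, `shade_class`, `diameter_init`.
#' @export
gen_tree_population <- function(climate, n_plots_per_site = 1,
                                n_trees_per_plot = 25,
                                diameter_init_range = c(5, 40),
                                shade_probs = c(0.15, 0.25, 0.3, 0.2, 0.1),
                                plot_size = 60, species = "sp1", genus = "g1",
                                seed = 1) {
  sites <- unique(climate$site_id)
  if (!length(sites)) stop("no sites in climate table")
  if (abs(sum(shade_probs) - 1) > 1e-8) stop("shade_probs must sum to 1")
  set.seed(seed)
  rows <- list()
  k <- 0L
  for (s in sites) for (p in seq_len(n_plots_per_site)) {
    n <- n_trees_per_plot
    k <- k + 1L
    rows[[k]] <- data.frame(
      tree_id = sprintf("t%05d", (k - 1L) * n + seq_len(n)),
      species = species, genus = genus, site_id = s,
      plot_id = sprintf("%s_p%d", s, p),
      x = stats::runif(n, 0, plot_size), y = stats::runif(n, 0, plot_size),
      shade_class = sample.int(5, n, replace = TRUE, prob = shade_probs),
      diameter_init = stats::runif(n, diameter_init_range[1],
                                   diameter_init_range[2]))
  }
  do.call(rbind, rows)
}

#' Simulate diameter growth trajectories
#'
#' Yearly increments are `max(0, m + N(0, sigma_g^2))` with `m` the growth
#' linear predictor on the shared covariate structure, so negative latent
#' growth is censored at zero and diameters never shrink.
#'
#' @param pop Population from [gen_tree_population()].
#' @param growth [growth_coefficients()].
#' @param clim Site climate list from [summarize_climate()].
#' @param years Integer vector of consecutive observation years (climate must
#'   cover `min(years) - 1`).
#' @param seed Integer seed.
#' @return Long tree table, one row per tree-year, with `diameter_cm`.
#' @export
sim_growth <- function(pop, growth, clim, years, seed = 1) {
  stopifnot(inherits(growth, "growth_coefficients"))
  set.seed(seed)
  n <- nrow(pop); Ty <- length(years)
  G <- matrix(NA_real_, n, Ty, dimnames = list(pop$tree_id, years))
  G[, 1] <- pop$diameter_init
  for (k in seq_len(Ty - 1)) {
    X <- year_design(G[, k], pop$shade_class, pop$site_id, clim, years[k])
    m <- drop(X %*% growth$beta_g)
    incr <- pmax(0, m + stats::rnorm(n, 0, growth$sigma_g))
    G[, k + 1] <- G[, k] + incr
  }
  data.frame(tree_id = rep(pop$tree_id, each = Ty),
             species = rep(pop$species, each = Ty),
             genus = rep(pop$genus, each = Ty),
             site_id = rep(pop$site_id, each = Ty),
             plot_id = rep(pop$plot_id, each = Ty),
             x = rep(pop$x, each = Ty), y = rep(pop$y, each = Ty),
             shade_class = rep(pop$shade_class, each = Ty),
             year = rep(years, n),
             diameter_cm = as.vector(t(G)))
}

#' @keywords internal
#' Reshape a long tree table into a diameter matrix plus per-tree attributes.
tree_panel <- function(trees) {
  trees <- trees[order(trees$tree_id, trees$year), ]
  years <- sort(unique(trees$year))
  ids <- unique(trees$tree_id)
  n <- length(ids); Ty <- length(years)
  if (nrow(trees) != n * Ty)
    stop("tree table is not a balanced tree x year panel")
  G <- matrix(trees$diameter_cm, n, Ty, byrow = TRUE,
              dimnames = list(ids, years))
  first <- trees[!duplicated(trees$tree_id), ]
  fsy <- if ("first_seed_year" %in% names(first)) first$first_seed_year
         else rep(NA_integer_, n)
  list(G = G, years = years, ids = ids,
       shade = first$shade_class, site_id = first$site_id,
       plot_id = first$plot_id, x = first$x, y = first$y,
       species = first$species, genus = first$genus,
       first_seed_year = fsy)
}

#' Simulate maturation and conditional fecundity
#'
#' Each tree draws a single uniform `u_i`; it is mature in year `t` when
#' `Phi(alpha0 + alpha_G G) >= u_i`.  This monotone coupling gives the
#' correct state probability at every size while making maturation an
#' absorbing state.  For mature tree-years, `log psi = x'beta + kappa +
#' b_i + eps` with per-tree random effects `b_i ~ N(0, sigma2_re)` and
#' residuals `eps ~ N(0, sigma2_resid)`; immature tree-years have fecundity
#' zero.  If `fec$kappa` is `NULL`, ecoregion year effects are drawn here
#' (shared yearly mean sd `kappa_sd[1]`, ecoregion deviations sd
#' `kappa_sd[2]`) and centered to zero mean per ecoregion, the model's
#' identifiability convention.
#'
#' @param trees Long tree table with diameter trajectories.
#' @param fec [fecundity_coefficients()].
#' @param clim Site climate list from [summarize_climate()].
#' @param kappa_sd Length-2 numeric: sd of the shared year effect and of
#'   between-ecoregion deviations.
#' @param seed Integer seed.
#' @return Object of class `simulation_truth`: the (completed) coefficients,
#'   matrices `z`, `psi` (gated to 0 when immature), `log_psi` (latent, all
#'   tree-years), per-tree `b`, `u`, `maturation_year`, and `seed`.
#' @export
sim_reproduction <- function(trees, fec, clim, kappa_sd = c(0.4, 0.2),
                             seed = 1) {
  stopifnot(inherits(fec, "fecundity_coefficients"))
  if (fec$alpha_G < 0) stop("alpha_G must be >= 0")
  set.seed(seed)
  tp <- tree_panel(trees)
  n <- length(tp$ids); Ty <- length(tp$years)
  eco_of_site <- vapply(clim, `[[`, "", "ecoregion")
  ecos <- sort(unique(eco_of_site))
  if (is.null(fec$kappa)) {
    shared <- stats::rnorm(Ty, 0, kappa_sd[1])
    kap <- matrix(rep(shared, each = length(ecos)), length(ecos), Ty,
                  dimnames = list(ecos, tp$years)) +
      matrix(stats::rnorm(length(ecos) * Ty, 0, kappa_sd[2]), length(ecos))
    kap <- kap - rowMeans(kap)
    fec$kappa <- kap
  }
  u <- stats::runif(n)
  rho <- maturation_prob(fec$alpha0, fec$alpha_G, tp$G)
  z <- (rho >= u) * 1L
  X <- panel_design_matrix(tp$G, tp$shade, tp$site_id, clim, tp$years)
  b <- stats::rnorm(n, 0, sqrt(fec$sigma2_re))
  eco_idx <- match(eco_of_site[tp$site_id], rownames(fec$kappa))
  kap_panel <- fec$kappa[rep(eco_idx, each = Ty) +
                           (rep(seq_len(Ty), n) - 1L) * nrow(fec$kappa)]
  eta <- drop(X %*% fec$beta) + kap_panel + rep(b, each = Ty) +
    stats::rnorm(n * Ty, 0, sqrt(fec$sigma2_resid))
  log_psi <- matrix(eta, n, Ty, byrow = TRUE, dimnames = dimnames(tp$G))
  psi <- exp(log_psi) * z
  mat_year <- apply(z, 1, function(zz) {
    w <- which(zz == 1)
    if (length(w)) as.integer(tp$years[w[1]]) else NA_integer_
  })
  structure(list(fec = fec, b = stats::setNames(b, tp$ids),
                 u = stats::setNames(u, tp$ids),
                 maturation_year = stats::setNames(mat_year, tp$ids),
                 z = z, psi = psi, log_psi = log_psi, seed = seed),
            class = "simulation_truth")
}

#' Generate seed-trap locations
#'
#' @param pop Population from [gen_tree_population()] (defines plots).
#' @param n_traps_per_plot Traps per plot.
#' @param area_m2 Collecting area per trap, m^2.
#' @param plot_size Plot side, m; traps are placed uniformly inside a margin.
#' @param margin Margin from plot edges, m.
#' @param seed Integer seed.
#' @return Data frame `trap_id`, `plot_id`, `x`, `y`, `area_m2`.
#' @export
gen_traps <- function(pop, n_traps_per_plot = 2, area_m2 = 0.5,
                      plot_size = 60, margin = 10, seed = 1) {
  set.seed(seed)
  plots <- unique(pop$plot_id)
  n <- length(plots) * n_traps_per_plot
  data.frame(trap_id = sprintf("trap%05d", seq_len(n)),
             plot_id = rep(plots, each = n_traps_per_plot),
             x = stats::runif(n, margin, plot_size - margin),
             y = stats::runif(n, margin, plot_size - margin),
             area_m2 = area_m2)
}

#' Simulate crop-count and seed-trap observations
#'
#' Crop counts are Poisson with rate `theta * psi`, where the observed
#' fraction `theta` is drawn uniformly per observation from `detection` and
#' stored with the count.  Trap counts are Poisson with rate
#' `area * sum_i z_i psi_i K(r_i; u)`.  Immature trees contribute nothing to
#' either layer.
#'
#' @param truth [sim_reproduction()] output.
#' @param trees Long tree table used to build `truth`.
#' @param traps Trap layout from [gen_traps()] (or `NULL` for none).
#' @param detection Length-2 range of the observed crop fraction, in (0, 1].
#' @param kernel_u Dispersal-kernel scale; defaults to the truth's value.
#' @param crop_prob Probability a tree-year receives a crop count (default 1).
#' @param seed Integer seed.
#' @return List with `cropcounts` (`tree_id`, `year`, `count`, `fraction`)
#'   and `trapcounts` (`trap_id`, `year`, `count`).
#' @export
sim_observations <- function(truth, trees, traps = NULL,
                             detection = c(0.5, 1),
                             kernel_u = truth$fec$kernel_u,
                             crop_prob = 1, seed = 1) {
  if (any(detection <= 0 | detection > 1))
    stop("detection fractions must be in (0,1]")
  set.seed(seed)
  tp <- tree_panel(trees)
  n <- length(tp$ids); Ty <- length(tp$years)
  keep <- stats::runif(n * Ty) <= crop_prob
  theta <- stats::runif(n * Ty, detection[1], detection[2])
  psi_flat <- as.vector(t(truth$psi))
  counts <- stats::rpois(n * Ty, theta * psi_flat)
  cropcounts <- data.frame(tree_id = rep(tp$ids, each = Ty),
                           year = rep(tp$years, n),
                           count = counts, fraction = theta)[keep, ]
  rownames(cropcounts) <- NULL
  trapcounts <- NULL
  if (!is.null(traps) && nrow(traps)) {
    rows <- vector("list", nrow(traps))
    for (k in seq_len(nrow(traps))) {
      tr <- traps[k, ]
      on_plot <- which(tp$plot_id == tr$plot_id)
      r <- sqrt((tp$x[on_plot] - tr$x)^2 + (tp$y[on_plot] - tr$y)^2)
      kern <- dispersal_kernel(r, kernel_u)
      lam <- tr$area_m2 * as.numeric(kern %*% truth$psi[on_plot, , drop = FALSE])
      rows[[k]] <- data.frame(trap_id = tr$trap_id, year = tp$years,
                              count = stats::rpois(Ty, lam))
    }
    trapcounts <- do.call(rbind, rows)
    rownames(trapcounts) <- NULL
  }
  list(cropcounts = cropcounts, trapcounts = trapcounts)
}

#' Simulate a complete synthetic dataset with ground truth
#'
#' Chains [gen_landscape()], [gen_tree_population()], [sim_growth()],
#' [sim_reproduction()], [gen_traps()], and [sim_observations()] under one
#' master seed, and records each tree's first year with a positive crop
#' count as `first_seed_year` (the known-mature constraint used in
#' fitting).
#'
#' @param n_sites,n_trees_per_plot,n_traps_per_plot Layout counts.
#' @param obs_years Integer `c(start, end)` of observation years.
#' @param window Climate norm/trend window.
#' @param truth Generating parameters, as from [default_truth()].
#' @param detection Crop-fraction range.
#' @param seed Master seed; stage seeds are derived from it.
#' @param ... Further arguments passed to [gen_landscape()].
#' @return List: `trees`, `climate`, `cropcounts`, `traps`, `trapcounts`,
#'   `clim` (summarized climate), `years`, `window`, `truth`.
#' @export
simulate_dataset <- function(n_sites = 40, n_trees_per_plot = 25,
                             n_traps_per_plot = 2,
                             obs_years = c(2005, 2019),
                             window = c(1990, 2019),
                             truth = default_truth(),
                             detection = c(0.5, 1), seed = 1, ...) {
  seeds <- seed + 0:5
  climate <- gen_landscape(n_sites, window = window, seed = seeds[1], ...)
  clim <- summarize_climate(climate, window)
  pop <- gen_tree_population(climate, n_trees_per_plot = n_trees_per_plot,
                             seed = seeds[2])
  years <- seq.int(obs_years[1], obs_years[2])
  trees <- sim_growth(pop, truth$growth, clim, years, seed = seeds[3])
  rep_truth <- sim_reproduction(trees, truth$fec, clim, seed = seeds[4])
  traps <- if (n_traps_per_plot > 0)
    gen_traps(pop, n_traps_per_plot, seed = seeds[5]) else NULL
  obs <- sim_observations(rep_truth, trees, traps, detection = detection,
                          seed = seeds[6])
  cc <- obs$cropcounts
  pos <- cc[cc$count > 0, ]
  fsy <- tapply(pos$year, pos$tree_id, min)
  trees$first_seed_year <- as.integer(fsy[trees$tree_id])
  rep_truth$growth <- truth$growth
  list(trees = trees, climate = climate, cropcounts = obs$cropcounts,
       traps = traps, trapcounts = obs$trapcounts, clim = clim,
       years = years, window = window, truth = rep_truth)
}

#' Write a synthetic fixture to disk
#'
#' Writes `trees.csv`, `climate.csv`, `cropcounts.csv`, `traps.csv`,
#' `trapcounts.csv`, and `truth.json` (generating parameters and latent
#' per-tree summaries) into `out_dir`.  Reading the directory back with
#' [read_tables()] reproduces the tables.
#'
#' @param out_dir Output directory (created if absent).
#' @param ... Arguments passed to [simulate_dataset()].
#' @param seed Master seed.
#' @return Invisibly, the [simulate_dataset()] result.
#' @export
make_fixture <- function(out_dir, ..., seed = 1) {
  ds <- simulate_dataset(..., seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                         row.names = FALSE, quote = FALSE)
  wr(ds$trees, "trees.csv")
  wr(ds$climate, "climate.csv")
  wr(ds$cropcounts, "cropcounts.csv")
  if (!is.null(ds$traps)) wr(ds$traps, "traps.csv")
  if (!is.null(ds$trapcounts)) wr(ds$trapcounts, "trapcounts.csv")
  tr <- ds$truth
  truth_json <- list(
    alpha0 = tr$fec$alpha0, alpha_G = tr$fec$alpha_G,
    beta = as.list(tr$fec$beta),
    kappa = as.data.frame(tr$fec$kappa),
    sigma2_resid = tr$fec$sigma2_resid, sigma2_re = tr$fec$sigma2_re,
    kernel_u = tr$fec$kernel_u,
    beta_g = as.list(tr$growth$beta_g), sigma_g = tr$growth$sigma_g,
    b = as.list(tr$b), maturation_year = as.list(tr$maturation_year),
    seed = seed)
  jsonlite::write_json(truth_json, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(ds)
}
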