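#' Read a dataset directory of schema CSV tables
#'
#' Expects `trees.csv` and `climate.csv`, plus optional `cropcounts.csv`,
#' `traps.csv`, `trapcounts.csv` (UTF-8, header row).  Column presence is
#' checked per file; the assembled dataset is run through
#' [validate_dataset()] and reading fails on any violation of severity
#' "error".
#'
#' @param dir Directory path.
#' @return List: `trees`, `climate`, `cropcounts`, `traps`, `trapcounts`
#'   (missing optional tables are `NULL`).
#' @export
read_tables <- function(dir) {
  schemas <- list(
    trees = c("tree_id", "species", "genus", "site_id", "plot_id", "x", "y",
              "shade_class", "year", "diameter_cm"),
    climate = c("site_id", "ecoregion", "year", "tsp_min", "tsum_mean",
                "deficit"),
    cropcounts = c("tree_id", "year", "count", "fraction"),
    traps = c("trap_id", "plot_id", "x", "y", "area_m2"),
    trapcounts = c("trap_id", "year", "count"))
  rd <- function(name, required) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) {
      if (required) stop("missing required table: ", f)
      return(NULL)
    }
    df <- utils::read.csv(f, stringsAsFactors = FALSE)
    miss <- setdiff(schemas[[name]], names(df))
    if (length(miss))
      stop("file ", f, " is missing column(s): ",
           paste(miss, collapse = ", "))
    df
  }
  ds <- list(trees = rd("trees", TRUE), climate = rd("climate", TRUE),
             cropcounts = rd("cropcounts", FALSE),
             traps = rd("traps", FALSE), trapcounts = rd("trapcounts", FALSE))
  vrep <- validate_dataset(ds$trees, ds$climate,
                           list(cropcounts = ds$cropcounts, traps = ds$traps,
                                trapcounts = ds$trapcounts))
  if (any(vrep$severity == "error"))
    stop("dataset in ", dir, " failed validation:\n",
         paste(utils::capture.output(print(vrep[vrep$severity == "error", ])),
               collapse = "\n"))
  ds
}

#' Write a dataset to a directory of schema CSV tables
#'
#' @param dataset List as returned by [read_tables()] or
#'   [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_tables <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in c("trees", "climate", "cropcounts", "traps", "trapcounts")) {
    if (!is.null(dataset[[name]]))
      utils::write.csv(dataset[[name]], file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read and validate a run configuration
#'
#' YAML file with blocks `window`, `seed`, `out_dir`, and optional
#' `data_dir`, `simulate:`, `fit:`, `growth:`, `attribution:`.  Defaults
#' are filled for any field not given.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(seed = 1, window = c(1990, 2019), out_dir = "artifacts",
                   data_dir = NULL, simulate = NULL,
                   fit = list(n_iter = 4000, n_burn = 2000, thin = 2,
                              bin_cm = 5, kernel_u = 100,
                              estimate_kernel = FALSE),
                   growth = list(), attribution = list(route_growth = TRUE))
  cfg <- utils::modifyList(defaults, cfg)
  w <- cfg$window
  if (length(w) != 2 || !is.numeric(w) || w[1] >= w[2])
    stop("invalid window in config: need [start, end] with start < end")
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    stop("seed must be an integer")
  if (is.null(cfg$data_dir) && is.null(cfg$simulate))
    stop("config needs either data_dir or a simulate block")
  if (!is.null(cfg$data_dir) && !dir.exists(cfg$data_dir))
    stop("data_dir does not exist: ", cfg$data_dir)
  cfg
}

#' Extract Tobit-ready growth increments and designs
#'
#' Yearly increments `G[t+1] - G[t]` (negative raw differences recorded as
#' zero, the Tobit censoring convention) with the canonical design evaluated
#' at year `t`.
#'
#' @param trees Long tree table (balanced panel).
#' @param climate Climate table.
#' @param window Norm window for [summarize_climate()].
#' @return List: `increments` (cm/yr), `designs` (matrix), `tree_id`,
#'   `year`.
#' @export
growth_increments <- function(trees, climate, window) {
  tp <- tree_panel(trees)
  clim <- summarize_climate(climate, window)
  Ty <- length(tp$years)
  if (Ty < 2) stop("need at least two years of diameters")
  X <- panel_design_matrix(tp$G[, -Ty, drop = FALSE], tp$shade, tp$site_id,
                           clim, tp$years[-Ty])
  incr <- t(tp$G[, -1, drop = FALSE] - tp$G[, -Ty, drop = FALSE])
  list(increments = pmax(0, as.vector(incr)), designs = X,
       tree_id = rep(tp$ids, each = Ty - 1),
       year = rep(tp$years[-Ty], length(tp$ids)))
}

#' Trend-attribution table for every tree-year
#'
#' Applies the fitted coefficients to each tree-year: builds the design,
#' computes direct terms against the site's climate trends, takes `dG` from
#' the growth model's expected increment, routes growth to climate when a
#' growth model is supplied, and attaches the site-level residual trend
#' `gamma` and expected fecundity `F`.
#'
#' @param coefficients [fecundity_coefficients()] (e.g. `coef(fit)`).
#' @param growth [growth_coefficients()], [fit_tobit()], or `NULL`.
#' @param trees,climate,window Dataset tables and the norm window.
#' @param years Years to decompose (default: all years with a usable
#'   design, i.e. all but requiring previous-year climate).
#' @return Data frame: `tree_id`, `plot_id`, `species`, `year`, the
#'   [ta_row()] columns, and `F` (expected seeds/yr).
#' @export
attribute_trees <- function(coefficients, growth, trees, climate, window,
                            years = NULL) {
  tp <- tree_panel(trees)
  clim <- summarize_climate(climate, window)
  if (is.null(years)) years <- tp$years
  gam <- estimate_gamma(coefficients, clim,
                        intersect(years, as.integer(colnames(coefficients$kappa))))
  out <- vector("list", length(tp$ids) * length(years))
  k <- 0L
  for (i in seq_along(tp$ids)) {
    site <- clim[[tp$site_id[i]]]
    trends <- c(tsp = unname(site$trends["tsp"]),
                tsum = unname(site$trends["tsum"]),
                d = unname(site$trends["d"]))
    for (y in years) {
      x <- year_design(tp$G[i, as.character(y)], tp$shade[i],
                       tp$site_id[i], clim, y)[1, ]
      dG <- if (is.null(growth)) 0 else predict_increment(growth, x)
      terms <- decompose_tree_year(coefficients, x, trends, dG,
                                   gamma = unname(gam[tp$site_id[i]]),
                                   growth = growth)
      r <- ta_row(terms)
      r <- cbind(data.frame(tree_id = tp$ids[i], plot_id = tp$plot_id[i],
                            species = tp$species[i], year = y), r)
      r$F <- predict_fecundity_point(coefficients, x,
                                     site$ecoregion, y)
      k <- k + 1L
      out[[k]] <- r
    }
  }
  do.call(rbind, out[seq_len(k)])
}

#' Run the full pipeline from a configuration
#'
#' Optionally simulates a dataset, fits the fecundity model and the Tobit
#' growth model, decomposes trends for every tree-year, aggregates to
#' plots, and writes all artifacts (`samples.csv`, `latent_summary.csv`,
#' `diagnostics.json`, `growth_fit.json`, `attribution.csv`,
#' `plot_summary.csv`, `run.log`) into the configured output directory.
#'
#' @param config Path to a YAML config or a config list
#'   (see [read_run_config()]).
#' @return Invisibly, the output directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)
  logline("run_pipeline start; seed=", cfg$seed, "; config_hash=",
          sum(utils::head(utf8ToInt(paste(deparse(cfg), collapse = "")),
                          10000)))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  ds <- stage("data", {
    if (!is.null(cfg$simulate)) {
      args <- cfg$simulate
      args$window <- cfg$window
      args$seed <- cfg$seed
      d <- do.call(simulate_dataset, args)
      write_tables(d, file.path(out, "data"))
      jsonlite::write_json(list(seed = cfg$seed,
                                alpha0 = d$truth$fec$alpha0,
                                alpha_G = d$truth$fec$alpha_G,
                                beta = as.list(d$truth$fec$beta),
                                sigma2_resid = d$truth$fec$sigma2_resid,
                                sigma2_re = d$truth$fec$sigma2_re,
                                beta_g = as.list(d$truth$growth$beta_g),
                                sigma_g = d$truth$growth$sigma_g),
                           file.path(out, "data", "truth.json"),
                           auto_unbox = TRUE, digits = NA)
      logline("simulated dataset: ", length(unique(d$trees$tree_id)),
              " trees")
      d
    } else read_tables(cfg$data_dir)
  })
  fit <- stage("fit_fecundity", {
    f <- do.call(fit_fecundity,
                 c(list(trees = ds$trees, climate = ds$climate,
                        cropcounts = ds$cropcounts, traps = ds$traps,
                        trapcounts = ds$trapcounts, window = cfg$window,
                        seed = cfg$seed),
                   cfg$fit))
    logline("fecundity fit done; acceptance eta=",
            signif(f$acceptance["eta"], 3))
    f
  })
  gfit <- stage("fit_tobit", {
    gd <- growth_increments(ds$trees, ds$climate, cfg$window)
    g <- fit_tobit(gd$increments, gd$designs)
    logline("tobit fit done; sigma_g=", signif(g$sigma, 4))
    g
  })
  att <- stage("attribute", {
    cf <- coef(fit)
    a <- attribute_trees(cf, if (isTRUE(cfg$attribution$route_growth)) gfit
                         else NULL, ds$trees, ds$climate, cfg$window)
    logline("attribution rows: ", nrow(a))
    a
  })
  stage("write", {
    sm <- fit$samples
    long <- do.call(rbind, lapply(c("beta", "alpha", "kappa"), function(nm)
      data.frame(iteration = rep(seq_len(nrow(sm[[nm]])),
                                 times = ncol(sm[[nm]])),
                 parameter = rep(colnames(sm[[nm]]),
                                 each = nrow(sm[[nm]])),
                 value = as.vector(sm[[nm]]))))
    long <- rbind(long,
                  data.frame(iteration = seq_along(sm$sigma2_resid),
                             parameter = "sigma2_resid",
                             value = sm$sigma2_resid),
                  data.frame(iteration = seq_along(sm$sigma2_re),
                             parameter = "sigma2_re", value = sm$sigma2_re))
    utils::write.csv(long, file.path(out, "samples.csv"), row.names = FALSE)
    ls_df <- data.frame(tree_id = rep(rownames(fit$z_mean),
                                      each = ncol(fit$z_mean)),
                        year = rep(colnames(fit$z_mean),
                                   nrow(fit$z_mean)),
                        z_mean = as.vector(t(fit$z_mean)),
                        F_mean = as.vector(t(fit$F_mean)))
    utils::write.csv(ls_df, file.path(out, "latent_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(acceptance = as.list(fit$acceptance),
                              rhat = as.list(fit$rhat),
                              dic = as.numeric(compute_dic(fit)),
                              n_retained = fit$n_retained,
                              seed = cfg$seed),
                         file.path(out, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    jsonlite::write_json(list(coefficients = as.list(gfit$coefficients),
                              se = as.list(gfit$se), sigma_g = gfit$sigma,
                              n = gfit$n, n_censored = gfit$n_censored,
                              convergence = gfit$convergence),
                         file.path(out, "growth_fit.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.csv(att, file.path(out, "attribution.csv"),
                     row.names = FALSE)
    ps <- aggregate_plot(att)
    ps_df <- do.call(rbind, lapply(ps, function(p)
      cbind(data.frame(plot_id = p$plot_id, n_trees = p$n_trees,
                       mean_df = p$mean_df, dF_stand = p$dF_stand),
            as.data.frame(t(p$components)))))
    utils::write.csv(ps_df, file.path(out, "plot_summary.csv"),
                     row.names = FALSE)
    logline("artifacts written to ", out)
  })
  invisible(out)
}

#' Human-readable summary of a pipeline artifact directory
#'
#' Coefficient tables with intervals, plot-level mean proportionate change
#' by component, and a recovery table against `truth.json` when the
#' artifact contains one.
#'
#' @param artifact_dir Directory written by [run_pipeline()].
#' @return Character vector of report lines (also written to `report.md`),
#'   invisibly.
#' @export
report <- function(artifact_dir) {
  need <- file.path(artifact_dir,
                    c("samples.csv", "attribution.csv", "plot_summary.csv"))
  if (!all(file.exists(need)))
    stop("artifact directory is missing: ",
         paste(basename(need)[!file.exists(need)], collapse = ", "))
  sm <- utils::read.csv(file.path(artifact_dir, "samples.csv"))
  att <- utils::read.csv(file.path(artifact_dir, "attribution.csv"))
  ps <- utils::read.csv(file.path(artifact_dir, "plot_summary.csv"))
  lines <- c("# Pipeline report", "", "## Posterior coefficients", "")
  core <- sm[sm$parameter %in% c(design_terms(), "alpha0", "alpha_G",
                                 "sigma2_resid", "sigma2_re"), ]
  for (p in unique(core$parameter)) {
    v <- core$value[core$parameter == p]
    q <- stats::quantile(v, c(0.05, 0.5, 0.95))
    lines <- c(lines, sprintf("- %-14s mean %9.4f  [%.4f, %.4f]",
                              p, mean(v), q[1], q[3]))
  }
  lines <- c(lines, "", "## Plot-level mean proportionate change (1/yr)", "")
  comp_cols <- intersect(c("direct_Tsp", "direct_Tsum", "direct_D",
                           "growth_term", "gamma", "total"), names(ps))
  for (cc in comp_cols)
    lines <- c(lines, sprintf("- %-12s mean over plots %9.5f", cc,
                              mean(ps[[cc]])))
  tj <- file.path(artifact_dir, "data", "truth.json")
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    lines <- c(lines, "", "## Recovery vs generating truth", "")
    est <- function(p) mean(sm$value[sm$parameter == p])
    for (p in names(truth$beta))
      lines <- c(lines, sprintf("- beta[%-13s] truth %9.4f  posterior %9.4f",
                                p, truth$beta[[p]], est(p)))
    lines <- c(lines,
               sprintf("- alpha0          truth %9.4f  posterior %9.4f",
                       truth$alpha0, est("alpha0")),
               sprintf("- alpha_G         truth %9.4f  posterior %9.4f",
                       truth$alpha_G, est("alpha_G")))
  }
  mean_total_att <- mean(att$total)
  lines <- c(lines, "",
             sprintf("Mean df/dt over all tree-years: %.5f /yr",
                     mean_total_att))
  writeLines(lines, file.path(artifact_dir, "report.md"))
  invisible(lines)
}
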