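#' Canonical design-vector term names
#'
#' The fecundity and growth regressions share one fixed design layout:
#' intercept; tree diameter `G` (cm) and its square; ordinal shade class `S`
#' (1--5, exposed to understory); spring minimum temperature norm and
#' current-year anomaly (degC); summer mean temperature norm, its square, and
#' current- and previous-year anomalies (degC); moisture deficit norm and
#' current- and previous-year anomalies (mm month, PET minus precipitation,
#' positive = drier); and the deficit-by-diameter interaction.
#'
#' Coefficient vectors (`beta`) are always aligned to this ordering.
#'
#' @return Character vector of the 14 term names, in canonical order.
#' @export
design_terms <- function() {
  c("intercept", "G", "G2", "S",
    "Tsp_norm", "Tsp_anom",
    "Tsum_norm", "Tsum_norm2", "Tsum_anom", "Tsum_anom_lag",
    "D_norm", "D_anom", "D_anom_lag",
    "DxG")
}

#' Construct a tree record
#'
#' @param tree_id,species,genus,site_id,plot_id Identifiers.
#' @param x,y Plot-local coordinates in metres.
#' @param shade_class Ordinal shade class in 1--5 (1 = fully exposed canopy).
#' @param diameters Named numeric vector of diameters (cm) keyed by calendar
#'   year; years must be consecutive and diameters positive.
#' @param first_seed_year Optional year of earliest observed seed or crop;
#'   must fall within the span of `diameters`.
#' @return A list of class `tree_record`.
#' @export
tree_record <- function(tree_id, species, genus, site_id, plot_id,
                        x = 0, y = 0, shade_class = 1L, diameters,
                        first_seed_year = NULL) {
  yrs <- as.integer(names(diameters))
  if (anyNA(yrs)) stop("diameters must be named by integer years")
  if (length(yrs) > 1 && any(diff(yrs) != 1L))
    stop("diameter series must be on consecutive years for tree ", tree_id)
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("diameters must be positive and finite for tree ", tree_id)
  if (!shade_class %in% 1:5)
    stop("shade_class must be in 1..5 for tree ", tree_id)
  if (!is.null(first_seed_year) && !is.na(first_seed_year)) {
    if (first_seed_year < min(yrs) || first_seed_year > max(yrs))
      stop("first_seed_year outside diameter series for tree ", tree_id)
  } else first_seed_year <- NA_integer_
  structure(list(tree_id = as.character(tree_id), species = species,
                 genus = genus, site_id = as.character(site_id),
                 plot_id = as.character(plot_id), x = x, y = y,
                 shade_class = as.integer(shade_class),
                 diameters = stats::setNames(as.numeric(diameters), yrs),
                 first_seed_year = as.integer(first_seed_year)),
            class = "tree_record")
}

#' Split a yearly series into a window norm and anomalies
#'
#' The norm is the mean over the analysis window; anomalies are deviations
#' from that norm for every year in the series (so anomalies over the window
#' sum to zero by construction).
#'
#' @param series Named numeric vector keyed by year.
#' @param window Integer vector `c(start, end)` of the norm window.
#' @return List with elements `norm` (scalar) and `anomalies` (named numeric,
#'   same years as `series`).
#' @export
split_norm_anomaly <- function(series, window) {
  yrs <- as.integer(names(series))
  w <- seq.int(window[1], window[2])
  if (!all(w %in% yrs))
    stop("series does not cover the window ", window[1], "-", window[2])
  norm <- mean(series[match(w, yrs)])
  list(norm = norm, anomalies = series - norm)
}

#' Least-squares trend of a yearly series
#'
#' Ordinary least-squares slope of value on calendar year over the window,
#' in units of the series per year.
#'
#' @inheritParams split_norm_anomaly
#' @return Scalar slope (units/yr).
#' @export
estimate_climate_trend <- function(series, window) {
  yrs <- as.integer(names(series))
  w <- seq.int(window[1], window[2])
  if (!all(w %in% yrs))
    stop("series does not cover the window ", window[1], "-", window[2])
  if (length(w) < 3) stop("need at least 3 years to estimate a trend")
  y <- series[match(w, yrs)]
  xc <- w - mean(w)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Summarize a site climate table into norms, anomalies, and trends
#'
#' @param climate Data frame with columns `site_id`, `ecoregion`, `year`,
#'   `tsp_min` (spring minimum temperature, degC), `tsum_mean` (summer mean
#'   temperature, degC), `deficit` (moisture deficit, mm month, PET - P).
#' @param window Integer `c(start, end)`; both norms and trends are computed
#'   over this window.
#' @return Named list (by `site_id`) of `site_climate` objects, each a list
#'   with `site_id`, `ecoregion`, `norms`, `anomalies` (year x 3 matrix),
#'   `trends`, and `window`.
#' @export
summarize_climate <- function(climate, window) {
  need <- c("site_id", "ecoregion", "year", "tsp_min", "tsum_mean", "deficit")
  miss <- setdiff(need, names(climate))
  if (length(miss)) stop("climate table missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(climate, climate$site_id), function(cs) {
    cs <- cs[order(cs$year), ]
    yrs <- cs$year
    vars <- c(tsp = "tsp_min", tsum = "tsum_mean", d = "deficit")
    norms <- numeric(3); names(norms) <- c("tsp_norm", "tsum_norm", "d_norm")
    trends <- numeric(3); names(trends) <- c("tsp", "tsum", "d")
    anom <- matrix(NA_real_, length(yrs), 3,
                   dimnames = list(yrs, c("tsp", "tsum", "d")))
    for (k in seq_along(vars)) {
      s <- stats::setNames(cs[[vars[k]]], yrs)
      sp <- split_norm_anomaly(s, window)
      norms[k] <- sp$norm
      anom[, k] <- sp$anomalies
      trends[k] <- estimate_climate_trend(s, window)
    }
    structure(list(site_id = as.character(cs$site_id[1]),
                   ecoregion = as.character(cs$ecoregion[1]),
                   norms = norms, anomalies = anom, trends = trends,
                   window = as.integer(window)),
              class = "site_climate")
  })
  out
}

#' Build the canonical design vector for one tree-year
#'
#' @param tree A [tree_record()].
#' @param site A `site_climate` object (one element of [summarize_climate()]).
#' @param year Calendar year; both `year` and `year - 1` must exist in the
#'   tree's diameter series and the site's anomaly series.
#' @param lag_only Logical; for spring-dispersing species the current-year
#'   summer-temperature and deficit anomalies are replaced by the
#'   previous-year values (seed is provisioned entirely in the prior season).
#' @return Named numeric vector in [design_terms()] order.
#' @export
build_design_vector <- function(tree, site, year, lag_only = FALSE) {
  yrs <- as.integer(names(tree$diameters))
  ayrs <- as.integer(rownames(site$anomalies))
  if (!(year %in% yrs))
    stop("tree ", tree$tree_id, " has no diameter for year ", year)
  if (!all(c(year, year - 1) %in% ayrs))
    stop("site ", site$site_id, " has no climate anomaly for year ",
         year, " (and ", year - 1, ")")
  G <- unname(tree$diameters[as.character(year)])
  a  <- site$anomalies[as.character(year), ]
  a1 <- site$anomalies[as.character(year - 1), ]
  if (lag_only) a[c("tsum", "d")] <- a1[c("tsum", "d")]
  n <- site$norms
  x <- c(1, G, G^2, tree$shade_class,
         n["tsp_norm"], a["tsp"],
         n["tsum_norm"], n["tsum_norm"]^2, a["tsum"], a1["tsum"],
         n["d_norm"], a["d"], a1["d"],
         n["d_norm"] * G)
  names(x) <- design_terms()
  x
}

#' Convert a long tree table to tree records
#'
#' @param trees Data frame with one row per tree-year: `tree_id`, `species`,
#'   `genus`, `site_id`, `plot_id`, `x`, `y`, `shade_class`, `year`,
#'   `diameter_cm`, and optionally `first_seed_year`.
#' @return Named list of [tree_record()] objects keyed by `tree_id`.
#' @export
tree_records <- function(trees) {
  lapply(split(trees, trees$tree_id), function(tt) {
    tt <- tt[order(tt$year), ]
    fsy <- if ("first_seed_year" %in% names(tt)) tt$first_seed_year[1] else NA
    tree_record(tt$tree_id[1], tt$species[1], tt$genus[1], tt$site_id[1],
                tt$plot_id[1], tt$x[1], tt$y[1], tt$shade_class[1],
                stats::setNames(tt$diameter_cm, tt$year),
                if (is.na(fsy)) NULL else fsy)
  })
}

#' Panel design matrix for a set of trees over a common year span
#'
#' Internal workhorse: stacks [build_design_vector()] rows for every tree-year
#' on a balanced panel, returning the matrix plus index columns.
#'
#' @param records List of `tree_record`s (all covering `years`).
#' @param clim List from [summarize_climate()].
#' @param years Integer vector of years to include (each needs year-1 climate).
#' @return List with `X` (n x 14 matrix), `tree_id`, `year`, `site_id`,
#'   `plot_id`, `ecoregion` index vectors (length n, ordered tree-major).
#' @keywords internal
design_panel <- function(records, clim, years) {
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    tr <- records[[i]]
    site <- clim[[tr$site_id]]
    if (is.null(site)) stop("unknown site_id ", tr$site_id,
                            " for tree ", tr$tree_id)
    rows[[i]] <- t(vapply(years, function(y) build_design_vector(tr, site, y),
                          numeric(14)))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- design_terms()
  n_y <- length(years)
  ids <- vapply(records, `[[`, "", "tree_id")
  sids <- vapply(records, `[[`, "", "site_id")
  pids <- vapply(records, `[[`, "", "plot_id")
  ecos <- vapply(sids, function(s) clim[[s]]$ecoregion, "")
  list(X = X,
       tree_id = rep(ids, each = n_y),
       year = rep(years, times = length(records)),
       site_id = rep(sids, each = n_y),
       plot_id = rep(pids, each = n_y),
       ecoregion = rep(unname(ecos), each = n_y))
}

#' Validate a dataset against the table schemas
#'
#' Reports structural violations without stopping: unknown site references,
#' non-positive diameters, shade classes outside 1--5, and (informationally)
#' shrinking diameter series; observation tables referencing unknown tree or
#' trap ids.
#'
#' @param trees Long tree table (see [tree_records()]).
#' @param climate Climate table (see [summarize_climate()]).
#' @param observations Optional list with any of `cropcounts`, `traps`,
#'   `trapcounts` data frames.
#' @return Data frame with columns `severity` ("error" or "info"), `table`,
#'   `id`, `message`; zero rows when the dataset is clean.
#' @export
validate_dataset <- function(trees, climate, observations = NULL) {
  v <- list()
  add <- function(severity, table, id, message)
    v[[length(v) + 1]] <<- data.frame(severity = severity, table = table,
                                      id = as.character(id), message = message)
  bad <- !trees$site_id %in% climate$site_id
  for (id in unique(trees$tree_id[bad]))
    add("error", "trees", id, "references unknown site_id")
  nd <- !is.finite(trees$diameter_cm) | trees$diameter_cm <= 0
  for (id in unique(trees$tree_id[nd]))
    add("error", "trees", id, "non-positive or missing diameter")
  sh <- !trees$shade_class %in% 1:5
  for (id in unique(trees$tree_id[sh]))
    add("error", "trees", id, "shade_class outside 1..5")
  for (tt in split(trees[!nd, ], trees$tree_id[!nd])) {
    tt <- tt[order(tt$year), ]
    if (nrow(tt) > 1 && any(diff(tt$diameter_cm) < 0))
      add("info", "trees", tt$tree_id[1], "diameter series shrinks")
  }
  if (!is.null(observations)) {
    cc <- observations$cropcounts
    if (!is.null(cc)) {
      for (id in unique(cc$tree_id[!cc$tree_id %in% trees$tree_id]))
        add("error", "cropcounts", id, "references unknown tree_id")
      if (any(cc$fraction <= 0 | cc$fraction > 1))
        add("error", "cropcounts", "-", "fraction outside (0,1]")
    }
    tr <- observations$traps
    if (!is.null(tr)) {
      for (id in unique(tr$plot_id[!tr$plot_id %in% trees$plot_id]))
        add("error", "traps", id, "references unknown plot_id")
    }
    tc <- observations$trapcounts
    if (!is.null(tc) && !is.null(tr)) {
      for (id in unique(tc$trap_id[!tc$trap_id %in% tr$trap_id]))
        add("error", "trapcounts", id, "references unknown trap_id")
    }
  }
  if (!length(v))
    return(data.frame(severity = character(), table = character(),
                      id = character(), message = character()))
  do.call(rbind, v)
}
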