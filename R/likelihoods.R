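#' Size-dependent maturation probability
#'
#' Probability that a tree of diameter `G` is reproductively mature,
#' `Phi(alpha0 + alpha_G * G)` with `Phi` the standard normal CDF (a probit).
#' Nondecreasing in `G` whenever `alpha_G >= 0`.
#'
#' @param alpha0 Probit intercept.
#' @param alpha_G Probit slope per cm of diameter (must be >= 0 in the model).
#' @param G Diameter in cm (vectorized).
#' @return Probability in \[0, 1\].
#' @export
maturation_prob <- function(alpha0, alpha_G, G) {
  stats::pnorm(alpha0 + alpha_G * G)
}

#' Inverse Mills ratio of the maturation probit
#'
#' `phi(mu) / Phi(mu)`, the derivative of `log Phi(mu)`; governs the
#' maturation contribution to fecundity trends.  Computed on the log scale
#' so deeply immature trees (very negative `mu`) return large finite values
#' rather than NaN from `0/0` underflow.
#'
#' @param mu Probit linear predictor `alpha0 + alpha_G * G` (vectorized).
#' @return `phi(mu)/Phi(mu)`, finite for all finite `mu`.
#' @export
inverse_mills <- function(mu) {
  exp(stats::dnorm(mu, log = TRUE) - stats::pnorm(mu, log.p = TRUE))
}

#' Isotropic 2D Student-t dispersal kernel
#'
#' Seed deposition density per unit ground area at distance `r` from the
#' source, `K(r; u) = u / (pi * (u + r^2)^2)`.  Integrates to 1 over the
#' plane; `u` (m^2) controls the spread (larger `u`, flatter shadow).
#'
#' @param r Distance from source tree in metres (vectorized).
#' @param u Kernel scale parameter in m^2 (> 0).
#' @return Density in seeds per m^2 per seed produced.
#' @export
dispersal_kernel <- function(r, u) {
  if (any(u <= 0)) stop("kernel parameter u must be > 0")
  u / (pi * (u + r^2)^2)
}

#' Crop-count log-likelihood
#'
#' Poisson log-density of an observed crop count given conditional fecundity
#' `psi` and the recorded fraction of the crop observed: rate
#' `fraction * psi`.  An immature tree (`psi = 0`) has likelihood 1 for a
#' zero count and 0 (returned as `-Inf`) for a positive count.
#'
#' @param count Non-negative integer count (vectorized).
#' @param fraction Fraction of the crop observed, in (0, 1\].
#' @param psi Conditional fecundity, seeds/yr (>= 0).
#' @return Log-likelihood (vectorized).
#' @export
crop_count_loglik <- function(count, fraction, psi) {
  if (any(count < 0)) stop("crop counts must be non-negative")
  if (any(fraction <= 0 | fraction > 1)) stop("fraction must be in (0,1]")
  rate <- fraction * psi
  ll <- stats::dpois(count, rate, log = TRUE)
  ll[rate == 0 & count == 0] <- 0
  ll[rate == 0 & count > 0] <- -Inf
  ll
}

#' Expected seed-trap rate for one trap-year
#'
#' `lambda = area * sum_i z_i * psi_i * K(r_i; u)` over trees on the trap's
#' plot: mature trees contribute their fecundity through the dispersal
#' kernel evaluated at the trap--tree distance.
#'
#' @param area Trap collecting area, m^2.
#' @param dist Distances (m) from the trap to each tree.
#' @param z Maturation indicators (0/1) per tree.
#' @param psi Conditional fecundities (seeds/yr) per tree.
#' @param u Kernel scale, m^2.
#' @return Scalar expected count.
#' @export
trap_rate <- function(area, dist, z, psi, u) {
  area * sum(z * psi * dispersal_kernel(dist, u))
}

#' Seed-trap log-likelihood
#'
#' Poisson log-density of trap counts at the kernel-predicted rates, summed
#' over trap-years.
#'
#' @param trap_counts Data frame with columns `trap_id`, `year`, `count`.
#' @param traps Data frame with `trap_id`, `plot_id`, `x`, `y`, `area_m2`.
#' @param tree_states Data frame with `tree_id`, `plot_id`, `x`, `y`, `year`,
#'   `z`, `psi` (one row per tree-year).
#' @param kernel_u Kernel scale, m^2.
#' @return Scalar total log-likelihood.
#' @export
seed_trap_loglik <- function(trap_counts, traps, tree_states, kernel_u) {
  if (any(!trap_counts$trap_id %in% traps$trap_id))
    stop("trap counts reference unknown trap_id")
  if (any(!traps$plot_id %in% tree_states$plot_id))
    stop("trap references a plot with no trees: ",
         paste(setdiff(traps$plot_id, tree_states$plot_id), collapse = ", "))
  total <- 0
  for (k in seq_len(nrow(trap_counts))) {
    tr <- traps[traps$trap_id == trap_counts$trap_id[k], ]
    st <- tree_states[tree_states$plot_id == tr$plot_id &
                        tree_states$year == trap_counts$year[k], ]
    r <- sqrt((st$x - tr$x)^2 + (st$y - tr$y)^2)
    lam <- trap_rate(tr$area_m2, r, st$z, st$psi, kernel_u)
    total <- total + if (lam == 0) {
      if (trap_counts$count[k] == 0) 0 else -Inf
    } else stats::dpois(trap_counts$count[k], lam, log = TRUE)
  }
  total
}

#' Inverse size-class-abundance observation weights
#'
#' Weighted regression balances the contribution of abundant and rare
#' diameter classes: each observation's weight is inversely proportional to
#' the number of observations in its diameter bin, normalized so weights
#' average 1.
#'
#' @param diameters Diameters (cm), one per observation.
#' @param bin_cm Bin width in cm (default 5).
#' @return Numeric weights, mean exactly 1, aligned with `diameters`.
#' @export
size_class_weights <- function(diameters, bin_cm = 5) {
  if (!length(diameters)) stop("no diameters supplied")
  if (bin_cm <= 0) stop("bin_cm must be > 0")
  bin <- floor(diameters / bin_cm)
  counts <- table(bin)
  w <- 1 / as.numeric(counts[match(as.character(bin), names(counts))])
  w / mean(w)
}
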