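#' @keywords internal
#' Changepoint prior probabilities under the maturation probit.
#' Column m is the probability the tree first appears mature in year m
#' (monotone coupling of states to a single uniform); the last column is
#' the probability it stays immature through the window.  A running max
#' guards against non-monotone diameter records.
cp_prior_mat <- function(alpha0, alpha_G, G) {
  PHI <- stats::pnorm(alpha0 + alpha_G * G)
  Ty <- ncol(G)
  if (Ty > 1)
    for (k in 2:Ty) PHI[, k] <- pmax(PHI[, k], PHI[, k - 1])
  cbind(PHI[, 1],
        if (Ty > 1) PHI[, -1, drop = FALSE] - PHI[, -Ty, drop = FALSE],
        1 - PHI[, Ty])
}

#' @keywords internal
#' Per-plot seed-trap bookkeeping: tree indices, kernel exposure matrix
#' A = area * K(dist), observed count matrix N (NA = trap-year not observed).
build_trapinfo <- function(tp, traps, trapcounts, years, kernel_u) {
  out <- list()
  if (is.null(traps) || !nrow(traps) || is.null(trapcounts)) return(out)
  Ty <- length(years)
  for (p in unique(traps$plot_id)) {
    tt <- traps[traps$plot_id == p, , drop = FALSE]
    I <- which(tp$plot_id == p)
    if (!length(I)) stop("trap references a plot with no trees: ", p)
    D <- sqrt(outer(tt$x, tp$x[I], "-")^2 + outer(tt$y, tp$y[I], "-")^2)
    N <- matrix(NA_real_, nrow(tt), Ty)
    tc <- trapcounts[trapcounts$trap_id %in% tt$trap_id, , drop = FALSE]
    ri <- match(tc$trap_id, tt$trap_id)
    ci <- match(tc$year, years)
    ok <- !is.na(ci)
    N[cbind(ri[ok], ci[ok])] <- tc$count[ok]
    out[[p]] <- list(I = I, D = D, area = tt$area_m2,
                     A = tt$area_m2 * dispersal_kernel(D, kernel_u),
                     N = N, obsT = !is.na(N))
  }
  out
}

#' Fit the hierarchical maturation + fecundity model by MCMC
#'
#' Gibbs/Metropolis sampler for the state-space masting model: latent
#' maturation (absorbing, sampled as a per-tree changepoint year under the
#' size-probit prior), latent log conditional fecundity per tree-year,
#' conjugate updates for the fecundity coefficients (size-class weighted),
#' hierarchical ecoregion year effects (fixed within, shrunk between),
#' per-tree random effects, and Metropolis updates for the maturation
#' probit.  Crop counts enter as Poisson(fraction x psi); seed-trap counts
#' as Poisson(area x sum z psi K), made conditionally independent across
#' trees by multinomial thinning of each trap count.  Trees observed
#' bearing seed (a positive crop count, or `first_seed_year`) are
#' constrained mature from that year on in every iteration.
#'
#' @param trees Long tree table (see [tree_records()]), balanced panel.
#' @param climate Climate table (see [summarize_climate()]).
#' @param cropcounts Data frame `tree_id`, `year`, `count`, `fraction`
#'   (or `NULL`).
#' @param traps,trapcounts Seed-trap layout and counts (or `NULL`).
#' @param window Climate norm/trend window, `c(start, end)`.
#' @param n_iter,n_burn,thin Chain length, burn-in, thinning.
#' @param bin_cm Size-class bin width (cm) for the inverse-abundance
#'   regression weights.
#' @param kernel_u Dispersal-kernel scale (m^2); fixed unless
#'   `estimate_kernel`.
#' @param estimate_kernel Sample `kernel_u` under a log-normal prior.
#' @param priors Optional overrides: `beta_sd`, `alpha0_mean`, `alpha0_sd`,
#'   `alphaG_mean`, `alphaG_sd`, `var_shape`, `var_rate`, `u_sdlog`.
#' @param terms Subset of [design_terms()] to include in the fecundity
#'   regression (default all); useful for DIC comparison of nested
#'   covariate sets.
#' @param seed Integer seed; the chain is fully reproducible from it.
#' @param verbose Print progress.
#' @return Object of class `fecundity_fit` with posterior `samples`
#'   (coefficients, variances, changepoints, deviance), latent posterior
#'   means (`z_mean`, `F_mean`), acceptance rates, and split-chain Rhat
#'   diagnostics.
#' @export
fit_fecundity <- function(trees, climate, cropcounts = NULL, traps = NULL,
                          trapcounts = NULL, window,
                          n_iter = 4000, n_burn = 2000, thin = 2,
                          bin_cm = 5, kernel_u = 100,
                          estimate_kernel = FALSE, priors = list(),
                          terms = design_terms(),
                          seed = 1, verbose = FALSE) {
  stopifnot(n_iter > n_burn, thin >= 1)
  pr <- utils::modifyList(list(beta_sd = 10, alpha0_mean = -3, alpha0_sd = 2,
                               alphaG_mean = 0.05, alphaG_sd = 0.05,
                               var_shape = 2, var_rate = 1, u_sdlog = 1),
                          priors)
  vrep <- validate_dataset(trees, climate,
                           list(cropcounts = cropcounts, traps = traps,
                                trapcounts = trapcounts))
  if (any(vrep$severity == "error"))
    stop("dataset failed validation:\n",
         paste(utils::capture.output(print(vrep[vrep$severity == "error", ])),
               collapse = "\n"))
  set.seed(seed)
  tp <- tree_panel(trees)
  n <- length(tp$ids); years <- tp$years; Ty <- length(years)
  clim <- summarize_climate(climate, window)
  G <- tp$G
  X <- panel_design_matrix(G, tp$shade, tp$site_id, clim, years)
  if (!all(terms %in% design_terms())) stop("unknown design terms")
  X <- X[, terms, drop = FALSE]
  p_beta <- length(terms)
  eco_of_site <- vapply(clim, `[[`, "", "ecoregion")
  ecos <- sort(unique(unname(eco_of_site)))
  E <- length(ecos)
  eco_idx <- match(unname(eco_of_site[tp$site_id]), ecos)
  rows_by_eco <- split(seq_len(n), eco_idx)

  # observation layers aligned to the panel
  C <- TH <- matrix(NA_real_, n, Ty, dimnames = list(tp$ids, years))
  if (!is.null(cropcounts) && nrow(cropcounts)) {
    ri <- match(cropcounts$tree_id, tp$ids)
    ci <- match(cropcounts$year, years)
    ok <- !is.na(ri) & !is.na(ci)
    C[cbind(ri, ci)[ok, , drop = FALSE]] <- cropcounts$count[ok]
    TH[cbind(ri, ci)[ok, , drop = FALSE]] <- cropcounts$fraction[ok]
  }
  has_crop <- !is.na(C)
  trapinfo <- build_trapinfo(tp, traps, trapcounts, years, kernel_u)
  expoM <- matrix(0, n, Ty)
  for (pf in trapinfo)
    expoM[pf$I, ] <- expoM[pf$I, ] + crossprod(pf$A, pf$obsT * 1)
  O <- has_crop | expoM > 0      # cells with any observation influence
  Oflat <- as.vector(t(O))
  n_obs_cells <- sum(O)
  if (n_obs_cells == 0)
    message("no observations supplied: posterior will reproduce the priors")

  # size-class weights on observation-bearing cells
  w_flat <- numeric(n * Ty)
  if (n_obs_cells > 0)
    w_flat[Oflat] <- size_class_weights(as.vector(t(G))[Oflat], bin_cm)
  XtWX <- crossprod(X, X * w_flat)
  wO <- matrix(w_flat, n, Ty, byrow = TRUE)      # 0 off observation cells
  wP <- wO; wP[!O] <- 1                          # latent-prior precisions
  wsum_eY <- do.call(rbind, lapply(rows_by_eco, function(I)
    colSums(wO[I, , drop = FALSE])))
  wsum_tree <- rowSums(wO)

  # known-mature constraint: first_seed_year and first positive crop count
  capidx <- rep(Ty + 1L, n)
  fsy <- tp$first_seed_year
  has_fsy <- !is.na(fsy)
  capidx[has_fsy] <- pmin(capidx[has_fsy],
                          match(fsy[has_fsy], years))
  first_pos <- apply(has_crop & !is.na(C) & C > 0, 1, function(r)
    if (any(r)) which(r)[1] else NA_integer_)
  hp <- !is.na(first_pos)
  capidx[hp] <- pmin(capidx[hp], first_pos[hp])
  allowM <- outer(capidx, seq_len(Ty + 1L), ">=")

  # initial state
  cp <- rep(1L, n)
  Z <- matrix(1, n, Ty)
  H <- matrix(NA_real_, n, Ty)
  H[has_crop] <- log((C[has_crop] + 0.5) / TH[has_crop])
  fill <- if (any(has_crop)) mean(H[has_crop]) else 0
  H[!has_crop] <- fill
  hflat <- as.vector(t(H))
  beta <- drop(solve(crossprod(X) + diag(1e-6, p_beta),
                     crossprod(X, hflat)))
  names(beta) <- terms
  kappa <- matrix(0, E, Ty, dimnames = list(ecos, years))
  kappa_bar <- numeric(Ty)
  tau2 <- 0.04
  b <- numeric(n)
  sig2 <- 0.5; sig2re <- 0.2
  alpha <- c(alpha0 = pr$alpha0_mean + 1, alpha_G = pr$alphaG_mean)
  u_cur <- kernel_u
  s_eta <- 0.5; s_alpha <- 0.05; s_u <- 0.15
  acc_eta <- acc_alpha <- acc_u <- c(0, 0)

  S <- floor((n_iter - n_burn) / thin)
  if (S < 1) stop("no retained iterations: check n_iter/n_burn/thin")
  store <- list(beta = matrix(NA_real_, S, p_beta,
                              dimnames = list(NULL, terms)),
                alpha = matrix(NA_real_, S, 2,
                               dimnames = list(NULL, c("alpha0", "alpha_G"))),
                sigma2_resid = numeric(S), sigma2_re = numeric(S),
                tau2 = numeric(S), kernel_u = numeric(S),
                kappa = matrix(NA_real_, S, E * Ty,
                               dimnames = list(NULL, as.vector(outer(
                                 ecos, years, paste, sep = ":")))),
                cp = matrix(NA_integer_, S, n), deviance = numeric(S))
  Fsum <- Zsum <- matrix(0, n, Ty)

  obs_deviance <- function(Fmat) {
    ll <- 0
    if (any(has_crop)) {
      rate <- TH[has_crop] * Fmat[has_crop]
      ll <- ll + sum(stats::dpois(C[has_crop], rate, log = TRUE))
    }
    for (pf in trapinfo) {
      lam <- pf$A %*% Fmat[pf$I, , drop = FALSE]
      l <- stats::dpois(pf$N, lam, log = TRUE)
      ll <- ll + sum(l[pf$obsT])
    }
    -2 * ll
  }

  tseq <- seq_len(Ty)
  for (it in seq_len(n_iter)) {
    PSI <- exp(H)
    ## -- 1. maturation changepoints (discrete Gibbs, exact trap terms) --
    d <- matrix(0, n, Ty)
    if (any(has_crop)) {
      dcrop <- -TH * PSI
      dcrop[!has_crop] <- 0
      dcrop[has_crop & C > 0] <- Inf
      d <- d + dcrop
    }
    for (pf in trapinfo) {
      Zp <- Z[pf$I, , drop = FALSE]; Pp <- PSI[pf$I, , drop = FALSE]
      lamfull <- pf$A %*% (Zp * Pp)
      Nz <- pf$N; Nz[!pf$obsT] <- 0
      for (j in seq_along(pf$I)) {
        contrib <- outer(pf$A[, j], Pp[j, ])
        lam_mi <- lamfull - outer(pf$A[, j], Zp[j, ] * Pp[j, ])
        lam_mi[lam_mi < 0] <- 0          # guard numeric cancellation
        term <- Nz * log1p(contrib / lam_mi)
        term[Nz == 0] <- 0
        d[pf$I[j], ] <- d[pf$I[j], ] +
          colSums(term) - colSums(contrib * pf$obsT)
      }
    }
    P <- matrix(0, n, Ty + 1L)
    for (k in tseq) P[, k + 1L] <- P[, k] + d[, k]
    logw <- log(pmax(cp_prior_mat(alpha[1], alpha[2], G), 0)) - P
    logw[!allowM] <- -Inf
    gum <- -log(-log(matrix(stats::runif(n * (Ty + 1L)), n)))
    cp <- max.col(logw + gum, ties.method = "first")
    Z <- outer(cp, tseq, "<=") * 1

    ## -- 2. multinomial thinning of trap counts over mature trees --
    NAs <- matrix(0, n, Ty)
    for (pf in trapinfo) {
      ZP <- Z[pf$I, , drop = FALSE] * PSI[pf$I, , drop = FALSE]
      pos <- which(pf$obsT & pf$N > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(pos))) {
        ti <- pos[r, 1]; yi <- pos[r, 2]
        pvec <- pf$A[ti, ] * ZP[, yi]
        draw <- stats::rmultinom(1, pf$N[ti, yi], pvec)
        NAs[pf$I, yi] <- NAs[pf$I, yi] + draw
      }
    }

    ## -- 3. latent log fecundity --
    kapflat <- kappa[cbind(rep(eco_idx, each = Ty), rep(tseq, n))]
    Xb <- drop(X %*% beta)
    M <- matrix(Xb + kapflat, n, Ty, byrow = TRUE) + b
    Ctot <- NAs; Ctot[has_crop] <- Ctot[has_crop] + C[has_crop]
    Eexp <- expoM; Eexp[has_crop] <- Eexp[has_crop] + TH[has_crop]
    mature <- Z == 1
    freecell <- !mature | Eexp == 0
    H[freecell] <- M[freecell] +
      stats::rnorm(sum(freecell), 0, sqrt(sig2 / wP[freecell]))
    mh <- which(mature & Eexp > 0)
    if (length(mh)) {
      h0 <- H[mh]
      h1 <- h0 + s_eta * stats::rnorm(length(mh))
      dl <- wP[mh] * (-(h1 - M[mh])^2 + (h0 - M[mh])^2) / (2 * sig2) +
        Ctot[mh] * (h1 - h0) - Eexp[mh] * (exp(h1) - exp(h0))
      accv <- log(stats::runif(length(mh))) < dl
      H[mh[accv]] <- h1[accv]
      rate <- mean(accv)
      if (it <= n_burn) {
        s_eta <- min(5, max(0.01, s_eta * exp(0.05 * (rate - 0.3))))
      } else acc_eta <- acc_eta + c(rate, 1)
    }

    ## -- 4. regression layer (observation-bearing cells only) --
    if (n_obs_cells > 0) {
      kapM <- matrix(kapflat, n, Ty, byrow = TRUE)
      XbM <- matrix(Xb, n, Ty, byrow = TRUE)
      # beta | . (size-class weighted)
      r2 <- H - kapM - b
      prec <- XtWX / sig2 + diag(1 / pr$beta_sd^2, p_beta)
      ch <- chol(prec)
      mb <- backsolve(ch, forwardsolve(t(ch), crossprod(X, w_flat *
                                                          as.vector(t(r2))) / sig2))
      beta <- drop(mb + backsolve(ch, stats::rnorm(p_beta)))
      names(beta) <- terms
      Xb <- drop(X %*% beta)
      XbM <- matrix(Xb, n, Ty, byrow = TRUE)
      # kappa | .
      r3 <- (H - XbM - b) * wO
      sums_eY <- do.call(rbind, lapply(rows_by_eco, function(I)
        colSums(r3[I, , drop = FALSE])))
      prec_k <- wsum_eY / sig2 + 1 / tau2
      mean_k <- (sums_eY / sig2 +
                   matrix(kappa_bar, E, Ty, byrow = TRUE) / tau2) / prec_k
      kappa <- mean_k + matrix(stats::rnorm(E * Ty), E) / sqrt(prec_k)
      dimnames(kappa) <- list(ecos, years)
      prec_kb <- E / tau2 + 1 / pr$beta_sd^2
      kappa_bar <- colSums(kappa) / tau2 / prec_kb +
        stats::rnorm(Ty) / sqrt(prec_kb)
      tau2 <- 1 / stats::rgamma(1, pr$var_shape + E * Ty / 2,
                                pr$var_rate + 0.5 *
                                  sum((kappa - matrix(kappa_bar, E, Ty,
                                                      byrow = TRUE))^2))
      kapflat <- kappa[cbind(rep(eco_idx, each = Ty), rep(tseq, n))]
      kapM <- matrix(kapflat, n, Ty, byrow = TRUE)
      # b | .
      r4 <- (H - XbM - kapM) * wO
      prec_b <- wsum_tree / sig2 + 1 / sig2re
      b <- rowSums(r4) / sig2 / prec_b + stats::rnorm(n) / sqrt(prec_b)
      # translation moves along likelihood-invariant directions
      prec_c <- (1 + Ty) / pr$beta_sd^2
      cc <- stats::rnorm(1, (-beta[1] + sum(kappa_bar)) / pr$beta_sd^2 /
                           prec_c, 1 / sqrt(prec_c))
      beta[1] <- beta[1] + cc; kappa_bar <- kappa_bar - cc
      kappa <- kappa - cc
      prec_c <- 1 / pr$beta_sd^2 + n / sig2re
      cc <- stats::rnorm(1, (-beta[1] / pr$beta_sd^2 + sum(b) / sig2re) /
                           prec_c, 1 / sqrt(prec_c))
      beta[1] <- beta[1] + cc; b <- b - cc
      kapflat <- kappa[cbind(rep(eco_idx, each = Ty), rep(tseq, n))]
      # variances
      res2 <- (H - matrix(drop(X %*% beta) + kapflat, n, Ty, byrow = TRUE) -
                 b)^2 * wO
      sig2 <- 1 / stats::rgamma(1, pr$var_shape + n_obs_cells / 2,
                                pr$var_rate + 0.5 * sum(res2))
      sig2re <- 1 / stats::rgamma(1, pr$var_shape + n / 2,
                                  pr$var_rate + 0.5 * sum(b^2))
    } else {
      beta <- stats::rnorm(p_beta, 0, pr$beta_sd); names(beta) <- terms
      kappa_bar <- stats::rnorm(Ty, 0, pr$beta_sd)
      tau2 <- 1 / stats::rgamma(1, pr$var_shape, pr$var_rate)
      kappa <- matrix(kappa_bar, E, Ty, byrow = TRUE) +
        matrix(stats::rnorm(E * Ty, 0, sqrt(tau2)), E)
      dimnames(kappa) <- list(ecos, years)
      sig2re <- 1 / stats::rgamma(1, pr$var_shape, pr$var_rate)
      sig2 <- 1 / stats::rgamma(1, pr$var_shape, pr$var_rate)
      b <- stats::rnorm(n, 0, sqrt(sig2re))
    }

    ## -- 5. maturation probit (joint random-walk Metropolis) --
    a_new <- alpha + s_alpha * stats::rnorm(2) * c(1, 0.05)
    if (a_new[2] >= 0) {
      lp <- function(a) {
        pdm <- cp_prior_mat(a[1], a[2], G)
        sum(log(pdm[cbind(seq_len(n), cp)])) +
          stats::dnorm(a[1], pr$alpha0_mean, pr$alpha0_sd, log = TRUE) +
          stats::dnorm(a[2], pr$alphaG_mean, pr$alphaG_sd, log = TRUE)
      }
      dl <- lp(a_new) - lp(alpha)
      accepted <- is.finite(dl) && log(stats::runif(1)) < dl
      if (accepted) alpha <- a_new
      if (it <= n_burn) {
        s_alpha <- min(2, max(1e-4,
                              s_alpha * exp(0.1 * ((accepted * 1) - 0.25))))
      } else acc_alpha <- acc_alpha + c(accepted * 1, 1)
    }

    ## -- 6. optional dispersal-kernel scale --
    if (estimate_kernel && length(trapinfo)) {
      lu_new <- log(u_cur) + s_u * stats::rnorm(1)
      Fnow <- Z * exp(H)
      llu <- function(u) {
        ll <- stats::dnorm(log(u), log(kernel_u), pr$u_sdlog, log = TRUE)
        for (pf in trapinfo) {
          Au <- pf$area * dispersal_kernel(pf$D, u)
          lam <- Au %*% Fnow[pf$I, , drop = FALSE]
          l <- stats::dpois(pf$N, lam, log = TRUE)
          ll <- ll + sum(l[pf$obsT])
        }
        ll
      }
      dl <- llu(exp(lu_new)) - llu(u_cur)
      if (is.finite(dl) && log(stats::runif(1)) < dl) {
        u_cur <- exp(lu_new)
        for (p in names(trapinfo)) {
          trapinfo[[p]]$A <- trapinfo[[p]]$area *
            dispersal_kernel(trapinfo[[p]]$D, u_cur)
        }
        expoM <- matrix(0, n, Ty)
        for (pf in trapinfo)
          expoM[pf$I, ] <- expoM[pf$I, ] + crossprod(pf$A, pf$obsT * 1)
        acc_u <- acc_u + c(1, 0)
      }
      acc_u[2] <- acc_u[2] + 1
    }

    ## -- 7. store --
    if (it > n_burn && (it - n_burn) %% thin == 0) {
      s <- (it - n_burn) %/% thin
      store$beta[s, ] <- beta
      store$alpha[s, ] <- alpha
      store$sigma2_resid[s] <- sig2
      store$sigma2_re[s] <- sig2re
      store$tau2[s] <- tau2
      store$kernel_u[s] <- u_cur
      store$kappa[s, ] <- as.vector(kappa)
      store$cp[s, ] <- cp
      Fnow <- Z * exp(H)
      store$deviance[s] <- obs_deviance(Fnow)
      Fsum <- Fsum + Fnow
      Zsum <- Zsum + Z
    }
    if (verbose && it %% 500 == 0)
      message("iter ", it, "/", n_iter, "  s_eta=", signif(s_eta, 3))
  }

  Fbar <- Fsum / S
  dimnames(Fbar) <- dimnames(G)
  Zbar <- Zsum / S
  dimnames(Zbar) <- dimnames(G)
  diag_tab <- c(apply(store$beta, 2, split_rhat),
                alpha0 = split_rhat(store$alpha[, 1]),
                alpha_G = split_rhat(store$alpha[, 2]),
                sigma2_resid = split_rhat(store$sigma2_resid),
                sigma2_re = split_rhat(store$sigma2_re))
  structure(list(samples = store, n_retained = S,
                 z_mean = Zbar, F_mean = Fbar,
                 deviance_at_mean = obs_deviance(Fbar),
                 acceptance = c(eta = if (acc_eta[2] > 0)
                   acc_eta[1] / acc_eta[2] else NA,
                   alpha = if (acc_alpha[2] > 0)
                     acc_alpha[1] / acc_alpha[2] else NA,
                   kernel_u = if (acc_u[2] > 0) acc_u[1] / acc_u[2] else NA),
                 rhat = diag_tab,
                 ecos = ecos, years = years, window = window,
                 terms = terms,
                 tree_ids = tp$ids, capidx = capidx,
                 eco_of_site = eco_of_site,
                 config = list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                               bin_cm = bin_cm, kernel_u = kernel_u,
                               estimate_kernel = estimate_kernel,
                               priors = pr, seed = seed),
                 call = match.call()),
            class = "fecundity_fit")
}

#' @keywords internal
#' Split-chain potential scale reduction factor from a single chain.
split_rhat <- function(x) {
  S <- length(x)
  if (S < 4) return(NA_real_)
  half <- floor(S / 2)
  ch <- cbind(x[seq_len(half)], x[seq.int(S - half + 1, S)])
  W <- mean(apply(ch, 2, stats::var))
  B <- half * stats::var(colMeans(ch))
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.fecundity_fit <- function(x, ...) {
  cat("Hierarchical maturation + fecundity model (MCMC)\n")
  cat(sprintf("  %d trees x %d years; %d retained draws (of %d, burn-in %d, thin %d)\n",
              length(x$tree_ids), length(x$years), x$n_retained,
              x$config$n_iter, x$config$n_burn, x$config$thin))
  cat(sprintf("  acceptance: latent psi %.2f, maturation probit %.2f\n",
              x$acceptance["eta"], x$acceptance["alpha"]))
  cat("Posterior means:\n")
  cm <- colMeans(x$samples$beta)
  print(round(cm, 4))
  cat(sprintf("  alpha0 = %.3f, alpha_G = %.4f, sigma2 = %.3f, sigma2_re = %.3f\n",
              mean(x$samples$alpha[, 1]), mean(x$samples$alpha[, 2]),
              mean(x$samples$sigma2_resid), mean(x$samples$sigma2_re)))
  invisible(x)
}

#' @export
summary.fecundity_fit <- function(object, probs = c(0.05, 0.5, 0.95), ...) {
  qs <- function(m) t(apply(m, 2, function(v)
    c(mean = mean(v), sd = stats::sd(v), stats::quantile(v, probs))))
  tab <- rbind(qs(object$samples$beta), qs(object$samples$alpha),
               qs(cbind(sigma2_resid = object$samples$sigma2_resid,
                        sigma2_re = object$samples$sigma2_re,
                        tau2 = object$samples$tau2)))
  rh <- object$rhat[match(rownames(tab), names(object$rhat))]
  tab <- cbind(tab, rhat = rh)
  structure(list(coefficients = tab, acceptance = object$acceptance,
                 n_retained = object$n_retained,
                 dic = tryCatch(compute_dic(object), error = function(e) NA)),
            class = "summary.fecundity_fit")
}

#' @export
print.summary.fecundity_fit <- function(x, ...) {
  cat("Posterior summary (", x$n_retained, " retained draws)\n", sep = "")
  print(round(x$coefficients, 4), na.print = "-")
  if (!is.na(x$dic)) cat(sprintf("DIC = %.1f\n", x$dic))
  invisible(x)
}

#' @export
coef.fecundity_fit <- function(object, ...) {
  E <- length(object$ecos); Ty <- length(object$years)
  kap <- matrix(colMeans(object$samples$kappa), E, Ty,
                dimnames = list(object$ecos, object$years))
  beta <- stats::setNames(numeric(14), design_terms())
  beta[object$terms] <- colMeans(object$samples$beta)
  fecundity_coefficients(
    alpha0 = mean(object$samples$alpha[, 1]),
    alpha_G = mean(object$samples$alpha[, 2]),
    beta = beta,
    kappa = kap,
    sigma2_resid = mean(object$samples$sigma2_resid),
    sigma2_re = mean(object$samples$sigma2_re),
    kernel_u = mean(object$samples$kernel_u))
}

#' @export
plot.fecundity_fit <- function(x, pars = c("intercept", "G", "alpha0",
                                           "sigma2_resid"), ...) {
  op <- graphics::par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    v <- if (p %in% colnames(x$samples$beta)) x$samples$beta[, p]
    else if (p %in% colnames(x$samples$alpha)) x$samples$alpha[, p]
    else x$samples[[p]]
    graphics::plot(v, type = "l", ylab = p, xlab = "")
  }
  invisible(x)
}

#' Expected fecundity for a tree-year
#'
#' `E[F] = Phi(mu) * exp(x'beta + kappa + sigma2_pred / 2)` with
#' `sigma2_pred = sigma2_resid + sigma2_re`: random individual effects are
#' marginalized for prediction, so the lognormal mean correction uses the
#' sum of residual and random-effect variance.  Given a fitted model the
#' value is computed per posterior draw.
#'
#' @param object [fecundity_coefficients()] or a `fecundity_fit`.
#' @param tree A [tree_record()].
#' @param site A `site_climate` object.
#' @param year Calendar year (needs a year effect; otherwise the ecoregion
#'   mean is used with a warning).
#' @return For coefficients, a scalar expected seed count; for a fit, a
#'   list with `mean`, `sd`, and per-draw `draws`.
#' @export
predict_fecundity <- function(object, tree, site, year) {
  x <- build_design_vector(tree, site, year)
  if (inherits(object, "fecundity_coefficients"))
    return(predict_fecundity_point(object, x, site$ecoregion, year))
  stopifnot(inherits(object, "fecundity_fit"))
  S <- nrow(object$samples$beta)
  E <- length(object$ecos); Ty <- length(object$years)
  kcol <- match(as.character(year), as.character(object$years))
  krow <- match(site$ecoregion, object$ecos)
  draws <- numeric(S)
  for (s in seq_len(S)) {
    kap <- if (is.na(krow)) 0 else {
      km <- matrix(object$samples$kappa[s, ], E, Ty)
      if (is.na(kcol)) mean(km[krow, ]) else km[krow, kcol]
    }
    mu <- object$samples$alpha[s, 1] + object$samples$alpha[s, 2] * x["G"]
    s2p <- object$samples$sigma2_resid[s] + object$samples$sigma2_re[s]
    draws[s] <- stats::pnorm(mu) *
      exp(sum(x[object$terms] * object$samples$beta[s, ]) + kap + s2p / 2)
  }
  if (is.na(kcol))
    warning("no year effect for ", year, "; using ecoregion mean")
  list(mean = mean(draws), sd = stats::sd(draws), draws = draws)
}

#' @keywords internal
predict_fecundity_point <- function(cf, x, eco, year) {
  kap <- 0
  if (!is.null(cf$kappa)) {
    krow <- match(eco, rownames(cf$kappa))
    kcol <- match(as.character(year), colnames(cf$kappa))
    if (!is.na(krow)) {
      if (is.na(kcol)) {
        warning("no year effect for ", year, "; using ecoregion mean")
        kap <- mean(cf$kappa[krow, ])
      } else kap <- cf$kappa[krow, kcol]
    }
  }
  mu <- cf$alpha0 + cf$alpha_G * unname(x["G"])
  s2p <- cf$sigma2_resid + cf$sigma2_re
  unname(stats::pnorm(mu) * exp(sum(x * cf$beta) + kap + s2p / 2))
}

#' @export
predict.fecundity_fit <- function(object, trees, climate, ...) {
  cf <- coef(object)
  clim <- summarize_climate(climate, object$window)
  recs <- tree_records(trees)
  rows <- list()
  k <- 0L
  for (tr in recs) {
    site <- clim[[tr$site_id]]
    yrs <- as.integer(names(tr$diameters))
    yrs <- yrs[yrs - 1 >= min(as.integer(rownames(site$anomalies)))]
    for (y in yrs) {
      k <- k + 1L
      rows[[k]] <- data.frame(tree_id = tr$tree_id, year = y,
                              F = predict_fecundity_point(
                                cf, build_design_vector(tr, site, y),
                                site$ecoregion, y))
    }
  }
  do.call(rbind, rows)
}

#' Deviance information criterion of a fitted model
#'
#' `DIC = mean deviance + p_D`, with effective parameter count
#' `p_D = mean deviance - deviance at the posterior mean` (here the
#' posterior-mean tree-year fecundity surface).
#'
#' @param x A `fecundity_fit`, or a numeric vector of per-iteration
#'   deviances (then `deviance_at_mean` is required).
#' @param deviance_at_mean Deviance evaluated at the posterior mean.
#' @return Scalar DIC, with attributes `p_D` and `mean_deviance`.
#' @export
compute_dic <- function(x, deviance_at_mean = NULL) {
  if (inherits(x, "fecundity_fit")) {
    dev <- x$samples$deviance
    deviance_at_mean <- x$deviance_at_mean
  } else {
    dev <- as.numeric(x)
    if (is.null(deviance_at_mean))
      stop("deviance_at_mean required for raw deviance draws")
  }
  if (length(dev) < 10) stop("need at least 10 retained iterations")
  pd <- mean(dev) - deviance_at_mean
  structure(mean(dev) + pd, p_D = pd, mean_deviance = mean(dev))
}
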