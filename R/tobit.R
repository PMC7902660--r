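#' Fit a Tobit model of annual diameter increment
#'
#' Maximum-likelihood fit of a normal linear model for yearly diameter
#' increments left-censored at zero: observed increments are
#' `max(0, x'beta_g + e)`, `e ~ N(0, sigma_g^2)`, so apparent zero (or
#' negative, recorded as zero) growth is treated as censoring rather than
#' truth.  Standard errors come from the observed information at the
#' optimum.
#'
#' @param increments Numeric vector of yearly increments (cm/yr), zeros
#'   marking censored observations; negative raw differences should be
#'   recorded as 0 before fitting.
#' @param designs Design matrix with columns [design_terms()] (or any
#'   full-rank design).
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return Object of class `tobit_fit`: `coefficients` (beta_g), `sigma`
#'   (sigma_g), `vcov` (beta and log sigma), `se`, `loglik`, `gradient`
#'   (at optimum), `n`, `n_censored`, `convergence`.
#' @export
fit_tobit <- function(increments, designs, control = list()) {
  y <- as.numeric(increments)
  X <- as.matrix(designs)
  p <- ncol(X)
  if (length(y) != nrow(X)) stop("increments and designs length mismatch")
  if (any(y < 0)) stop("increments must be recorded as >= 0 (censored at 0)")
  if (length(y) < 2 * (p + 1))
    stop("need at least twice as many observations as parameters")
  cen <- y == 0
  if (all(cen))
    stop("all observations censored at zero: beta_g is not identifiable")
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(p))
  # constant columns (single-site norms, fixed shade) duplicate the
  # intercept; drop them from estimation, report their coefficients as 0
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  keep[1] <- TRUE
  # and drop linearly dependent columns (few-site designs leave the
  # site-level norms collinear with the intercept and each other)
  qd <- qr(X[, keep, drop = FALSE])
  if (qd$rank < sum(keep))
    keep[which(keep)[-qd$pivot[seq_len(qd$rank)]]] <- FALSE
  Xk <- X[, keep, drop = FALSE]
  pk <- ncol(Xk)
  nll <- function(par) {
    b <- par[1:pk]; s <- exp(par[pk + 1])
    m <- drop(Xk %*% b)
    u <- (y - m) / s
    ll <- sum(stats::dnorm(u[!cen], log = TRUE)) - sum(!cen) * log(s) +
      sum(stats::pnorm(-m[cen] / s, log.p = TRUE))
    -ll
  }
  ngr <- function(par) {
    b <- par[1:pk]; s <- exp(par[pk + 1])
    m <- drop(Xk %*% b)
    u <- (y - m) / s
    gb <- numeric(pk); gs <- 0
    if (any(!cen)) {
      gb <- gb + drop(crossprod(Xk[!cen, , drop = FALSE], u[!cen] / s))
      gs <- gs + sum(u[!cen]^2 - 1)
    }
    if (any(cen)) {
      v <- -m[cen] / s
      lam <- inverse_mills(v)
      gb <- gb - drop(crossprod(Xk[cen, , drop = FALSE], lam / s))
      gs <- gs - sum(lam * v)
    }
    -c(gb, gs)
  }
  ols <- stats::lm.fit(Xk, y)
  s0 <- max(stats::sd(ols$residuals), 1e-3)
  par0 <- c(ols$coefficients, log(s0))
  par0[is.na(par0)] <- 0
  opt <- stats::optim(par0, nll, ngr, method = "BFGS",
                      control = utils::modifyList(list(maxit = 500,
                                                       reltol = 1e-14),
                                                  control))
  # polish to a tight stationary point (BFGS alone can stop early)
  pol <- stats::nlminb(opt$par, nll, ngr,
                       control = list(rel.tol = 1e-15, iter.max = 500))
  if (pol$objective <= opt$value) {
    opt$par <- pol$par
    opt$value <- pol$objective
    opt$convergence <- pol$convergence
  }
  for (i in 1:20) {   # Newton steps until the gradient is numerically zero
    g <- ngr(opt$par)
    if (sqrt(sum(g^2)) < 1e-9) break
    Hm <- stats::optimHess(opt$par, nll, ngr)
    step <- tryCatch(solve(Hm, g), error = function(e) NULL)
    if (is.null(step)) break
    cand <- opt$par - step
    if (!is.finite(nll(cand)) || nll(cand) > opt$value + 1e-9) break
    opt$par <- cand
    opt$value <- nll(cand)
  }
  opt$hessian <- stats::optimHess(opt$par, nll, ngr)
  beta <- stats::setNames(rep(0, p), colnames(X))
  beta[keep] <- opt$par[1:pk]
  sigma <- unname(exp(opt$par[pk + 1]))
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    warning("observed information is singular; SEs unavailable")
    matrix(NA_real_, pk + 1, pk + 1)
  })
  se <- stats::setNames(rep(NA_real_, p), colnames(X))
  se[keep] <- sqrt(pmax(diag(V)[1:pk], 0))
  structure(list(coefficients = beta, sigma = sigma,
                 sigma_se = sigma * sqrt(pmax(diag(V)[pk + 1], 0)),
                 vcov = V, se = se, loglik = -opt$value,
                 gradient = -ngr(opt$par), kept = keep,
                 n = length(y), n_censored = sum(cen),
                 convergence = opt$convergence),
            class = "tobit_fit")
}

#' @export
print.tobit_fit <- function(x, ...) {
  cat("Tobit growth model (left-censored at 0)\n")
  cat(sprintf("  n = %d tree-years (%d censored, %.1f%%)\n", x$n,
              x$n_censored, 100 * x$n_censored / x$n))
  cat(sprintf("  sigma_g = %.4f cm/yr, log-likelihood = %.2f\n",
              x$sigma, x$loglik))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' @export
summary.tobit_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$coefficients / object$se)
  structure(list(coefficients = tab, sigma = object$sigma,
                 sigma_se = object$sigma_se, n = object$n,
                 n_censored = object$n_censored, loglik = object$loglik),
            class = "summary.tobit_fit")
}

#' @export
print.summary.tobit_fit <- function(x, ...) {
  cat("Tobit growth model: coefficient table\n")
  stats::printCoefmat(x$coefficients, na.print = "-")
  cat(sprintf("sigma_g = %.4f (se %.4f); n = %d, censored = %d\n",
              x$sigma, x$sigma_se, x$n, x$n_censored))
  invisible(x)
}

#' @export
coef.tobit_fit <- function(object, ...) object$coefficients

#' @export
vcov.tobit_fit <- function(object, ...) object$vcov

#' @export
logLik.tobit_fit <- function(object, ...) {
  structure(object$loglik, df = sum(object$kept) + 1, class = "logLik")
}

#' @export
residuals.tobit_fit <- function(object, y = NULL, X = NULL, ...) {
  if (is.null(y) || is.null(X))
    stop("supply the original increments (y) and designs (X)")
  y - predict_increment(object, X)
}

#' Expected censored growth increment
#'
#' Mean of `max(0, N(m, sigma_g^2))` with `m = x'beta_g`:
#' `m * Phi(m/sigma) + sigma * phi(m/sigma)`.  Nonnegative, and approaches
#' `m` as `m/sigma` grows.
#'
#' @param coefficients A [growth_coefficients()] or [fit_tobit()] object.
#' @param design Design vector or matrix aligned to the coefficients.
#' @return Expected increment(s), cm/yr.
#' @export
predict_increment <- function(coefficients, design) {
  if (inherits(coefficients, "tobit_fit")) {
    b <- coefficients$coefficients; s <- coefficients$sigma
  } else {
    b <- coefficients$beta_g; s <- coefficients$sigma_g
  }
  X <- if (is.matrix(design)) design else matrix(design, nrow = 1,
                                                 dimnames = list(NULL,
                                                                 names(design)))
  m <- drop(X %*% b[colnames(X)])
  r <- m / s
  m * stats::pnorm(r) + s * stats::dnorm(r)
}

#' @export
predict.tobit_fit <- function(object, newdata, ...) {
  predict_increment(object, newdata)
}

#' @keywords internal
#' Partial derivatives of a canonical-design linear predictor with respect
#' to the climate variables, diameter, and shade.  Quadratic and
#' interaction terms contribute via their current design values.
linpred_partials <- function(beta, design) {
  beta <- beta[design_terms()]
  G <- unname(design["G"])
  Tn <- unname(design["Tsum_norm"])
  Dn <- unname(design["D_norm"])
  c(Tsp = unname(beta["Tsp_norm"]),
    Tsum = unname(beta["Tsum_norm"] + 2 * beta["Tsum_norm2"] * Tn),
    D = unname(beta["D_norm"] + beta["DxG"] * G),
    G = unname(beta["G"] + 2 * beta["G2"] * G + beta["DxG"] * Dn),
    S = unname(beta["S"]))
}

#' Partial derivatives of the latent growth predictor
#'
#' Analytic partials of the (uncensored) growth linear predictor with
#' respect to each trend-bearing variable, combining main, quadratic, and
#' interaction terms.  Used to route climate trends through growth.
#'
#' @param coefficients [growth_coefficients()] or [fit_tobit()].
#' @param design Named design vector from [build_design_vector()].
#' @return Named vector: `Tsp`, `Tsum`, `D`, `G`, `S` (cm/yr per unit).
#' @export
growth_partials <- function(coefficients, design) {
  b <- if (inherits(coefficients, "tobit_fit")) coefficients$coefficients
       else coefficients$beta_g
  linpred_partials(b, design)
}
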