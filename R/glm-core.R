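#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 loglik + 2k + 2k(k+1)/(n - k - 1)`.  Throughout the package
#' `k` counts every estimated parameter, including the Gaussian variance or
#' the generalized-Poisson dispersion, applied consistently so that AICc
#' differences between same-family models are unaffected by the convention.
#'
#' @param loglik maximised log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations; must exceed `k + 1`.
#' @return The AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1 (n = ", n, ", k = ", k, ")")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

new_fit_result <- function(family, coefficients, loglik, n, k,
                           converged = TRUE, ...) {
  structure(
    list(family = family, coefficients = coefficients, loglik = loglik,
         n = n, k = k,
         aicc = if (n > k + 1) aicc(loglik, k, n) else Inf,
         converged = converged, ...),
    class = "nestwin_fit")
}

#' @export
print.nestwin_fit <- function(x, ...) {
  cat("<nestwin_fit> family =", x$family,
      sprintf("| n = %d, k = %d, logLik = %.3f, AICc = %.3f%s\n",
              x$n, x$k, x$loglik, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

check_design <- function(X, n) {
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)) - 1L)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  if (n < ncol(X) + 1) stop("too few rows: need n > ncol(X)")
  X
}

#' Gaussian linear model by maximum likelihood
#'
#' Ordinary least squares with the log-likelihood evaluated at the
#' maximum-likelihood variance (`RSS/n`).  The parameter count `k` includes
#' the variance, so `k = ncol(X) + 1`.  Wald t statistics use the usual
#' unbiased residual variance with `n - ncol(X)` degrees of freedom.
#'
#' @param y numeric response vector (no missing values).
#' @param X design matrix, including any intercept column.
#' @return A `nestwin_fit` with `family = "gaussian"`; the ML residual
#'   standard deviation is stored as `sigma`.
#' @export
fit_gaussian_lm <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y), !anyNA(X))
  X <- check_design(X, n)
  p <- ncol(X)

  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  loglik <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)

  sigma2_hat <- rss / (n - p)
  XtX_inv <- chol2inv(qr.R(qr(X)))
  se <- sqrt(diag(XtX_inv) * sigma2_hat)
  est <- fit$coefficients
  tval <- est / se
  coefs <- data.frame(
    term = colnames(X), estimate = unname(est), se = se,
    statistic = tval,
    p_value = 2 * pt(abs(tval), df = n - p, lower.tail = FALSE),
    row.names = NULL)

  new_fit_result("gaussian", coefs, loglik, n, k = p + 1L,
                 sigma = sqrt(sigma2_ml), df_residual = n - p)
}

# Admissibility: variance = phi * mu with phi = 1/(1-lambda)^2 requires
# lambda > -1, i.e. phi > 1/4.
check_phi <- function(phi) {
  if (!is.numeric(phi) || length(phi) != 1 || is.na(phi) || phi <= 0.25) {
    stop("inadmissible generalized-Poisson dispersion phi (need phi > 0.25): ", phi)
  }
  phi
}

genpois_logpmf_raw <- function(y, mu, phi) {
  s <- sqrt(phi)
  lam <- 1 - 1 / s
  theta <- mu / s
  arg <- theta + lam * y
  out <- ifelse(arg > 0 & theta > 0,
                log(theta) + (y - 1) * log(pmax(arg, .Machine$double.xmin)) -
                  theta - lam * y - lgamma(y + 1),
                -Inf)
  out
}

#' Generalized Poisson log probability mass
#'
#' Mean-parameterized generalized Poisson (Consul form) with mean `mu` and
#' variance `phi * mu`: with `lambda = 1 - 1/sqrt(phi)` and
#' `theta = mu/sqrt(phi)`,
#' `P(Y = y) = theta (theta + lambda y)^(y-1) exp(-theta - lambda y) / y!`.
#' At `phi = 1` this is exactly the Poisson pmf; `phi < 1` gives
#' underdispersion (admissible down to `phi > 1/4`, i.e. `lambda > -1`),
#' `phi > 1` overdispersion.  For underdispersed parameters the mass is
#' zero (log pmf `-Inf`) beyond the support bound `theta + lambda y <= 0`.
#'
#' @param y vector of non-negative integer counts.
#' @param mu positive mean.
#' @param phi dispersion (`> 0.25`); variance is `phi * mu`.
#' @return Vector of log probabilities.
#' @export
genpois_logpmf <- function(y, mu, phi) {
  check_phi(phi)
  stopifnot(all(mu > 0), all(y >= 0), all(y == floor(y)))
  genpois_logpmf_raw(y, mu, phi)
}

#' Generalized Poisson random deviates
#'
#' Sampling by inversion of the cumulative mass (adequate for the
#' moderate means of clutch/brood-type counts).
#'
#' @inheritParams genpois_logpmf
#' @param n number of draws; `mu` is recycled to length `n`.
#' @return Integer vector of counts.
#' @export
rgenpois <- function(n, mu, phi) {
  check_phi(phi)
  mu <- rep_len(mu, n)
  u <- runif(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    ymax <- max(20, ceiling(mu[i] + 12 * sqrt(phi * mu[i])))
    cdf <- cumsum(exp(genpois_logpmf_raw(0:ymax, mu[i], phi)))
    out[i] <- findInterval(u[i], cdf)  # smallest y with cdf >= u
  }
  out
}

#' Generalized Poisson GLM with log link
#'
#' Joint maximum-likelihood fit of regression coefficients (log link for
#' the mean) and the dispersion `phi` (variance `= phi * mu`), optimised by
#' [stats::nlminb()] from a Poisson starting fit.  `k` counts `phi`.  Wald
#' z statistics are reported for the mean coefficients.  Non-convergence
#' (including a dispersion estimate pinned at the admissibility boundary
#' `phi = 0.25`) is reported through `converged = FALSE`, never silently
#' dropped.
#'
#' @param y non-negative integer response vector.
#' @param X design matrix, including any intercept column.
#' @return A `nestwin_fit` with `family = "genpois"` and the dispersion
#'   estimate stored as `phi`.
#' @export
fit_genpois_glm <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n, !anyNA(y), !anyNA(X), all(y >= 0), all(y == floor(y)))
  X <- check_design(X, n)
  p <- ncol(X)

  pois <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta0 <- pois$coefficients
  mu0 <- pmax(exp(drop(X %*% beta0)), 1e-8)
  phi0 <- max(0.3, sum((y - mu0)^2 / mu0) / max(n - p, 1))
  # phi = 0.25 + exp(eta) keeps the dispersion inside the admissible region
  par0 <- c(beta0, log(max(phi0 - 0.25, 0.05)))

  negll <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    if (any(eta > 50)) return(1e10)
    mu <- exp(eta)
    phi <- 0.25 + exp(par[p + 1L])
    ll <- genpois_logpmf_raw(y, mu, phi)
    if (any(!is.finite(ll))) return(1e10)
    -sum(ll)
  }

  negll_grad <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    if (any(eta > 50)) return(rep(0, p + 1L))
    mu <- exp(eta)
    ephi <- exp(par[p + 1L])
    phi <- 0.25 + ephi
    s <- sqrt(phi); lam <- 1 - 1 / s
    theta <- mu / s
    arg <- theta + lam * y
    if (any(arg <= 0) || any(theta <= 0)) return(rep(0, p + 1L))
    dll_dtheta <- 1 / theta + (y - 1) / arg - 1
    g_beta <- drop(crossprod(X, dll_dtheta * mu / s))
    dll_ds <- sum(dll_dtheta * (-mu / s^2) + ((y - 1) * y / arg - y) / s^2)
    g_eta <- dll_ds / (2 * s) * ephi
    -c(g_beta, g_eta)
  }

  opt <- nlminb(par0, negll, gradient = negll_grad,
                control = list(iter.max = 500, eval.max = 1000,
                               rel.tol = 1e-12, x.tol = 1e-10))
  phi <- 0.25 + exp(opt$par[p + 1L])
  boundary <- exp(opt$par[p + 1L]) < 1e-6
  # nlminb's code alone is too strict at tight tolerances ("singular
  # convergence" at a genuine optimum); accept a stationary point
  grad_ok <- max(abs(negll_grad(opt$par))) < 1e-3 * (1 + abs(opt$objective))
  converged <- (opt$convergence == 0 || grad_ok) && !boundary &&
    opt$objective < 1e9

  se <- rep(NA_real_, p)
  H <- try(optimHess(opt$par, negll), silent = TRUE)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V)[seq_len(p)] > 0)) {
      se <- sqrt(diag(V)[seq_len(p)])
    }
  }
  est <- opt$par[seq_len(p)]
  zval <- est / se
  coefs <- data.frame(
    term = colnames(X), estimate = est, se = se, statistic = zval,
    p_value = 2 * pnorm(abs(zval), lower.tail = FALSE), row.names = NULL)

  new_fit_result("genpois", coefs, loglik = -opt$objective, n = n,
                 k = p + 1L, converged = converged, phi = phi)
}

#' Likelihood-ratio test between nested fits
#'
#' @param full,reduced `nestwin_fit` objects for nested models on the same
#'   rows and family; `reduced` must have fewer parameters.
#' @return List with `chisq` (`2 * (loglik_full - loglik_reduced)`), `df`
#'   (`k_full - k_reduced`) and the chi-square upper-tail `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "nestwin_fit"), inherits(reduced, "nestwin_fit"))
  if (full$family != reduced$family) stop("LRT requires a common family")
  if (full$n != reduced$n) stop("LRT requires identical rows (n differs)")
  df <- full$k - reduced$k
  if (df <= 0) stop("LRT requires reduced nested in full (df must be > 0)")
  chisq <- 2 * (full$loglik - reduced$loglik)
  list(chisq = chisq, df = df,
       p = pchisq(max(chisq, 0), df = df, lower.tail = FALSE))
}

#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (at least 3) with nonzero
#'   variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) stop("pearson_r undefined for zero-variance input")
  cor(x, y)
}
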