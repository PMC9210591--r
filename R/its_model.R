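# Segmented linear regression with AR(1) errors for interrupted time
# series, fit by restricted maximum likelihood with the AR(1) coefficient
# profiled out by bounded one-dimensional optimization.
#
# Model: y_t = b0 + b1 t + b2 I(t > t0) + b3 (t - t0) I(t > t0) + e_t,
#        e_t = rho e_{t-1} + u_t,  u_t iid N(0, sigma2).
# Cov(y_ti, y_tj) = sigma2 rho^|ti - tj| / (1 - rho^2), which is exact at
# arbitrary integer lags, so months missing from the series are handled by
# the covariance at true calendar spacing rather than by re-indexing.

#' Build the segmented-regression design
#'
#' Columns: intercept, time `t` (months, continuous), post-intervention
#' indicator `I(t > t0)`, and time after intervention `(t - t0) I(t > t0)`.
#' Months absent from the input are omitted as rows; `t` keeps calendar
#' values so the AR(1) covariance sees the true lags.
#'
#' @param series A `monthly_series` (one group) from [aggregate_monthly()],
#'   or any data frame with columns `t` and `proportion_pct` (alias `y`).
#'   Rows with missing outcome are dropped.
#' @param t0 Last pre-intervention month.
#' @return List of class `its_design` with `y`, `t`, `t0`, and matrix `X`.
#' @export
build_design <- function(series, t0) {
  if (!is.null(series$group) && length(unique(series$group)) > 1)
    stop("build_design expects a single group's series; got ",
         length(unique(series$group)), call. = FALSE)
  y <- if (!is.null(series$proportion_pct)) series$proportion_pct else
    series$y
  if (is.null(y)) stop("series must have a proportion_pct or y column",
                       call. = FALSE)
  t <- series$t
  keep <- !is.na(y)
  y <- y[keep]; t <- t[keep]
  o <- order(t)
  y <- y[o]; t <- t[o]
  n_pre <- sum(t <= t0); n_post <- sum(t > t0)
  if (n_pre < 3 || n_post < 3)
    stop(sprintf(paste0("need at least 3 pre- and 3 post-intervention ",
                        "observations to fit (have %d pre, %d post)"),
                 n_pre, n_post), call. = FALSE)
  post <- as.numeric(t > t0)
  X <- cbind(intercept = 1, time = t, level = post,
             trend = (t - t0) * post)
  structure(list(y = y, t = t, t0 = t0, X = X), class = "its_design")
}

# Whitening transform for AR(1) correlation at integer times t (gaps
# allowed).  With R_ij = rho^|ti-tj| / (1 - rho^2), the Markov property
# gives an O(n) lower-triangular whitener W with W R W' = I:
#   w_1 = sqrt(1 - rho^2) z_1
#   w_i = sqrt((1 - rho^2) / (1 - rho^(2 d_i))) (z_i - rho^(d_i) z_{i-1}),
# d_i = t_i - t_{i-1}.  Also returns log det R.
ar1_whiten <- function(t, rho) {
  n <- length(t)
  if (abs(rho) < 1e-12) {
    return(list(apply = identity, logdet = 0))
  }
  d <- diff(t)
  r_d <- rho^d
  s1 <- sqrt(1 - rho^2)
  si <- sqrt((1 - rho^2) / (1 - r_d^2))
  logdet <- -log(1 - rho^2) + sum(log((1 - r_d^2) / (1 - rho^2)))
  apply_w <- function(z) {
    z <- as.matrix(z)
    w <- z
    w[1, ] <- s1 * z[1, ]
    if (n > 1)
      w[-1, ] <- si * (z[-1, , drop = FALSE] -
                         r_d * z[-n, , drop = FALSE])
    w
  }
  list(apply = apply_w, logdet = logdet)
}

# Restricted log-likelihood, beta profiled out, as a function of rho and
# (optionally) sigma2.  If sigma2 is NULL it is profiled too and the
# REML variance estimate is returned alongside.
reml_objective <- function(design, rho, sigma2 = NULL) {
  y <- design$y; X <- design$X; t <- design$t
  n <- length(y); p <- ncol(X)
  wh <- ar1_whiten(t, rho)
  yw <- wh$apply(y)
  Xw <- wh$apply(X)
  qrX <- qr(Xw)
  if (qrX$rank < p) stop("singular design matrix", call. = FALSE)
  beta <- qr.coef(qrX, yw)
  rss <- sum(qr.resid(qrX, yw)^2)
  logdet_xtx <- sum(log(abs(diag(qr.R(qrX))^2)))
  if (is.null(sigma2)) sigma2 <- rss / (n - p)
  ll <- -0.5 * ((n - p) * log(2 * pi * sigma2) + wh$logdet + logdet_xtx +
                  rss / sigma2)
  list(loglik = ll, beta = drop(beta), sigma2_profile = rss / (n - p),
       rss = rss, qrX = qrX, wh = wh)
}

#' Fit the segmented model with AR(1) errors by REML
#'
#' Profiles the restricted likelihood over the AR(1) coefficient with
#' bounded one-dimensional optimization (tolerance 1e-8 on rho); for each
#' rho the GLS coefficients and REML innovation variance have closed forms
#' via an O(n) whitening of the AR(1) covariance, exact across gaps from
#' missing months.
#'
#' @param design An `its_design` from [build_design()].
#' @param rho Either `NULL` (estimate by REML, the default) or a fixed
#'   value in (-1, 1) — e.g. `rho = 0` gives the OLS fit.
#' @param rho_bounds Search interval for the AR(1) coefficient.
#' @return Object of class `its_fit`: `beta` (intercept, pre-slope, level
#'   change, trend change), `rho`, `rho_fixed`, `sigma2` (innovation
#'   variance), `cov_beta`, `reml_loglik`, `fitted`, `residuals`, `mse`,
#'   `n`, `boundary` (logical: optimizer at the rho bound), plus the design.
#' @export
reml_fit_ar1 <- function(design, rho = NULL, rho_bounds = c(-0.99, 0.99)) {
  stopifnot(inherits(design, "its_design"))
  rho_fixed <- !is.null(rho)
  boundary <- FALSE
  if (rho_fixed) {
    rho_hat <- rho
    stopifnot(abs(rho_hat) < 1)
  } else {
    opt <- stats::optimize(function(r) reml_objective(design, r)$loglik,
                           interval = rho_bounds, maximum = TRUE,
                           tol = 1e-8)
    rho_hat <- opt$maximum
    if (min(rho_hat - rho_bounds[1], rho_bounds[2] - rho_hat) < 1e-4) {
      boundary <- TRUE
      warning("REML optimizer converged at the AR(1) boundary (rho = ",
              signif(rho_hat, 3), ")", call. = FALSE)
    }
  }
  obj <- reml_objective(design, rho_hat)
  n <- length(design$y); p <- ncol(design$X)
  sigma2 <- obj$sigma2_profile
  R_chol <- qr.R(obj$qrX)
  xtvxi <- chol2inv(R_chol)  # (X' V^-1 X)^-1 with V the AR(1) correlation
  cov_beta <- sigma2 * xtvxi
  dimnames(cov_beta) <- list(colnames(design$X), colnames(design$X))
  fitted <- drop(design$X %*% obj$beta)
  resid <- design$y - fitted

  structure(list(
    beta = stats::setNames(obj$beta, colnames(design$X)),
    rho = rho_hat, rho_fixed = rho_fixed, sigma2 = sigma2,
    cov_beta = cov_beta, reml_loglik = obj$loglik,
    fitted = fitted, residuals = resid, mse = mean(resid^2),
    n = n, p = p, boundary = boundary, design = design),
    class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat("Segmented regression with AR(1) errors (REML)\n")
  cat(sprintf("  n = %d observations, last pre-intervention month t0 = %d\n",
              x$n, x$design$t0))
  se <- sqrt(diag(x$cov_beta))
  tab <- data.frame(estimate = x$beta, se = se)
  rownames(tab) <- c("intercept (baseline %)", "pre-intervention slope",
                     "level change (immediate)", "trend change (gradual)")
  print(round(tab, 4))
  cat(sprintf("  rho = %.4f%s, innovation variance = %.4f, MSE = %.4f\n",
              x$rho, if (x$rho_fixed) " (fixed)" else "", x$sigma2, x$mse))
  cat(sprintf("  REML log-likelihood = %.4f%s\n", x$reml_loglik,
              if (x$boundary) "  [converged at rho boundary]" else ""))
  invisible(x)
}
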