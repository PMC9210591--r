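# Linear contrasts of the segmented-model coefficients: immediate (level)
# and gradual (trend) intervention effects, and the overall effect at a
# horizon h, i.e. the fitted-minus-counterfactual difference h months after
# implementation, c'beta with c = (0, 0, 1, h).
#
# Confidence intervals and p-values use a t reference distribution.  The
# default denominator degrees of freedom follow Satterthwaite's method:
#   df = 2 v^2 / Var(v),  v = c' cov_beta c,
# where Var(v) is obtained by the delta method from the observed REML
# information of the variance parameters (rho, sigma2).  When rho is held
# fixed the only variance parameter is sigma2, the information is analytic,
# and df reduces exactly to n - p.

# negative restricted log-likelihood as a function of theta = (rho, sigma2)
neg_reml <- function(design, theta) {
  if (theta[2] <= 0 || abs(theta[1]) >= 1) return(Inf)
  -reml_objective(design, theta[1], theta[2])$loglik
}

# contrast variance v(theta) = sigma2 * c'(X' V(rho)^-1 X)^-1 c
contrast_var <- function(design, contrast, theta) {
  wh <- ar1_whiten(design$t, theta[1])
  Xw <- wh$apply(design$X)
  xtvxi <- chol2inv(qr.R(qr(Xw)))
  theta[2] * drop(t(contrast) %*% xtvxi %*% contrast)
}

# Satterthwaite df for one contrast; numeric gradient/Hessian at the REML
# estimate, with a residual-df fallback on numerical failure
satterthwaite_df <- function(fit, contrast) {
  design <- fit$design
  n <- fit$n; p <- fit$p
  v <- drop(t(contrast) %*% fit$cov_beta %*% contrast)
  if (fit$sigma2 < 1e-12) return(n - p)  # degenerate noiseless fit
  if (fit$rho_fixed) {
    # theta = sigma2 alone: v = k sigma2, I = (n-p)/(2 sigma2^2), so
    # df = 2 v^2 / (k^2 I^-1) = n - p exactly
    return(n - p)
  }
  theta <- c(fit$rho, fit$sigma2)
  h <- c(1e-5, 1e-5 * max(fit$sigma2, 1e-8))
  g <- numeric(2)
  for (i in 1:2) {
    e <- c(0, 0); e[i] <- h[i]
    g[i] <- (contrast_var(design, contrast, theta + e) -
               contrast_var(design, contrast, theta - e)) / (2 * h[i])
  }
  H <- matrix(0, 2, 2)
  f0 <- neg_reml(design, theta)
  for (i in 1:2) {
    ei <- c(0, 0); ei[i] <- h[i]
    H[i, i] <- (neg_reml(design, theta + ei) - 2 * f0 +
                  neg_reml(design, theta - ei)) / h[i]^2
  }
  e1 <- c(h[1], 0); e2 <- c(0, h[2])
  H[1, 2] <- H[2, 1] <-
    (neg_reml(design, theta + e1 + e2) - neg_reml(design, theta + e1 - e2) -
       neg_reml(design, theta - e1 + e2) +
       neg_reml(design, theta - e1 - e2)) / (4 * h[1] * h[2])
  df <- tryCatch({
    denom <- drop(t(g) %*% solve(H, g))
    if (!is.finite(denom) || denom <= 0) stop("non-positive variance")
    2 * v^2 / denom
  }, error = function(e) n - p)
  # guard against degenerate curvature inflating or deflating df absurdly
  if (!is.finite(df) || df < 1) df <- n - p
  df
}

#' Estimate a linear contrast of the segmented-model coefficients
#'
#' @param fit An `its_fit` from [reml_fit_ar1()].
#' @param contrast Numeric 4-vector `c` defining the estimand `c' beta`.
#' @param df_method `"satterthwaite"` (default) or `"residual"`
#'   (`df = n - 4`).
#' @param level Confidence level (default 0.95).
#' @param name Label for the estimate.
#' @param horizon Months post-implementation, for overall effects
#'   (`NA` otherwise).
#' @return One-row data frame of class `effect_estimate`: `name`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value`, `df`, `horizon`.
#'   Units are percentage points (per month for slope-type contrasts).
#' @export
effect_contrast <- function(fit, contrast,
                            df_method = c("satterthwaite", "residual"),
                            level = 0.95, name = "contrast",
                            horizon = NA_real_) {
  stopifnot(inherits(fit, "its_fit"))
  df_method <- match.arg(df_method)
  if (length(contrast) != length(fit$beta))
    stop("contrast must have length ", length(fit$beta), call. = FALSE)
  est <- drop(crossprod(contrast, fit$beta))
  se <- sqrt(drop(t(contrast) %*% fit$cov_beta %*% contrast))
  df <- if (df_method == "satterthwaite") satterthwaite_df(fit, contrast)
        else fit$n - fit$p
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tstat <- if (se > 0) est / se else Inf * sign(est)
  out <- data.frame(
    name = name, estimate = est, se = se,
    ci_low = est - tcrit * se, ci_high = est + tcrit * se,
    p_value = 2 * stats::pt(-abs(tstat), df),
    df = df, horizon = horizon, stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Overall intervention effect at a horizon
#'
#' The fitted-minus-counterfactual difference `h` months after
#' implementation; algebraically the contrast `c = (0, 0, 1, h)`, i.e.
#' level change plus `h` times the trend change.
#'
#' @param fit An `its_fit`.
#' @param h Horizon in months post-implementation (default 12).
#' @inheritParams effect_contrast
#' @return An `effect_estimate` row.
#' @export
overall_effect_at <- function(fit, h = 12,
                              df_method = c("satterthwaite", "residual"),
                              level = 0.95) {
  stopifnot(h >= 0)
  effect_contrast(fit, c(0, 0, 1, h), df_method = df_method, level = level,
                  name = sprintf("overall_at_%g", h), horizon = h)
}

#' Standard effect table for a fit
#'
#' The five-row summary reported for each group: baseline percentage
#' (intercept), pre-intervention slope, immediate (level) and gradual
#' (trend) effects, and the overall effect at horizon `h`.
#'
#' @inheritParams overall_effect_at
#' @return Data frame with one `effect_estimate` row per parameter.
#' @export
effect_table <- function(fit, h = 12,
                         df_method = c("satterthwaite", "residual"),
                         level = 0.95) {
  df_method <- match.arg(df_method)
  rows <- list(
    effect_contrast(fit, c(1, 0, 0, 0), df_method, level,
                    name = "intercept"),
    effect_contrast(fit, c(0, 1, 0, 0), df_method, level,
                    name = "pre_slope"),
    effect_contrast(fit, c(0, 0, 1, 0), df_method, level,
                    name = "level_change"),
    effect_contrast(fit, c(0, 0, 0, 1), df_method, level,
                    name = "trend_change"),
    overall_effect_at(fit, h, df_method, level))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fitted and counterfactual trajectories
#'
#' The fitted series is the full-model prediction at the observed months;
#' the counterfactual extrapolates the pre-intervention line
#' `beta0 + beta1 t` over all months (it coincides with the fitted values
#' pre-intervention).
#'
#' @param fit An `its_fit`.
#' @return Data frame with columns `t`, `observed`, `fitted`,
#'   `counterfactual`, `post_indicator`.
#' @export
trajectories <- function(fit) {
  d <- fit$design
  data.frame(t = d$t,
             observed = d$y,
             fitted = fit$fitted,
             counterfactual = fit$beta[1] + fit$beta[2] * d$t,
             post_indicator = as.integer(d$t > d$t0))
}
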