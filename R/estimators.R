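#' @title BCEF estimators: ratio-based and least-squares through the origin
#' @description
#' A biomass conversion and expansion factor (BCEF) is the slope of the
#' no-intercept regression \eqn{\hat W = BCEF \times V} of component dry
#' biomass W (Mg) on stem volume V (m^3).  The traditional practice computes
#' the slope as a ratio of observed biomass to volume; the alternative fits
#' the same model by least squares, which minimises the residual sum of
#' squares.  Both are one-parameter linear smoothers, so each has a hat
#' (projection) diagonal that feeds the prediction-error machinery.
#' @name bcef-estimators
NULL

new_bcef_fit <- function(method, estimate, se, n, residuals, fitted, hat,
                         df_resid, component = NA_character_,
                         species = NA_character_, gate = NULL,
                         W = NULL, V = NULL) {
  structure(list(
    method = method, component = component, species = species,
    estimate = estimate, se = se,
    se_pct = if (estimate != 0) 100 * se / abs(estimate) else NA_real_,
    n = n, residuals = residuals, fitted = fitted, hat_diag = hat,
    df_resid = df_resid, gate = gate, W = W, V = V
  ), class = "bcef_fit")
}

#' @export
print.bcef_fit <- function(x, ...) {
  cat("BCEF fit (", x$method, ")", sep = "")
  if (!is.na(x$component)) cat(" - ", x$component, sep = "")
  if (!is.na(x$species)) cat(", ", x$species, sep = "")
  cat("\n  BCEF = ", format(x$estimate, digits = 5), " Mg m^-3  (SE ",
      format(x$se, digits = 4), ", SE% ", format(x$se_pct, digits = 3),
      ", n = ", x$n, ")\n", sep = "")
  if (!is.null(x$gate)) {
    cat("  normality gate: Shapiro-Wilk p = ",
        format(x$gate$p_value, digits = 3),
        if (x$gate$tripped) " -> GLM fallback used" else " -> Gaussian LS kept",
        "\n", sep = "")
  }
  invisible(x)
}

check_wv <- function(W, V, min_n = 2L) {
  if (length(W) != length(V)) stop("W and V must have equal length", call. = FALSE)
  if (any(!is.finite(W)) || any(!is.finite(V))) {
    stop("W and V must be finite", call. = FALSE)
  }
  if (length(W) < min_n) {
    stop("need at least ", min_n, " trees, got ", length(W), call. = FALSE)
  }
  invisible(length(W))
}

#' Ratio-based BCEF
#'
#' The classical ratio estimator of the BCEF: either the mean of the per-tree
#' biomass/volume ratios (default) or the ratio of the totals (equivalently of
#' the means).  For `mean_of_ratios` the standard error is the standard error
#' of the mean ratio; for `ratio_of_means` it is the classical ratio-estimator
#' standard error
#' \deqn{\sqrt{\frac{1}{n\bar V^2}\,\frac{\sum_i (W_i - R V_i)^2}{n-1}}.}
#' Residuals, fitted values and the hat diagonal treat the estimate as the
#' slope of the through-origin line, so the fit can be scored exactly like the
#' least-squares one.
#'
#' @param W component dry biomass, Mg.
#' @param V stem volume, m^3 (all > 0).
#' @param variant `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @param component,species optional labels carried into the fit.
#' @return a `bcef_fit`.
#' @examples
#' ratio_bcef(c(2, 3, 10), c(1, 2, 4))$estimate                      # 2
#' ratio_bcef(c(2, 3, 10), c(1, 2, 4), "ratio_of_means")$estimate    # 15/7
#' @export
ratio_bcef <- function(W, V, variant = c("mean_of_ratios", "ratio_of_means"),
                       component = NA_character_, species = NA_character_) {
  variant <- match.arg(variant)
  n <- check_wv(W, V, min_n = 2L)
  if (any(V <= 0)) stop("all stem volumes must be > 0", call. = FALSE)
  if (any(W < 0)) stop("biomass must be >= 0", call. = FALSE)
  if (variant == "mean_of_ratios") {
    r <- W / V
    est <- mean(r)
    se <- stats::sd(r) / sqrt(n)
    method <- "ratio_mean_of_ratios"
  } else {
    est <- sum(W) / sum(V)
    dev <- W - est * V
    se <- sqrt(sum(dev^2) / (n - 1) / (n * mean(V)^2))
    method <- "ratio_ratio_of_means"
  }
  fitted <- est * V
  new_bcef_fit(method, est, se, n, W - fitted, fitted,
               hat_diagonal(V, method), df_resid = n - 1L,
               component = component, species = species, W = W, V = V)
}

#' Least-squares BCEF (regression through the origin)
#'
#' Fits \eqn{W = \beta V + \varepsilon} with no intercept by ordinary least
#' squares: \eqn{\hat\beta = \sum W_i V_i / \sum V_i^2}.  The residual
#' variance uses n - 1 degrees of freedom (one mean parameter), the slope
#' standard error is \eqn{\sqrt{\hat\sigma^2/\sum V_i^2}}, and the hat
#' diagonal is \eqn{V_i^2/\sum V_j^2}.
#'
#' @inheritParams ratio_bcef
#' @return a `bcef_fit`.
#' @examples
#' fit <- ls_rto_bcef(c(2, 3, 10), c(1, 2, 4))
#' fit$estimate   # 48/21
#' fit$se         # ~0.2797
#' @export
ls_rto_bcef <- function(W, V, component = NA_character_,
                        species = NA_character_) {
  n <- check_wv(W, V, min_n = 2L)
  svv <- sum(V^2)
  if (svv == 0) stop("all volumes are zero; slope undefined", call. = FALSE)
  est <- sum(W * V) / svv
  fitted <- est * V
  e <- W - fitted
  sigma2 <- sum(e^2) / (n - 1)
  se <- sqrt(sigma2 / svv)
  new_bcef_fit("ls_rto", est, se, n, e, fitted, V^2 / svv, df_resid = n - 1L,
               component = component, species = species, W = W, V = V)
}

#' GLM BCEF for non-normal residuals (regression through the origin)
#'
#' Fits the no-intercept proportional model under a generalized linear model,
#' by default Gamma with identity link: the mean is still \eqn{BCEF \times V}
#' (so the estimate keeps its Mg m^-3 interpretation) while the variance grows
#' with the mean, which suits positive right-skewed biomass.  The slope
#' standard error comes from the asymptotic covariance and the hat diagonal
#' from the IRLS weighted projection matrix.
#'
#' @inheritParams ratio_bcef
#' @param family a [stats::family] object; default `Gamma(link = "identity")`.
#' @param max_iter maximum IRLS iterations.
#' @return a `bcef_fit`; residuals are on the response scale (W - fitted).
#' @export
glm_rto_bcef <- function(W, V, family = stats::Gamma(link = "identity"),
                         max_iter = 100L, component = NA_character_,
                         species = NA_character_) {
  n <- check_wv(W, V, min_n = 3L)
  if (family$family == "Gamma" && any(W <= 0)) {
    stop("Gamma GLM requires strictly positive biomass; ",
         sum(W <= 0), " value(s) <= 0", call. = FALSE)
  }
  start <- sum(W * V) / sum(V^2)
  dat <- data.frame(W = W, V = V)
  fit <- stats::glm(W ~ V - 1, family = family, data = dat,
                    start = start,
                    control = stats::glm.control(maxit = max_iter))
  if (!fit$converged) {
    stop("GLM did not converge in ", max_iter, " iterations (deviance ",
         signif(fit$deviance, 6), ")", call. = FALSE)
  }
  est <- unname(stats::coef(fit)[["V"]])
  se <- sqrt(stats::vcov(fit)[1, 1])
  fitted <- as.numeric(stats::fitted(fit))
  hat <- as.numeric(stats::hatvalues(fit))
  new_bcef_fit("glm_rto", est, se, n, W - fitted, fitted, hat,
               df_resid = n - 1L, component = component, species = species,
               W = W, V = V)
}

#' BCEF with automatic residual-normality gate
#'
#' The operative model-selection rule: fit the least-squares through-origin
#' model first, test its residuals with Shapiro-Wilk, and fall back to the
#' GLM fit when normality is rejected at `alpha_level`.  The returned fit
#' carries the gate decision (`$gate`).
#'
#' @inheritParams glm_rto_bcef
#' @param alpha_level significance level of the normality gate.
#' @return a `bcef_fit` with `method` `"ls_rto"` or `"glm_rto"`.
#' @export
fit_bcef_auto <- function(W, V, alpha_level = 0.05,
                          family = stats::Gamma(link = "identity"),
                          component = NA_character_, species = NA_character_) {
  check_wv(W, V, min_n = 3L)
  ls_fit <- ls_rto_bcef(W, V, component = component, species = species)
  if (stats::sd(ls_fit$residuals) > 0) {
    sw <- shapiro_wilk(ls_fit$residuals, target = "OLS residuals")
    gate <- list(w_stat = sw$w_stat, p_value = sw$p_value,
                 alpha = alpha_level, tripped = sw$p_value < alpha_level)
  } else {
    # a perfect fit carries no evidence against normality
    gate <- list(w_stat = NA_real_, p_value = NA_real_, alpha = alpha_level,
                 tripped = FALSE)
  }
  if (gate$tripped && all(W > 0)) {
    fit <- glm_rto_bcef(W, V, family = family, component = component,
                        species = species)
  } else {
    # W = 0 rows (leaf-off trees) are outside the Gamma domain: keep LS
    gate$tripped <- gate$tripped && all(W > 0)
    fit <- ls_fit
  }
  fit$gate <- gate
  fit
}
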