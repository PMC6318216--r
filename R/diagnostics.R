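#' Shapiro-Wilk normality report
#'
#' Thin wrapper around [stats::shapiro.test()] that records what was tested
#' (raw biomass or regression residuals), for use both as a standalone
#' diagnostic and as the gate inside [fit_bcef_auto()].
#'
#' @param x numeric sample, 3 <= n <= 5000.
#' @param target label of what is being tested.
#' @return a list of class `normality_report`: `w_stat`, `p_value`, `n`,
#'   `target`.
#' @export
shapiro_wilk <- function(x, target = "sample") {
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk needs 3 <= n <= 5000, got n = ", n, call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  structure(list(w_stat = unname(sw$statistic), p_value = sw$p.value,
                 n = n, target = target),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat("Shapiro-Wilk on ", x$target, ": W = ", format(x$w_stat, digits = 4),
      ", p = ", format(x$p_value, digits = 3), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' Normal Q-Q points (no rendering)
#'
#' Theoretical normal quantiles at plotting positions (i - 0.5)/n paired with
#' the ordered sample, i.e. the data behind a normal Q-Q plot.
#'
#' @param x numeric sample, n >= 2.
#' @return data.frame with columns `theoretical`, `sample`.
#' @export
qq_points <- function(x) {
  n <- length(x)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(x))
}

#' Test that the intercept of W = alpha + beta V + epsilon is zero
#'
#' Fits the ordinary two-parameter regression of biomass on volume and tests
#' H0: alpha = 0 with a two-sided t test on n - 2 degrees of freedom.  A
#' non-significant intercept is the standard justification for constraining
#' the BCEF regression through the origin; a clearly non-zero intercept warns
#' that the through-origin slope will be biased.
#'
#' @param W component dry biomass, Mg.
#' @param V stem volume, m^3 (not constant).
#' @return a list of class `intercept_test`: `alpha_hat`, `beta_hat`,
#'   `se_alpha`, `t_stat`, `p_value`, `df`, `n`.
#' @examples
#' intercept_zero_test(c(2.1, 3.9, 6.0), c(1, 2, 3))   # t ~ 0.534
#' @export
intercept_zero_test <- function(W, V) {
  n <- check_wv(W, V, min_n = 3L)
  if (stats::var(V) == 0) stop("V is constant; slope undefined", call. = FALSE)
  fit <- stats::lm(W ~ V)
  rss <- sum(stats::residuals(fit)^2)
  if (rss <= .Machine$double.eps * sum(W^2)) {
    stop("zero residual variance; intercept t statistic undefined",
         call. = FALSE)
  }
  cf <- summary(fit)$coefficients
  structure(list(
    alpha_hat = cf["(Intercept)", "Estimate"],
    beta_hat = cf["V", "Estimate"],
    se_alpha = cf["(Intercept)", "Std. Error"],
    t_stat = cf["(Intercept)", "t value"],
    p_value = cf["(Intercept)", "Pr(>|t|)"],
    df = n - 2L, n = n
  ), class = "intercept_test")
}

#' @export
print.intercept_test <- function(x, ...) {
  cat("W = ", format(x$alpha_hat, digits = 4), " + ",
      format(x$beta_hat, digits = 4), " V + e;  H0 alpha = 0: t(",
      x$df, ") = ", format(x$t_stat, digits = 4), ", p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Confidence interval for a fitted BCEF
#'
#' `estimate +/- t * SE` with the critical value taken from the t
#' distribution on n - 2 degrees of freedom for every method, the convention
#' used when displaying BCEF error bars; note the through-origin fits
#' themselves use n - 1 residual degrees of freedom for the variance, so the
#' interval is mildly conservative for those.  The `significant` flag records
#' whether the interval excludes zero.
#'
#' @param fit a `bcef_fit` with `n >= 3`.
#' @param level confidence level.
#' @return list with `lower`, `upper`, `level`, `df`, `significant`.
#' @export
confidence_interval <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "bcef_fit"))
  if (fit$n < 3) stop("need n >= 3 for a t interval", call. = FALSE)
  df <- fit$n - 2L
  half <- stats::qt(1 - (1 - level) / 2, df) * fit$se
  lower <- fit$estimate - half
  upper <- fit$estimate + half
  list(lower = lower, upper = upper, level = level, df = df,
       significant = (lower > 0) || (upper < 0))
}
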