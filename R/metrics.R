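#' @title Predictive accuracy and ability metrics for BCEF fits
#' @description
#' The score card used to compare ratio-based and least-squares BCEFs.
#' Accuracy side: Gaussian AIC (model misspecification), slope SE%
#' (parameter uncertainty), coefficient of variation of the residuals and
#' Furnival's index (residual variability).  Ability side: the hat-matrix
#' mean quadratic error of prediction (PRESS/n) and K-fold cross-validated
#' prediction error.
#' @name bcef-metrics
NULL

#' Gaussian AIC from residuals
#'
#' Full Gaussian log-likelihood convention:
#' \deqn{AIC = n\log(2\pi\hat\sigma^2) + n + 2k, \quad \hat\sigma^2 = RSS/n,}
#' where `k_params` counts the mean parameters plus the variance parameter.
#' Both estimator families are scored with the likelihood evaluated at their
#' own slope, so a ratio-based fit pays for its larger residual sum of
#' squares.
#'
#' @param residuals fit residuals, Mg.
#' @param k_params number of parameters (slope count + 1 for the variance).
#' @return the AIC (unitless).
#' @export
aic_gaussian <- function(residuals, k_params) {
  n <- length(residuals)
  if (n <= k_params) stop("need n > k_params", call. = FALSE)
  rss <- sum(residuals^2)
  if (rss == 0) {
    stop("zero residual sum of squares: Gaussian AIC undefined", call. = FALSE)
  }
  sigma2 <- rss / n
  n * log(2 * pi * sigma2) + n + 2 * k_params
}

#' Coefficient of variation of the residuals
#'
#' Residual standard error as a percentage of mean observed biomass:
#' `100 * sqrt(RSS / (n - dof)) / mean(W)`.
#'
#' @param residuals fit residuals, Mg.
#' @param W observed biomass, Mg (positive mean).
#' @param dof number of estimated mean parameters (1 for a single slope).
#' @return CVr in percent.
#' @export
cvr <- function(residuals, W, dof = 1L) {
  n <- length(residuals)
  if (n <= dof) stop("need n > dof", call. = FALSE)
  wbar <- mean(W)
  if (wbar <= 0) stop("mean biomass must be > 0", call. = FALSE)
  100 * sqrt(sum(residuals^2) / (n - dof)) / wbar
}

#' Furnival's index of fit
#'
#' Root mean squared error on the modelling scale divided by the geometric
#' mean of the derivative of the response transform over the observations,
#' which puts fits on transformed responses back on comparable (Mg) footing.
#' For the identity transform the index is just the RMSE.
#'
#' @param residuals residuals on the (possibly transformed) modelling scale.
#' @param W observed biomass on the original scale, Mg.
#' @param transform `"identity"` (default) or `"log"`.
#' @param dof number of estimated mean parameters.
#' @return the index, Mg.
#' @export
furnival_index <- function(residuals, W, transform = c("identity", "log"),
                           dof = 1L) {
  transform <- match.arg(transform)
  n <- length(residuals)
  if (n <= dof) stop("need n > dof", call. = FALSE)
  rmse <- sqrt(sum(residuals^2) / (n - dof))
  if (transform == "identity") return(rmse)
  if (any(W <= 0)) stop("log transform needs positive biomass", call. = FALSE)
  # f(w) = log w, f'(w) = 1/w; geometric mean of f'
  gm_deriv <- exp(mean(log(1 / W)))
  rmse / gm_deriv
}

#' Hat-matrix diagonal of the one-parameter linear smoothers
#'
#' Each BCEF estimator maps observations linearly to fitted values, so each
#' has a projection (hat) matrix.  Diagonals: least squares through the
#' origin `V_i^2 / sum(V^2)`; mean of ratios `1/n` (every tree contributes
#' equally to the mean ratio); ratio of means `V_i / sum(V)`.  All three sum
#' to 1 (one parameter).
#'
#' @param V stem volumes, m^3 (> 0).
#' @param method one of `"ls_rto"`, `"ratio_mean_of_ratios"`,
#'   `"ratio_ratio_of_means"`.
#' @return leverage vector in [0, 1).
#' @export
hat_diagonal <- function(V, method) {
  if (any(V <= 0)) stop("volumes must be > 0", call. = FALSE)
  n <- length(V)
  switch(method,
    ls_rto = V^2 / sum(V^2),
    ratio_mean_of_ratios = rep(1 / n, n),
    ratio_ratio_of_means = V / sum(V),
    stop("unknown method '", method, "'", call. = FALSE)
  )
}

#' Mean quadratic error of prediction (PRESS/n)
#'
#' \deqn{MEP = \frac{1}{n}\sum_i \frac{e_i^2}{(1 - H_{ii})^2},}
#' the mean squared leave-one-out prediction error of a linear smoother,
#' computed without refitting via the hat diagonal.
#'
#' @param residuals fit residuals, Mg.
#' @param hat_diag leverages in [0, 1), same length.
#' @return MEP in Mg^2.
#' @export
mep <- function(residuals, hat_diag) {
  if (length(residuals) != length(hat_diag)) {
    stop("residuals and hat_diag must have equal length", call. = FALSE)
  }
  if (any(hat_diag >= 1)) {
    stop("degenerate leverage: H_ii >= 1", call. = FALSE)
  }
  if (any(hat_diag < 0)) stop("leverage must be >= 0", call. = FALSE)
  mean(residuals^2 / (1 - hat_diag)^2)
}

# deterministic K near-equal folds after a seeded shuffle
kfold_assignments <- function(n, K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold_sizes <- rep(n %/% K, K) + c(rep(1L, n %% K), rep(0L, K - n %% K))
  assignment <- rep(seq_len(K), times = fold_sizes)
  assignment[sample.int(n)]
}

refit_bcef <- function(W, V, method,
                       family = stats::Gamma(link = "identity")) {
  switch(method,
    ls_rto = ls_rto_bcef(W, V),
    ratio_mean_of_ratios = ratio_bcef(W, V, "mean_of_ratios"),
    ratio_ratio_of_means = ratio_bcef(W, V, "ratio_of_means"),
    glm_rto = glm_rto_bcef(W, V, family = family),
    stop("unknown method '", method, "'", call. = FALSE)
  )
}

#' K-fold cross-validated model prediction error
#'
#' Shuffles the indices (seeded), splits them into K near-equal folds, fits
#' the chosen estimator on each complement and predicts the held-out trees,
#' then pools all n held-out predictions into a single cost: root mean
#' squared prediction error by default, mean absolute error on request.
#' Falls back to leave-one-out (with a message) when n < K.
#'
#' @param W component dry biomass, Mg.
#' @param V stem volume, m^3.
#' @param method `"ls_rto"`, `"ratio_mean_of_ratios"`,
#'   `"ratio_ratio_of_means"` or `"glm_rto"`.
#' @param K number of folds (default 10).
#' @param seed integer seed for the shuffle; `NULL` uses the current RNG
#'   state.
#' @param cost `"rmspe"` (default) or `"mae"`.
#' @param folds optional explicit fold-assignment vector (length n, values in
#'   `1:K`), overriding the shuffle.
#' @return the pooled prediction error, Mg.
#' @export
kfold_mpe <- function(W, V, method = "ls_rto", K = 10L, seed = NULL,
                      cost = c("rmspe", "mae"), folds = NULL) {
  cost <- match.arg(cost)
  n <- check_wv(W, V, min_n = 2L)
  if (is.null(folds)) {
    if (n < K) {
      message("n = ", n, " < K = ", K, ": falling back to leave-one-out")
      K <- n
    }
    folds <- kfold_assignments(n, K, seed)
  } else {
    K <- max(folds)
  }
  pred <- numeric(n)
  for (k in seq_len(K)) {
    hold <- which(folds == k)
    if (!length(hold)) next
    fit <- refit_bcef(W[-hold], V[-hold], method)
    pred[hold] <- fit$estimate * V[hold]
  }
  err <- W - pred
  if (cost == "rmspe") sqrt(mean(err^2)) else mean(abs(err))
}

#' Full score card for a fitted BCEF
#'
#' Assembles the six comparison metrics for one fit: AIC, SE%, CVr%,
#' Furnival's index, MEP and the K-fold MPE (the last recomputed from the
#' stored data by cross-validation).
#'
#' @param fit a `bcef_fit` carrying its data (`$W`, `$V`).
#' @param K,seed,cost passed to [kfold_mpe()].
#' @param hat_source `"own"` (default) scores MEP with the fit's own
#'   smoother leverage; `"ls"` applies the least-squares through-origin hat
#'   diagonal to every method.
#' @return a list of class `fit_metrics`: `aic`, `se_pct`, `cvr_pct`, `fi`,
#'   `mep`, `mpe`, `n`, `k_params`.
#' @export
score_fit <- function(fit, K = 10L, seed = NULL, cost = c("rmspe", "mae"),
                      hat_source = c("own", "ls")) {
  stopifnot(inherits(fit, "bcef_fit"))
  hat_source <- match.arg(hat_source)
  cost <- match.arg(cost)
  if (is.null(fit$W) || is.null(fit$V)) {
    stop("fit does not carry its data; refit with the package estimators",
         call. = FALSE)
  }
  hat <- if (hat_source == "ls") hat_diagonal(fit$V, "ls_rto") else fit$hat_diag
  rss <- sum(fit$residuals^2)
  structure(list(
    aic = if (rss > 0) aic_gaussian(fit$residuals, k_params = 2L) else -Inf,
    se_pct = fit$se_pct,
    cvr_pct = cvr(fit$residuals, fit$W, dof = 1L),
    fi = furnival_index(fit$residuals, fit$W, dof = 1L),
    mep = mep(fit$residuals, hat),
    mpe = kfold_mpe(fit$W, fit$V, method = fit$method, K = K, seed = seed,
                    cost = cost),
    n = fit$n, k_params = 2L
  ), class = "fit_metrics")
}
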