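toy_residuals <- function() {
  fit <- ls_rto_bcef(c(2, 3, 10), c(1, 2, 4))
  fit$residuals
}

test_that("Gaussian AIC matches the full-likelihood convention", {
  e <- toy_residuals()
  expect_equal(aic_gaussian(e, 2), 12.789, tolerance = 1e-3)
  # scaling the residuals by c adds 2 n log(c)
  expect_equal(aic_gaussian(3 * e, 2) - aic_gaussian(e, 2), 2 * 3 * log(3),
               tolerance = 1e-10)
  expect_error(aic_gaussian(rep(0, 5), 2), "zero residual")
  expect_error(aic_gaussian(c(0.1, 0.2), 2), "n > k")
})

test_that("CVr is the residual SE as a percentage of mean biomass", {
  e <- toy_residuals()
  expect_equal(cvr(e, c(2, 3, 10), dof = 1), 25.634, tolerance = 1e-3)
  expect_equal(cvr(rep(0, 4), c(1, 2, 3, 4)), 0)
  expect_equal(cvr(2 * e, 2 * c(2, 3, 10), dof = 1),
               cvr(e, c(2, 3, 10), dof = 1), tolerance = 1e-12)
  expect_error(cvr(e, c(-2, -3, -10)), "> 0")
})

test_that("Furnival's index reduces to RMSE on the identity scale", {
  e <- toy_residuals()
  expect_equal(furnival_index(e, c(2, 3, 10), dof = 1), 1.2817,
               tolerance = 1e-4)
  set.seed(21)
  e2 <- rnorm(10)
  W <- rlnorm(10, 0, 0.5)
  expect_equal(furnival_index(e2, W), sqrt(sum(e2^2) / 9), tolerance = 1e-12)
  # log transform with unit weights: geometric mean of 1/W is 1 when W = 1
  expect_equal(furnival_index(e2[1:3], c(1, 1, 1), transform = "log"),
               sqrt(sum(e2[1:3]^2) / 2), tolerance = 1e-12)
  expect_error(furnival_index(e2[1:3], c(1, -1, 1), transform = "log"),
               "positive")
})

test_that("hat diagonals follow the smoother closed forms and sum to one", {
  expect_equal(hat_diagonal(c(1, 2), "ls_rto"), c(0.2, 0.8))
  expect_equal(hat_diagonal(c(1, 2, 3), "ratio_ratio_of_means"),
               c(1, 2, 3) / 6)
  expect_equal(hat_diagonal(c(5, 9, 2, 7), "ratio_mean_of_ratios"),
               rep(0.25, 4))
  set.seed(3)
  V <- rlnorm(9, 0, 1)
  for (m in c("ls_rto", "ratio_mean_of_ratios", "ratio_ratio_of_means")) {
    expect_equal(sum(hat_diagonal(V, m)), 1, tolerance = 1e-12)
  }
  expect_error(hat_diagonal(V, "nope"), "unknown method")
})

test_that("MEP matches the worked instance and basic bounds", {
  fit <- ls_rto_bcef(c(1, 3), c(1, 2))
  expect_equal(fit$estimate, 1.4)
  expect_equal(mep(fit$residuals, fit$hat_diag), 0.625, tolerance = 1e-12)
  expect_equal(mep(rep(0, 4), rep(0.1, 4)), 0)
  expect_error(mep(c(1, 2), c(0.5, 1)), "H_ii >= 1")
  expect_error(mep(c(1, 2), c(0.5)), "equal length")
})

test_that("MEP equals PRESS/n under explicit leave-one-out refitting", {
  set.seed(55)
  methods <- c("ls_rto", "ratio_mean_of_ratios", "ratio_ratio_of_means")
  for (i in 1:30) {
    wv <- random_wv(sample(3:12, 1))
    for (m in methods) {
      fit <- bcef:::refit_bcef(wv$W, wv$V, m)
      press <- mean(vapply(seq_along(wv$W), function(j) {
        loo <- bcef:::refit_bcef(wv$W[-j], wv$V[-j], m)
        (wv$W[j] - loo$estimate * wv$V[j])^2
      }, numeric(1)))
      expect_equal(mep(fit$residuals, hat_diagonal(wv$V, m)), press,
                   tolerance = 1e-9)
    }
  }
})

test_that("MEP strictly exceeds RSS/n for noisy fits", {
  set.seed(56)
  for (i in 1:10) {
    wv <- random_wv(sample(4:15, 1))
    fit <- ls_rto_bcef(wv$W, wv$V)
    expect_gt(mep(fit$residuals, fit$hat_diag),
              sum(fit$residuals^2) / fit$n)
  }
})

test_that("K-fold prediction error is zero for noiseless data and seeded", {
  V <- seq(0.5, 5, length.out = 30)
  expect_equal(kfold_mpe(3 * V, V, seed = 1), 0, tolerance = 1e-12)
  expect_equal(kfold_mpe(3 * V, V, method = "ratio_mean_of_ratios", seed = 2),
               0, tolerance = 1e-12)
  # determinism under a fixed seed
  set.seed(9)
  wv <- random_wv(40)
  expect_identical(kfold_mpe(wv$W, wv$V, seed = 123),
                   kfold_mpe(wv$W, wv$V, seed = 123))
})

test_that("K-fold MPE estimates the noise sd consistently and is seed stable", {
  set.seed(60)
  mpes <- replicate(30, {
    V <- rlnorm(1000, 0, 0.6)
    W <- abs(0.5 * V + rnorm(1000, 0, 0.1))
    kfold_mpe(W, V, K = 10, seed = sample.int(1e6, 1))
  })
  expect_lt(abs(mean(mpes) - 0.1) / 0.1, 0.05)

  set.seed(61)
  V <- rlnorm(1000, 0, 0.6)
  W <- abs(0.5 * V + rnorm(1000, 0, 0.1))
  m1 <- kfold_mpe(W, V, seed = 7)
  m2 <- kfold_mpe(W, V, seed = 8)
  expect_lt(abs(m1 - m2) / m1, 0.02)
})

test_that("K-fold MPE is invariant to fold labels and falls back to LOO", {
  set.seed(62)
  wv <- random_wv(20)
  folds <- bcef:::kfold_assignments(20, 5, seed = 3)
  perm <- c(3, 5, 1, 4, 2)
  expect_equal(kfold_mpe(wv$W, wv$V, folds = folds),
               kfold_mpe(wv$W, wv$V, folds = perm[folds]), tolerance = 1e-12)
  wv_small <- random_wv(6)
  expect_message(kfold_mpe(wv_small$W, wv_small$V, K = 10, seed = 1),
                 "leave-one-out")
})

test_that("the score card assembles all six metrics and respects the hat convention", {
  set.seed(63)
  wv <- random_wv(25)
  fit <- ratio_bcef(wv$W, wv$V)
  sc_own <- score_fit(fit, seed = 1, hat_source = "own")
  sc_ls <- score_fit(fit, seed = 1, hat_source = "ls")
  expect_equal(sc_own$mep,
               mep(fit$residuals, hat_diagonal(wv$V, "ratio_mean_of_ratios")),
               tolerance = 1e-12)
  expect_equal(sc_ls$mep,
               mep(fit$residuals, hat_diagonal(wv$V, "ls_rto")),
               tolerance = 1e-12)
  expect_equal(sc_own$se_pct, 100 * fit$se / fit$estimate, tolerance = 1e-12)
  expect_true(all(c("aic", "cvr_pct", "fi", "mpe") %in% names(sc_own)))
  # AIC ordering is invariant to common scaling of W and V
  fit2 <- ratio_bcef(10 * wv$W, 10 * wv$V)
  expect_equal(score_fit(fit2, seed = 1)$aic - sc_own$aic, 2 * 25 * log(10),
               tolerance = 1e-8)
})
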