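simple_spec <- function(n = 50, noise = list(model = "additive_normal",
                                             sd = c(stem = 0.05,
                                                    branches = 0.02,
                                                    foliage = 0.005)),
                        shift = 0) {
  synthetic_spec("test_sp", n = n, meanlog = -0.3, sdlog = 0.7,
                 v_min = 0.05, v_max = 8,
                 true_bcef = c(stem = 0.68, branches = 0.3, foliage = 0.01),
                 noise = noise, intercept_shift = shift)
}

test_that("generation is deterministic under a fixed seed", {
  spec <- simple_spec()
  a <- generate_population(spec, seed = 42)
  b <- generate_population(spec, seed = 42)
  expect_identical(a$volume_m3, b$volume_m3)
  expect_identical(a$w_agb, b$w_agb)
  c <- generate_population(spec, seed = 43)
  expect_false(identical(a$volume_m3, c$volume_m3))
  # different seeds, same distribution: summaries agree at large n
  big <- simple_spec(n = 4000)
  m1 <- mean(generate_population(big, seed = 1)$volume_m3)
  m2 <- mean(generate_population(big, seed = 2)$volume_m3)
  expect_equal(m1, m2, tolerance = 0.1)
})

test_that("zero-variance noise yields exact proportionality", {
  spec <- simple_spec(noise = list(model = "additive_normal",
                                   sd = c(stem = 0, branches = 0,
                                          foliage = 0)))
  pop <- generate_population(spec, seed = 1)
  W <- pop$w_stem; V <- pop$volume_m3
  expect_equal(ls_rto_bcef(W, V)$estimate, 0.68, tolerance = 1e-12)
  expect_equal(ratio_bcef(W, V)$estimate, 0.68, tolerance = 1e-12)
  expect_equal(attr(pop, "resampled"), 0L)
})

test_that("volumes respect the truncation bounds and components add up", {
  spec <- simple_spec(n = 2000)
  pop <- generate_population(spec, seed = 9)
  expect_true(all(pop$volume_m3 >= 0.05 & pop$volume_m3 <= 8))
  expect_equal(pop$w_crown, pop$w_branches + pop$w_foliage)
  expect_equal(pop$w_agb, pop$w_stem + pop$w_crown)
  expect_true(all(pop$w_stem >= 0))
})

test_that("the LS slope concentrates on the true BCEF at large n", {
  spec <- synthetic_spec("big", n = 1e4, meanlog = 0, sdlog = 0.5,
                         v_min = 0.1, v_max = 10,
                         true_bcef = c(stem = 0.68, branches = 0.3,
                                       foliage = 0.01),
                         noise = list(model = "additive_normal",
                                      sd = c(stem = 0.1, branches = 0.05,
                                             foliage = 0.002)))
  pop <- generate_population(spec, seed = 4)
  expect_lt(abs(ls_rto_bcef(pop$w_stem, pop$volume_m3)$estimate - 0.68),
            0.01)
})

test_that("LS slope is unbiased when the noise rarely hits the zero floor", {
  spec <- simple_spec(n = 30)
  ls_est <- vapply(1:600, function(r) {
    pop <- generate_population(spec, seed = 10000 + r)
    ls_rto_bcef(pop$w_stem, pop$volume_m3)$estimate
  }, numeric(1))
  expect_lt(abs(mean(ls_est) - 0.68) / 0.68, 0.01)
})

test_that("mean-of-ratios is biased upward under additive noise with small trees", {
  # additive noise spanning small volumes: nonnegativity resampling inflates
  # small-tree ratios, pulling the mean-of-ratios estimator upward while the
  # volume-weighted LS slope barely moves
  spec <- synthetic_spec("bias", n = 30, meanlog = -1, sdlog = 1,
                         v_min = 0.02, v_max = 6,
                         true_bcef = c(stem = 0.68, branches = 0.3,
                                       foliage = 0.01),
                         noise = list(model = "additive_normal",
                                      sd = c(stem = 0.15, branches = 0.05,
                                             foliage = 0.002)))
  est <- vapply(1:600, function(r) {
    pop <- generate_population(spec, seed = 10000 + r)
    c(ls_rto_bcef(pop$w_stem, pop$volume_m3)$estimate,
      ratio_bcef(pop$w_stem, pop$volume_m3)$estimate)
  }, numeric(2))
  expect_gt(mean(est[2, ]), 1.02 * 0.68)
  expect_gt(mean(est[2, ]), mean(est[1, ]))
})

test_that("an intercept shift is detected by the intercept-zero test", {
  spec <- synthetic_spec("shifted", n = 100, meanlog = -0.3, sdlog = 0.7,
                         v_min = 0.05, v_max = 8,
                         true_bcef = c(stem = 0.68, branches = 0.3,
                                       foliage = 0.01),
                         noise = list(model = "additive_normal",
                                      sd = c(stem = 0.1, branches = 0.05,
                                             foliage = 0.002)),
                         intercept_shift = 0.2)  # = 2 x stem noise sd
  hits <- 0
  for (r in 1:300) {
    pop <- generate_population(spec, seed = 5000 + r)
    p <- intercept_zero_test(pop$w_stem, pop$volume_m3)$p_value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 300, 0.8)
})

test_that("the four-species scenario matches the published sampling layout", {
  specs <- miombo_mopane_scenario()
  expect_equal(vapply(specs, function(s) s$n, integer(1)),
               c(17L, 24L, 15L, 19L))
  pop <- generate_scenario(specs, seed = 2)
  expect_equal(nrow(pop), 75)
  cm <- pop[pop$species == "C. mopane", ]
  expect_true(all(cm$volume_m3 >= 0.01 & cm$volume_m3 <= 10.55))
  expect_equal(pop$w_crown, pop$w_branches + pop$w_foliage)
  # scenario mean volumes sit near the published means
  vmeans <- vapply(specs, function(s) {
    mean(generate_population(s, seed = 77)$volume_m3)
  }, numeric(1))
  expect_equal(vmeans, c(3.11, 0.98, 0.84, 0.35), tolerance = 0.5)
})

test_that("specs survive a YAML round trip and reject bad truncation", {
  specs <- miombo_mopane_scenario()
  path <- tempfile(fileext = ".yaml")
  write_synthetic_spec(specs, path)
  back <- read_synthetic_spec(path)
  expect_equal(length(back), 4)
  expect_equal(back[[1]]$true_bcef, specs[[1]]$true_bcef)
  expect_equal(back[[1]]$intercept_shift, specs[[1]]$intercept_shift)
  expect_equal(back[[3]]$noise$sd_coef, specs[[3]]$noise$sd_coef)
  a <- generate_population(specs[[2]], seed = 8)
  b <- generate_population(back[[2]], seed = 8)
  expect_equal(a$w_agb, b$w_agb, tolerance = 1e-9)
  expect_error(synthetic_spec("x", 10, 0, 1, v_min = 2, v_max = 1,
                              true_bcef = c(stem = 1, branches = 1,
                                            foliage = 1)),
               "infeasible")
})
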