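# Shared fixture builders: everything is generated in code at test time.

# the worked three-tree instance used across estimator/metric tests
toy_wv <- function() list(W = c(2, 3, 10), V = c(1, 2, 4))

# a small random biomass/volume instance with positive W
random_wv <- function(n, beta = 0.7, sd = 0.2) {
  V <- stats::rlnorm(n, 0, 0.8)
  W <- abs(beta * V + stats::rnorm(n, 0, sd * sqrt(V))) + 1e-8
  list(W = W, V = V)
}

# write a canonical tree CSV (masses in kg) and return its path
write_toy_tree_csv <- function(path = tempfile(fileext = ".csv"),
                               volume = c(1.5, 2.0, 0.8),
                               stem_kg = c(500, 700, 300),
                               branches_kg = c(100, 150, 60),
                               foliage_kg = c(10, 20, 5),
                               species = "sp1") {
  df <- data.frame(species = species, dbh_cm = c(20, 25, 15),
                   height_m = c(10, 12, 8), volume_m3 = volume,
                   stem_kg = stem_kg, branches_kg = branches_kg,
                   foliage_kg = foliage_kg)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a minimal noiseless two-species tree table
proportional_tree_data <- function(n = 6, bcef = c(stem = 0.4,
                                                   branches = 0.2,
                                                   foliage = 0.01)) {
  V <- seq(0.2, 2, length.out = n)
  tree_data(data.frame(
    species = rep(c("spA", "spB"), each = n),
    volume_m3 = rep(V, 2),
    w_stem = rep(bcef[["stem"]] * V, 2),
    w_branches = rep(bcef[["branches"]] * V, 2),
    w_foliage = rep(bcef[["foliage"]] * V, 2)
  ))
}
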