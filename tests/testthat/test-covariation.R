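test_that("correlation matrix equals the brute-force definition", {
  tab <- random_trait_table(36, seed = 1)
  m <- trait_matrix(tab)
  corr <- correlation_matrix(tab)
  oracle <- matrix(NA_real_, 9, 9)
  for (i in 1:9) for (j in 1:9) {
    x <- m[, i] - mean(m[, i]); y <- m[, j] - mean(m[, j])
    oracle[i, j] <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  }
  expect_equal(unname(corr$r), oracle, tolerance = 1e-12)
  expect_equal(unname(diag(corr$r)), rep(1, 9))
  # p-values from the t transform with n - 2 df
  r <- corr$r[1, 2]; n <- corr$n
  expect_equal(corr$p[1, 2],
               2 * pt(abs(r * sqrt((n - 2) / (1 - r^2))), n - 2,
                      lower.tail = FALSE))
})

test_that("exact linear dependence gives r = 1 with a vanishing p-value", {
  tab <- random_trait_table(20, p = 1, seed = 2)
  tab$t2 <- 2 * tab$t1
  corr <- correlation_matrix(tab)
  expect_equal(corr$r["t1", "t2"], 1)
  expect_lt(corr$p["t1", "t2"], 1e-12)
  expect_true(corr$sig["t1", "t2"])
})

test_that("constant traits are reported as missing correlations", {
  tab <- random_trait_table(15, p = 3, seed = 3)
  tab$t2 <- 4
  expect_warning(corr <- correlation_matrix(tab), "t2")
  expect_true(all(is.na(corr$r["t2", ])))
  expect_false(anyNA(corr$r["t1", "t3"]))
})

test_that("trait groups are the connected components of the thresholded correlation graph", {
  # two blocks + two independent traits -> exactly 4 groups
  withr::with_seed(5, {
    n <- 60
    f1 <- rnorm(n); f2 <- rnorm(n)
    tab <- data.frame(strain_id = sprintf("s%02d", rep(1:20, each = 3)),
                      species = "sp", replicate = rep(1:3, 20),
                      environment = "standard",
                      a1 = f1 + rnorm(n, 0, 0.2), a2 = f1 + rnorm(n, 0, 0.2),
                      a3 = f1 + rnorm(n, 0, 0.2),
                      b1 = f2 + rnorm(n, 0, 0.2), b2 = f2 + rnorm(n, 0, 0.2),
                      solo1 = rnorm(n), solo2 = rnorm(n))
  })
  scape <- build_traitscape(tab)
  corr <- correlation_matrix(tab)
  groups <- identify_trait_groups(corr, scape)
  expect_length(groups$groups, 4)
  membership <- groups$membership
  expect_length(unique(membership[c("a1", "a2", "a3")]), 1)
  expect_length(unique(membership[c("b1", "b2")]), 1)
  expect_false(membership[["solo1"]] == membership[["solo2"]])
  # threshold extremes
  everyone_alone <- identify_trait_groups(corr, scape, threshold = 0.999)
  expect_length(everyone_alone$groups, 7)
  expect_error(identify_trait_groups(corr, scape, threshold = 1.2),
               "threshold")
})

test_that("a fully correlated panel collapses to a single group", {
  tab <- random_trait_table(20, p = 1, seed = 6)
  for (k in 2:4) tab[[paste0("t", k)]] <- (1 + 0.5 * k) * tab$t1
  scape <- build_traitscape(tab)
  groups <- identify_trait_groups(correlation_matrix(tab), scape)
  expect_length(groups$groups, 1)
  expect_setequal(groups$groups[[1]], paste0("t", 1:4))
})

test_that("centroid distance implements the printed weighted formula", {
  expect_equal(centroid_distance(c(1, 2), c(1, 2), 58.3, 19.4), 0)
  expect_equal(centroid_distance(c(1, 0), c(0, 0), 58.3, 19.4), 58.3)
  expect_equal(centroid_distance(c(1, 1), c(0, 0), 58.3, 19.4),
               sqrt(58.3^2 + 19.4^2))
  expect_equal(centroid_distance(c(1, 1), c(0, 0), 58.3, 19.4), 61.443,
               tolerance = 1e-4)
  expect_error(centroid_distance(c(0, 0), c(1, 1), -1, 5))
})

test_that("centroid distance satisfies the metric axioms on random triples", {
  withr::with_seed(7, {
    for (i in 1:100) {
      x <- rnorm(2); y <- rnorm(2); z <- rnorm(2)
      a <- runif(1, 1, 100); b <- runif(1, 1, 100)
      dxy <- centroid_distance(x, y, a, b)
      dyx <- centroid_distance(y, x, a, b)
      dxz <- centroid_distance(x, z, a, b)
      dzy <- centroid_distance(z, y, a, b)
      expect_equal(dxy, dyx)
      expect_gte(dxy, 0)
      expect_lte(dxy, dxz + dzy + 1e-12)
    }
  })
  expect_equal(centroid_distance(c(1, 1), c(1, 1), 10, 10), 0)
  expect_gt(centroid_distance(c(1, 1), c(1, 1 + 1e-9), 10, 10), 0)
})

test_that("distance regression is exact on linear data and scale-invariant", {
  withr::with_seed(8, d_ref <- runif(78, 1, 10))
  reg <- suppressWarnings(distance_regression(d_ref, 3 * d_ref))
  expect_equal(reg$r_squared, 1)
  expect_equal(reg$adj_r_squared, 1)
  expect_equal(reg$slope, 3)
  withr::with_seed(9, d_alt <- d_ref + rnorm(78, 0, 2))
  r_pct <- distance_regression(d_ref * 100, d_alt)
  r_prop <- distance_regression(d_ref, d_alt / 7)
  expect_equal(r_pct$r_squared, r_prop$r_squared, tolerance = 1e-12)
  expect_equal(r_pct$adj_r_squared,
               1 - (1 - r_pct$r_squared) * 77 / 76, tolerance = 1e-12)
  expect_error(distance_regression(1:2, 1:2), "3 pairs")
})

test_that("recovery with the full trait set is perfect; representative subsets beat size-free ones", {
  sim <- simulate_trait_table(simulation_config(seed = 2))
  full_rec <- suppressWarnings(
    reduced_traitscape_recovery(sim$table, trait_names()))
  expect_equal(full_rec$regression$r_squared, 1, tolerance = 1e-9)
  r4 <- reduced_traitscape_recovery(
    sim$table, c("growth_rate", "cell_size", "ros", "etrmax"))
  rno <- reduced_traitscape_recovery(
    sim$table, c("growth_rate", "ros", "etrmax", "ik"))
  expect_gt(r4$regression$adj_r_squared, rno$regression$adj_r_squared)
  expect_error(reduced_traitscape_recovery(sim$table, "chl"), "at least 2")
})

test_that("genotype regression flags constant identity and detects coupled structure", {
  cfg <- simulation_config(seed = 4)
  sim <- simulate_trait_table(cfg)
  cen <- strain_centroids(build_traitscape(sim$table))
  flat <- matrix(95, 13, 13, dimnames = list(cen$strain_id, cen$strain_id))
  diag(flat) <- 100
  flat_fit <- genotype_phenotype_regression(flat, cen)
  # off-diagonal identity constant -> undefined slope
  expect_true(flat_fit$degenerate)
  expect_true(is.na(flat_fit$r_squared))
  coupled <- simulate_identity_matrix(cfg, mode = "coupled",
                                      factor_scores = sim$truth$factor_scores)
  fit <- genotype_phenotype_regression(coupled, cen)
  # identity built from factor distance predicts trait-scape distance well
  expect_gt(fit$r_squared, 0.5)
  expect_lt(fit$p_value, 0.01)
})

test_that("mantel permutation agrees qualitatively with the regression", {
  cfg <- simulation_config(seed = 5)
  sim <- simulate_trait_table(cfg)
  cen <- strain_centroids(build_traitscape(sim$table))
  coupled <- simulate_identity_matrix(cfg, mode = "coupled",
                                      factor_scores = sim$truth$factor_scores)
  mt <- mantel_identity_test(coupled, cen, n_perm = 199, seed = 1)
  expect_lt(mt$p_value, 0.05)
})
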