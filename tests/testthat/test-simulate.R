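test_that("zero replicate noise makes replicates of a strain identical", {
  sim <- simulate_trait_table(pinned_config(n_strains = 4))
  for (s in unique(sim$table$strain_id)) {
    reps <- trait_matrix(sim$table[sim$table$strain_id == s, ])
    expect_equal(max(apply(reps, 2, function(v) diff(range(v)))), 0)
  }
})

test_that("standard environment carries zero shift: pinned cultures sit at the trait means", {
  sim <- simulate_trait_table(pinned_config(n_strains = 3))
  units <- default_trait_units()
  for (tr in setdiff(trait_names(), "ik"))
    expect_equal(unique(sim$table[[tr]]), unname(units$mean[tr]))
  expect_equal(unique(sim$table$ik),
               unname(units$mean["etrmax"] / units$mean["alpha"]))
})

test_that("default panel has the designed shape and strong within-size-group correlation", {
  sim <- simulate_trait_table(simulation_config(seed = 1))
  expect_equal(nrow(sim$table), 13 * 3)
  expect_setequal(names(sim$table),
                  c("strain_id", "species", "replicate", "environment",
                    trait_names()))
  r <- cor(trait_matrix(sim$table))
  expect_gt(r["cell_size", "chl"], 0.8)
  size <- c("cell_size", "chl", "granularity", "lipid")
  expect_true(all(r[size, size] > 0.8))
})

test_that("identical configuration and seed reproduce the table exactly", {
  s1 <- simulate_trait_table(simulation_config(seed = 7))
  s2 <- simulate_trait_table(simulation_config(seed = 7))
  expect_identical(s1$table, s2$table)
  expect_identical(s1$truth$factor_scores, s2$truth$factor_scores)
  s3 <- simulate_trait_table(simulation_config(seed = 8))
  expect_false(identical(s1$table, s3$table))
})

test_that("config validation rejects degenerate designs", {
  expect_error(simulation_config(n_strains = 1), "2 strains")
  bad_sd <- default_replicate_noise_sd(); bad_sd["chl"] <- -0.1
  expect_error(simulation_config(replicate_noise_sd = bad_sd), "non-negative")
  L <- default_factor_loadings(); L[, 2] <- 2 * L[, 1]
  expect_error(simulation_config(factor_loadings = L), "collinear")
})

test_that("sample correlations converge to the implied matrix as noise vanishes", {
  cfg <- simulation_config(n_strains = 200,
                           replicate_noise_sd = default_replicate_noise_sd() * 0)
  sim <- simulate_trait_table(cfg)
  observed <- cor(trait_matrix(sim$table, cfg$linear_traits))
  implied <- implied_correlation(cfg)
  expect_lt(mean(abs(observed - implied[rownames(observed), colnames(observed)])),
            0.05)
})

test_that("noise-free plasticity shift reproduces the environment vector exactly", {
  cfg <- pinned_config(n_strains = 4)
  sim <- simulate_plasticity_shift(simulate_trait_table(cfg))
  units <- default_trait_units()
  std <- sim$table[sim$table$environment == "standard", ]
  for (env in names(cfg$env_shift_vectors)) {
    shift <- cfg$env_shift_vectors[[env]]
    treat <- sim$table[sim$table$environment == env, ]
    for (tr in names(shift)) {
      # latent-scale mean change per strain == the shared shift component
      tm <- tapply(treat[[tr]], treat$strain_id, mean)
      sm <- tapply(std[[tr]], std$strain_id, mean)[names(tm)]
      delta <- as.numeric(tm - sm) / units$scale[[tr]]
      expect_equal(delta, rep(unname(shift[[tr]]), length(delta)),
                   tolerance = 1e-9)
    }
  }
})

test_that("plasticity shift errors on unknown environments and keeps strains within the panel", {
  sim <- simulate_trait_table(simulation_config(seed = 1))
  expect_error(simulate_plasticity_shift(sim, environments = "volcano"),
               "no shift vector")
  expect_error(simulate_plasticity_shift(sim, strains = "strain_99"),
               "not present")
})

test_that("low-nutrient response reverses the chlorophyll/lipid relationship within every strain", {
  sim <- simulate_plasticity_shift(simulate_trait_table(simulation_config(seed = 1)))
  std <- sim$table[sim$table$environment == "standard", ]
  ln <- sim$table[sim$table$environment == "LN", ]
  # across strains (standard environment): positive chl-lipid correlation
  chl_m <- tapply(std$chl, std$strain_id, mean)
  lip_m <- tapply(std$lipid, std$strain_id, mean)
  expect_gt(cor(chl_m, lip_m), 0)
  # within each shifted strain: chl down, lipid up
  for (s in unique(ln$strain_id)) {
    expect_lt(mean(ln$chl[ln$strain_id == s]), chl_m[s])
    expect_gt(mean(ln$lipid[ln$strain_id == s]), lip_m[s])
  }
})

test_that("growth series follow the exact exponential in the noiseless limit", {
  params <- data.frame(culture_id = "c1", mu = 0.5, f0 = 100, days = 5)
  g <- simulate_growth_series(params, seed = 1)
  expect_equal(g$fluorescence, 100 * exp(0.5 * 0:5))
  flat <- simulate_growth_series(
    data.frame(culture_id = "c2", mu = 0, f0 = 50, days = 6), seed = 1)
  expect_equal(flat$fluorescence, rep(50, 7))
  n1 <- simulate_growth_series(transform(params, noise_sd = 0.05), seed = 3)
  n2 <- simulate_growth_series(transform(params, noise_sd = 0.05), seed = 3)
  expect_identical(n1, n2)
  expect_error(simulate_growth_series(
    data.frame(culture_id = "c", mu = 1, f0 = 10, days = 2)), "days")
})

test_that("simulated light curves follow the saturating tanh model", {
  params <- data.frame(culture_id = "c1", alpha = 0.3, etrmax = 60)
  lc <- simulate_light_curves(params, seed = 1)
  expect_equal(nrow(lc), 8)
  expect_equal(lc$etr[lc$irradiance == 140][1], 60 * tanh(0.3 * 140 / 60))
  # closed-form value at E = 200 on a custom grid
  lc2 <- simulate_light_curves(params, irradiance = c(50, 100, 200, 400, 800,
                                                      1000, 1200, 1400),
                               seed = 1)
  expect_equal(lc2$etr[lc2$irradiance == 200], 60 * tanh(1))
  # small-irradiance slope -> alpha; saturation -> etrmax
  lo <- simulate_light_curves(params, irradiance = c(1e-3, 1, 2, 3, 4, 5, 6, 7),
                              seed = 1)
  expect_equal(lo$etr[1] / 1e-3, 0.3, tolerance = 1e-6)
  hi <- simulate_light_curves(params, irradiance = seq(4000, 11000, 1000),
                              seed = 1)
  expect_equal(hi$etr[8], 60, tolerance = 1e-8)
  expect_error(simulate_light_curves(transform(params, alpha = -1)), "alpha")
})

test_that("identity matrices are symmetric with unit-diagonal 100", {
  cfg <- simulation_config(seed = 2)
  m <- simulate_identity_matrix(cfg)
  expect_equal(unname(diag(m)), rep(100, 13))
  expect_equal(m, t(m))
  expect_true(all(m[upper.tri(m)] >= cfg$identity_range[1] &
                  m[upper.tri(m)] <= cfg$identity_range[2]))
  expect_identical(m, simulate_identity_matrix(cfg))
})

test_that("coupled identity decreases monotonically with factor distance when noise-free", {
  cfg <- simulation_config(seed = 3)
  sim <- simulate_trait_table(cfg)
  m <- simulate_identity_matrix(cfg, mode = "coupled",
                                factor_scores = sim$truth$factor_scores)
  d <- as.matrix(dist(sim$truth$factor_scores))
  up <- upper.tri(m)
  expect_equal(cor(m[up], d[up], method = "spearman"), -1)
})

test_that("instrument CSV emitters round-trip through the documented schemas", {
  dir <- withr::local_tempdir()
  cfg <- quiet_instruments(seed = 5, n_strains = 4)
  sim <- simulate_trait_table(cfg)
  idm <- simulate_identity_matrix(cfg)
  paths <- write_simulation(sim, dir, identity = idm)
  expect_true(all(file.exists(paths)))
  expect_equal(read_identity_csv(paths["identity"]), idm)
  traits_in <- utils::read.csv(paths["traits"])
  expect_equal(trait_matrix(traits_in), trait_matrix(sim$table))
})
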