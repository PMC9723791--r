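test_that("step growth rates implement the log-difference quotient", {
  doubling <- data.frame(day = 0:1, fluorescence = c(100, 200))
  expect_equal(step_growth_rates(doubling)$rate, log(2))
  flat <- data.frame(day = 0:4, fluorescence = rep(7, 5))
  expect_equal(step_growth_rates(flat)$rate, rep(0, 4))
  expo <- data.frame(day = 0:6, fluorescence = 10 * exp(0.5 * 0:6))
  expect_equal(step_growth_rates(expo)$rate, rep(0.5, 6))
  bad <- data.frame(day = 0:2, fluorescence = c(10, -1, 5))
  expect_error(step_growth_rates(bad), "day 1")
  expect_error(step_growth_rates(data.frame(day = c(0, 0, 1),
                                            fluorescence = c(1, 2, 3))),
               "strictly increasing")
})

test_that("maximum growth rate scans 2-4 step windows with earliest-window ties", {
  expo <- data.frame(day = 0:6, fluorescence = 10 * exp(0.5 * 0:6))
  expect_equal(as.numeric(max_growth_rate(expo)), 0.5)
  # step rates (0.1, 0.6, 0.7, 0.1): best window is mean(0.6, 0.7)
  f <- 100 * exp(cumsum(c(0, 0.1, 0.6, 0.7, 0.1)))
  series <- data.frame(day = 0:4, fluorescence = f)
  expect_equal(as.numeric(max_growth_rate(series)), 0.65)
  expect_equal(attr(max_growth_rate(series), "start"), 2L)
  expect_equal(attr(max_growth_rate(series), "length"), 2L)
  # exactly 3 points: the single 2-step window is forced
  three <- data.frame(day = 0:2, fluorescence = c(10, 30, 40))
  expect_equal(as.numeric(max_growth_rate(three)),
               mean(diff(log(c(10, 30, 40)))))
  expect_error(max_growth_rate(data.frame(day = 0:1,
                                          fluorescence = c(1, 2))),
               "at least 2")
})

test_that("maximum growth rate equals the brute-force window search on random series", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(4:12, 1)
      f <- exp(cumsum(rnorm(n, 0.2, 0.5)))
      series <- data.frame(day = seq_len(n) - 1, fluorescence = f)
      rates <- step_growth_rates(series)$rate
      expect_equal(as.numeric(max_growth_rate(series)),
                   brute_force_max_rate(rates))
    }
  })
})

test_that("ESD conversion reproduces the built-in calibration arithmetic", {
  expect_equal(fsc_to_esd(566254), (566254 + 194636) / 75775)
  expect_equal(fsc_to_esd(566254), 10.0414, tolerance = 1e-4)
  expect_equal(fsc_to_esd(0), 194636 / 75775)
  # strictly increasing in FSC
  fsc <- seq(0, 2e6, length.out = 50)
  expect_true(all(diff(fsc_to_esd(fsc)) > 0))
  expect_warning(out <- fsc_to_esd(-4e5), "below the calibration range")
  expect_true(is.na(out))
})

test_that("bead calibration refit on exact data recovers the diameters", {
  d <- c(2, 4, 6, 10, 15)
  fsc <- 75775 * d - 194636
  cal <- bead_calibration(d, fsc)
  expect_equal(cal$slope, 75775)
  expect_equal(cal$intercept, -194636)
  expect_equal(fsc_to_esd(fsc, cal), d)
  expect_error(bead_calibration(c(2, 2), c(1, 2)), "distinct")
})

test_that("flow-cytometry traits follow the size-normalized differencing rules", {
  s <- data.frame(chl_median = 50, ssc_median = 30, prestain_median = 400,
                  poststain_median = 400, ros_stained = 3000,
                  ros_blank = 1000, cell_count = 100)
  tr <- derive_fcm_traits(s, esd = 5)
  expect_equal(tr$chl, 10)
  expect_equal(tr$lipid, 0)          # poststain == prestain
  tr2 <- derive_fcm_traits(transform(s, poststain_median = 650), esd = 4)
  expect_equal(tr2$ros, ((3000 - 1000) / 100) / 4)  # = 5
  expect_equal(tr2$lipid, 250 / 4)
  # negative differences preserved, not clipped
  tr3 <- derive_fcm_traits(transform(s, poststain_median = 300), esd = 5)
  expect_equal(tr3$lipid, -20)
  expect_error(derive_fcm_traits(transform(s, cell_count = 0), esd = 5),
               "cell_count")
  # all per-size traits scale as 1/esd
  expect_equal(unlist(derive_fcm_traits(transform(s, poststain_median = 650),
                                        esd = 8)[c("chl", "granularity",
                                                   "lipid", "ros")]),
               unlist(tr2[c("chl", "granularity", "lipid", "ros")]) / 2)
})

test_that("light-curve fit recovers tanh parameters exactly on noiseless curves", {
  E <- c(25, 45, 80, 140, 240, 420, 740, 1300)
  etr <- 60 * tanh(0.3 * E / 60)
  fit <- fit_light_curve(E, etr)
  expect_true(fit$converged)
  expect_equal(fit$alpha, 0.3, tolerance = 1e-6)
  expect_equal(fit$etrmax, 60, tolerance = 1e-6)
  expect_equal(fit$ik, 200, tolerance = 1e-6)
  expect_error(fit_light_curve(E, rep(0, 8)), "identically zero")
  expect_error(fit_light_curve(E[1:3], etr[1:3]), "at least 4")
})

test_that("light-curve fit is scale-equivariant in ETR", {
  E <- c(25, 45, 80, 140, 240, 420, 740, 1300)
  etr <- 45 * tanh(0.25 * E / 45)
  f1 <- fit_light_curve(E, etr)
  f2 <- fit_light_curve(E, 3 * etr)
  expect_equal(f2$alpha, 3 * f1$alpha, tolerance = 1e-6)
  expect_equal(f2$etrmax, 3 * f1$etrmax, tolerance = 1e-6)
  expect_equal(f2$ik, f1$ik, tolerance = 1e-6)
})

test_that("Eilers-Peeters fit recovers its own parameterization", {
  E <- c(25, 45, 80, 140, 240, 420, 740, 1300)
  a <- 1e-5; b <- 5e-3; cc <- 3
  etr <- E / (a * E^2 + b * E + cc)
  fit <- fit_light_curve(E, etr, model = "eilers")
  expect_true(fit$converged)
  expect_equal(fit$alpha, 1 / cc, tolerance = 1e-5)
  expect_equal(fit$etrmax, 1 / (b + 2 * sqrt(a * cc)), tolerance = 1e-5)
})

test_that("derivation round-trips the noiseless synthetic instruments exactly", {
  cfg <- quiet_instruments(seed = 3)
  sim <- simulate_trait_table(cfg)
  inst <- simulate_instrument_data(sim)
  der <- derive_trait_table(inst$cultures, inst$growth, inst$light_curves,
                            inst$fcm, beads = inst$beads)
  expect_equal(trait_matrix(der), trait_matrix(sim$table), tolerance = 1e-8)
  # and through the CSV layer
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  der2 <- derive_trait_table_dir(dir)
  expect_equal(trait_matrix(der2), trait_matrix(sim$table), tolerance = 1e-6)
})
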