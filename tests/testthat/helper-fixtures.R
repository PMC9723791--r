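# shared fixtures: everything is generated in code at test time

# a deterministic generator config with all noise silenced and strain factor
# scores pinned at zero: every culture sits exactly at the trait means
pinned_config <- function(n_strains = 5, seed = 1, ...) {
  zero_sd <- default_replicate_noise_sd() * 0
  simulation_config(
    n_strains = n_strains,
    strain_factor_means = matrix(0, n_strains, 3),
    replicate_noise_sd = zero_sd,
    env_shift_noise_sd = 0,
    seed = seed, ...)
}

# noiseless instruments for exact derivation round trips
quiet_instruments <- function(seed = 1, n_strains = 6) {
  simulation_config(
    n_strains = n_strains, seed = seed,
    growth = list(f0 = 100, days = 8, noise_sd = 0),
    light = list(irradiance = c(25, 45, 80, 140, 240, 420, 740, 1300),
                 noise_sd = 0))
}

# random trait table with the canonical metadata columns
random_trait_table <- function(n = 36, p = 9, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("t", seq_len(p))))
    data.frame(strain_id = sprintf("s%02d", rep(seq_len(ceiling(n / 3)),
                                                each = 3)[seq_len(n)]),
               species = "sp", replicate = rep_len(1:3, n),
               environment = "standard", m)
  })
}

# brute-force oracle for the windowed maximum growth rate
brute_force_max_rate <- function(rates, lengths = 2:4) {
  best <- -Inf
  for (len in lengths) {
    if (len > length(rates)) next
    for (start in seq_len(length(rates) - len + 1))
      best <- max(best, mean(rates[start:(start + len - 1)]))
  }
  best
}
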