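#' Simulate daily fluorescence growth series
#'
#' Generates `F(t) = F0 * exp(mu * t) * (1 + noise)` at days `0..days`, with
#' an optional lag phase (no growth before `lag` days) and an optional plateau
#' (fluorescence capped at `plateau`). The noiseless series is exactly
#' exponential.
#'
#' @param params data frame with columns `culture_id`, `mu` (d^-1), `f0`
#'   (> 0), `days` (>= 4), and optionally `noise_sd`, `lag`, `plateau`
#' @param seed integer seed; the same seed reproduces the series exactly
#' @return data frame `culture_id`, `day`, `fluorescence`
#' @export
simulate_growth_series <- function(params, seed = 1L) {
  stopifnot(is.data.frame(params),
            all(c("culture_id", "mu", "f0", "days") %in% names(params)))
  check_that(
    "mu must be finite" = all(is.finite(params$mu)),
    "f0 must be > 0" = all(params$f0 > 0),
    "days must be >= 4 (need at least a 2-step growth window)" =
      all(params$days >= 4))
  noise_sd <- params$noise_sd %||% rep(0, nrow(params))
  if (is.null(params$noise_sd)) params$noise_sd <- 0
  if (is.null(params$lag)) params$lag <- 0
  if (is.null(params$plateau)) params$plateau <- Inf
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      t <- 0:p$days
      f <- p$f0 * exp(p$mu * pmax(t - p$lag, 0))
      f <- pmin(f, p$plateau)
      if (p$noise_sd > 0)
        f <- f * pmax(1 + stats::rnorm(length(t), 0, p$noise_sd), 1e-6)
      data.frame(culture_id = p$culture_id, day = t, fluorescence = f)
    })
    do.call(rbind, out)
  })
}

#' Simulate rapid light curves
#'
#' Eight increasing irradiance steps per culture; the relative electron
#' transport rate follows the saturating tanh model
#' `ETR(E) = ETRmax * tanh(alpha * E / ETRmax)` plus additive Gaussian noise.
#'
#' @param params data frame with columns `culture_id`, `alpha` (> 0),
#'   `etrmax` (> 0) and optionally `noise_sd`
#' @param irradiance strictly increasing vector of irradiance steps
#'   (umol photons m^-2 s^-1)
#' @param seed integer seed
#' @return data frame `culture_id`, `step`, `irradiance`, `etr`
#' @export
simulate_light_curves <- function(params,
                                  irradiance = c(25, 45, 80, 140, 240, 420, 740, 1300),
                                  seed = 1L) {
  stopifnot(is.data.frame(params),
            all(c("culture_id", "alpha", "etrmax") %in% names(params)))
  check_that(
    "alpha must be > 0" = all(params$alpha > 0),
    "etrmax must be > 0" = all(params$etrmax > 0),
    "irradiance must be strictly increasing" = all(diff(irradiance) > 0))
  if (is.null(params$noise_sd)) params$noise_sd <- 0
  withr::with_seed(as.integer(seed), {
    out <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      etr <- p$etrmax * tanh(p$alpha * irradiance / p$etrmax)
      if (p$noise_sd > 0)
        etr <- etr + stats::rnorm(length(irradiance), 0, p$noise_sd)
      data.frame(culture_id = p$culture_id, step = seq_along(irradiance),
                 irradiance = irradiance, etr = etr)
    })
    do.call(rbind, out)
  })
}

#' Generate the full instrument-level dataset for a simulated experiment
#'
#' Inverts the trait-derivation equations so that running the derivation
#' module on the returned instrument data reproduces the simulated trait
#' table: growth series are exponential with the table's growth rate, light
#' curves use the table's alpha and ETRmax, the forward-scatter median is
#' `slope * ESD + intercept`, per-cell fluorescence medians are
#' `trait * ESD`, and the ROS channel is inverted through the cell count.
#' Instrument noise defaults to zero here (replicate noise already lives in
#' the trait table); the `growth`/`light` config entries control it.
#'
#' @param sim a `trait_sim`
#' @return list of data frames: `cultures`, `growth`, `light_curves`, `beads`,
#'   `fcm`
#' @export
simulate_instrument_data <- function(sim) {
  stopifnot(inherits(sim, "trait_sim"))
  config <- sim$config
  tab <- sim$table
  cid <- culture_id(tab$strain_id, tab$environment, tab$replicate)
  cultures <- data.frame(culture_id = cid, tab[.meta_cols], row.names = NULL)

  growth <- simulate_growth_series(
    data.frame(culture_id = cid, mu = tab$growth_rate,
               f0 = config$growth$f0, days = config$growth$days,
               noise_sd = config$growth$noise_sd %||% 0),
    seed = sim_seed(config, "growth"))
  light <- simulate_light_curves(
    data.frame(culture_id = cid, alpha = tab$alpha, etrmax = tab$etrmax,
               noise_sd = config$light$noise_sd %||% 0),
    irradiance = config$light$irradiance, seed = sim_seed(config, "light"))

  b <- config$beads
  fsc_bead <- b$slope * b$diameter_um + b$intercept
  if ((b$noise_sd %||% 0) > 0)
    fsc_bead <- withr::with_seed(sim_seed(config, "fcm"),
      fsc_bead + stats::rnorm(length(fsc_bead), 0, b$noise_sd))
  beads <- data.frame(diameter_um = b$diameter_um, fsc_median = fsc_bead)

  esd <- tab$cell_size
  prestain <- 420                      # arbitrary background stain level
  ros_blank <- 900
  cell_count <- 5000L
  fcm <- data.frame(
    culture_id = cid,
    fsc_median = b$slope * esd + b$intercept,
    chl_median = tab$chl * esd,
    ssc_median = tab$granularity * esd,
    prestain_median = prestain,
    poststain_median = prestain + tab$lipid * esd,
    ros_stained = ros_blank + tab$ros * cell_count * esd,
    ros_blank = ros_blank,
    cell_count = cell_count)
  list(cultures = cultures, growth = growth, light_curves = light,
       beads = beads, fcm = fcm)
}

#' Write a simulated experiment to CSV files
#'
#' Emits the canonical CSV schemas consumed by the pipeline: `traits.csv`,
#' `cultures.csv`, `growth.csv`, `light_curves.csv`, `beads.csv`, `fcm.csv`
#' and, when an identity matrix is supplied, `identity.csv` (long format:
#' `strain_a`, `strain_b`, `pct_identity`).
#'
#' @param sim a `trait_sim`
#' @param dir output directory (created if needed)
#' @param identity optional strain x strain percent-identity matrix
#' @return invisibly, the paths written
#' @export
write_simulation <- function(sim, dir, identity = NULL) {
  stopifnot(inherits(sim, "trait_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  inst <- simulate_instrument_data(sim)
  paths <- c(traits = file.path(dir, "traits.csv"),
             cultures = file.path(dir, "cultures.csv"),
             growth = file.path(dir, "growth.csv"),
             light_curves = file.path(dir, "light_curves.csv"),
             beads = file.path(dir, "beads.csv"),
             fcm = file.path(dir, "fcm.csv"))
  utils::write.csv(sim$table, paths["traits"], row.names = FALSE)
  for (nm in setdiff(names(paths), "traits"))
    utils::write.csv(inst[[nm]], paths[[nm]], row.names = FALSE)
  if (!is.null(identity)) {
    up <- which(upper.tri(identity), arr.ind = TRUE)
    long <- data.frame(strain_a = rownames(identity)[up[, 1]],
                       strain_b = colnames(identity)[up[, 2]],
                       pct_identity = identity[up])
    p <- file.path(dir, "identity.csv")
    utils::write.csv(long, p, row.names = FALSE)
    paths <- c(paths, identity = p)
  }
  invisible(paths)
}

#' Read a pairwise identity matrix from the long CSV schema
#'
#' @param path CSV with columns `strain_a`, `strain_b`, `pct_identity`
#' @return symmetric matrix with 100 on the diagonal
#' @export
read_identity_csv <- function(path) {
  long <- utils::read.csv(path)
  stopifnot(all(c("strain_a", "strain_b", "pct_identity") %in% names(long)))
  ids <- sort(unique(c(long$strain_a, long$strain_b)))
  m <- matrix(100, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(long))) {
    m[long$strain_a[i], long$strain_b[i]] <- long$pct_identity[i]
    m[long$strain_b[i], long$strain_a[i]] <- long$pct_identity[i]
  }
  m
}
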