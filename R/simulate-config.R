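#' Canonical trait names
#'
#' The nine phenotypic traits handled by the pipeline, in canonical order:
#' exponential growth rate (d^-1), cell size (equivalent spherical diameter,
#' um), chlorophyll-a fluorescence per ESD, side scatter ("granularity") per
#' ESD, neutral lipid stain fluorescence per ESD, reactive oxygen species
#' signal per cell per ESD, and the three photophysiological parameters of the
#' rapid light curve: alpha (light-limited slope), ETRmax (maximum relative
#' electron transport rate) and Ik = ETRmax/alpha (saturation irradiance,
#' umol photons m^-2 s^-1).
#'
#' @export
trait_names <- function() {
  c("growth_rate", "cell_size", "chl", "granularity", "lipid",
    "ros", "alpha", "etrmax", "ik")
}

# default strain-level factor loadings (8 linear traits x 3 latent factors).
# Factor 1 is the cell-size axis, factor 2 the photophysiology axis, factor 3
# an axis of growth-rate variation largely independent of the other two.
# Magnitudes are calibrated so that the implied standardized correlation
# structure matches the covariance regime reported for a 13-strain
# Thalassiosira panel: within-group correlations ~0.9 for the size-related
# traits and ~0.75-0.8 among photophysiology traits, ROS moderately tied to
# the photophysiology axis (r ~ 0.6, below the 0.7 grouping threshold), growth
# rate weakly correlated with everything, a two-axis variance share near 78%,
# and a wider strain spread along the size axis than along the others.
# Ik is not a row here: it is emergent as ETRmax/alpha (see simulate_trait_table).
default_factor_loadings <- function() {
  L <- rbind(
    growth_rate = c(-0.25, 0.22, 0.46),
    cell_size   = c( 1.55, 0.28, 0.00),
    chl         = c( 1.58, 0.11, 0.05),
    granularity = c( 1.52, 0.28, 0.10),
    lipid       = c( 1.47, 0.27, 0.05),
    ros         = c(-0.20, 0.78, 0.05),
    alpha       = c(-0.55, 0.83, 0.12),
    etrmax      = c(-0.95, 1.10, 0.00))
  colnames(L) <- c("size_axis", "photo_axis", "growth_axis")
  L
}

# replicate-level measurement noise, sd on the latent (standardized-ish) scale;
# instrument-noisy assays (ROS, alpha) get substantially more
default_replicate_noise_sd <- function() {
  c(growth_rate = 0.45, cell_size = 0.32, chl = 0.26, granularity = 0.25,
    lipid = 0.41, ros = 0.79, alpha = 0.71, etrmax = 0.33)
}

# affine map latent -> natural units (natural = mean + scale * latent);
# PCA re-standardizes, so these only set realistic instrument scales
default_trait_units <- function() {
  list(
    mean = c(growth_rate = 0.9, cell_size = 9.5, chl = 260, granularity = 150,
             lipid = 85, ros = 14, alpha = 0.30, etrmax = 58),
    scale = c(growth_rate = 0.18, cell_size = 2.6, chl = 60, granularity = 35,
              lipid = 20, ros = 3.5, alpha = 0.05, etrmax = 10))
}

# mean trait shifts (latent units) shared across strains, per treatment
# environment. HT: high temperature/light -- photophysiology up, chlorophyll
# down, ROS up. LN: low nutrients -- growth and photophysiology down,
# chlorophyll strongly down while lipids go up (the within-strain sign
# reversal of the chl/lipid trade-off), ROS up.
default_env_shifts <- function() {
  list(
    HT = c(growth_rate = 0.3, cell_size = -0.5, chl = -0.7, granularity = -0.4,
           lipid = 0.4, ros = 0.9, alpha = 0.6, etrmax = 1.5),
    LN = c(growth_rate = -0.9, cell_size = -0.4, chl = -1.2, granularity = -0.3,
           lipid = 1.1, ros = 0.7, alpha = -0.7, etrmax = -1.1))
}

#' Grouping of traits into a priori functional groups
#'
#' @return named character vector mapping trait name to group label
#' @export
trait_group_truth <- function() {
  c(growth_rate = "growth", cell_size = "size", chl = "size",
    granularity = "size", lipid = "size", ros = "ros",
    alpha = "photophysiology", etrmax = "photophysiology",
    ik = "photophysiology")
}

#' Configuration for the synthetic phenotyping experiment
#'
#' Defines a simulated culturing experiment: `n_strains` strains grown in
#' `n_replicates` replicate cultures, phenotyped for the nine canonical traits
#' (see [trait_names()]). Strain-level trait means follow a linear latent
#' factor model `latent = loadings %*% factor_scores + env_shift`; replicate
#' cultures add independent Gaussian measurement noise; Ik is derived as
#' ETRmax/alpha in natural units so the table is exactly consistent with the
#' photosynthesis-irradiance fit definition.
#'
#' @param n_strains number of strains (>= 2)
#' @param n_replicates replicate cultures per strain x environment
#' @param factor_loadings traits x factors loading matrix for the 8 linear
#'   traits (Ik is emergent); rows must be named
#' @param strain_factor_means optional `n_strains` x factors matrix of latent
#'   factor scores; default: drawn N(0,1) from `seed`
#' @param replicate_noise_sd per-trait replicate noise sd (latent scale),
#'   non-negative
#' @param env_shift_vectors named list, one per treatment environment, of
#'   per-trait mean shifts on the latent scale (shared across strains). The
#'   standard environment is implicit with zero shift.
#' @param env_shift_noise_sd sd of the strain-specific deviation around each
#'   environment's shared shift vector
#' @param trait_units list with `mean` and `scale` vectors mapping the latent
#'   scale to natural instrument units
#' @param n_treatment_strains how many strains (the first ones) are grown in
#'   the treatment environments
#' @param growth list: `f0` starting fluorescence, `days` series length,
#'   `noise_sd` multiplicative noise sd for simulated growth series
#' @param light list: `irradiance` vector of 8 increasing irradiance steps,
#'   `noise_sd` additive ETR noise for simulated rapid light curves
#' @param beads list: `diameter_um` bead diameters, `slope`, `intercept` of
#'   the FSC-vs-ESD line, `noise_sd` FSC noise (defaults use the built-in
#'   calibration constants, see [esd_calibration()])
#' @param identity_range percent-identity bounds for the simulated pairwise
#'   genetic identity matrix
#' @param seed master seed; all randomness derives from it
#' @return object of class `sim_config`
#' @seealso [simulate_trait_table()], [simulate_instrument_data()]
#' @export
simulation_config <- function(n_strains = 13,
                              n_replicates = 3,
                              factor_loadings = default_factor_loadings(),
                              strain_factor_means = NULL,
                              replicate_noise_sd = default_replicate_noise_sd(),
                              env_shift_vectors = default_env_shifts(),
                              env_shift_noise_sd = 0.15,
                              trait_units = default_trait_units(),
                              n_treatment_strains = 5,
                              growth = list(f0 = 100, days = 8, noise_sd = 0.03),
                              light = list(irradiance = c(25, 45, 80, 140, 240, 420, 740, 1300),
                                           noise_sd = 0.8),
                              beads = list(diameter_um = c(2, 4, 6, 10, 15),
                                           slope = 75775, intercept = -194636,
                                           noise_sd = 0),
                              identity_range = c(85, 99.5),
                              seed = 1L) {
  linear_traits <- setdiff(trait_names(), "ik")
  factor_loadings <- as.matrix(factor_loadings)
  check_that(
    "need at least 2 strains" = n_strains >= 2,
    "n_replicates must be >= 1" = n_replicates >= 1,
    "factor_loadings rows must be named with the linear traits" =
      setequal(rownames(factor_loadings), linear_traits),
    "replicate_noise_sd must be named, non-negative and finite" =
      setequal(names(replicate_noise_sd), linear_traits) &&
      all(is.finite(replicate_noise_sd)) && all(replicate_noise_sd >= 0),
    "env_shift_noise_sd must be non-negative" = env_shift_noise_sd >= 0,
    "identity_range must be increasing within [0, 100]" =
      length(identity_range) == 2 && identity_range[1] < identity_range[2] &&
      identity_range[1] >= 0 && identity_range[2] <= 100,
    "seed must be a single finite number" = length(seed) == 1 && is.finite(seed))
  factor_loadings <- factor_loadings[linear_traits, , drop = FALSE]
  if (qr(factor_loadings)$rank < ncol(factor_loadings))
    stop("factor_loadings columns are collinear")
  for (env in names(env_shift_vectors)) {
    v <- env_shift_vectors[[env]]
    if (!setequal(names(v), linear_traits))
      stop("env_shift_vectors[['", env, "']] must be named with the linear traits")
    env_shift_vectors[[env]] <- v[linear_traits]
  }
  if (!is.null(strain_factor_means)) {
    strain_factor_means <- as.matrix(strain_factor_means)
    stopifnot(nrow(strain_factor_means) == n_strains,
              ncol(strain_factor_means) == ncol(factor_loadings))
  }
  replicate_noise_sd <- replicate_noise_sd[linear_traits]
  structure(list(
    n_strains = as.integer(n_strains), n_replicates = as.integer(n_replicates),
    trait_names = trait_names(), linear_traits = linear_traits,
    factor_loadings = factor_loadings, strain_factor_means = strain_factor_means,
    replicate_noise_sd = replicate_noise_sd,
    env_shift_vectors = env_shift_vectors, env_shift_noise_sd = env_shift_noise_sd,
    trait_units = trait_units, n_treatment_strains = as.integer(n_treatment_strains),
    growth = growth, light = light, beads = beads,
    identity_range = identity_range, seed = as.integer(seed)),
    class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic phenotyping experiment configuration\n")
  cat(sprintf("  %d strains x %d replicates, traits: %s\n", x$n_strains,
              x$n_replicates, paste(x$trait_names, collapse = ", ")))
  cat(sprintf("  latent factors: %s\n",
              paste(colnames(x$factor_loadings), collapse = ", ")))
  cat(sprintf("  treatment environments: %s (first %d strains)\n",
              paste(names(x$env_shift_vectors), collapse = ", "),
              x$n_treatment_strains))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Population trait correlation matrix implied by a configuration
#'
#' The standardized strain-plus-replicate covariance implied by the linear part
#' of the factor model: `loadings %*% t(loadings) + diag(replicate_noise_sd^2)`,
#' converted to a correlation matrix. Covers the 8 linear traits only (Ik is a
#' nonlinear function of alpha and ETRmax).
#'
#' @param config a [simulation_config()]
#' @return correlation matrix over the linear traits
#' @export
implied_correlation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$factor_loadings
  S <- L %*% t(L) + diag(config$replicate_noise_sd^2)
  stats::cov2cor(S)
}
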