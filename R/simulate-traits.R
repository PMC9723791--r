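# child-seed positions in the master split; one documented stream per stage
.seed_slots <- c(factors = 1L, table = 2L, plasticity = 3L, growth = 4L,
                 light = 5L, fcm = 6L, identity = 7L)

sim_seed <- function(config, slot) {
  split_seed(config$seed, max(.seed_slots))[[.seed_slots[[slot]]]]
}

# natural-unit floors: sizes and P-I parameters must stay positive for the
# downstream instrument inversion; other traits may legitimately go negative
.natural_floor <- c(cell_size = 0.5, alpha = 0.02, etrmax = 2)

latent_to_natural <- function(latent, units) {
  nat <- sweep(sweep(latent, 2, units$scale[colnames(latent)], "*"),
               2, units$mean[colnames(latent)], "+")
  for (tr in intersect(names(.natural_floor), colnames(nat)))
    nat[, tr] <- pmax(nat[, tr], .natural_floor[[tr]])
  nat
}

strain_ids <- function(n) sprintf("strain_%02d", seq_len(n))

# culture identifier used across the instrument-level CSV schemas
culture_id <- function(strain, environment, replicate)
  paste(strain, environment, replicate, sep = ".")

#' Simulate a strains x replicates trait table with known ground truth
#'
#' Draws strain-level latent factor scores (unless supplied), forms strain
#' trait means through the loading matrix, adds replicate measurement noise,
#' maps to natural units and appends the emergent trait Ik = ETRmax/alpha.
#' All cultures are in the `"standard"` environment (zero environmental shift);
#' see [simulate_plasticity_shift()] for treatments.
#'
#' @param config a [simulation_config()]
#' @return list of class `trait_sim` with elements `table` (the trait table),
#'   `truth` (factor scores, strain latent means, group assignment, shift
#'   vectors) and `config`
#' @examples
#' sim <- simulate_trait_table(simulation_config(seed = 42))
#' head(sim$table)
#' @export
simulate_trait_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$factor_loadings
  nS <- config$n_strains; nR <- config$n_replicates
  f <- config$strain_factor_means
  if (is.null(f)) {
    f <- withr::with_seed(sim_seed(config, "factors"),
                          matrix(stats::rnorm(nS * ncol(L)), nS, ncol(L)))
  }
  dimnames(f) <- list(strain_ids(nS), colnames(L))
  strain_means <- f %*% t(L)                      # nS x 8, latent scale
  eps <- withr::with_seed(sim_seed(config, "table"),
    sapply(config$replicate_noise_sd,
           function(s) stats::rnorm(nS * nR, 0, s)))
  latent <- strain_means[rep(seq_len(nS), each = nR), , drop = FALSE] + eps
  nat <- latent_to_natural(latent, config$trait_units)
  tab <- data.frame(
    strain_id = rep(strain_ids(nS), each = nR),
    species = rep(sprintf("species_%02d", ((seq_len(nS) - 1L) %% 7L) + 1L),
                  each = nR),
    replicate = rep(seq_len(nR), nS),
    environment = "standard",
    nat, row.names = NULL)
  tab$ik <- tab$etrmax / tab$alpha
  tab <- tab[, c(.meta_cols, trait_names())]
  structure(list(
    table = tab,
    truth = list(factor_scores = f, strain_latent_means = strain_means,
                 group_assignment = trait_group_truth(),
                 env_shift_vectors = config$env_shift_vectors,
                 realized_env_shifts = list()),
    config = config), class = "trait_sim")
}

#' @export
print.trait_sim <- function(x, ...) {
  cat(sprintf("Synthetic trait data: %d cultures (%d strains), environments: %s\n",
              nrow(x$table), length(unique(x$table$strain_id)),
              paste(unique(x$table$environment), collapse = ", ")))
  invisible(x)
}

#' Append treatment-environment cultures to a simulated trait table
#'
#' For each requested strain and treatment environment, the strain's latent
#' mean is displaced by the environment's shared shift vector plus a
#' strain-specific deviation (sd `env_shift_noise_sd`), then replicate noise
#' is added as in the standard environment. The realized per-strain shift
#' vectors are stored in `truth$realized_env_shifts`.
#'
#' @param sim a `trait_sim` from [simulate_trait_table()]
#' @param environments treatment environments to simulate (default: all
#'   configured shift vectors)
#' @param strains strain ids to grow in the treatments (default: the first
#'   `n_treatment_strains` of the panel)
#' @return the `trait_sim` with treatment rows appended
#' @export
simulate_plasticity_shift <- function(sim, environments = NULL, strains = NULL) {
  stopifnot(inherits(sim, "trait_sim"))
  config <- sim$config
  environments <- environments %||% names(config$env_shift_vectors)
  unknown <- setdiff(environments, names(config$env_shift_vectors))
  if (length(unknown))
    stop("no shift vector configured for environment(s): ",
         paste(unknown, collapse = ", "))
  strains <- strains %||% strain_ids(config$n_strains)[
    seq_len(min(config$n_treatment_strains, config$n_strains))]
  if (!all(strains %in% sim$table$strain_id))
    stop("strains not present in the base table")
  nR <- config$n_replicates
  p <- length(config$linear_traits)
  species <- sim$table$species[match(strains, sim$table$strain_id)]
  blocks <- withr::with_seed(sim_seed(config, "plasticity"), {
    lapply(environments, function(env) {
      shift <- config$env_shift_vectors[[env]]
      lapply(seq_along(strains), function(i) {
        s <- strains[i]
        delta <- shift + stats::rnorm(p, 0, config$env_shift_noise_sd)
        names(delta) <- config$linear_traits
        base <- sim$truth$strain_latent_means[s, ]
        latent <- matrix(rep(base + delta, each = nR), nR, p,
                         dimnames = list(NULL, config$linear_traits)) +
          sapply(config$replicate_noise_sd,
                 function(sd) stats::rnorm(nR, 0, sd))
        nat <- latent_to_natural(latent, config$trait_units)
        tab <- data.frame(strain_id = s, species = species[i],
                          replicate = seq_len(nR), environment = env, nat,
                          row.names = NULL)
        tab$ik <- tab$etrmax / tab$alpha
        list(rows = tab[, c(.meta_cols, trait_names())], delta = delta)
      })
    })
  })
  for (e in seq_along(environments)) {
    env <- environments[e]
    deltas <- do.call(rbind, lapply(blocks[[e]], `[[`, "delta"))
    rownames(deltas) <- strains
    sim$truth$realized_env_shifts[[env]] <- deltas
    sim$table <- rbind(sim$table,
                       do.call(rbind, lapply(blocks[[e]], `[[`, "rows")))
  }
  rownames(sim$table) <- NULL
  sim
}

#' Simulate a pairwise percent-identity matrix over the strain panel
#'
#' In `"independent"` mode (the null structure: genetic relatedness carries no
#' information about phenotype), off-diagonal identities are drawn uniformly
#' within `identity_range`, independently of the latent factors. In
#' `"coupled"` mode identity decreases linearly with the distance between
#' strain factor scores (plus optional noise), for power checks.
#'
#' @param config a [simulation_config()]
#' @param mode `"independent"` or `"coupled"`
#' @param factor_scores strains x factors matrix, required for `"coupled"`
#'   (use `sim$truth$factor_scores`)
#' @param coupling_noise_sd sd of identity noise in coupled mode
#' @param seed optional override of the derived child seed
#' @return symmetric percent-identity matrix with 100 on the diagonal
#' @export
simulate_identity_matrix <- function(config, mode = c("independent", "coupled"),
                                     factor_scores = NULL,
                                     coupling_noise_sd = 0, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mode <- match.arg(mode)
  nS <- config$n_strains
  if (nS < 3) stop("need at least 3 strains for a pairwise identity matrix")
  lo <- config$identity_range[1]; hi <- config$identity_range[2]
  seed <- seed %||% sim_seed(config, "identity")
  ids <- strain_ids(nS)
  m <- matrix(100, nS, nS, dimnames = list(ids, ids))
  up <- upper.tri(m)
  vals <- withr::with_seed(seed, {
    if (mode == "independent") {
      stats::runif(sum(up), lo, hi)
    } else {
      if (is.null(factor_scores))
        stop("coupled mode requires factor_scores")
      d <- as.matrix(stats::dist(factor_scores))[up]
      hi - (hi - lo) * d / max(d) + stats::rnorm(sum(up), 0, coupling_noise_sd)
    }
  })
  m[up] <- vals
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}
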