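#' Serialize a trait-scape to JSON
#'
#' Round-trips the standardization parameters, loadings, eigenvalues,
#' proportions and contributions (scores travel separately as CSV).
#'
#' @param scape a `traitscape`
#' @param path output path
#' @return the path, invisibly
#' @export
write_traitscape_json <- function(scape, path) {
  stopifnot(inherits(scape, "traitscape"))
  obj <- list(traits = scape$traits, n = scape$n,
              center = as.list(scape$center), scale = as.list(scape$scale),
              eigenvalues = scape$eigenvalues, proportion = scape$proportion,
              loadings = apply(scape$loadings, 2, identity, simplify = FALSE),
              contributions = apply(scape$contributions, 2, identity,
                                    simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trait-scape written by [write_traitscape_json()]
#'
#' Scores and row metadata are not stored in the JSON; the returned object
#' supports projection ([project_traitscape()]) but not score-level queries.
#'
#' @param path JSON path
#' @return a `traitscape` (without `scores`/`meta`)
#' @export
read_traitscape_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  traits <- obj$traits
  mk <- function(x) {
    m <- do.call(cbind, x)
    rownames(m) <- traits
    m
  }
  structure(list(center = unlist(obj$center)[traits],
                 scale = unlist(obj$scale)[traits],
                 loadings = mk(obj$loadings), scores = NULL,
                 eigenvalues = obj$eigenvalues, proportion = obj$proportion,
                 contributions = mk(obj$contributions), meta = NULL,
                 traits = traits, n = obj$n),
            class = "traitscape")
}

#' Configuration for an end-to-end pipeline run
#'
#' Either `traits_csv` (plus optional `identity_csv`) points at existing
#' input tables, or `simulate = TRUE` generates them from `sim_config`.
#'
#' @param outdir output directory
#' @param traits_csv path to a trait table CSV (ignored when simulating)
#' @param identity_csv optional path to a pairwise identity CSV
#' @param simulate generate inputs with the synthetic module
#' @param sim_config a [simulation_config()] used when simulating
#' @param alpha significance level for correlations
#' @param group_threshold |r| threshold for trait-group edges
#' @param subset reduced trait subset; `NULL` picks the group representatives
#' @param scales,nboot multiscale bootstrap settings
#' @param baseline_env baseline environment name
#' @param seed master seed (also used for `sim_config` when simulating
#'   unless that carries its own)
#' @return list of class `run_config`
#' @export
run_config <- function(outdir,
                       traits_csv = NULL, identity_csv = NULL,
                       simulate = is.null(traits_csv),
                       sim_config = NULL,
                       alpha = 0.05, group_threshold = 0.7,
                       subset = NULL,
                       scales = seq(0.5, 1.4, by = 0.1), nboot = 1000,
                       baseline_env = "standard", seed = 1L) {
  if (!simulate) {
    if (is.null(traits_csv)) stop("traits_csv required when not simulating")
    if (!file.exists(traits_csv)) stop("traits_csv not found: ", traits_csv)
    if (!is.null(identity_csv) && !file.exists(identity_csv))
      stop("identity_csv not found: ", identity_csv)
  }
  structure(list(outdir = outdir, traits_csv = traits_csv,
                 identity_csv = identity_csv, simulate = simulate,
                 sim_config = sim_config %||% simulation_config(seed = seed),
                 alpha = alpha, group_threshold = group_threshold,
                 subset = subset, scales = scales, nboot = nboot,
                 baseline_env = baseline_env, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML or JSON document
#'
#' Scalar fields of [run_config()] may be given in the file; unknown fields
#' raise an error.
#'
#' @param path `.yaml`/`.yml` or `.json` file
#' @param outdir output directory (overrides any value in the file)
#' @return a `run_config`
#' @export
read_run_config <- function(path, outdir = NULL) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- setdiff(names(formals(run_config)), "sim_config")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (!is.null(outdir)) vals$outdir <- outdir
  do.call(run_config, vals)
}

#' Run the full trait-scape pipeline
#'
#' Stages, in dependency order: obtain the trait table (simulate or read),
#' build the standard-environment trait-scape, correlation matrix and trait
#' groups, score reduced-trait recovery for the group representatives,
#' cluster replicate phenotypes with AU support, and -- when treatment
#' environments are present -- build the expanded trait-scape and the
#' strategy PCA of relative changes. A genotype-vs-phenotype regression runs
#' when an identity matrix is available (simulated in independent mode when
#' simulating). Every file written is listed in `manifest.json` with its MD5
#' hash; identical configuration and seed give identical hashes.
#'
#' @param config a [run_config()]
#' @return the manifest, invisibly
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    writer(path)
    files <<- c(files, path)
    path
  }

  # stage: inputs
  identity <- NULL
  if (config$simulate) {
    sim <- simulate_trait_table(config$sim_config)
    if (length(config$sim_config$env_shift_vectors))
      sim <- simulate_plasticity_shift(sim)
    identity <- simulate_identity_matrix(config$sim_config)
    table <- sim$table
    emit("traits.csv", function(p) utils::write.csv(table, p, row.names = FALSE))
  } else {
    table <- utils::read.csv(config$traits_csv)
    if (!is.null(config$identity_csv))
      identity <- read_identity_csv(config$identity_csv)
  }
  standard <- table[table$environment == config$baseline_env, , drop = FALSE]
  treatments <- table[table$environment != config$baseline_env, , drop = FALSE]

  # stage: trait-scape
  scape <- build_traitscape(standard)
  emit("scape.json", function(p) write_traitscape_json(scape, p))
  emit("scores.csv", function(p)
    utils::write.csv(data.frame(scape$meta, scape$scores), p, row.names = FALSE))

  # stage: covariation and groups
  corr <- correlation_matrix(standard, alpha = config$alpha)
  emit("correlation.csv", function(p) utils::write.csv(corr$r, p))
  groups <- identify_trait_groups(corr, scape, threshold = config$group_threshold)
  emit("groups.json", function(p)
    jsonlite::write_json(list(groups = groups$groups,
                              representatives = groups$representatives),
                         p, auto_unbox = TRUE, pretty = TRUE))

  # stage: reduced-trait recovery
  subset <- config$subset %||% unname(groups$representatives)
  if (length(subset) >= 2) {
    recovery <- reduced_traitscape_recovery(standard, subset, full = scape)
    emit("recovery.json", function(p)
      jsonlite::write_json(list(subset = subset,
                                regression = recovery$regression),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }

  # stage: clustering with AU support
  clust <- cluster_with_support(standard, scales = config$scales,
                                nboot = config$nboot, seed = config$seed)
  emit("dendrogram.newick", function(p) as_newick(clust, p))
  emit("cluster_support.csv", function(p)
    utils::write.csv(clust$support, p, row.names = FALSE))

  # stage: plasticity
  if (nrow(treatments)) {
    expanded <- expanded_traitscape(standard, treatments)
    emit("expanded_scape.json", function(p) write_traitscape_json(expanded, p))
    changes <- relative_changes(table, baseline_env = config$baseline_env)
    emit("relative_changes.csv", function(p)
      utils::write.csv(as.data.frame(changes), p, row.names = FALSE))
    strategy <- strategy_pca(changes)
    emit("strategy.json", function(p)
      jsonlite::write_json(list(env_centroids = strategy$env_centroids,
                                separation = strategy$separation),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }

  # stage: genotype vs phenotype
  if (!is.null(identity)) {
    gp <- genotype_phenotype_regression(identity, strain_centroids(scape))
    emit("genotype.json", function(p)
      jsonlite::write_json(gp, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  }

  # diagnostics + manifest
  diag <- traitscape_diagnostics(scape)
  emit("diagnostics.json", function(p)
    jsonlite::write_json(diag, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  manifest <- list(seed = config$seed,
                   files = data.frame(
                     file = basename(files),
                     md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
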