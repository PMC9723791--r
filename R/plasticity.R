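#' Relative trait changes versus the standard-environment baseline
#'
#' For every treatment culture, each trait's relative change is
#' `(value - baseline) / baseline`, where the baseline is that strain's mean
#' trait value across its standard-environment replicates. Baselines with
#' magnitude below `tol` would explode the ratio and raise an error naming
#' the strain and trait.
#'
#' @param table trait table containing the baseline environment and at least
#'   one other environment
#' @param baseline_env name of the baseline environment
#' @param tol minimum |baseline| allowed
#' @return data frame of class `relative_changes`: metadata columns plus one
#'   relative-change column per trait; the per-strain baselines are attached
#'   as attribute `baselines`
#' @export
relative_changes <- function(table, baseline_env = "standard", tol = 1e-9) {
  traits <- setdiff(names(table), .meta_cols)
  base <- table[table$environment == baseline_env, , drop = FALSE]
  treat <- table[table$environment != baseline_env, , drop = FALSE]
  if (!nrow(base)) stop("no cultures in baseline environment '", baseline_env, "'")
  if (!nrow(treat)) stop("no treatment cultures to compare")
  missing_base <- setdiff(unique(treat$strain_id), unique(base$strain_id))
  if (length(missing_base))
    stop("no baseline cultures for strain(s): ",
         paste(missing_base, collapse = ", "))
  baselines <- do.call(rbind, lapply(split(base[traits], base$strain_id),
                                     colMeans))
  for (s in rownames(baselines)) {
    small <- abs(baselines[s, ]) < tol
    if (any(small))
      stop("baseline mean within tolerance of zero for strain ", s,
           ", trait(s): ", paste(traits[small], collapse = ", "))
  }
  b <- baselines[treat$strain_id, , drop = FALSE]
  rel <- (as.matrix(treat[traits]) - b) / b
  out <- data.frame(treat[.meta_cols], rel, row.names = NULL)
  attr(out, "baselines") <- baselines
  attr(out, "baseline_env") <- baseline_env
  class(out) <- c("relative_changes", "data.frame")
  out
}

#' Strategy ordination of multi-trait plastic responses
#'
#' PCA of the relative-change table (standardized by default), asking whether
#' whole-phenotype responses cluster by environment rather than by strain.
#' Reports per-environment centroids on the first two axes and a separation
#' diagnostic: the ratio of the mean between-environment to the mean
#' within-environment pairwise score distance. Strains grown only in the
#' baseline environment can optionally be included as zero-change rows.
#'
#' @param changes a [relative_changes()] table
#' @param standardize standardize the change columns before PCA (default TRUE)
#' @param include_baseline_zeros include zero-change rows for `extra_strains`
#' @param extra_strains strain ids for the zero rows
#' @return list of class `strategy_pca`: `scape`, `env_centroids`,
#'   `separation` (list `between`, `within`, `ratio`), `n_environments`
#' @export
strategy_pca <- function(changes, standardize = TRUE,
                         include_baseline_zeros = FALSE,
                         extra_strains = NULL) {
  stopifnot(inherits(changes, "relative_changes"))
  traits <- setdiff(names(changes), .meta_cols)
  tab <- as.data.frame(changes)
  if (include_baseline_zeros && length(extra_strains)) {
    zeros <- data.frame(strain_id = extra_strains, species = NA,
                        replicate = 1L,
                        environment = attr(changes, "baseline_env"))
    zeros[traits] <- 0
    tab <- rbind(tab, zeros[names(tab)])
  }
  scape <- build_traitscape(tab, scale_sd = standardize)
  env <- scape$meta$environment
  sc <- scape$scores[, 1:2, drop = FALSE]
  cen <- apply(sc, 2, function(s) tapply(s, env, mean))
  d <- as.matrix(stats::dist(sc))
  same <- outer(env, env, "==")
  up <- upper.tri(d)
  within <- mean(d[up & same]); between <- mean(d[up & !same])
  n_env <- length(unique(env))
  structure(list(scape = scape,
                 env_centroids = data.frame(environment = rownames(cen), cen,
                                            row.names = NULL),
                 separation = list(between = between, within = within,
                                   ratio = if (n_env > 1) between / within
                                           else NA_real_),
                 n_environments = n_env),
            class = "strategy_pca")
}

#' @export
print.strategy_pca <- function(x, ...) {
  cat(sprintf("Strategy PCA over %d environments\n", x$n_environments))
  if (x$n_environments < 2)
    cat("  single environment: separation diagnostic not applicable\n")
  else
    cat(sprintf("  between/within score distance ratio: %.2f\n",
                x$separation$ratio))
  invisible(x)
}

#' Permutation test of environment separation in the strategy PCA
#'
#' Permutes environment labels across the relative-change rows and recomputes
#' the between/within distance ratio on the fixed scores, giving a null
#' distribution for the observed separation.
#'
#' @param strategy a [strategy_pca()] result
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list `observed`, `null` (vector), `p_value`
#' @export
strategy_permutation_test <- function(strategy, n_perm = 500, seed = 1L) {
  stopifnot(inherits(strategy, "strategy_pca"))
  if (strategy$n_environments < 2)
    stop("need at least 2 environments to test separation")
  sc <- strategy$scape$scores[, 1:2, drop = FALSE]
  env <- strategy$scape$meta$environment
  d <- as.matrix(stats::dist(sc))
  up <- upper.tri(d)
  ratio_for <- function(labels) {
    same <- outer(labels, labels, "==")
    mean(d[up & !same]) / mean(d[up & same])
  }
  obs <- ratio_for(env)
  null <- withr::with_seed(as.integer(seed),
    vapply(seq_len(n_perm), function(i) ratio_for(sample(env)), numeric(1)))
  list(observed = obs, null = null,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm))
}

#' Across-strain versus within-strain contrast for a trait pair
#'
#' Contrasts the between-strain relationship of two traits in the baseline
#' environment (Pearson r of strain means) with the within-strain direction
#' of their plastic responses (sign of the treatment-minus-baseline change
#' per strain). A positive across-strain correlation combined with opposite
#' within-strain change signs is the signature of a short-term physiological
#' trade-off hidden beneath a positive interspecific relationship.
#'
#' @param table trait table with baseline and treatment environments
#' @param trait_x,trait_y trait names
#' @param treatment_env treatment environment to contrast
#' @param baseline_env baseline environment name
#' @return list `across_r` (strain-mean correlation in the baseline),
#'   `within` (per-strain data frame of changes and signs), `consistent`
#'   (TRUE when every strain shares the same non-zero sign pattern),
#'   `direction` (the shared sign pattern or `"none"`)
#' @export
tradeoff_contrast <- function(table, trait_x, trait_y, treatment_env,
                              baseline_env = "standard") {
  stopifnot(all(c(trait_x, trait_y) %in% names(table)))
  envs <- unique(table$environment)
  if (!all(c(baseline_env, treatment_env) %in% envs))
    stop("environment(s) missing from the table")
  base <- table[table$environment == baseline_env, ]
  treat <- table[table$environment == treatment_env, ]
  bx <- tapply(base[[trait_x]], base$strain_id, mean)
  by <- tapply(base[[trait_y]], base$strain_id, mean)
  across_r <- stats::cor(bx, by)
  strains <- sort(unique(treat$strain_id))
  tx <- tapply(treat[[trait_x]], treat$strain_id, mean)[strains]
  ty <- tapply(treat[[trait_y]], treat$strain_id, mean)[strains]
  within <- data.frame(strain_id = strains,
                       delta_x = tx - bx[strains], delta_y = ty - by[strains],
                       sign_x = sign(tx - bx[strains]),
                       sign_y = sign(ty - by[strains]), row.names = NULL)
  consistent <- nrow(within) > 0 &&
    length(unique(within$sign_x)) == 1 && all(within$sign_x != 0) &&
    length(unique(within$sign_y)) == 1 && all(within$sign_y != 0)
  direction <- if (consistent)
    sprintf("%s %s, %s %s", trait_x,
            ifelse(within$sign_x[1] > 0, "up", "down"), trait_y,
            ifelse(within$sign_y[1] > 0, "up", "down"))
  else "none"
  list(across_r = across_r, within = within,
       consistent = consistent, direction = direction)
}
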