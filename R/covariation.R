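#' Pairwise Pearson correlation matrix with significance mask
#'
#' Pearson correlations between all trait pairs, with two-sided p-values from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. No
#' multiple-testing correction is applied by default (Holm available via
#' `adjust`). Constant traits yield `NA` correlations for their pairs.
#'
#' @param table trait table data frame (or numeric matrix)
#' @param alpha significance level for the mask
#' @param adjust `"none"` (default) or any method of [stats::p.adjust()]
#' @return object of class `trait_cor`: `r`, `p`, `sig` (logical mask at
#'   `alpha`), `n`, `alpha`
#' @export
correlation_matrix <- function(table, alpha = 0.05, adjust = "none") {
  m <- if (is.data.frame(table)) trait_matrix(table) else as.matrix(table)
  n <- nrow(m)
  if (n < 3) stop("need at least 3 rows")
  flat <- apply(m, 2, stats::sd) == 0
  if (any(flat))
    warning("constant trait(s), correlations undefined: ",
            paste(colnames(m)[flat], collapse = ", "))
  suppressWarnings(r <- stats::cor(m))
  r[flat, ] <- NA; r[, flat] <- NA; diag(r)[!flat] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  if (adjust != "none") {
    up <- upper.tri(p)
    p[up] <- stats::p.adjust(p[up], method = adjust)
    p[lower.tri(p)] <- t(p)[lower.tri(p)]
  }
  structure(list(r = r, p = p, sig = p < alpha, n = n, alpha = alpha),
            class = "trait_cor")
}

#' @export
print.trait_cor <- function(x, ...) {
  cat(sprintf("Trait correlation matrix (n = %d, alpha = %g)\n", x$n, x$alpha))
  print(round(x$r, 2))
  invisible(x)
}

#' Identify orthogonal trait groups from correlations and contributions
#'
#' Builds a graph on traits with an edge wherever `|r| >= threshold` and the
#' correlation is significant at the matrix's alpha; connected components are
#' the trait groups (singletons form their own group). Each group's
#' representative is the trait with the largest contribution to the group's
#' dominant axis (the axis receiving the group's largest total contribution),
#' ties broken alphabetically.
#'
#' @param corr a `trait_cor` over the scape traits
#' @param scape a `traitscape` over the same traits
#' @param threshold absolute-correlation threshold in (0, 1)
#' @return object of class `trait_groups`: `groups` (named list of trait
#'   vectors), `membership` (trait -> group id), `representatives`
#' @export
identify_trait_groups <- function(corr, scape, threshold = 0.7) {
  stopifnot(inherits(corr, "trait_cor"), inherits(scape, "traitscape"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  traits <- scape$traits
  if (!setequal(rownames(corr$r), traits))
    stop("correlation matrix and trait-scape cover different traits")
  r <- corr$r[traits, traits]
  adj <- abs(r) >= threshold & corr$sig[traits, traits]
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  # connected components by breadth-first search
  comp <- rep(NA_integer_, length(traits)); names(comp) <- traits
  cid <- 0L
  for (t0 in traits) {
    if (!is.na(comp[t0])) next
    cid <- cid + 1L
    queue <- t0
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, traits[adj[v, ] & is.na(comp)])
    }
  }
  groups <- split(names(comp), comp)
  reps <- vapply(groups, function(g) {
    contr <- scape$contributions[g, , drop = FALSE]
    dominant <- which.max(colSums(contr))
    g[order(-contr[, dominant], g)][1]
  }, character(1))
  names(groups) <- names(reps) <- reps
  structure(list(groups = groups, membership = comp, representatives = reps,
                 threshold = threshold),
            class = "trait_groups")
}

#' @export
print.trait_groups <- function(x, ...) {
  cat(sprintf("%d trait group(s) at |r| >= %g:\n", length(x$groups), x$threshold))
  for (nm in names(x$groups))
    cat(sprintf("  [%s] %s\n", nm, paste(x$groups[[nm]], collapse = ", ")))
  invisible(x)
}

#' Variance-weighted distance between two trait-scape centroids
#'
#' `distance = sqrt((dPC1 * a)^2 + (dPC2 * b)^2)`, where `a` and `b` are the
#' percent variance explained by the first two axes.
#'
#' @param c1,c2 numeric length-2 centroid coordinates (PC1, PC2)
#' @param a,b axis weights, percent variance of PC1 and PC2 (> 0)
#' @return the weighted Euclidean distance
#' @export
centroid_distance <- function(c1, c2, a, b) {
  stopifnot(length(c1) == 2, length(c2) == 2, a > 0, b > 0)
  sqrt(((c1[1] - c2[1]) * a)^2 + ((c1[2] - c2[2]) * b)^2)
}

#' Per-strain centroids on the first two trait-scape axes
#'
#' @param scape a `traitscape`
#' @param by metadata column to aggregate by (default `strain_id`); use e.g.
#'   `c("strain_id", "environment")` for per-strain-per-environment centroids
#' @return data frame with the grouping column(s), `PC1`, `PC2`, and the axis
#'   weights as attributes `a`, `b` (percent variance)
#' @export
strain_centroids <- function(scape, by = "strain_id") {
  stopifnot(inherits(scape, "traitscape"), all(by %in% names(scape$meta)))
  key <- interaction(scape$meta[by], drop = TRUE, lex.order = TRUE)
  cen <- apply(scape$scores[, 1:2, drop = FALSE], 2,
               function(s) tapply(s, key, mean))
  cen <- matrix(cen, ncol = 2, dimnames = list(levels(key), c("PC1", "PC2")))
  ids <- do.call(rbind, strsplit(rownames(cen), ".", fixed = TRUE))
  out <- data.frame(ids, cen, row.names = NULL)
  names(out)[seq_along(by)] <- by
  attr(out, "a") <- 100 * scape$proportion[1]
  attr(out, "b") <- 100 * scape$proportion[2]
  out
}

# pairwise distances between centroid rows; weights = NULL gives plain
# plot-plane distances, otherwise the variance-weighted metric
pairwise_centroid_distances <- function(centroids, weights = NULL) {
  m <- as.matrix(centroids[, c("PC1", "PC2")])
  if (!is.null(weights)) m <- sweep(m, 2, weights, "*")
  d <- stats::dist(m)
  attr(d, "Labels") <- centroids[[1]]
  d
}

#' Regression between two sets of pairwise centroid distances
#'
#' Ordinary least squares of `d_alt` on `d_ref` over the strain pairs, as a
#' measure of whether two ordinations place the strains in the same relative
#' positions. Adjusted R^2 uses one predictor:
#' `1 - (1 - R^2) (m - 1) / (m - 2)` for m pairs. The result is invariant to
#' rescaling either distance set.
#'
#' @param d_ref,d_alt `dist` objects or numeric vectors over the same pairs
#' @return list `r_squared`, `adj_r_squared`, `p_value`, `slope`,
#'   `intercept`, `n_pairs`
#' @export
distance_regression <- function(d_ref, d_alt) {
  x <- as.numeric(d_ref); y <- as.numeric(d_alt)
  if (length(x) != length(y)) stop("distance sets cover different pair counts")
  if (length(x) < 3) stop("need at least 3 pairs")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  m <- length(x)
  r2 <- sm$r.squared
  list(r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (m - 1) / (m - 2),
       p_value = unname(stats::coef(sm)[2, 4]),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_pairs = m)
}

#' Score how well a reduced trait set recovers the full trait-scape
#'
#' Builds a trait-scape from `subset` only, computes per-strain centroids in
#' the full and reduced scapes, and regresses the reduced inter-strain
#' distances on the full ones. By default distances are plain Euclidean in
#' each scape's PC1-PC2 plane (`weights = "plot"`); `weights = "variance"`
#' applies each scape's percent-variance weighting (the
#' [centroid_distance()] metric) instead.
#'
#' @param table trait table data frame
#' @param subset character vector of >= 2 trait names
#' @param full optional pre-built full `traitscape` of `table`
#' @param weights `"plot"` or `"variance"`
#' @return list `scape` (the reduced trait-scape), `regression` (see
#'   [distance_regression()]), `subset`
#' @export
reduced_traitscape_recovery <- function(table, subset, full = NULL,
                                        weights = c("plot", "variance")) {
  weights <- match.arg(weights)
  if (length(subset) < 2) stop("subset must contain at least 2 traits")
  full <- full %||% build_traitscape(table)
  if (!all(subset %in% full$traits))
    stop("subset traits not in the table: ",
         paste(setdiff(subset, full$traits), collapse = ", "))
  reduced <- build_traitscape(table, traits = subset)
  cf <- strain_centroids(full); cr <- strain_centroids(reduced)
  stopifnot(identical(cf$strain_id, cr$strain_id))
  wf <- if (weights == "variance") c(attr(cf, "a"), attr(cf, "b"))
  wr <- if (weights == "variance") c(attr(cr, "a"), attr(cr, "b"))
  reg <- distance_regression(pairwise_centroid_distances(cf, wf),
                             pairwise_centroid_distances(cr, wr))
  list(scape = reduced, regression = reg, subset = subset, weights = weights)
}

#' Regression of phenotypic distance on genetic identity
#'
#' Ordinary least squares of the pairwise variance-weighted centroid
#' distances (the [centroid_distance()] metric) on pairwise percent sequence
#' identity, to ask whether genetic relatedness predicts proximity in the
#' trait-scape.
#'
#' @param identity strain x strain percent-identity matrix
#' @param centroids centroid data frame from [strain_centroids()] (carrying
#'   the `a`, `b` weight attributes)
#' @return list `r_squared`, `adj_r_squared`, `p_value`, `slope`, `n_pairs`;
#'   `degenerate = TRUE` with `NA` statistics if identity is constant
#' @export
genotype_phenotype_regression <- function(identity, centroids) {
  ids <- centroids$strain_id
  if (!all(ids %in% rownames(identity)))
    stop("identity matrix does not cover all strains")
  identity <- identity[ids, ids]
  up <- upper.tri(identity)
  x <- identity[up]
  d <- as.matrix(pairwise_centroid_distances(
    centroids, c(attr(centroids, "a"), attr(centroids, "b"))))[up]
  if (stats::sd(x) == 0)
    return(list(r_squared = NA_real_, adj_r_squared = NA_real_,
                p_value = NA_real_, slope = NA_real_, n_pairs = sum(up),
                degenerate = TRUE))
  out <- distance_regression(x, d)
  out$degenerate <- FALSE
  out
}

#' Mantel permutation test between identity and phenotypic distance
#'
#' Permutation-based complement to [genotype_phenotype_regression()] that
#' respects the non-independence of shared-strain pairs: strain labels of the
#' identity matrix are permuted and the regression R^2 recomputed.
#'
#' @param identity strain x strain percent-identity matrix
#' @param centroids centroid data frame from [strain_centroids()]
#' @param n_perm number of permutations
#' @param seed integer seed
#' @return list `observed_r_squared`, `p_value`, `n_perm`
#' @export
mantel_identity_test <- function(identity, centroids, n_perm = 999, seed = 1L) {
  obs <- genotype_phenotype_regression(identity, centroids)$r_squared
  ids <- centroids$strain_id
  null <- withr::with_seed(as.integer(seed), vapply(seq_len(n_perm), function(i) {
    perm <- sample(ids)
    m <- identity[perm, perm]
    dimnames(m) <- list(ids, ids)
    genotype_phenotype_regression(m, centroids)$r_squared
  }, numeric(1)))
  list(observed_r_squared = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_perm),
       n_perm = n_perm)
}
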