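#' Standardize trait columns to zero mean and unit sample sd
#'
#' Each trait column is centred on its mean and divided by its sample
#' standard deviation (n - 1 denominator); the parameters are stored so new
#' samples can be projected onto the same scale.
#'
#' @param x numeric matrix or trait table data frame
#' @param traits optional trait subset
#' @param scale_sd divide by the sample sd (default); `FALSE` centres only
#' @return list with `z` (standardized matrix), `center`, `scale`
#' @export
standardize_traits <- function(x, traits = NULL, scale_sd = TRUE) {
  m <- if (is.data.frame(x)) trait_matrix(x, traits) else as.matrix(x)
  if (anyNA(m)) stop("trait matrix contains missing values; drop incomplete rows first")
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  if (scale_sd) {
    flat <- which(scale == 0 | !is.finite(scale))
    if (length(flat))
      stop("constant trait column(s): ",
           paste(colnames(m)[flat] %||% flat, collapse = ", "))
  } else {
    scale[] <- 1
  }
  z <- sweep(sweep(m, 2, center, "-"), 2, scale, "/")
  list(z = z, center = center, scale = scale)
}

# fix the arbitrary PCA sign: flip each loading column so that its
# largest-magnitude element is positive (distances are sign-invariant)
fix_signs <- function(loadings, scores) {
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Build a trait-scape by PCA of standardized traits
#'
#' Standardizes each trait (so the decomposition is of the trait correlation
#' matrix) and computes principal axes via singular value decomposition.
#' Axes are ordered by decreasing eigenvalue; the proportion of variance on
#' axis k is `eigenvalue_k / n_traits`; the contribution of trait j to axis k
#' is `100 * loading_jk^2` (contributions sum to 100 on each positive-variance
#' axis). Axes beyond the matrix rank carry zero eigenvalue, loadings, scores
#' and contributions. Rows with missing trait values are dropped with a
#' warning. The "trait-scape" proper is the plane of axes 1-2.
#'
#' @param table trait table data frame
#' @param traits optional trait subset (default: all trait columns)
#' @param scale_sd standardize to unit sd (default; correlation PCA). `FALSE`
#'   centres only (covariance PCA); proportions are then relative to the
#'   total variance rather than the trait count.
#' @return object of class `traitscape`: standardization parameters,
#'   `loadings` (traits x axes), `scores` (cultures x axes), `eigenvalues`,
#'   `proportion` (per-axis variance proportions), `contributions` (percent,
#'   traits x axes), `meta` (metadata of retained rows), `n`
#' @export
build_traitscape <- function(table, traits = NULL, scale_sd = TRUE) {
  stopifnot(is.data.frame(table))
  traits <- traits %||% setdiff(names(table), .meta_cols)
  if (length(traits) < 2) stop("need at least 2 traits")
  keep <- stats::complete.cases(table[traits])
  if (!all(keep))
    warning(sum(!keep), " culture(s) dropped from the ordination due to missing traits")
  table <- table[keep, , drop = FALSE]
  if (nrow(table) < 2) stop("need at least 2 complete cultures")
  std <- standardize_traits(table, traits, scale_sd = scale_sd)
  p <- length(traits); n <- nrow(std$z)
  pc <- stats::prcomp(std$z, center = FALSE, scale. = FALSE)
  k <- ncol(pc$rotation)
  loadings <- matrix(0, p, p, dimnames = list(traits, paste0("PC", 1:p)))
  scores <- matrix(0, n, p, dimnames = list(NULL, paste0("PC", 1:p)))
  eig <- numeric(p)
  loadings[, 1:k] <- pc$rotation
  scores[, 1:k] <- pc$x
  eig[1:k] <- pc$sdev^2
  # numerically-zero axes (rank deficiency) are hard zeros, never NaN
  null_axes <- eig < max(eig) * 1e-12
  eig[null_axes] <- 0
  loadings[, null_axes] <- 0
  scores[, null_axes] <- 0
  fx <- fix_signs(loadings, scores)
  contrib <- 100 * fx$loadings^2
  meta <- table[, intersect(.meta_cols, names(table)), drop = FALSE]
  rownames(meta) <- NULL
  # for standardized traits sum(eig) = p exactly, so this is eigenvalue / p
  structure(list(center = std$center, scale = std$scale,
                 loadings = fx$loadings, scores = fx$scores,
                 eigenvalues = eig, proportion = eig / sum(eig),
                 contributions = contrib, meta = meta,
                 traits = traits, n = n),
            class = "traitscape")
}

#' @export
print.traitscape <- function(x, ...) {
  cat(sprintf("Trait-scape: %d cultures x %d traits\n", x$n, length(x$traits)))
  cat(sprintf("  axes 1-2 capture %.1f%% of trait variance (PC1 %.1f%%, PC2 %.1f%%)\n",
              100 * sum(x$proportion[1:2]), 100 * x$proportion[1],
              100 * x$proportion[2]))
  invisible(x)
}

#' @export
summary.traitscape <- function(object, axes = 1:3, ...) {
  axes <- axes[axes <= length(object$eigenvalues)]
  tab <- rbind(`Standard deviation` = sqrt(object$eigenvalues[axes]),
               `Proportion of variance` = object$proportion[axes],
               `Cumulative proportion` = cumsum(object$proportion)[axes])
  colnames(tab) <- paste0("PC", axes)
  cat("Trait-scape summary\n")
  print(round(tab, 3))
  cat("\nTrait contributions (%)\n")
  print(round(object$contributions[, axes, drop = FALSE], 2))
  invisible(tab)
}

#' Project samples into an existing trait-scape
#'
#' Applies the stored standardization (training means and sds) and the stored
#' loadings; projecting the training table reproduces the stored scores.
#'
#' @param scape a `traitscape`
#' @param samples trait table (or numeric matrix) containing all scape traits
#' @return scores matrix (samples x axes)
#' @export
project_traitscape <- function(scape, samples) {
  stopifnot(inherits(scape, "traitscape"))
  m <- if (is.data.frame(samples)) trait_matrix(samples, scape$traits)
       else as.matrix(samples)[, scape$traits, drop = FALSE]
  z <- sweep(sweep(m, 2, scape$center, "-"), 2, scape$scale, "/")
  z %*% scape$loadings
}

#' Expanded trait-scape over standard plus treatment cultures
#'
#' Concatenates the standard-environment table with treatment rows and
#' rebuilds the ordination over the combined data (the combined table is
#' re-standardized; the standard-environment scaling is not reused).
#'
#' @param standard trait table of standard-environment cultures
#' @param treatments trait table of treatment cultures (may be empty)
#' @return a `traitscape` over the combined rows
#' @export
expanded_traitscape <- function(standard, treatments) {
  t1 <- setdiff(names(standard), .meta_cols)
  t2 <- setdiff(names(treatments), .meta_cols)
  if (nrow(treatments) && !setequal(t1, t2))
    stop("trait columns differ between the standard and treatment tables")
  combined <- if (nrow(treatments))
    rbind(standard[c(.meta_cols, t1)], treatments[c(.meta_cols, t1)])
  else standard
  build_traitscape(combined)
}

#' Diagnostics for a trait-scape
#'
#' Reports the cumulative variance on the first two axes, the null
#' expectations for two axes under randomly distributed trait values --
#' both `2/(T-1)` (rank-based, excluding the constraint axis) and `2/T` for
#' T traits -- and a consistency recomputation of each axis proportion from
#' its standard deviation (`sd^2 / T`).
#'
#' @param scape a `traitscape`
#' @return list with `two_axis_pct`, `null_pct_rank`, `null_pct_traits`,
#'   `recomputed_proportion`
#' @export
traitscape_diagnostics <- function(scape) {
  stopifnot(inherits(scape, "traitscape"))
  p <- length(scape$traits)
  list(two_axis_pct = 100 * sum(scape$proportion[1:2]),
       null_pct_rank = 100 * 2 / (p - 1),
       null_pct_traits = 100 * 2 / p,
       recomputed_proportion = proportion_from_sd(sqrt(scape$eigenvalues), p))
}

#' Recompute an axis variance proportion from its standard deviation
#'
#' For PCA of T standardized traits the eigenvalues sum to T, so the
#' proportion of variance on an axis with score standard deviation `sd` is
#' `sd^2 / T`. Useful as an arithmetic consistency check on reported PCA
#' summary tables.
#'
#' @param sd axis standard deviation(s)
#' @param n_traits number of traits T
#' @return proportion(s) of variance
#' @export
proportion_from_sd <- function(sd, n_traits) sd^2 / n_traits
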