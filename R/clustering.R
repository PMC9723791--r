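#' UPGMA (average linkage) clustering of a distance matrix
#'
#' Thin validating wrapper around [stats::hclust()] with
#' `method = "average"`. Agglomeration is deterministic; when two merges are
#' tied at the same height the pair with the lowest indices is merged first
#' (the underlying implementation's tie-breaking).
#'
#' @param d a `dist` object or a symmetric distance matrix
#' @return an `hclust` tree
#' @export
upgma <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
      stop("distance matrix must be square and symmetric")
    d <- stats::as.dist(d)
  }
  stopifnot(inherits(d, "dist"))
  stats::hclust(d, method = "average")
}

#' Leaf member sets of every internal node of a dendrogram
#'
#' @param hc an `hclust` tree over n leaves
#' @return list of n - 1 integer vectors (sorted leaf indices), one per
#'   internal node in merge order; the last is the root (all leaves)
#' @export
cluster_members <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  members <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    pick <- function(j) if (j < 0) -j else members[[j]]
    members[[i]] <- sort(c(pick(hc$merge[i, 1]), pick(hc$merge[i, 2])))
  }
  members
}

#' Multiscale bootstrap of cluster support by trait resampling
#'
#' For each scale factor r, `round(r * n_traits)` trait columns are resampled
#' with replacement `nboot` times; each resampled matrix is re-clustered
#' (Euclidean distance + UPGMA) and every internal node of the original
#' dendrogram is scored by the fraction of bootstrap dendrograms containing
#' exactly the same leaf member set (its bootstrap probability, BP, at that
#' scale). Deterministic given `seed` (one derived substream per scale).
#'
#' @param x numeric matrix, rows = cultures, columns = traits (standardize
#'   first; see [cluster_with_support()] for the full pipeline)
#' @param scales resample-size factors r
#' @param nboot bootstrap replicates per scale (>= 100)
#' @param seed integer master seed
#' @return object of class `msboot`: the original tree `hc`, `members`,
#'   `bp` (nodes x scales), `sizes` (resample sizes), `scales`, `nboot`,
#'   `n_traits`
#' @export
multiscale_bootstrap <- function(x, scales = seq(0.5, 1.4, by = 0.1),
                                 nboot = 1000, seed = 1L) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (nboot < 100) stop("nboot must be >= 100")
  sizes <- round(scales * p)
  if (any(sizes < 1)) stop("scale(s) give a resample size of 0 traits")
  hc <- upgma(stats::dist(x))
  members <- cluster_members(hc)
  keys <- vapply(members, member_key, character(1))
  bp <- matrix(0, length(keys), length(scales),
               dimnames = list(NULL, paste0("r", scales)))
  scale_seeds <- split_seed(seed, length(scales))
  for (si in seq_along(scales)) {
    m <- sizes[si]
    counts <- withr::with_seed(scale_seeds[si], {
      cnt <- integer(length(keys))
      for (b in seq_len(nboot)) {
        cols <- sample.int(p, m, replace = TRUE)
        hb <- stats::hclust(stats::dist(x[, cols, drop = FALSE]),
                            method = "average")
        kb <- vapply(cluster_members(hb), member_key, character(1))
        cnt <- cnt + (keys %in% kb)
      }
      cnt
    })
    bp[, si] <- counts / nboot
  }
  structure(list(hc = hc, members = members, keys = keys, bp = bp,
                 sizes = sizes, scales = scales, nboot = nboot, n_traits = p),
            class = "msboot")
}

#' Approximately unbiased p-values from multiscale bootstrap probabilities
#'
#' For each cluster, transforms the per-scale bootstrap probabilities to
#' normal quantiles `z_r = qnorm(1 - BP_r)` and fits
#' `z_r = v * sqrt(s_r) + c / sqrt(s_r)` (s_r = resample size / data size) by
#' weighted least squares with binomial-variance weights
#' `nboot * dnorm(z_r)^2 / (BP_r (1 - BP_r))`. The signed distance v and
#' curvature c give `AU = 1 - pnorm(v - c)` and the scale-1 estimate
#' `BP0 = 1 - pnorm(v + c)`. BP values of 0 or 1 are clamped to `1/(2 nboot)`
#' and `1 - 1/(2 nboot)`; clusters whose BP sits at the same bound on every
#' scale are degenerate and reported as AU = 0 or 1 with a flag. The root
#' cluster always has AU = BP = 1.
#'
#' @param ms an `msboot` object
#' @return data frame, one row per internal node: `node`, `height`,
#'   `members`, `bp` (at the scale closest to 1), `au`, `bp0`, `v`, `c`,
#'   `degenerate`
#' @export
au_from_multiscale <- function(ms) {
  stopifnot(inherits(ms, "msboot"))
  s <- ms$sizes / ms$n_traits
  ref_col <- which.min(abs(s - 1))
  n_leaves <- length(ms$hc$order)
  eps <- 1 / (2 * ms$nboot)
  out <- lapply(seq_along(ms$keys), function(i) {
    raw <- ms$bp[i, ]
    res <- list(node = i, height = ms$hc$height[i],
                members = ms$keys[i], bp = raw[ref_col],
                au = NA_real_, bp0 = NA_real_, v = NA_real_, c = NA_real_,
                degenerate = FALSE)
    if (length(ms$members[[i]]) == n_leaves) {      # root: always present
      res$au <- res$bp0 <- 1
      res$v <- -Inf; res$c <- 0
      return(res)
    }
    if (all(raw <= 0)) {
      res$au <- res$bp0 <- 0; res$degenerate <- TRUE; return(res)
    }
    if (all(raw >= 1)) {
      res$au <- res$bp0 <- 1; res$degenerate <- TRUE; return(res)
    }
    bp <- pmin(pmax(raw, eps), 1 - eps)
    z <- stats::qnorm(1 - bp)
    w <- ms$nboot * stats::dnorm(z)^2 / (bp * (1 - bp))
    sq <- sqrt(s); isq <- 1 / sqrt(s)
    fit <- stats::lm(z ~ 0 + sq + isq, weights = w)
    res$v <- unname(stats::coef(fit)["sq"])
    res$c <- unname(stats::coef(fit)["isq"])
    res$au <- 1 - stats::pnorm(res$v - res$c)
    res$bp0 <- 1 - stats::pnorm(res$v + res$c)
    res
  })
  do.call(rbind, lapply(out, as.data.frame))
}

#' Hierarchical clustering of phenotypes with AU support values
#'
#' The full replicate-level clustering pipeline: standardize the trait
#' columns, cluster cultures by Euclidean distance and UPGMA, run the
#' multiscale trait-resampling bootstrap and fit AU p-values.
#'
#' @param table trait table data frame
#' @param scales resample-size factors
#' @param nboot bootstrap replicates per scale
#' @param seed integer master seed
#' @return object of class `traitclust`: `hc` (labelled tree), `support`
#'   (the [au_from_multiscale()] table), `msboot`
#' @export
cluster_with_support <- function(table, scales = seq(0.5, 1.4, by = 0.1),
                                 nboot = 1000, seed = 1L) {
  keep <- stats::complete.cases(table[setdiff(names(table), .meta_cols)])
  table <- table[keep, , drop = FALSE]
  z <- standardize_traits(table)$z
  ms <- multiscale_bootstrap(z, scales = scales, nboot = nboot, seed = seed)
  ms$hc$labels <- paste(table$strain_id, table$environment, table$replicate,
                        sep = ".")
  list(hc = ms$hc, support = au_from_multiscale(ms), msboot = ms) |>
    structure(class = "traitclust")
}

#' @export
print.traitclust <- function(x, ...) {
  n_hi <- sum(x$support$au > 0.95 &
              x$support$node < max(x$support$node), na.rm = TRUE)
  cat(sprintf("Phenotype dendrogram: %d cultures, %d internal nodes (%d non-root with AU > 0.95; nboot = %d)\n",
              length(x$hc$order), nrow(x$support), n_hi, x$msboot$nboot))
  invisible(x)
}

#' Export a supported dendrogram as a Newick string
#'
#' Internal nodes are labelled `au<AU>_bp<BP>` (values in percent).
#'
#' @param tc a `traitclust`
#' @param file optional path; when given the tree is written there
#' @return the Newick string, invisibly when `file` is given
#' @export
as_newick <- function(tc, file = NULL) {
  stopifnot(inherits(tc, "traitclust"))
  ph <- ape::as.phylo(tc$hc)
  parts <- ape::prop.part(ph)
  labs <- attr(parts, "labels")
  part_keys <- vapply(parts, function(tips)
    member_key(match(labs[tips], tc$hc$labels)), character(1))
  idx <- match(part_keys, tc$support$members)
  ph$node.label <- ifelse(is.na(idx), "",
    sprintf("au%.0f_bp%.0f", 100 * tc$support$au[idx],
            100 * tc$support$bp[idx]))
  nwk <- ape::write.tree(ph)
  if (!is.null(file)) {
    writeLines(nwk, file)
    return(invisible(nwk))
  }
  nwk
}
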