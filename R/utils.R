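# internal helpers shared across modules

# canonical metadata columns of a trait table; everything else is a trait
.meta_cols <- c("strain_id", "species", "replicate", "environment")

#' Extract the numeric trait matrix from a trait table
#'
#' A trait table is a data frame with metadata columns `strain_id`, `species`,
#' `replicate`, `environment` and one numeric column per trait.
#'
#' @param table trait table data frame
#' @param traits optional character vector restricting/ordering the traits
#' @return numeric matrix, rows = cultures, columns = traits
#' @export
trait_matrix <- function(table, traits = NULL) {
  stopifnot(is.data.frame(table))
  if (is.null(traits)) traits <- setdiff(names(table), .meta_cols)
  missing <- setdiff(traits, names(table))
  if (length(missing))
    stop("trait column(s) not found: ", paste(missing, collapse = ", "))
  m <- as.matrix(table[, traits, drop = FALSE])
  if (!is.numeric(m)) stop("trait columns must be numeric")
  rownames(m) <- NULL
  m
}

# derive n independent child seeds from one master seed; all randomness in the
# package flows through this splitter so a single seed fixes every output
split_seed <- function(seed, n) {
  stopifnot(length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# sorted member set as a canonical string key (cluster identity in bootstraps)
member_key <- function(idx) paste(sort(as.integer(idx)), collapse = ",")

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() unless all named conditions hold; names are the messages
check_that <- function(...) {
  conds <- list(...)
  for (nm in names(conds)) if (!isTRUE(conds[[nm]])) stop(nm, call. = FALSE)
  invisible(TRUE)
}
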