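#' Per-step exponential growth rates from a fluorescence series
#'
#' For each consecutive pair of measurements the specific growth rate is
#' `mu_i = (ln F_{i+1} - ln F_i) / (t_{i+1} - t_i)`.
#'
#' @param series data frame with columns `day` (strictly increasing) and
#'   `fluorescence` (> 0) for a single culture
#' @return data frame `t1`, `t2`, `rate` with one row per step
#' @export
step_growth_rates <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("day", "fluorescence") %in% names(series)))
  t <- series$day; f <- series$fluorescence
  if (any(diff(t) <= 0)) stop("time points must be strictly increasing")
  bad <- which(f <= 0)
  if (length(bad))
    stop("non-positive fluorescence at day ", paste(t[bad], collapse = ", "))
  n <- length(f)
  if (n < 2) stop("need at least two time points")
  data.frame(t1 = t[-n], t2 = t[-1],
             rate = diff(log(f)) / diff(t))
}

#' Maximum growth rate over short windows of consecutive steps
#'
#' The maximum, over every contiguous window of `window_lengths` consecutive
#' step rates, of the window mean rate. Ties are broken toward the earliest
#' window (and, within a start point, the shortest window). Window lengths
#' longer than the available number of steps are skipped.
#'
#' @param series growth series data frame (see [step_growth_rates()])
#' @param window_lengths window lengths in steps; default 2:4
#' @return the maximum windowed mean rate (d^-1), with attributes `start` and
#'   `length` identifying the winning window
#' @export
max_growth_rate <- function(series, window_lengths = 2:4) {
  rates <- step_growth_rates(series)$rate
  if (length(rates) < min(window_lengths))
    stop("need at least ", min(window_lengths), " step rates, got ",
         length(rates))
  best <- -Inf; best_start <- NA_integer_; best_len <- NA_integer_
  for (start in seq_along(rates)) {       # earliest start wins ties
    for (len in sort(window_lengths)) {   # then shortest window
      if (start + len - 1L > length(rates)) next
      m <- mean(rates[start:(start + len - 1L)])
      if (m > best) {
        best <- m; best_start <- start; best_len <- len
      }
    }
  }
  structure(best, start = best_start, length = best_len)
}
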