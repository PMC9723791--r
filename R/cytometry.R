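#' Bead calibration of forward scatter against spherical diameter
#'
#' Fits the linear map `FSC = slope * diameter + intercept` by ordinary least
#' squares on beads of known diameter, so that cell size can be read back as
#' an equivalent spherical diameter (ESD) with [fsc_to_esd()].
#'
#' @param diameter_um bead diameters (um), at least two distinct values
#' @param fsc_median median forward scatter per bead population
#' @return object of class `esd_calibration` with `slope`, `intercept` and
#'   the fit residuals
#' @export
bead_calibration <- function(diameter_um, fsc_median) {
  stopifnot(length(diameter_um) == length(fsc_median))
  if (length(unique(diameter_um)) < 2)
    stop("need at least two distinct bead diameters")
  fit <- stats::lm(fsc_median ~ diameter_um)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("fitted calibration slope must be positive")
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit))),
            class = "esd_calibration")
}

#' Built-in forward-scatter to ESD calibration
#'
#' The default instrument calibration `ESD = (FSC + 194636) / 75775`, i.e.
#' slope 75775 and intercept -194636 of the FSC-vs-diameter line.
#'
#' @return an `esd_calibration`
#' @export
esd_calibration <- function() {
  structure(list(slope = 75775, intercept = -194636, residuals = numeric(0)),
            class = "esd_calibration")
}

#' @export
print.esd_calibration <- function(x, ...) {
  cat(sprintf("FSC -> ESD calibration: ESD = (FSC - (%g)) / %g\n",
              x$intercept, x$slope))
  invisible(x)
}

#' Convert forward scatter to equivalent spherical diameter
#'
#' `ESD = (FSC - intercept) / slope`. Values at or below zero are outside the
#' calibration range and returned as `NA` with a warning.
#'
#' @param fsc forward scatter median(s)
#' @param calibration an `esd_calibration` (default: the built-in constants)
#' @return ESD in um
#' @export
fsc_to_esd <- function(fsc, calibration = esd_calibration()) {
  stopifnot(inherits(calibration, "esd_calibration"))
  esd <- (fsc - calibration$intercept) / calibration$slope
  below <- is.finite(esd) & esd <= 0
  if (any(below)) {
    warning(sum(below), " value(s) below the calibration range set to NA")
    esd[below] <- NA_real_
  }
  esd
}

#' Derive the flow-cytometry traits from per-culture channel medians
#'
#' Size-normalized traits: chlorophyll and side scatter medians are divided by
#' ESD; neutral lipid content is the post- minus pre-stain median difference
#' per ESD; the ROS signal is the stained-minus-blank difference per cell,
#' again per ESD. Negative differences are preserved, not clipped.
#'
#' @param summary data frame with columns `chl_median`, `ssc_median`,
#'   `prestain_median`, `poststain_median`, `ros_stained`, `ros_blank`,
#'   `cell_count` (and any id columns, carried through)
#' @param esd equivalent spherical diameter per row (> 0)
#' @return data frame `cell_size`, `chl`, `granularity`, `lipid`, `ros`
#' @export
derive_fcm_traits <- function(summary, esd) {
  needed <- c("chl_median", "ssc_median", "prestain_median",
              "poststain_median", "ros_stained", "ros_blank", "cell_count")
  stopifnot(is.data.frame(summary), all(needed %in% names(summary)),
            length(esd) == nrow(summary))
  if (any(summary$cell_count <= 0, na.rm = TRUE))
    stop("cell_count must be positive")
  if (any(esd <= 0, na.rm = TRUE)) stop("esd must be positive")
  data.frame(
    cell_size = esd,
    chl = summary$chl_median / esd,
    granularity = summary$ssc_median / esd,
    lipid = (summary$poststain_median - summary$prestain_median) / esd,
    ros = ((summary$ros_stained - summary$ros_blank) / summary$cell_count) / esd)
}
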