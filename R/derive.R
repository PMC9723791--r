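#' Assemble the nine-trait table from instrument-level data
#'
#' Runs the full trait derivation: windowed maximum growth rate from each
#' culture's fluorescence series, P-I parameters from each rapid light curve,
#' ESD from forward scatter via the bead calibration (refit from `beads`
#' when supplied, otherwise the built-in constants), and the size-normalized
#' flow-cytometry traits. Cultures missing any trait (e.g. a non-convergent
#' light-curve fit) are kept with `NA` values and reported in a warning;
#' downstream ordination drops them explicitly.
#'
#' @param cultures data frame `culture_id`, `strain_id`, `species`,
#'   `replicate`, `environment`
#' @param growth data frame `culture_id`, `day`, `fluorescence`
#' @param light_curves data frame `culture_id`, `step`, `irradiance`, `etr`
#' @param fcm data frame of per-culture channel medians (see
#'   [derive_fcm_traits()]) including `fsc_median`
#' @param beads optional data frame `diameter_um`, `fsc_median` to refit the
#'   ESD calibration
#' @param model P-I model passed to [fit_light_curve()]
#' @return a trait table data frame (metadata + nine trait columns)
#' @export
derive_trait_table <- function(cultures, growth, light_curves, fcm,
                               beads = NULL, model = "tanh") {
  stopifnot(all(c("culture_id", "strain_id", "replicate", "environment")
                %in% names(cultures)))
  calib <- if (is.null(beads)) esd_calibration()
           else bead_calibration(beads$diameter_um, beads$fsc_median)

  mu <- vapply(cultures$culture_id, function(id) {
    s <- growth[growth$culture_id == id, ]
    if (!nrow(s)) return(NA_real_)
    as.numeric(max_growth_rate(s))
  }, numeric(1))

  pi_fit <- lapply(cultures$culture_id, function(id) {
    lc <- light_curves[light_curves$culture_id == id, ]
    if (!nrow(lc)) return(list(alpha = NA_real_, etrmax = NA_real_, ik = NA_real_))
    fit_light_curve(lc$irradiance, lc$etr, model = model)
  })

  fcm <- fcm[match(cultures$culture_id, fcm$culture_id), ]
  esd <- fsc_to_esd(fcm$fsc_median, calib)
  fcm_traits <- derive_fcm_traits(fcm, esd)

  tab <- data.frame(
    cultures[, c("strain_id", "species", "replicate", "environment")],
    growth_rate = mu, fcm_traits,
    alpha = vapply(pi_fit, `[[`, numeric(1), "alpha"),
    etrmax = vapply(pi_fit, `[[`, numeric(1), "etrmax"),
    ik = vapply(pi_fit, `[[`, numeric(1), "ik"),
    row.names = NULL)
  tab <- tab[, c(.meta_cols, trait_names())]
  incomplete <- !stats::complete.cases(tab[trait_names()])
  if (any(incomplete))
    warning(sum(incomplete), " culture(s) have missing traits: ",
            paste(cultures$culture_id[incomplete], collapse = ", "))
  tab
}

#' Read a directory of instrument CSV files and derive the trait table
#'
#' Convenience wrapper over [derive_trait_table()] for the CSV schemas
#' written by [write_simulation()].
#'
#' @param dir directory containing `cultures.csv`, `growth.csv`,
#'   `light_curves.csv`, `fcm.csv` and optionally `beads.csv`
#' @param ... passed to [derive_trait_table()]
#' @return a trait table data frame
#' @export
derive_trait_table_dir <- function(dir, ...) {
  rd <- function(f) utils::read.csv(file.path(dir, f))
  beads_path <- file.path(dir, "beads.csv")
  derive_trait_table(rd("cultures.csv"), rd("growth.csv"),
                     rd("light_curves.csv"), rd("fcm.csv"),
                     beads = if (file.exists(beads_path)) rd("beads.csv"),
                     ...)
}
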