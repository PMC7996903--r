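#' Band-integrated fluxes and total current
#'
#' Integrates the per-bin flux tallies over the three standard neutron
#' bands. Each bin is assigned wholly to the band its geometric center
#' falls in (boundary bins are not split). The total directed current is
#' summed over all bins.
#'
#' @param spectrum A \code{beam_spectrum}.
#' @return A list with \code{phi_th}, \code{phi_epi}, \code{phi_fast}
#'   (cm^-2 s^-1) and \code{J_total} (cm^-2 s^-1).
#' @examples
#' sp <- generate_beam_spectrum(make_energy_grid(), beam_model_params())
#' band_integrals(sp)
#' @export
band_integrals <- function(spectrum) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  if (spectrum$grid$n_bins == 0L || length(spectrum$flux_per_bin) == 0L)
    stop("empty spectrum")
  band <- classify_energy(spectrum$grid$mids)
  list(phi_th = sum(spectrum$flux_per_bin[band == "thermal"]),
       phi_epi = sum(spectrum$flux_per_bin[band == "epithermal"]),
       phi_fast = sum(spectrum$flux_per_bin[band == "fast"]),
       J_total = sum(spectrum$current_per_bin))
}

#' In-air figures of merit of an epithermal beam
#'
#' Computes the five IAEA figures of merit from beam-port tallies:
#' the epithermal flux phi_epi; the thermal-to-epithermal flux ratio
#' phi_th/phi_epi; the fast-neutron and gamma dose rates per unit
#' epithermal flux (cm^2 Gy); and the collimation ratio J/phi_epi, where
#' J is the total directed neutron current over the port.
#'
#' @param spectrum A \code{beam_spectrum} with nonzero epithermal flux.
#' @return A \code{fom_report}.
#' @seealso [check_compliance()], [fom_report()]
#' @export
compute_foms <- function(spectrum) {
  b <- band_integrals(spectrum)
  if (b$phi_epi <= 0)
    stop("epithermal flux is zero: FOM ratios undefined")
  fom_report(phi_epi = b$phi_epi,
             ratio_th_epi = b$phi_th / b$phi_epi,
             fast_dose_per_epi = spectrum$fast_dose_rate / b$phi_epi,
             gamma_dose_per_epi = spectrum$gamma_dose_rate / b$phi_epi,
             j_over_phi_epi = b$J_total / b$phi_epi)
}

#' Construct a figure-of-merit report directly from its five values
#'
#' Used both by [compute_foms()] and to evaluate externally published
#' FOM rows (e.g. Monte Carlo results reported for candidate assemblies).
#'
#' @param phi_epi Epithermal flux, cm^-2 s^-1.
#' @param ratio_th_epi Thermal-to-epithermal flux ratio.
#' @param fast_dose_per_epi Fast dose rate per unit epithermal flux,
#'   cm^2 Gy.
#' @param gamma_dose_per_epi Gamma dose rate per unit epithermal flux,
#'   cm^2 Gy.
#' @param j_over_phi_epi Current-to-epithermal-flux (collimation) ratio.
#' @return An object of class \code{fom_report}.
#' @export
fom_report <- function(phi_epi, ratio_th_epi, fast_dose_per_epi,
                       gamma_dose_per_epi, j_over_phi_epi) {
  vals <- c(phi_epi = phi_epi, ratio_th_epi = ratio_th_epi,
            fast_dose_per_epi = fast_dose_per_epi,
            gamma_dose_per_epi = gamma_dose_per_epi,
            j_over_phi_epi = j_over_phi_epi)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all figures of merit must be finite and nonnegative")
  structure(as.list(vals), class = "fom_report")
}

#' @export
print.fom_report <- function(x, ...) {
  cat("<fom_report>\n")
  cat(sprintf("  phi_epi            %.3g cm^-2 s^-1\n", x$phi_epi))
  cat(sprintf("  phi_th/phi_epi     %.3g\n", x$ratio_th_epi))
  cat(sprintf("  Dfast/phi_epi      %.3g cm^2 Gy\n", x$fast_dose_per_epi))
  cat(sprintf("  Dgamma/phi_epi     %.3g cm^2 Gy\n", x$gamma_dose_per_epi))
  cat(sprintf("  J/phi_epi          %.3g\n", x$j_over_phi_epi))
  invisible(x)
}

#' IAEA-recommended figure-of-merit thresholds
#'
#' The recommended in-air values for a clinical epithermal beam:
#' phi_epi above 1e9 cm^-2 s^-1, thermal contamination below 5% of the
#' epithermal flux, fast and gamma dose per unit epithermal flux below
#' 2e-13 cm^2 Gy each, and collimation J/phi_epi above 0.7. All are
#' overridable.
#'
#' @param min_phi_epi,max_ratio_th_epi,max_fast,max_gamma,min_collimation
#'   Threshold values; all must be positive.
#' @return An object of class \code{iaea_thresholds}.
#' @export
iaea_thresholds <- function(min_phi_epi = 1e9,
                            max_ratio_th_epi = 0.05,
                            max_fast = 2e-13,
                            max_gamma = 2e-13,
                            min_collimation = 0.7) {
  vals <- c(min_phi_epi, max_ratio_th_epi, max_fast, max_gamma,
            min_collimation)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("thresholds must be positive")
  structure(list(min_phi_epi = min_phi_epi,
                 max_ratio_th_epi = max_ratio_th_epi,
                 max_fast = max_fast,
                 max_gamma = max_gamma,
                 min_collimation = min_collimation),
            class = "iaea_thresholds")
}

#' Check a figure-of-merit report against recommended thresholds
#'
#' All comparisons are strict, in the recommended directions: flux and
#' collimation must exceed their minima; contamination ratios must fall
#' below their maxima.
#'
#' @param report A \code{fom_report}.
#' @param thresholds An \code{iaea_thresholds} (defaults to the
#'   recommended values).
#' @return A list with \code{flags} (named logical vector of length 5:
#'   \code{flux}, \code{thermal_ratio}, \code{fast_dose},
#'   \code{gamma_dose}, \code{collimation}) and \code{n_pass}.
#' @examples
#' r <- fom_report(1.08e9, 0.009, 9.5e-13, 4.17e-13, 0.74)
#' check_compliance(r)
#' @export
check_compliance <- function(report, thresholds = iaea_thresholds()) {
  stopifnot(inherits(report, "fom_report"),
            inherits(thresholds, "iaea_thresholds"))
  flags <- c(
    flux = report$phi_epi > thresholds$min_phi_epi,
    thermal_ratio = report$ratio_th_epi < thresholds$max_ratio_th_epi,
    fast_dose = report$fast_dose_per_epi < thresholds$max_fast,
    gamma_dose = report$gamma_dose_per_epi < thresholds$max_gamma,
    collimation = report$j_over_phi_epi > thresholds$min_collimation)
  list(flags = flags, n_pass = sum(flags))
}

#' Dose rate from per-bin kerma coefficients
#'
#' Hook for users who want scalar dose-rate tallies recomputed from an
#' energy-resolved flux and a user-supplied kerma coefficient table,
#' rather than accepted as inputs: the dose rate is the flux-weighted sum
#' of the coefficients.
#'
#' @param spectrum A \code{beam_spectrum}.
#' @param kerma_per_bin Kerma coefficients, Gy cm^2, one per grid bin.
#' @return Dose rate, Gy s^-1.
#' @export
dose_rate_from_kerma <- function(spectrum, kerma_per_bin) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  if (length(kerma_per_bin) != spectrum$grid$n_bins)
    stop("need one kerma coefficient per grid bin")
  if (any(kerma_per_bin < 0)) stop("kerma coefficients must be nonnegative")
  sum(spectrum$flux_per_bin * kerma_per_bin)
}
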