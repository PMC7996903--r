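#' Default simplified whole-body organ set
#'
#' Nineteen organs of a stylized adult phantom positioned for a head
#' irradiation, each summarized by its distance from the center of the
#' irradiation field (cm) and a characteristic size (cm). Head-region
#' organs sit at small distances and trunk/pelvic organs far away, which
#' is what drives the strong decrease of out-of-field dose down the
#' body.
#'
#' @return A data.frame with columns \code{organ}, \code{distance_cm},
#'   \code{size_cm}.
#' @export
default_organ_set <- function() {
  data.frame(
    organ = c("Brain", "Head", "Pharynx", "Thyroid", "Skin", "Thymus",
              "Lungs", "Heart", "Marrow", "Trunk", "Stomach", "Spleen",
              "Liver", "Adrenal", "Pancreas", "Kidneys", "Intestine",
              "Bladder", "Testicles"),
    distance_cm = c(0, 4, 8, 13, 18, 22, 27, 29, 32, 33, 38, 39, 40,
                    44, 45, 46, 54, 64, 74),
    size_cm = c(15, 20, 5, 4, 170, 6, 20, 12, 40, 60, 12, 10, 15, 4,
                12, 11, 30, 8, 5))
}

#' Generate per-organ raw dose-rate components
#'
#' Kernel stand-in for whole-body transport: each dose-rate component
#' decays exponentially with the organ's distance from the irradiation
#' field, with component-specific relaxation lengths (the fast-neutron
#' component dies off fastest, the gamma component slowest). Out-of-field
#' dose is leakage, so it also scales with how poorly the beam is
#' collimated: every component carries a leakage factor
#' \code{1 - collimation_leakage * J/phi}, with the directionality ratio
#' J/phi taken from the spectrum's current and flux tallies. An
#' organ-averaged neutron energy proxy also softens with distance, from
#' a fast-dominated spectrum in-field toward thermal energies in the far
#' trunk; it feeds the energy-dependent neutron weighting. Everything
#' scales linearly with the beam's total flux. Optional multiplicative
#' log-normal noise (seeded) emulates tally uncertainty; it is off by
#' default.
#'
#' @param spectrum A \code{beam_spectrum}.
#' @param organs Data.frame with columns \code{organ},
#'   \code{distance_cm} (and optionally \code{size_cm}); nonnegative
#'   distances; at least one row.
#' @param kernels A \code{dose_kernel_params} (supplies the dose-rate
#'   normalizations and reference flux).
#' @param seed Integer seed for the noise.
#' @param noise_sd Log-scale standard deviation of the noise
#'   (default 0 = off).
#' @param body_attenuation Relaxation length of the neutron-driven
#'   components along the body, cm.
#' @param fast_attenuation Relaxation length of the fast-neutron
#'   component, cm.
#' @param gamma_attenuation Relaxation length of the gamma component,
#'   cm.
#' @param collimation_leakage Strength of the collimation effect on
#'   leakage, in [0, 1): a perfectly directed beam (J/phi = 1) leaks
#'   \code{1 - collimation_leakage} of what an undirected one would.
#' @return An object of class \code{organ_components}: data.frame with
#'   \code{organ}, \code{distance_cm}, the four dose-rate components
#'   (Gy min^-1; boron per ppm) and \code{mean_neutron_energy_ev}.
#' @examples
#' sp <- generate_beam_spectrum(make_energy_grid(), beam_model_params())
#' head(generate_organ_doses(sp, default_organ_set(),
#'                           dose_kernel_params()), 3)
#' @export
generate_organ_doses <- function(spectrum, organs,
                                 kernels = dose_kernel_params(),
                                 seed = NULL, noise_sd = 0,
                                 body_attenuation = 12,
                                 fast_attenuation = 8,
                                 gamma_attenuation = 14,
                                 collimation_leakage = 0.8) {
  stopifnot(inherits(spectrum, "beam_spectrum"),
            inherits(kernels, "dose_kernel_params"))
  if (!is.data.frame(organs) || nrow(organs) == 0L)
    stop("organ list is empty")
  if (!all(c("organ", "distance_cm") %in% names(organs)))
    stop("organs needs columns 'organ' and 'distance_cm'")
  d <- organs$distance_cm
  if (any(!is.finite(d)) || any(d < 0))
    stop("organ distances must be nonnegative")

  if (collimation_leakage < 0 || collimation_leakage >= 1)
    stop("collimation_leakage must lie in [0, 1)")
  flux_tot <- sum(spectrum$flux_per_bin)
  directionality <- if (flux_tot > 0)
    sum(spectrum$current_per_bin) / flux_tot else 0
  scale <- flux_tot / kernels$reference_flux *
    (1 - collimation_leakage * directionality)
  out <- data.frame(
    organ = organs$organ,
    distance_cm = d,
    boron_per_ppm = kernels$s_boron_per_ppm * exp(-d / body_attenuation) *
      scale,
    thermal_n = kernels$s_thermal * exp(-d / body_attenuation) * scale,
    fast_n = kernels$s_fast * exp(-d / fast_attenuation) * scale,
    gamma = kernels$s_gamma * exp(-d / gamma_attenuation) * scale,
    mean_neutron_energy_ev = 2e5 * exp(-d / fast_attenuation) + 0.025)

  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
      on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
    }
    for (col in c("boron_per_ppm", "thermal_n", "fast_n", "gamma"))
      out[[col]] <- out[[col]] *
        exp(stats::rnorm(nrow(out), 0, noise_sd))
  }
  class(out) <- c("organ_components", "data.frame")
  out
}
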