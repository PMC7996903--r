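#' Cumulative dose-volume histogram
#'
#' Fraction of the (masked) structure volume receiving at least each
#' dose level, assuming equal voxel volumes. The histogram starts at 1
#' for dose 0 and is non-increasing.
#'
#' @param doses Numeric vector or array of per-voxel doses, Gy-Eq.
#' @param mask Optional logical mask selecting the structure's voxels;
#'   must select at least one voxel.
#' @param n_bins Number of dose thresholds above zero.
#' @return An object of class \code{dvh}: a data.frame with columns
#'   \code{dose} and \code{volume_fraction}.
#' @examples
#' compute_dvh(c(2, 4), n_bins = 4)
#' @export
compute_dvh <- function(doses, mask = NULL, n_bins = 100L) {
  d <- as.vector(doses)
  if (!is.null(mask)) d <- d[as.vector(mask)]
  if (length(d) == 0L) stop("empty mask: no voxels selected")
  if (any(!is.finite(d)) || any(d < 0))
    stop("doses must be finite and nonnegative")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("n_bins must be at least 1")
  top <- max(d)
  if (top == 0) top <- 1
  edges <- seq(0, top, length.out = n_bins + 1L)
  frac <- vapply(edges, function(th) mean(d >= th), numeric(1L))
  frac[1L] <- 1  # every voxel receives at least zero dose
  structure(data.frame(dose = edges, volume_fraction = frac),
            class = c("dvh", "data.frame"))
}

#' Export a DVH as a two-column CSV
#'
#' @param dvh A \code{dvh}.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_dvh <- function(dvh, file) {
  stopifnot(inherits(dvh, "dvh"))
  utils::write.csv(as.data.frame(dvh), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' Parameters of the Poisson linear-quadratic TCP model
#'
#' @param alpha Radiosensitivity, Gy^-1 (> 0).
#' @param beta Quadratic coefficient, Gy^-2 (>= 0).
#' @param clonogen_density Clonogenic cell density, cells cm^-3 (> 0).
#' @details The defaults (alpha 0.25 Gy^-1, beta 0.025 Gy^-2, 1e7
#'   clonogens cm^-3) are in the range commonly used for head-and-neck
#'   squamous carcinoma; published sets can be substituted when
#'   available.
#' @return An object of class \code{tcp_params}.
#' @export
tcp_params <- function(alpha = 0.25, beta = 0.025,
                       clonogen_density = 1e7) {
  if (alpha <= 0 || beta < 0 || clonogen_density <= 0)
    stop("need alpha > 0, beta >= 0, clonogen_density > 0")
  structure(list(alpha = alpha, beta = beta,
                 clonogen_density = clonogen_density),
            class = "tcp_params")
}

#' Tumor control probability for an inhomogeneous dose distribution
#'
#' Poisson TCP with linear-quadratic cell kill: the expected number of
#' surviving clonogens is summed over voxels,
#' TCP = exp(-sum_i rho v_i exp(-alpha D_i - beta D_i^2)),
#' so the probability is driven by the coldest parts of the tumor. The
#' result is invariant under voxel subdivision and non-decreasing in
#' every voxel dose.
#'
#' @param doses Per-voxel photon-equivalent doses, Gy-Eq (>= 0).
#' @param params A \code{tcp_params}.
#' @param voxel_volume Voxel volume, cm^3 (scalar, or one per voxel).
#' @return Probability in [0, 1].
#' @examples
#' tcp(rep(30, 8), tcp_params(), voxel_volume = 4)
#' @export
tcp <- function(doses, params = tcp_params(), voxel_volume) {
  stopifnot(inherits(params, "tcp_params"))
  d <- as.vector(doses)
  if (any(!is.finite(d)) || any(d < 0))
    stop("doses must be finite and nonnegative")
  if (any(voxel_volume <= 0)) stop("voxel_volume must be positive")
  surv <- params$clonogen_density * voxel_volume *
    exp(-params$alpha * d - params$beta * d^2)
  exp(-sum(surv))
}

#' Parameters of the logistic NTCP model
#'
#' @param d50 Dose giving a 50% complication probability, Gy-Eq (> 0).
#' @param gamma50 Normalized slope at D50 (> 0).
#' @details The defaults (D50 8 Gy-Eq, gamma50 1.5) place severe-mucositis
#'   risk near 20% at 6 Gy-Eq to the mucosal dose-limiting point,
#'   consistent with single-session photon-equivalent tolerance of oral
#'   mucosa; published model fits can be substituted via configuration.
#' @return An object of class \code{ntcp_params}.
#' @export
ntcp_params <- function(d50 = 8, gamma50 = 1.5) {
  if (d50 <= 0 || gamma50 <= 0) stop("need d50 > 0 and gamma50 > 0")
  structure(list(d50 = d50, gamma50 = gamma50), class = "ntcp_params")
}

#' Normal-tissue complication probability (logistic dose response)
#'
#' NTCP(D) = 1 / (1 + exp(4 gamma50 (1 - D / D50))): strictly increasing
#' in dose, equal to 0.5 at D50, with normalized slope gamma50 there.
#' Used here for severe (grade >= 3) mucositis of the dose-limiting
#' mucosal point.
#'
#' @param dose Dose metric at the limiting point, Gy-Eq (vectorized,
#'   >= 0).
#' @param params A \code{ntcp_params}.
#' @return Probability in [0, 1].
#' @examples
#' ntcp(c(0, 8, 20), ntcp_params(d50 = 8, gamma50 = 1))
#' @export
ntcp <- function(dose, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose must be finite and nonnegative")
  1 / (1 + exp(4 * params$gamma50 * (1 - dose / params$d50)))
}

#' Uncomplicated tumor control probability
#'
#' The probability of controlling the tumor without normal-tissue
#' complication: UTCP = TCP * (1 - NTCP).
#'
#' @param tcp,ntcp Probabilities in [0, 1] (vectorized).
#' @return UTCP in [0, 1].
#' @examples
#' utcp(0.58, 0.18)
#' @export
utcp <- function(tcp, ntcp) {
  if (any(!is.finite(tcp)) || any(tcp < 0) || any(tcp > 1))
    stop("tcp must lie in [0, 1]")
  if (any(!is.finite(ntcp)) || any(ntcp < 0) || any(ntcp > 1))
    stop("ntcp must lie in [0, 1]")
  tcp * (1 - ntcp)
}

#' Irradiation time to reach a dose limit
#'
#' @param rate Dose rate at the limiting point, Gy-Eq min^-1 (> 0).
#' @param limit Prescribed dose limit, Gy-Eq.
#' @return Time in minutes, \code{limit / rate}.
#' @export
time_for_dose_limit <- function(rate, limit) {
  if (any(rate <= 0)) stop("dose rate must be positive")
  if (any(limit < 0)) stop("dose limit must be nonnegative")
  limit / rate
}

#' Find the irradiation time that maximizes UTCP
#'
#' Dose is assumed linear in time (constant dose rates): the tumor
#' voxel doses are \code{tumor_rates * t} and the healthy-tissue
#' limiting-point dose is \code{healthy_rate * t}. UTCP(t) =
#' TCP(t) * (1 - NTCP(t)) is maximized by an exhaustive scan over a
#' uniform time grid followed by golden-section refinement around the
#' best grid point; ties are broken toward the smaller time.
#'
#' @param tumor_rates Per-voxel weighted dose rates in the tumor,
#'   Gy-Eq min^-1.
#' @param healthy_rate Weighted dose rate at the mucosal dose-limiting
#'   point, Gy-Eq min^-1.
#' @param tcp_pars,ntcp_pars Model parameter objects.
#' @param voxel_volume Tumor voxel volume, cm^3.
#' @param t_range Search bracket, minutes.
#' @param t_step Scan step, minutes (default 0.5).
#' @param refine Golden-section refinement of the grid optimum
#'   (default TRUE).
#' @return An object of class \code{outcome_result}: list with
#'   \code{t_irr}, \code{tcp}, \code{ntcp}, \code{utcp},
#'   \code{d_max_healthy} (Gy-Eq at \code{t_irr}) and
#'   \code{flat_tumor_warning} (TRUE when the tumor receives no dose, in
#'   which case UTCP cannot reward longer irradiation).
#' @export
optimize_time <- function(tumor_rates, healthy_rate,
                          tcp_pars = tcp_params(),
                          ntcp_pars = ntcp_params(),
                          voxel_volume,
                          t_range = c(0, 120), t_step = 0.5,
                          refine = TRUE) {
  rates <- as.vector(tumor_rates)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("tumor dose rates must be finite and nonnegative")
  if (!is.finite(healthy_rate) || healthy_rate < 0)
    stop("healthy_rate must be finite and nonnegative")
  if (length(t_range) != 2L || t_range[1L] < 0 ||
      t_range[2L] <= t_range[1L])
    stop("t_range must be an increasing nonnegative pair")

  flat <- all(rates == 0)
  if (flat)
    warning("all-zero tumor dose rate: UTCP cannot reward irradiation")

  f <- function(t)
    utcp(tcp(rates * t, tcp_pars, voxel_volume),
         ntcp(healthy_rate * t, ntcp_pars))

  ts <- seq(t_range[1L], t_range[2L], by = t_step)
  if (ts[length(ts)] < t_range[2L]) ts <- c(ts, t_range[2L])
  us <- vapply(ts, f, numeric(1L))
  best <- which.max(us)  # first maximum: ties toward smaller t
  t_best <- ts[best]
  u_best <- us[best]

  if (refine && !flat) {
    lo <- ts[max(1L, best - 1L)]
    hi <- ts[min(length(ts), best + 1L)]
    if (hi > lo) {
      opt <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                             tol = 1e-6)
      # accept the refined point only if strictly better
      if (opt$objective > u_best ||
          (opt$objective == u_best && opt$maximum < t_best)) {
        t_best <- opt$maximum
        u_best <- opt$objective
      }
    }
  }

  structure(list(
    t_irr = t_best,
    tcp = tcp(rates * t_best, tcp_pars, voxel_volume),
    ntcp = ntcp(healthy_rate * t_best, ntcp_pars),
    utcp = u_best,
    d_max_healthy = healthy_rate * t_best,
    flat_tumor_warning = flat),
    class = "outcome_result")
}

#' @export
print.outcome_result <- function(x, ...) {
  cat(sprintf(
    "<outcome_result> Tirr %.1f min | UTCP %.3f (TCP %.3f, NTCP %.3f) | D %.2f Gy-Eq\n",
    x$t_irr, x$utcp, x$tcp, x$ntcp, x$d_max_healthy))
  if (!is.null(x$percent_dose))
    cat(sprintf("  %% dose at limiting point: boron %.0f / (n,p) %.0f / (n,n') %.0f / gamma %.0f\n",
                x$percent_dose[["boron"]], x$percent_dose[["thermal_n"]],
                x$percent_dose[["fast_n"]], x$percent_dose[["gamma"]]))
  invisible(x)
}

#' In-phantom radiobiological evaluation of a beam
#'
#' Ties the phantom tier together: deposits the beam into the cylinder
#' phantom, converts the dose-rate components into weighted dose rates
#' (tumor factors inside the tumor sphere, healthy-tissue factors
#' elsewhere), finds the mucosal dose-limiting point (the healthy voxel
#' with the highest weighted rate), and maximizes UTCP over the
#' irradiation time. Two-field plans can be evaluated by passing a list
#' of spectra with weights: their dose-rate fields are summed before
#' outcome evaluation.
#'
#' @param spectrum A \code{beam_spectrum}, or a list of them for a
#'   multi-field plan.
#' @param phantom A \code{cylinder_phantom_spec}.
#' @param kernels A \code{dose_kernel_params}.
#' @param tissues Tissue table (data.frame as
#'   [default_tissue_table()]); must contain \code{tumor} and
#'   \code{mucosa}.
#' @param tcp_pars,ntcp_pars Outcome model parameters.
#' @param t_range,t_step Time search bracket and step, minutes.
#' @param field_weights Relative weights of the fields when
#'   \code{spectrum} is a list (default equal).
#' @param convert Dose conversion (default fixed RBE/CBE; see
#'   [dose_conversion()]).
#' @return An \code{outcome_result} with, additionally,
#'   \code{percent_dose} (component percentages of the weighted dose at
#'   the limiting point), \code{dvh} (tumor DVH at \code{t_irr}) and the
#'   underlying \code{field}.
#' @export
evaluate_phantom_outcome <- function(spectrum,
                                     phantom = cylinder_phantom_spec(),
                                     kernels = dose_kernel_params(),
                                     tissues = default_tissue_table(),
                                     tcp_pars = tcp_params(),
                                     ntcp_pars = ntcp_params(),
                                     t_range = c(0, 120), t_step = 0.5,
                                     field_weights = NULL,
                                     convert = dose_conversion()) {
  spectra <- if (inherits(spectrum, "beam_spectrum")) list(spectrum)
             else spectrum
  if (is.null(field_weights))
    field_weights <- rep(1 / length(spectra), length(spectra))
  if (length(field_weights) != length(spectra))
    stop("need one field weight per spectrum")

  field <- NULL
  for (i in seq_along(spectra)) {
    fi <- deposit_dose_cylinder(spectra[[i]], phantom, kernels)
    if (is.null(field)) {
      field <- fi
      field$components <- lapply(fi$components,
                                 function(a) a * field_weights[i])
    } else {
      field$components <- Map(function(a, b) a + b * field_weights[i],
                              field$components, fi$components)
    }
  }

  tumor <- lookup_tissue("tumor", tissues, default_ok = FALSE)
  mucosa <- lookup_tissue("mucosa", tissues, default_ok = FALSE)

  weighted_rate <- function(tissue) {
    comp <- field$components
    convert(list(boron = comp$boron_per_ppm * tissue$boron_ppm,
                 thermal_n = comp$thermal_n,
                 fast_n = comp$fast_n,
                 gamma = comp$gamma), tissue)
  }
  w_tumor <- weighted_rate(tumor)
  w_healthy <- weighted_rate(mucosa)

  tumor_rates <- w_tumor[field$in_tumor]
  healthy_mask <- field$in_cylinder & !field$in_tumor
  if (!any(healthy_mask)) stop("no healthy-tissue voxels in phantom")
  limit_idx <- which(healthy_mask)[which.max(w_healthy[healthy_mask])]
  healthy_rate <- w_healthy[limit_idx]

  out <- optimize_time(tumor_rates, healthy_rate, tcp_pars, ntcp_pars,
                       voxel_volume = field$voxel_volume,
                       t_range = t_range, t_step = t_step)

  # component shares of the weighted dose at the limiting point
  comp_at <- lapply(field$components, function(a) a[limit_idx])
  w_parts <- list(
    boron = comp_at$boron_per_ppm * mucosa$boron_ppm * mucosa$cbe_boron,
    thermal_n = comp_at$thermal_n * mucosa$rbe_neutron,
    fast_n = comp_at$fast_n * mucosa$rbe_neutron,
    gamma = comp_at$gamma * mucosa$rbe_gamma)
  out$percent_dose <- if (sum(unlist(w_parts)) > 0)
    component_percentages(w_parts)
  else c(boron = NA_real_, thermal_n = NA_real_, fast_n = NA_real_,
         gamma = NA_real_)
  out$dvh <- compute_dvh(w_tumor[field$in_tumor] * out$t_irr)
  out$field <- field
  out
}
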