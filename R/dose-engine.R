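#' Tissue composition and radiobiological weighting factors
#'
#' A tissue is described by its 10B concentration (micrograms of 10B per
#' gram of tissue, "ppm") and by the factors converting each absorbed
#' dose component into photon-equivalent dose: RBE for gammas (usually 1),
#' a single neutron RBE applied to both the thermal-capture and the
#' fast-recoil components, and the compound biological effectiveness
#' (CBE) of the boron carrier in that tissue.
#'
#' @param name Tissue name.
#' @param boron_ppm 10B concentration, ppm (>= 0).
#' @param rbe_gamma,rbe_neutron,cbe_boron Positive weighting factors.
#' @return An object of class \code{tissue_composition}.
#' @examples
#' tissue_composition("tumor", 52.5, 1, 2.2, 5.3)
#' @export
tissue_composition <- function(name, boron_ppm, rbe_gamma = 1,
                               rbe_neutron = 3.2, cbe_boron = 1.3) {
  if (boron_ppm < 0) stop("boron_ppm must be nonnegative")
  if (any(c(rbe_gamma, rbe_neutron, cbe_boron) <= 0))
    stop("RBE/CBE factors must be positive")
  structure(list(name = name, boron_ppm = boron_ppm,
                 rbe_gamma = rbe_gamma, rbe_neutron = rbe_neutron,
                 cbe_boron = cbe_boron),
            class = "tissue_composition")
}

#' Default tissue table
#'
#' RBE/CBE factors and boron concentrations for the tissues used in BNCT
#' dosimetry of BPA-mediated treatments: 15 ppm in blood and most normal
#' tissues, 30 ppm in mucosa (twice blood), 52.5 ppm in tumor (3.5x
#' blood), 22.5 ppm in skin and 75 ppm in kidneys (renal excretion of the
#' carrier). Tumor takes RBEn 2.2 and CBE 5.3; skin 2.5/2.5; liver CBE
#' 4.2; other tissues RBEn 3.2 and CBE 1.3.
#'
#' @return A data.frame with columns \code{tissue}, \code{rbe_gamma},
#'   \code{rbe_neutron}, \code{cbe_boron}, \code{boron_ppm}.
#' @export
default_tissue_table <- function() {
  data.frame(
    tissue = c("brain", "skin", "liver", "lung", "kidney", "bladder",
               "tumor", "mucosa", "blood"),
    rbe_gamma = 1,
    rbe_neutron = c(3.2, 2.5, 3.2, 3.2, 3.2, 3.2, 2.2, 3.2, 3.2),
    cbe_boron = c(1.3, 2.5, 4.2, 1.3, 1.3, 1.3, 5.3, 1.3, 1.3),
    boron_ppm = c(15, 22.5, 15, 15, 75, 15, 52.5, 30, 15))
}

#' Read / write a tissue table
#'
#' CSV with columns \code{tissue}, \code{rbe_gamma}, \code{rbe_neutron},
#' \code{cbe_boron}, \code{boron_ppm}.
#'
#' @param file Path.
#' @return \code{read_tissue_table} returns the data.frame;
#'   \code{write_tissue_table} the path, invisibly.
#' @export
read_tissue_table <- function(file) {
  df <- utils::read.csv(file)
  need <- c("tissue", "rbe_gamma", "rbe_neutron", "cbe_boron",
            "boron_ppm")
  if (!all(need %in% names(df)))
    stop("tissue table lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df[need]
}

#' @rdname read_tissue_table
#' @param table Tissue data.frame.
#' @export
write_tissue_table <- function(table, file) {
  utils::write.csv(table, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

# look up one tissue row as a tissue_composition; fall back to the
# generic normal-tissue factors (1, 3.2, 1.3, 15 ppm) when allowed
lookup_tissue <- function(name, table, default_ok = TRUE) {
  i <- match(tolower(name), tolower(table$tissue))
  if (is.na(i) && grepl("s$", name, ignore.case = TRUE))
    i <- match(tolower(sub("s$", "", name, ignore.case = TRUE)),
               tolower(table$tissue))
  if (is.na(i)) {
    if (!default_ok)
      stop("no tissue factors for '", name, "'")
    return(tissue_composition(name, 15, 1, 3.2, 1.3))
  }
  tissue_composition(table$tissue[i], table$boron_ppm[i],
                     table$rbe_gamma[i], table$rbe_neutron[i],
                     table$cbe_boron[i])
}

#' Per-component dose rates at a point or voxel
#'
#' @param boron_per_ppm Boron-capture dose rate per 1 ppm of 10B,
#'   Gy min^-1 ppm^-1.
#' @param thermal_n Thermal-neutron (nitrogen-capture) dose rate,
#'   Gy min^-1.
#' @param fast_n Fast-neutron (recoil) dose rate, Gy min^-1.
#' @param gamma Gamma dose rate, Gy min^-1.
#' @return An object of class \code{dose_components}.
#' @export
dose_components <- function(boron_per_ppm = 0, thermal_n = 0,
                            fast_n = 0, gamma = 0) {
  v <- c(boron_per_ppm, thermal_n, fast_n, gamma)
  if (any(!is.finite(v)) || any(v < 0))
    stop("dose-rate components must be finite and nonnegative")
  structure(list(boron_per_ppm = boron_per_ppm, thermal_n = thermal_n,
                 fast_n = fast_n, gamma = gamma),
            class = "dose_components")
}

#' Absorbed dose components after an irradiation
#'
#' Multiplies each dose-rate component by the irradiation time; the
#' boron component additionally picks up the tissue's 10B concentration.
#' Dose rates are assumed constant over the irradiation.
#'
#' @param components A \code{dose_components} (rates, Gy min^-1; boron
#'   per ppm).
#' @param tissue A \code{tissue_composition}.
#' @param t_min Irradiation time, minutes (>= 0).
#' @return A list with absorbed doses in Gy: \code{boron},
#'   \code{thermal_n}, \code{fast_n}, \code{gamma}, \code{total}.
#' @examples
#' cmp <- dose_components(boron_per_ppm = 0.01)
#' tum <- tissue_composition("tumor", 52.5, 1, 2.2, 5.3)
#' absorbed_dose(cmp, tum, t_min = 10)$boron  # 5.25 Gy
#' @export
absorbed_dose <- function(components, tissue, t_min) {
  stopifnot(inherits(components, "dose_components"),
            inherits(tissue, "tissue_composition"))
  if (!is.finite(t_min) || t_min < 0)
    stop("irradiation time must be nonnegative")
  out <- list(boron = components$boron_per_ppm * tissue$boron_ppm * t_min,
              thermal_n = components$thermal_n * t_min,
              fast_n = components$fast_n * t_min,
              gamma = components$gamma * t_min)
  out$total <- out$boron + out$thermal_n + out$fast_n + out$gamma
  out
}

#' Fixed-RBE/CBE weighted (photon-equivalent) dose
#'
#' Converts absorbed dose components into Gy-Eq with constant factors:
#' gamma dose times RBE_gamma, both neutron components times the single
#' tissue RBE_n, boron dose times the CBE. This is the shipped default
#' dose-conversion; see [dose_conversion()] for plugging in other models.
#'
#' @param absorbed A list with components \code{boron},
#'   \code{thermal_n}, \code{fast_n}, \code{gamma} in Gy (as returned by
#'   [absorbed_dose()]).
#' @param tissue A \code{tissue_composition}.
#' @return Weighted dose, Gy-Eq.
#' @export
weighted_dose_fixed_rbe <- function(absorbed, tissue) {
  stopifnot(inherits(tissue, "tissue_composition"))
  absorbed$gamma * tissue$rbe_gamma +
    (absorbed$thermal_n + absorbed$fast_n) * tissue$rbe_neutron +
    absorbed$boron * tissue$cbe_boron
}

#' Pluggable dose-conversion interface
#'
#' Returns a function mapping (absorbed components, tissue) to a
#' photon-equivalent dose. The shipped default is the fixed-RBE/CBE
#' conversion; radiobiologically motivated alternatives (e.g. an
#' iso-effective dose model with its own published parameters) can be
#' supplied as \code{fun}.
#'
#' @param fun Optional replacement conversion,
#'   \code{function(absorbed, tissue) -> Gy-Eq}.
#' @return The conversion function.
#' @export
dose_conversion <- function(fun = NULL) {
  if (is.null(fun)) return(weighted_dose_fixed_rbe)
  if (!is.function(fun)) stop("fun must be a function(absorbed, tissue)")
  fun
}

#' ICRP energy-dependent neutron radiation weighting factor
#'
#' The continuous three-piece log-normal curve of the current ICRP
#' recommendations: for neutron energy E in MeV,
#' \itemize{
#'   \item E < 1 MeV: 2.5 + 18.2 exp(-(ln E)^2 / 6)
#'   \item 1 <= E <= 50 MeV: 5.0 + 17.0 exp(-(ln 2E)^2 / 6)
#'   \item E > 50 MeV: 2.5 + 3.25 exp(-(ln 0.04E)^2 / 6)
#' }
#' The curve is continuous, peaks near 20.7 around 1 MeV, and falls to
#' about 2.5 for thermal neutrons.
#'
#' @param energy_ev Neutron energy (vectorized), eV; positive.
#' @return Weighting factor w_R (dimensionless, Sv/Gy).
#' @examples
#' neutron_wr(c(0.025, 1e4, 1e6))
#' @export
neutron_wr <- function(energy_ev) {
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0))
    stop("neutron energies must be positive")
  E <- energy_ev / 1e6  # MeV
  w <- ifelse(E < 1, 2.5 + 18.2 * exp(-log(E)^2 / 6),
       ifelse(E <= 50, 5.0 + 17.0 * exp(-log(2 * E)^2 / 6),
              2.5 + 3.25 * exp(-log(0.04 * E)^2 / 6)))
  as.numeric(w)
}

#' ICRP-style equivalent dose
#'
#' Weights the absorbed dose components for radiation-protection style
#' reporting: photons by 1, the boron-capture dose by 20, and the neutron
#' dose by the energy-dependent w_R curve. The neutron dose may be given
#' energy-resolved (vectors \code{neutron_dose_gy} and
#' \code{neutron_energy_ev} of equal length) or lumped with a scalar
#' mean-energy proxy.
#'
#' @param absorbed A list with components \code{boron},
#'   \code{thermal_n}, \code{fast_n}, \code{gamma} in Gy.
#' @param neutron_energy_ev Energy (eV) at which to evaluate w_R: a
#'   scalar mean-energy proxy, or a vector matching
#'   \code{neutron_dose_gy}.
#' @param neutron_dose_gy Optional energy-resolved neutron doses, Gy;
#'   when supplied they replace \code{absorbed$thermal_n +
#'   absorbed$fast_n}.
#' @param scheme A \code{weighting_scheme} (for non-default photon or
#'   boron weights, or a replacement w_R curve).
#' @return Equivalent dose, Sv.
#' @examples
#' a <- list(boron = 0.5, thermal_n = 0, fast_n = 0, gamma = 0)
#' equivalent_dose_icrp(a)  # 10 Sv
#' @export
equivalent_dose_icrp <- function(absorbed, neutron_energy_ev = NULL,
                                 neutron_dose_gy = NULL,
                                 scheme = weighting_scheme()) {
  stopifnot(inherits(scheme, "weighting_scheme"))
  n_lumped <- absorbed$thermal_n + absorbed$fast_n
  if (is.null(neutron_dose_gy)) {
    if (n_lumped > 0 && is.null(neutron_energy_ev))
      stop(paste("neutron dose present but no energy information:",
                 "supply neutron_energy_ev (mean-energy proxy) or an",
                 "energy-resolved neutron_dose_gy"))
    neutron_sv <- if (n_lumped > 0)
      n_lumped * scheme$wr(neutron_energy_ev) else 0
  } else {
    if (is.null(neutron_energy_ev) ||
        length(neutron_energy_ev) != length(neutron_dose_gy))
      stop("neutron_dose_gy needs a matching neutron_energy_ev vector")
    neutron_sv <- sum(neutron_dose_gy * scheme$wr(neutron_energy_ev))
  }
  absorbed$gamma * scheme$photon_weight +
    absorbed$boron * scheme$boron_weight + neutron_sv
}

#' Weighting scheme for dose conversion
#'
#' @param mode \code{"fixed_rbe"} (tissue RBE/CBE factors) or
#'   \code{"icrp_equivalent"} (photon 1, boron 20, neutron w_R(E)).
#' @param photon_weight,boron_weight Positive weights for the
#'   equivalent-dose mode.
#' @param wr Neutron weighting function of energy in eV (default the
#'   ICRP curve, [neutron_wr()]).
#' @return An object of class \code{weighting_scheme}.
#' @export
weighting_scheme <- function(mode = c("fixed_rbe", "icrp_equivalent"),
                             photon_weight = 1, boron_weight = 20,
                             wr = neutron_wr) {
  mode <- match.arg(mode)
  if (photon_weight <= 0 || boron_weight <= 0)
    stop("weights must be positive")
  if (!is.function(wr)) stop("wr must be a function of energy (eV)")
  structure(list(mode = mode, photon_weight = photon_weight,
                 boron_weight = boron_weight, wr = wr),
            class = "weighting_scheme")
}

#' Percent contribution of each dose component
#'
#' @param absorbed A list with components \code{boron},
#'   \code{thermal_n}, \code{fast_n}, \code{gamma} (Gy or Gy-Eq, any
#'   consistent scale) with positive total.
#' @return Named numeric of length 4 (\code{boron}, \code{thermal_n},
#'   \code{fast_n}, \code{gamma}) summing to 100.
#' @export
component_percentages <- function(absorbed) {
  v <- c(boron = absorbed$boron, thermal_n = absorbed$thermal_n,
         fast_n = absorbed$fast_n, gamma = absorbed$gamma)
  if (any(v < 0)) stop("components must be nonnegative")
  tot <- sum(v)
  if (tot <= 0) stop("total dose is zero: percentages undefined")
  100 * v / tot
}
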