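#' Log-spaced neutron energy grid
#'
#' Builds the energy axis used by all spectral quantities: a set of
#' strictly increasing bin edges, log-spaced between \code{emin} and
#' \code{emax}. The default range (1e-3 eV to 1e7 eV) covers the thermal,
#' epithermal and fast neutron ranges relevant to BNCT beam design.
#'
#' @param emin Lower edge of the first bin, in eV. Must be positive.
#' @param emax Upper edge of the last bin, in eV. Must exceed \code{emin}.
#' @param n_bins Number of energy bins (at least 3).
#'
#' @return An object of class \code{energy_grid}: a list with elements
#'   \code{edges} (length \code{n_bins + 1}), \code{mids} (geometric bin
#'   centers), \code{widths} and \code{n_bins}.
#'
#' @examples
#' g <- make_energy_grid()
#' range(g$edges)
#' @export
make_energy_grid <- function(emin = 1e-3, emax = 1e7, n_bins = 100L) {
  stopifnot(is.numeric(emin), is.numeric(emax), length(emin) == 1L,
            length(emax) == 1L)
  if (!is.finite(emin) || !is.finite(emax) || emin <= 0 || emax <= emin)
    stop("need 0 < emin < emax, got [", emin, ", ", emax, "]")
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 3L)
    stop("n_bins must be an integer >= 3")
  edges <- exp(seq(log(emin), log(emax), length.out = n_bins + 1L))
  # guard against rounding making neighbours equal on extreme inputs
  if (any(diff(edges) <= 0))
    stop("energy range too narrow for ", n_bins, " log-spaced bins")
  structure(
    list(edges = edges,
         mids = sqrt(edges[-length(edges)] * edges[-1L]),
         widths = diff(edges),
         n_bins = n_bins),
    class = "energy_grid")
}

#' @export
print.energy_grid <- function(x, ...) {
  cat(sprintf("<energy_grid> %d log-spaced bins, %.3g eV to %.3g eV\n",
              x$n_bins, x$edges[1L], x$edges[length(x$edges)]))
  invisible(x)
}

#' Classify a neutron energy into the standard BNCT bands
#'
#' Thermal neutrons are those below 0.5 eV and fast neutrons those above
#' 10 keV; everything in between is epithermal. The band boundaries
#' themselves (0.5 eV and 10 keV exactly) are assigned to the epithermal
#' band, i.e. the epithermal interval is closed.
#'
#' @param energy_ev Neutron energy (or vector of energies) in eV; must be
#'   positive.
#' @return A character vector with values \code{"thermal"},
#'   \code{"epithermal"} or \code{"fast"}.
#' @examples
#' classify_energy(c(0.025, 0.5, 5e3, 2e4))
#' @export
classify_energy <- function(energy_ev) {
  if (!is.numeric(energy_ev) || length(energy_ev) == 0L)
    stop("energy_ev must be a non-empty numeric vector")
  if (any(!is.finite(energy_ev)) || any(energy_ev <= 0))
    stop("all energies must be positive and finite")
  out <- rep("epithermal", length(energy_ev))
  out[energy_ev < THERMAL_EDGE_EV] <- "thermal"
  out[energy_ev > FAST_EDGE_EV] <- "fast"
  out
}

# Band boundaries in eV: thermal < 0.5 eV, fast > 10 keV.
THERMAL_EDGE_EV <- 0.5
FAST_EDGE_EV <- 1e4
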