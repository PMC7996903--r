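#' Assemble the per-organ dose table at a treatment time
#'
#' Converts raw per-organ dose-rate components into the standard
#' out-of-beam dosimetry table: per-component absorbed doses (cGy), the
#' ICRP-style equivalent dose DW (cSv, photon weight 1, boron weight 20,
#' neutron dose weighted by w_R at the organ's mean neutron energy), and
#' the fixed-RBE/CBE biologically weighted dose DEq (cGy-Eq). Column
#' naming: DN is the fast-neutron recoil dose, DB the boron-capture
#' dose, DH the thermal-neutron capture dose, Dgamma the photon dose.
#'
#' Organs without a row in the tissue table receive the generic
#' normal-tissue factors (RBE_gamma 1, RBE_n 3.2, CBE 1.3, 15 ppm) when
#' \code{default_factors} is TRUE, otherwise an error is raised.
#' When per-component relative errors are supplied, the DEq uncertainty
#' is propagated in quadrature; otherwise it is omitted (NA).
#'
#' @param raw An \code{organ_components} data.frame (see
#'   [generate_organ_doses()]).
#' @param tissues Tissue table data.frame (default
#'   [default_tissue_table()]).
#' @param t_irr Irradiation time, minutes.
#' @param scheme A \code{weighting_scheme} for the equivalent dose.
#' @param default_factors Allow default factors for unlisted organs.
#' @param rel_err Optional named numeric of per-component relative
#'   errors (names among \code{boron}, \code{thermal_n}, \code{fast_n},
#'   \code{gamma}).
#' @return An object of class \code{organ_dose_table}: data.frame with
#'   columns \code{organ}, \code{DN_cGy}, \code{DB_cGy}, \code{DH_cGy},
#'   \code{Dgamma_cGy}, \code{DW_cSv}, \code{DEq_cGyEq},
#'   \code{DEq_err_cGyEq}.
#' @export
assemble_organ_table <- function(raw, tissues = default_tissue_table(),
                                 t_irr,
                                 scheme = weighting_scheme("icrp_equivalent"),
                                 default_factors = TRUE,
                                 rel_err = NULL) {
  stopifnot(is.data.frame(raw), inherits(scheme, "weighting_scheme"))
  if (!is.finite(t_irr) || t_irr < 0)
    stop("t_irr must be nonnegative")
  rows <- lapply(seq_len(nrow(raw)), function(i) {
    tissue <- lookup_tissue(raw$organ[i], tissues,
                            default_ok = default_factors)
    comp <- dose_components(raw$boron_per_ppm[i], raw$thermal_n[i],
                            raw$fast_n[i], raw$gamma[i])
    a <- absorbed_dose(comp, tissue, t_irr)
    deq <- weighted_dose_fixed_rbe(a, tissue)
    dw <- equivalent_dose_icrp(
      a, neutron_energy_ev = raw$mean_neutron_energy_ev[i],
      scheme = scheme)
    err <- NA_real_
    if (!is.null(rel_err)) {
      w <- c(boron = tissue$cbe_boron, thermal_n = tissue$rbe_neutron,
             fast_n = tissue$rbe_neutron, gamma = tissue$rbe_gamma)
      parts <- c(boron = a$boron, thermal_n = a$thermal_n,
                 fast_n = a$fast_n, gamma = a$gamma) * w
      re <- rel_err[names(parts)]
      re[is.na(re)] <- 0
      err <- sqrt(sum((parts * re)^2)) * 100
    }
    data.frame(organ = raw$organ[i],
               DN_cGy = a$fast_n * 100,
               DB_cGy = a$boron * 100,
               DH_cGy = a$thermal_n * 100,
               Dgamma_cGy = a$gamma * 100,
               DW_cSv = dw * 100,
               DEq_cGyEq = deq * 100,
               DEq_err_cGyEq = err)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("organ_dose_table", "data.frame")
  out
}

#' Out-of-field dose summary statistic
#'
#' Aggregates the biologically weighted organ doses outside the
#' irradiation field into one scalar used to rank beams by safety. The
#' default statistic is the sum of DEq over out-of-field organs;
#' \code{"max"} and \code{"mean"} are also available. For a head
#' irradiation the in-field set defaults to brain, head, pharynx and
#' thyroid.
#'
#' @param table An \code{organ_dose_table}.
#' @param in_field Character set of in-field organ names
#'   (case-insensitive).
#' @param statistic One of \code{"sum"}, \code{"max"}, \code{"mean"}.
#' @return The scalar statistic, cGy-Eq.
#' @export
out_of_field_summary <- function(table,
                                 in_field = c("brain", "head",
                                              "pharynx", "thyroid"),
                                 statistic = c("sum", "max", "mean")) {
  stopifnot(is.data.frame(table))
  statistic <- match.arg(statistic)
  out <- table[!(tolower(table$organ) %in% tolower(in_field)), ]
  if (nrow(out) == 0L)
    stop("no out-of-field organs: cannot summarize")
  switch(statistic,
         sum = sum(out$DEq_cGyEq),
         max = max(out$DEq_cGyEq),
         mean = mean(out$DEq_cGyEq))
}

#' Select the safest beam
#'
#' Picks the beam with the smallest out-of-field dose statistic. Ties
#' are broken by higher UTCP (when supplied), then lexicographically by
#' beam id.
#'
#' @param summaries Named numeric vector of per-beam out-of-field
#'   statistics (names are beam ids).
#' @param utcps Optional named numeric of per-beam UTCP values for
#'   tie-breaking.
#' @return The selected beam id (character scalar).
#' @examples
#' select_safest_beam(c(a = 10, b = 5, c = 7))
#' @export
select_safest_beam <- function(summaries, utcps = NULL) {
  if (length(summaries) == 0L) stop("empty beam set")
  if (is.null(names(summaries)) || anyNA(names(summaries)))
    stop("summaries must be named by beam id")
  ids <- names(summaries)
  u <- if (is.null(utcps)) rep(0, length(ids)) else {
    m <- utcps[ids]
    m[is.na(m)] <- 0
    as.numeric(m)
  }
  ord <- order(summaries, -u, ids)
  ids[ord[1L]]
}
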