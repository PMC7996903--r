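#' Cylindrical neck phantom bearing a spherical tumor
#'
#' The standard geometry for in-phantom radiobiological evaluation of
#' head-and-neck beams: a cylinder of mucosa-equivalent tissue (default
#' radius 10 cm, height 24 cm) containing a 2 cm radius tumor sphere
#' whose center sits 3 cm below the irradiated face, positioned at a
#' beam-to-phantom distance of 7.5 cm.
#'
#' Coordinate convention used throughout: the cylinder axis coincides
#' with the beam axis; depth z is measured from the irradiated face;
#' voxel centers sit at (i + 0.5) * voxel_size for 0-based indices.
#'
#' @param radius Cylinder radius, cm.
#' @param height Cylinder height (extent along the beam axis), cm.
#' @param tumor_radius Tumor sphere radius, cm.
#' @param tumor_center_depth Depth of the tumor center below the
#'   irradiated face, cm.
#' @param beam_distance Beam-port-to-phantom distance, cm.
#' @param voxel_size Isotropic voxel edge, cm.
#' @return An object of class \code{cylinder_phantom_spec}.
#' @export
cylinder_phantom_spec <- function(radius = 10, height = 24,
                                  tumor_radius = 2,
                                  tumor_center_depth = 3,
                                  beam_distance = 7.5,
                                  voxel_size = 0.5) {
  stopifnot(radius > 0, height > 0, tumor_radius > 0, voxel_size > 0,
            beam_distance >= 0)
  if (tumor_center_depth - tumor_radius < 0 ||
      tumor_center_depth + tumor_radius > height ||
      tumor_radius > radius)
    stop("tumor sphere must lie fully inside the cylinder")
  structure(list(radius = radius, height = height,
                 tumor_radius = tumor_radius,
                 tumor_center_depth = tumor_center_depth,
                 beam_distance = beam_distance,
                 voxel_size = voxel_size),
            class = "cylinder_phantom_spec")
}

#' Analytic dose-deposition kernels for the phantom
#'
#' Parametric stand-in for full radiation transport inside the phantom.
#' The thermal-neutron fluence (which drives the boron-capture and
#' nitrogen-capture dose) follows a difference-of-exponentials build-up
#' in depth, exp(-z/lambda_fall) - exp(-z/lambda_rise), normalized to its
#' sub-surface maximum; the fast-neutron and gamma components attenuate
#' exponentially from the surface; the lateral profile is the port disk
#' softened by a Gaussian of width \code{lateral_sigma}. Surface
#' normalizations are dose rates at the reference flux, at the depth-curve
#' maximum for the thermal-driven components and at the surface for the
#' attenuating ones. All components scale linearly with the total beam
#' flux.
#'
#' @param lambda_rise,lambda_fall Build-up length pair of the thermal
#'   component, cm; \code{lambda_rise < lambda_fall}.
#' @param lambda_fast Fast-neutron attenuation length, cm.
#' @param lambda_gamma Gamma attenuation length, cm.
#' @param lateral_sigma Gaussian lateral spread of the port edge, cm.
#' @param s_boron_per_ppm Boron-capture dose-rate normalization per 1 ppm
#'   of 10B, Gy min^-1 ppm^-1 at the reference flux.
#' @param s_thermal Thermal-neutron (nitrogen-capture) dose-rate
#'   normalization, Gy min^-1.
#' @param s_fast Fast-neutron (recoil) dose-rate normalization,
#'   Gy min^-1.
#' @param s_gamma Gamma dose-rate normalization, Gy min^-1.
#' @param reference_flux Total flux the normalizations refer to,
#'   cm^-2 s^-1.
#' @return An object of class \code{dose_kernel_params}.
#' @export
dose_kernel_params <- function(lambda_rise = 0.8, lambda_fall = 6,
                               lambda_fast = 4, lambda_gamma = 13,
                               lateral_sigma = 1.0,
                               s_boron_per_ppm = 0.0039,
                               s_thermal = 0.0069,
                               s_fast = 0.0073,
                               s_gamma = 0.065,
                               reference_flux = 1e9) {
  if (any(c(lambda_rise, lambda_fall, lambda_fast, lambda_gamma,
            lateral_sigma, reference_flux) <= 0))
    stop("all kernel lengths and the reference flux must be positive")
  if (lambda_rise >= lambda_fall)
    stop("lambda_rise must be smaller than lambda_fall")
  if (any(c(s_boron_per_ppm, s_thermal, s_fast, s_gamma) < 0))
    stop("dose-rate normalizations must be nonnegative")
  structure(list(lambda_rise = lambda_rise, lambda_fall = lambda_fall,
                 lambda_fast = lambda_fast, lambda_gamma = lambda_gamma,
                 lateral_sigma = lateral_sigma,
                 s_boron_per_ppm = s_boron_per_ppm,
                 s_thermal = s_thermal, s_fast = s_fast,
                 s_gamma = s_gamma, reference_flux = reference_flux),
            class = "dose_kernel_params")
}

#' Depth of the thermal-fluence maximum (closed form)
#'
#' The difference-of-exponentials build-up peaks at
#' z* = lambda_rise * lambda_fall / (lambda_fall - lambda_rise) *
#' log(lambda_fall / lambda_rise).
#'
#' @param kernels A \code{dose_kernel_params}.
#' @return Depth of the maximum, cm.
#' @export
thermal_peak_depth <- function(kernels) {
  stopifnot(inherits(kernels, "dose_kernel_params"))
  a <- kernels$lambda_rise
  b <- kernels$lambda_fall
  a * b / (b - a) * log(b / a)
}

# depth shape of the thermal component, normalized to 1 at its maximum
thermal_depth_shape <- function(z, kernels) {
  a <- kernels$lambda_rise
  b <- kernels$lambda_fall
  zp <- thermal_peak_depth(kernels)
  peak <- exp(-zp / b) - exp(-zp / a)
  (exp(-z / b) - exp(-z / a)) / peak
}

# lateral profile: port disk convolved with a Gaussian edge,
# approximated by the erf edge profile and normalized to 1 on axis
lateral_shape <- function(r, port_radius, sigma) {
  stats::pnorm((port_radius - r) / sigma) /
    stats::pnorm(port_radius / sigma)
}

#' Deposit a beam into the cylinder phantom
#'
#' Evaluates the four dose-rate components on the phantom voxel grid:
#' boron-capture dose per 1 ppm of 10B and thermal-neutron dose (both
#' following the thermal-fluence build-up), fast-neutron recoil dose and
#' gamma dose (both attenuating from the surface). Voxels outside the
#' cylinder are zero. Every component scales linearly with the total
#' neutron flux of the spectrum relative to the kernel reference flux,
#' so a zero-flux beam yields an all-zero field.
#'
#' @param spectrum A \code{beam_spectrum} (its band structure sets the
#'   overall source strength; the port radius and the phantom lateral
#'   geometry set the lateral profile).
#' @param phantom A \code{cylinder_phantom_spec}.
#' @param kernels A \code{dose_kernel_params}.
#' @return An object of class \code{dose_field}: a list with
#'   \code{components} (named list of 3-D arrays \code{boron_per_ppm}
#'   (Gy min^-1 ppm^-1), \code{thermal_n}, \code{fast_n}, \code{gamma}
#'   (Gy min^-1)), voxel-center coordinate vectors \code{x}, \code{y},
#'   \code{z}, logical masks \code{in_cylinder} and \code{in_tumor}, and
#'   the \code{phantom} spec.
#' @examples
#' sp <- generate_beam_spectrum(make_energy_grid(), beam_model_params())
#' fld <- deposit_dose_cylinder(sp, cylinder_phantom_spec(voxel_size = 1),
#'                              dose_kernel_params())
#' range(fld$components$thermal_n)
#' @export
deposit_dose_cylinder <- function(spectrum, phantom, kernels) {
  stopifnot(inherits(spectrum, "beam_spectrum"),
            inherits(phantom, "cylinder_phantom_spec"),
            inherits(kernels, "dose_kernel_params"))
  h <- phantom$voxel_size
  if (2 * phantom$tumor_radius / h < 2)
    stop("voxel grid too coarse: fewer than 2 voxels across the tumor")

  nx <- as.integer(ceiling(2 * phantom$radius / h))
  nz <- as.integer(ceiling(phantom$height / h))
  x <- (seq_len(nx) - 0.5) * h - phantom$radius
  z <- (seq_len(nz) - 0.5) * h

  rr <- sqrt(outer(x^2, x^2, `+`))                 # nx x nx transverse radius
  in_cyl2d <- rr <= phantom$radius
  lat2d <- lateral_shape(rr, spectrum$port_radius, kernels$lateral_sigma)
  lat2d[!in_cyl2d] <- 0

  scale <- sum(spectrum$flux_per_bin) / kernels$reference_flux

  field_from <- function(depth_shape, s0) {
    a <- outer(as.vector(lat2d), depth_shape * s0 * scale)
    array(a, dim = c(nx, nx, nz))
  }
  th_z <- thermal_depth_shape(z, kernels)
  components <- list(
    boron_per_ppm = field_from(th_z, kernels$s_boron_per_ppm),
    thermal_n = field_from(th_z, kernels$s_thermal),
    fast_n = field_from(exp(-z / kernels$lambda_fast), kernels$s_fast),
    gamma = field_from(exp(-z / kernels$lambda_gamma), kernels$s_gamma))

  in_cyl <- array(rep(in_cyl2d, nz), dim = c(nx, nx, nz))
  d2 <- outer(as.vector(rr^2), (z - phantom$tumor_center_depth)^2, `+`)
  in_tumor <- array(d2 <= phantom$tumor_radius^2, dim = c(nx, nx, nz)) &
    in_cyl

  structure(list(components = components, x = x, y = x, z = z,
                 in_cylinder = in_cyl, in_tumor = in_tumor,
                 phantom = phantom,
                 voxel_volume = h^3),
            class = "dose_field")
}

#' @export
print.dose_field <- function(x, ...) {
  d <- dim(x$components[[1L]])
  cat(sprintf(
    "<dose_field> %d x %d x %d voxels (%.2g cm), %d in cylinder, %d in tumor\n",
    d[1L], d[2L], d[3L], x$phantom$voxel_size,
    sum(x$in_cylinder), sum(x$in_tumor)))
  invisible(x)
}

#' Write a dose field as a directory of plain-text arrays
#'
#' One whitespace-separated flat file per component (values in
#' column-major order) plus a JSON sidecar holding the phantom spec and
#' the array dimensions.
#'
#' @param field A \code{dose_field}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dose_field <- function(field, dir) {
  stopifnot(inherits(field, "dose_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(field$components))
    utils::write.table(
      data.frame(value = as.vector(field$components[[nm]])),
      file.path(dir, paste0(nm, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  sidecar <- list(dims = dim(field$components[[1L]]),
                  phantom = unclass(field$phantom))
  jsonlite::write_json(sidecar, file.path(dir, "field.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dose field written by [write_dose_field()]
#'
#' @param dir Directory containing the component files and sidecar.
#' @return A \code{dose_field}.
#' @export
read_dose_field <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "field.json"),
                                 simplifyVector = TRUE)
  phantom <- do.call(cylinder_phantom_spec, as.list(sidecar$phantom))
  dims <- as.integer(sidecar$dims)
  comp_names <- c("boron_per_ppm", "thermal_n", "fast_n", "gamma")
  components <- lapply(comp_names, function(nm) {
    v <- utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                           header = TRUE)$value
    if (length(v) != prod(dims))
      stop("component ", nm, " has wrong length")
    array(v, dim = dims)
  })
  names(components) <- comp_names
  h <- phantom$voxel_size
  x <- (seq_len(dims[1L]) - 0.5) * h - phantom$radius
  z <- (seq_len(dims[3L]) - 0.5) * h
  rr <- sqrt(outer(x^2, x^2, `+`))
  in_cyl <- array(rep(rr <= phantom$radius, dims[3L]), dim = dims)
  d2 <- outer(as.vector(rr^2), (z - phantom$tumor_center_depth)^2, `+`)
  in_tumor <- array(d2 <= phantom$tumor_radius^2, dim = dims) & in_cyl
  structure(list(components = components, x = x, y = x, z = z,
                 in_cylinder = in_cyl, in_tumor = in_tumor,
                 phantom = phantom, voxel_volume = h^3),
            class = "dose_field")
}
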