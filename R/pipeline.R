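#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used in the rendered
#' tables (R's own \code{round} rounds half to even).
#'
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# tiny FNV-1a over a string; enough to fingerprint a config in reports
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Build a pipeline configuration
#'
#' A configuration names the candidate beams (either generator parameter
#' sets or spectrum files) and the shared evaluation settings. It can be
#' given as an R list or loaded from a YAML file with the same
#' structure.
#'
#' @param beams List of beam entries; each entry has an \code{id} and
#'   either \code{params} (arguments to [beam_model_params()], with
#'   \code{fractions} as a named list) or \code{spectrum_file}.
#' @param grid Arguments to [make_energy_grid()].
#' @param phantom Arguments to [cylinder_phantom_spec()].
#' @param kernels Arguments to [dose_kernel_params()].
#' @param tissue_table Optional path to a tissue CSV; defaults to the
#'   built-in table.
#' @param tcp,ntcp Arguments to [tcp_params()] / [ntcp_params()].
#' @param thresholds Arguments to [iaea_thresholds()].
#' @param in_field In-field organ names for the safety statistic.
#' @param organs Optional data.frame of organs (default
#'   [default_organ_set()]).
#' @param t_range,t_step UTCP time search settings, minutes.
#' @param seed Integer seed recorded in every output and used for any
#'   stochastic generator option.
#' @param noise_sd Log-normal noise level passed to the generators
#'   (default 0).
#' @param out_dir Optional output directory for reports.
#' @return An object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(beams, grid = list(), phantom = list(),
                            kernels = list(), tissue_table = NULL,
                            tcp = list(), ntcp = list(),
                            thresholds = list(),
                            in_field = c("brain", "head", "pharynx",
                                         "thyroid"),
                            organs = NULL,
                            t_range = c(0, 120), t_step = 0.5,
                            seed = 1L, noise_sd = 0,
                            out_dir = NULL) {
  if (length(beams) == 0L) stop("at least one beam must be configured")
  ids <- vapply(beams, function(b) as.character(b$id %||% ""),
                character(1L))
  if (any(ids == "") || anyDuplicated(ids))
    stop("every beam needs a unique id")
  for (b in beams)
    if (!is.null(b$spectrum_file) && !file.exists(b$spectrum_file))
      stop("spectrum file not found: ", b$spectrum_file)
  if (!is.null(tissue_table) && !file.exists(tissue_table))
    stop("tissue table not found: ", tissue_table)
  structure(list(beams = beams, grid = grid, phantom = phantom,
                 kernels = kernels, tissue_table = tissue_table,
                 tcp = tcp, ntcp = ntcp, thresholds = thresholds,
                 in_field = in_field, organs = organs,
                 t_range = t_range, t_step = t_step,
                 seed = as.integer(seed), noise_sd = noise_sd,
                 out_dir = out_dir),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a pipeline configuration from YAML
#'
#' @param file YAML file whose top-level keys mirror the arguments of
#'   [pipeline_config()].
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(file) {
  raw <- yaml::read_yaml(file)
  raw$beams <- lapply(raw$beams, function(b) {
    if (!is.null(b$params$fractions))
      b$params$fractions <- unlist(b$params$fractions)
    b
  })
  if (!is.null(raw$organs)) raw$organs <- as.data.frame(raw$organs)
  do.call(pipeline_config, raw)
}

# resolve one beam entry to a beam_spectrum
beam_entry_spectrum <- function(entry, grid, config) {
  if (!is.null(entry$spectrum_file))
    return(read_beam_spectrum(entry$spectrum_file))
  params <- do.call(beam_model_params, entry$params %||% list())
  generate_beam_spectrum(grid, params, seed = config$seed,
                         noise_sd = config$noise_sd)
}

#' Run the full three-tier beam evaluation
#'
#' For every configured beam: (1) in-air figures of merit and
#' compliance with the recommended thresholds; (2) in-phantom
#' radiobiological outcome -- the irradiation time maximizing UTCP, with
#' TCP, NTCP, the maximum healthy-tissue dose and the component shares
#' at the dose-limiting point; (3) the out-of-beam organ dose table at
#' that irradiation time and its out-of-field summary. The beam with the
#' smallest out-of-field dose is selected (ties broken by higher UTCP,
#' then by id). When \code{out_dir} is set, a JSON report and CSV tables
#' are written; outputs are byte-identical across reruns with the same
#' configuration and seed.
#'
#' @param config A \code{pipeline_config}, or a path to a YAML file.
#' @param verbose Log per-stage progress to stderr.
#' @return A list with \code{beams} (per-beam results), \code{selected},
#'   and \code{provenance} (seed, config fingerprint, package version).
#' @export
run_evaluation <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  grid <- do.call(make_energy_grid, config$grid)
  phantom <- do.call(cylinder_phantom_spec, config$phantom)
  kernels <- do.call(dose_kernel_params, config$kernels)
  tissues <- if (is.null(config$tissue_table)) default_tissue_table()
             else read_tissue_table(config$tissue_table)
  tcp_pars <- do.call(tcp_params, config$tcp)
  ntcp_pars <- do.call(ntcp_params, config$ntcp)
  thr <- do.call(iaea_thresholds, config$thresholds)
  organs <- config$organs %||% default_organ_set()

  beams <- list()
  for (entry in config$beams) {
    id <- entry$id
    say("beam %s: spectrum", id)
    spectrum <- tryCatch(
      beam_entry_spectrum(entry, grid, config),
      error = function(e) stop("stage spectrum [", id, "]: ",
                               conditionMessage(e), call. = FALSE))
    say("beam %s: in-air FOM", id)
    fom <- tryCatch(compute_foms(spectrum),
      error = function(e) stop("stage fom [", id, "]: ",
                               conditionMessage(e), call. = FALSE))
    compliance <- check_compliance(fom, thr)
    say("beam %s: in-phantom outcome", id)
    outcome <- tryCatch(
      evaluate_phantom_outcome(spectrum, phantom, kernels, tissues,
                               tcp_pars, ntcp_pars,
                               t_range = config$t_range,
                               t_step = config$t_step),
      error = function(e) stop("stage phantom [", id, "]: ",
                               conditionMessage(e), call. = FALSE))
    say("beam %s: organ dosimetry", id)
    organ_table <- tryCatch(
      assemble_organ_table(
        generate_organ_doses(spectrum, organs, kernels,
                             seed = config$seed,
                             noise_sd = config$noise_sd),
        tissues, t_irr = outcome$t_irr),
      error = function(e) stop("stage organ [", id, "]: ",
                               conditionMessage(e), call. = FALSE))
    oof <- out_of_field_summary(organ_table, config$in_field)
    beams[[id]] <- list(id = id, fom = fom, compliance = compliance,
                        outcome = outcome[c("t_irr", "tcp", "ntcp",
                                            "utcp", "d_max_healthy",
                                            "percent_dose",
                                            "flat_tumor_warning")],
                        organ_table = organ_table,
                        out_of_field = oof)
  }

  summaries <- vapply(beams, function(b) b$out_of_field, numeric(1L))
  utcps <- vapply(beams, function(b) b$outcome$utcp, numeric(1L))
  selected <- select_safest_beam(summaries, utcps)
  say("selected beam: %s", selected)

  cfg_string <- jsonlite::toJSON(
    unclass(config[setdiff(names(config), "out_dir")]),
    auto_unbox = TRUE, digits = NA, force = TRUE)
  report <- list(
    beams = beams, selected = selected,
    provenance = list(seed = config$seed,
                      config_fingerprint = fnv1a(cfg_string),
                      package = "bnctbeams",
                      version = as.character(
                        utils::packageVersion("bnctbeams"))))

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    serializable <- report
    serializable$beams <- lapply(report$beams, function(b) {
      b$fom <- unclass(b$fom)
      b$compliance$flags <- as.list(b$compliance$flags)
      b$outcome$percent_dose <- as.list(b$outcome$percent_dose)
      b$organ_table <- NULL  # rendered as CSV instead
      b
    })
    jsonlite::write_json(serializable,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    render_tables(report, config$out_dir)
  }
  report
}

#' Render the evaluation report as CSV tables
#'
#' Writes the standard table layouts: one row per beam of in-air
#' figures of merit (flux in 1e9 cm^-2 s^-1 and dose contamination in
#' 1e-13 cm^2 Gy, three significant figures); one row per beam of
#' radiobiological outcome (probabilities at two decimals, half-up); and
#' one organ dose table per beam (cGy / cSv / cGy-Eq, one decimal).
#'
#' @param report Result of [run_evaluation()].
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)

  fom_df <- do.call(rbind, lapply(report$beams, function(b)
    data.frame(beam = b$id,
               phi_epi_1e9 = signif(b$fom$phi_epi / 1e9, 3),
               ratio_th_epi = signif(b$fom$ratio_th_epi, 3),
               fast_dose_1e13 = signif(b$fom$fast_dose_per_epi / 1e-13, 3),
               gamma_dose_1e13 = signif(b$fom$gamma_dose_per_epi / 1e-13, 3),
               j_over_phi_epi = signif(b$fom$j_over_phi_epi, 3),
               n_criteria_passed = b$compliance$n_pass)))
  p <- file.path(dir, "fom_table.csv")
  utils::write.csv(fom_df, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  out_df <- do.call(rbind, lapply(report$beams, function(b)
    data.frame(beam = b$id,
               t_irr_min = round_half_up(b$outcome$t_irr, 1),
               utcp = round_half_up(b$outcome$utcp, 2),
               tcp = round_half_up(b$outcome$tcp, 2),
               ntcp = round_half_up(b$outcome$ntcp, 2),
               d_max_gy = round_half_up(b$outcome$d_max_healthy, 2),
               pct_boron = round_half_up(b$outcome$percent_dose[["boron"]], 0),
               pct_thermal_n = round_half_up(b$outcome$percent_dose[["thermal_n"]], 0),
               pct_fast_n = round_half_up(b$outcome$percent_dose[["fast_n"]], 0),
               pct_gamma = round_half_up(b$outcome$percent_dose[["gamma"]], 0))))
  p <- file.path(dir, "outcome_table.csv")
  utils::write.csv(out_df, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  for (b in report$beams) {
    tb <- b$organ_table
    num <- vapply(tb, is.numeric, logical(1L))
    tb[num] <- lapply(tb[num], round_half_up, digits = 3L)
    p <- file.path(dir, paste0("organ_table_", b$id, ".csv"))
    utils::write.csv(tb, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
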