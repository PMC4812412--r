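# Solute library, device fixtures, run configuration and reporting

REQUIRED_LIBRARY_COLUMNS <- c("name", "D0_cm2_per_s", "radius_nm",
                              "generation_mmol_per_h", "physiological_mM",
                              "source_note")

#' Load a solute library
#'
#' Reads a CSV of solute transport and kinetic properties and returns
#' validated [solute()] objects.  Required columns: `name`,
#' `D0_cm2_per_s`, `radius_nm`, `generation_mmol_per_h`,
#' `physiological_mM`, `source_note`; an optional `target_L_per_h` column
#' stores a target clearance for solutes whose generation rate is known
#' only as the generation/concentration ratio (urea in the bundled
#' library).  Malformed numeric cells are rejected with an error naming the
#' row and column.
#'
#' @param path Path to the CSV; `NULL` (default) loads the bundled library
#'   of uremic-toxin kinetics (urea, creatinine, beta2-microglobulin,
#'   albumin). The bundled transport values (D0, radius) are literature
#'   values, not measurements.
#' @return Named list of [solute()] objects (empty, with a warning, for an
#'   empty file).
#' @export
load_solute_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "solute_library.csv",
                        package = "nanodialyzer", mustWork = TRUE)
  if (!file.exists(path)) stop_invalid(sprintf("no such file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(REQUIRED_LIBRARY_COLUMNS, names(df))
  if (length(missing_cols))
    stop_invalid(sprintf("solute library missing column(s): %s",
                         paste(missing_cols, collapse = ", ")))
  if (nrow(df) == 0) {
    warning("solute library is empty")
    return(list())
  }
  num <- function(x, row, col, required = FALSE) {
    if (is.na(x) || !nzchar(trimws(x))) {
      if (required)
        stop_invalid(sprintf("row %d ('%s'), column '%s': value required",
                             row, df$name[row], col))
      return(NA_real_)
    }
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v))
      stop_invalid(sprintf("row %d ('%s'), column '%s': '%s' is not numeric",
                           row, df$name[row], col, x))
    v
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    solute(
      name = df$name[i],
      D0_cm2_s = num(df$D0_cm2_per_s[i], i, "D0_cm2_per_s", required = TRUE),
      radius_nm = num(df$radius_nm[i], i, "radius_nm", required = TRUE),
      generation_mmol_h = num(df$generation_mmol_per_h[i], i, "generation_mmol_per_h"),
      conc_mM = num(df$physiological_mM[i], i, "physiological_mM"),
      target_L_per_h = if ("target_L_per_h" %in% names(df))
        num(df$target_L_per_h[i], i, "target_L_per_h") else NA_real_
    )
  })
  names(out) <- df$name
  out
}

#' Benchtop experimental device fixture
#'
#' The benchtop microfluidic dialyzer used to validate the models: a
#' 0.7 x 2 mm membrane over a 1 mm-wide blood channel, mean blood velocity
#' 0.2 mm/s (channel heights 0.1, 0.3 and 1.0 mm paired with flows 0.02,
#' 0.06 and 0.20 mm^3/s), 10 s residence time, and 70% membrane coverage
#' of the channel width.
#'
#' @param height_mm Channel height variant: 0.1, 0.3 or 1.0 mm.
#' @param membrane_pore_nm,membrane_thickness_nm,membrane_porosity Membrane
#'   description attached to the fixture (defaults are the package's
#'   nanomembrane defaults; the benchtop assays used small solutes for
#'   which the membrane resistance is negligible).
#' @return List with elements `design` ([dialyzer_design()]) and
#'   `membrane` ([membrane()]).
#' @export
fixture_experimental_device <- function(height_mm = 0.3,
                                        membrane_pore_nm = 23,
                                        membrane_thickness_nm = 50,
                                        membrane_porosity = 0.03) {
  heights <- c(0.1, 0.3, 1.0)
  flows_mm3_s <- c(0.02, 0.06, 0.20)
  i <- match(height_mm, heights)
  if (is.na(i))
    stop_invalid("height_mm must be one of 0.1, 0.3, 1.0 (mm)")
  design <- dialyzer_design(
    channel_height_um = heights[i] * 1000,
    membrane_area_cm2 = 0.07 * 0.2,          # 0.7 mm x 2 mm
    flow_L_min = flows_mm3_s[i] * 1e-6 * 60, # mm^3/s -> L/min
    membrane_length_mm = 2,
    channel_width_mm = 1,
    coverage = 0.7)
  list(design = design,
       membrane = membrane(thickness_nm = membrane_thickness_nm,
                           pore_nm = membrane_pore_nm,
                           porosity = membrane_porosity))
}

# ---------------------------------------------------------------------------
# Run configuration + report

CONFIG_KEYS <- c("version", "stage", "design", "membrane", "solutes",
                 "solute_library", "targets", "options", "output")
CONFIG_STAGES <- c("clearance", "adequacy", "design", "oracle",
                   "hydraulics", "hindrance")

#' Validate a run configuration
#'
#' A run configuration is a list (typically parsed from a YAML file) with
#' keys `stage` (one of clearance, adequacy, design, oracle, hydraulics,
#' hindrance), `design`, `membrane`, `solutes`, `solute_library`,
#' `targets`, `options` and `output`.  Unknown keys are rejected.
#'
#' @param config A list, or a path to a YAML file.
#' @return The validated configuration (class `run_config`).
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_invalid(sprintf("no such config: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_invalid("config must be a list or a YAML path")
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown))
    stop_invalid(sprintf("unknown config key(s): %s",
                         paste(unknown, collapse = ", ")))
  if (is.null(config$stage) || !config$stage %in% CONFIG_STAGES)
    stop_invalid(sprintf("config `stage` must be one of: %s",
                         paste(CONFIG_STAGES, collapse = ", ")))
  structure(config, class = c("run_config", "list"))
}

config_design <- function(config) {
  d <- config$design
  if (is.null(d)) stop_invalid("config requires a `design` block")
  do.call(dialyzer_design, d)
}

config_membrane <- function(config) {
  if (is.null(config$membrane)) return(NULL)
  do.call(membrane, config$membrane)
}

config_solutes <- function(config) {
  lib <- load_solute_library(config$solute_library)
  if (is.null(config$solutes)) return(lib)
  sol <- config$solutes
  if (is.character(sol)) {
    missing <- setdiff(sol, names(lib))
    if (length(missing))
      stop_invalid(sprintf("solute(s) not in library: %s",
                           paste(missing, collapse = ", ")))
    return(lib[sol])
  }
  out <- lapply(sol, function(s) do.call(solute, s))
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Run a configured analysis and write its report
#'
#' Dispatches a validated configuration to the clearance, adequacy,
#' design-selection, numerical-oracle, hydraulics or hindrance stage,
#' logs every model choice made (hindrance model, beta per solute, series
#' model), and optionally writes CSV (tables/curves) and JSON (records)
#' outputs.  Repeated runs of the same configuration are byte-identical:
#' every stage is deterministic.
#'
#' @param config A [read_run_config()] list or YAML path.
#' @param quiet Suppress the INFO log of model choices.
#' @return The stage result, invisibly: a `clearance_result`, an
#'   [adequacy_table()], a `design_selection`, an oracle result list,
#'   a hydraulics record or a hindrance record.
#' @export
run_report <- function(config, quiet = FALSE) {
  config <- read_run_config(config)
  opts <- config$options %||% list()
  hind <- opts$hindrance_model %||% "renkin"
  info <- function(...) if (!quiet) message("INFO: ", sprintf(...))
  info("stage = %s, hindrance model = %s", config$stage, hind)

  result <- switch(config$stage,
    clearance = {
      design <- config_design(config)
      mem <- config_membrane(config)
      sol <- config_solutes(config)[[1]]
      r <- fractional_clearance(design, sol, mem,
                                model = opts$model %||% "auto",
                                hindrance_model = hind)
      info("solute %s: beta = %.4g, model = %s, f = %.6g",
           sol$name, r$beta, r$model_used, r$fractional_clearance)
      r
    },
    adequacy = {
      design <- config_design(config)
      mem <- config_membrane(config)
      sols <- config_solutes(config)
      tab <- adequacy_table(design, mem, sols, hindrance_model = hind)
      for (i in seq_len(nrow(tab)))
        info("solute %s: beta = %.4g, model = %s, f = %.6g",
             tab$solute[i], tab$beta[i], tab$model[i], tab$f[i])
      tab
    },
    design = {
      sols <- config_solutes(config)
      targets <- config$targets
      if (is.null(targets)) stop_invalid("design stage requires `targets`")
      sel <- select_design(
        area_cm2 = config$design$membrane_area_cm2 %||%
          stop_invalid("design stage requires design$membrane_area_cm2"),
        solutes = list(urea = sols[["urea"]], albumin = sols[["albumin"]],
                       beta2m = sols[["beta2-microglobulin"]] %||% sols[["beta2m"]]),
        targets = targets,
        membrane_template = config_membrane(config) %||% membrane(pore_nm = 20),
        min_height_um = opts$min_height_um,
        hindrance_model = hind)
      info("recommended a = %.4g um, Q = %.4g L/min, pore = %.4g nm",
           sel$recommended$height_um, sel$recommended$flow_L_min,
           sel$recommended$pore_nm)
      sel
    },
    oracle = {
      solver <- opts$solver %||% "1d"
      if (solver == "1d") {
        solve_diffusion_1d(tbar_end = opts$tbar_end %||% 0.1,
                           beta = opts$beta %||% 0,
                           nodes = opts$nodes %||% 2001,
                           dt0 = opts$dt0 %||% 1e-5)
      } else {
        solve_channel_2d(config_design(config), config_solutes(config)[[1]],
                         config_membrane(config),
                         profile = opts$profile %||% "plug",
                         ny = opts$ny %||% 401, nz = opts$nz %||% 1500,
                         hindrance_model = hind)
      }
    },
    hydraulics = {
      d <- config$design
      ch <- rect_channel(width_cm = d$width_cm, height_um = d$height_um,
                         length_cm = d$length_cm,
                         viscosity_mPa_s = opts$viscosity_mPa_s %||% 1.0)
      dp <- opts$delta_p_Pa %||% 14000
      list(flow_L_min = flow_from_pressure(ch, dp),
           resistance_Pa_s_m3 = hydraulic_resistance(ch),
           priming_uL = if (!is.null(d$area_cm2))
             priming_volume(d$area_cm2, d$height_um) else NA_real_,
           delta_p_Pa = dp)
    },
    hindrance = {
      mem <- config_membrane(config) %||% stop_invalid("hindrance stage requires `membrane`")
      sol <- config_solutes(config)[[1]]
      lambda <- sol$rs / (mem$pore_diameter / 2)
      list(solute = sol$name, lambda = lambda, model = hind,
           hindrance_factor = hindrance_factor(lambda, hind),
           Dm_cm2_s = effective_membrane_diffusivity(sol, mem, hind) * 1e4)
    })

  write_outputs(result, config$output, info)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_outputs <- function(result, output, info) {
  if (is.null(output)) return(invisible(NULL))
  as_record <- function(x) {
    if (inherits(x, "design_selection"))
      return(list(recommended = as.list(x$recommended),
                  argmax = as.list(x$argmax)))
    if (inherits(x, "clearance_result") || is.list(x)) return(unclass(x))
    x
  }
  if (!is.null(output$csv)) {
    tab <- if (inherits(result, "design_selection")) result$curve
           else if (is.data.frame(result)) as.data.frame(result)
           else if (!is.null(result$checkpoints) && nrow(result$checkpoints)) result$checkpoints
           else if (!is.null(result$outlet_profile)) result$outlet_profile
           else as.data.frame(as_record(result)[
             vapply(as_record(result), function(v)
               is.atomic(v) && length(v) == 1L, logical(1))])
    utils::write.csv(tab, output$csv, row.names = FALSE)
    info("wrote %s", output$csv)
  }
  if (!is.null(output$json)) {
    rec <- as_record(result)
    rec <- rec[!vapply(rec, is.data.frame, logical(1))]
    jsonlite::write_json(rec, output$json, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    info("wrote %s", output$json)
  }
  invisible(NULL)
}
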