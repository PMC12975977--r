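# File interfaces: 1-port Touchstone sweeps, trace and feature CSV, YAML
# configuration with unit-suffixed quantities, and JSON run manifests.

#' Write an S11 sweep as a 1-port Touchstone file
#'
#' Supports the real/imaginary (`"RI"`) and dB-angle (`"DB"`) dialects.
#' Values are written with 17 significant digits so that an RI round trip
#' reproduces the sweep bit-stably.
#'
#' @param sweep An [s11_sweep()].
#' @param path Output path (conventionally `.s1p`).
#' @param format `"RI"` or `"DB"`.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(sweep, path, format = c("RI", "DB")) {
  format <- match.arg(format)
  s <- sweep$reflection
  cols <- if (format == "RI") {
    cbind(Re(s), Im(s))
  } else {
    cbind(20 * log10(Mod(s)), Arg(s) * 180 / pi)
  }
  lines <- c(
    "! 1-port S-parameter sweep",
    sprintf("# Hz S %s R 50", format),
    sprintf("%.17g %.17g %.17g", sweep$frequencies, cols[, 1], cols[, 2])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a 1-port Touchstone file
#'
#' Accepts RI and DB dialects with Hz/kHz/MHz/GHz frequency units. Files
#' with more than one port (more than three numeric columns) are rejected.
#'
#' @param path Path to a `.s1p` file.
#' @return An [s11_sweep()]-shaped object (grid reconstructed as the raw
#'   frequency vector).
#' @export
read_touchstone <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("!.*$", "", lines))
  lines <- lines[nzchar(lines)]
  opt <- grep("^#", lines, value = TRUE)
  if (length(opt) != 1L) {
    stop("malformed Touchstone file: expected exactly one option line",
         call. = FALSE)
  }
  toks <- toupper(strsplit(trimws(sub("^#", "", opt)), "\\s+")[[1]])
  funit <- c(HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)[[toks[1]]]
  if (is.null(funit) || is.na(funit)) {
    stop("malformed Touchstone header: unknown frequency unit", call. = FALSE)
  }
  if (toks[2] != "S") stop("only S-parameter files are supported", call. = FALSE)
  dialect <- toks[3]
  if (!dialect %in% c("RI", "DB", "MA")) {
    stop("unsupported Touchstone data format '", dialect, "'", call. = FALSE)
  }
  data_lines <- lines[!grepl("^#", lines)]
  fields <- strsplit(data_lines, "\\s+")
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L || ncols != 3L) {
    stop("not a 1-port Touchstone file (expected 3 columns per line)",
         call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 3L, byrow = TRUE)
  if (anyNA(m)) stop("malformed Touchstone data", call. = FALSE)
  freq <- m[, 1] * funit
  s <- switch(dialect,
    RI = complex(real = m[, 2], imaginary = m[, 3]),
    DB = 10^(m[, 2] / 20) * exp(1i * m[, 3] * pi / 180),
    MA = m[, 2] * exp(1i * m[, 3] * pi / 180))
  structure(
    list(grid = NULL, frequencies = freq, reflection = s,
         magnitude_db = 20 * log10(Mod(s))),
    class = "s11_sweep")
}

#' Write a resonance trace as tidy CSV
#'
#' Columns: `timestamp_s`, `f_res_sensor1_hz`, `f_res_sensor2_hz`,
#' `gt_phase`, `gt_cycle`, `session_id`, `activity`, plus `assigned_phase`
#' and `detected_cycle` when present.
#'
#' @param trace A `resonance_trace` data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  out <- data.frame(
    timestamp_s = trace$time,
    f_res_sensor1_hz = trace$f1_hz,
    f_res_sensor2_hz = trace$f2_hz,
    gt_phase = as.character(trace$gt_phase),
    gt_cycle = trace$gt_cycle,
    session_id = trace$session,
    activity = trace$activity)
  if ("assigned_phase" %in% names(trace)) {
    out$assigned_phase <- as.character(trace$assigned_phase)
    out$detected_cycle <- trace$det_cycle
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a resonance trace from CSV
#'
#' Accepts the schema written by [write_trace_csv()]; the same schema can
#' carry real recordings into the processing pipeline.
#'
#' @param path CSV path.
#' @return A `resonance_trace` data.frame.
#' @export
read_trace_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_s", "f_res_sensor1_hz", "f_res_sensor2_hz")
  if (!all(need %in% names(raw))) {
    stop("trace CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    time = raw$timestamp_s,
    f1_hz = raw$f_res_sensor1_hz,
    f2_hz = raw$f_res_sensor2_hz,
    gt_phase = if ("gt_phase" %in% names(raw)) {
      factor(raw$gt_phase, levels = c("stand", "activity", "transition"))
    } else factor(rep(NA_character_, nrow(raw)),
                  levels = c("stand", "activity", "transition")),
    gt_cycle = if ("gt_cycle" %in% names(raw)) raw$gt_cycle else NA_integer_,
    session = if ("session_id" %in% names(raw)) raw$session_id else 1L,
    activity = if ("activity" %in% names(raw)) raw$activity else "unknown",
    stringsAsFactors = FALSE)
  fs <- 1 / stats::median(diff(out$time))
  structure(out, sampling_rate = fs,
            class = c("resonance_trace", "data.frame"))
}

#' Default run configuration
#'
#' Nested configuration covering the circuit geometry and materials, the
#' sweep grid, the synthesis protocols and artifact model, and the
#' processing pipeline. Physical quantities carry explicit unit suffixes.
#'
#' @return A named list (YAML-serialisable).
#' @export
default_config <- function() {
  list(
    circuit = list(
      inductor = list(outer_diameter = "40 mm", n_turns = 3,
                      trace_width = "0.23 mm", gap = "2 mm",
                      resistance_per_length = "3.3 ohm/m",
                      parasitic_capacitance = "2 pF",
                      tap_turns = c(1L, 3L)),
      sensors = list(
        list(plate_length = "70 mm", plate_width = "15 mm",
             dielectric_thickness = "0.8 mm", relative_permittivity = 1.77,
             gauge_factor = 1.0, baseline_capacitance = "22 pF"),
        list(plate_length = "80 mm", plate_width = "10 mm",
             dielectric_thickness = "0.8 mm", relative_permittivity = 1.77,
             gauge_factor = 1.0, baseline_capacitance = "17 pF")),
      coupling = list(axial_distance = "1.5 mm",
                      reader_inner_radius = "19 mm",
                      reader_outer_radius = "20 mm",
                      coupling_override = 0.35),
      sub_inductances = c("1.28 uH", "0.45 uH"),
      sub_resistances = c("1.3 ohm", "1.0 ohm")
    ),
    sweep = list(f_start = "20 MHz", f_stop = "60 MHz",
                 spacing_mode = "linear", resolution = "200 kHz"),
    synthesis = list(
      sampling_rate_hz = 70,
      hold_duration_s = 4, stand_duration_s = 4, ramp_duration_s = 0.5,
      n_cycles = 10, gait_cycles = 20,
      walk_period_s = 1.0, jog_period_s = 0.6, pose_period_s = 2.0,
      artifacts = list(noise_sd_stand = "0.33 MHz",
                       noise_sd_active = "0.15 MHz",
                       baseline_drift_rate = 0.001,
                       hysteresis_offset = 0.15,
                       relaxation_time = "3 s"),
      sessions = list(n_sessions = 1, baseline_shift_sd = 0.05,
                      amplitude_scale_sd = 0.15),
      seed = 1L
    ),
    pipeline = list(
      cutoff_static = "1 Hz", cutoff_dynamic = "5 Hz",
      stand_tolerance = 0.20, activity_tolerance = 0.15,
      window_static_s = 1.0, window_dynamic_s = 0.2, overlap = 0.8,
      split_ratios = c(0.8, 0.1, 0.1), cv_folds = 4,
      include_stand_class = TRUE, seed = 1L
    )
  )
}

#' Load and validate a run configuration
#'
#' @param path YAML file; `NULL` returns [default_config()].
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- if (is.null(path)) default_config() else yaml::read_yaml(path)
  validate_config(cfg)
  cfg
}

#' Save a configuration as YAML
#'
#' @param cfg Configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks the section layout, parses every unit-suffixed quantity, and
#' enforces the basic invariants (positive geometry, tolerances in range,
#' at least one sensor).
#'
#' @param cfg Configuration list.
#' @return `TRUE`, invisibly; errors with a precise message otherwise.
#' @export
validate_config <- function(cfg) {
  for (sec in c("circuit", "sweep", "synthesis", "pipeline")) {
    if (is.null(cfg[[sec]])) stop("config missing section '", sec, "'",
                                  call. = FALSE)
  }
  ind <- cfg$circuit$inductor
  for (fld in c("outer_diameter", "n_turns", "trace_width", "gap")) {
    if (is.null(ind[[fld]])) {
      stop("config circuit.inductor missing field '", fld, "'", call. = FALSE)
    }
  }
  # constructing the objects performs the numeric validation
  spiral_inductor(ind$outer_diameter, ind$n_turns, ind$trace_width, ind$gap,
                  tap_turns = ind$tap_turns)
  if (length(cfg$circuit$sensors) < 1L) {
    stop("config must define at least one sensor", call. = FALSE)
  }
  for (sn in cfg$circuit$sensors) {
    strain_sensor(sn$plate_length, sn$plate_width, sn$dielectric_thickness,
                  sn$relative_permittivity %||% 1.77,
                  sn$gauge_factor %||% 1,
                  sn$baseline_capacitance)
  }
  frequency_grid(cfg$sweep$f_start, cfg$sweep$f_stop,
                 cfg$sweep$spacing_mode %||% "linear",
                 cfg$sweep$resolution)
  labeler_config(cfg$pipeline$stand_tolerance %||% 0.20,
                 cfg$pipeline$activity_tolerance %||% 0.15)
  if (abs(sum(cfg$pipeline$split_ratios) - 1) > 1e-8) {
    stop("config pipeline.split_ratios must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a JSON run manifest
#'
#' Records the configuration, seeds and stage parameters of a run so any
#' output can be regenerated.
#'
#' @param manifest Named list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  manifest$written_at <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
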