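# Seeded generator of synthetic two-sensor activity recordings: per-activity
# strain profiles, textile-sensor artifacts (hysteresis, baseline drift,
# phase-dependent noise), inter-session shifts, and rendering of the strain
# into resonance-frequency traces through the circuit model.

#' Activity protocol
#'
#' Describes one recorded movement test. Static protocols hold a pose for
#' `hold_duration` seconds followed by `stand_duration` seconds of standing,
#' repeated `n_cycles` times; dynamic protocols repeat the pose continuously
#' as raised-cosine strain cycles of `cycle_period` seconds. Every recording
#' begins and ends with a standing phase.
#'
#' @param activity_name One of `"squat"`, `"deep_squat"`, `"foot_to_glute"`,
#'   `"knee_drive"`, `"hip_flexion"`, `"hip_abduction"`, `"lunge"`,
#'   `"walk"`, `"jog"`, `"stand"`.
#' @param mode `"static"` or `"dynamic"`.
#' @param n_cycles Number of pose repetitions (>= 1); gait activities use 20
#'   steps by convention.
#' @param strain_amplitudes Length-2 numeric: peak strain on the kneecap and
#'   glute sensors, each in `[0, 0.3]`.
#' @param hold_duration Hold time per static cycle, seconds (default 4).
#' @param stand_duration Standing time between static cycles and at the
#'   recording boundaries, seconds (default 4).
#' @param cycle_period Period of one dynamic cycle, seconds (default 2;
#'   1.0 for walking, 0.6 for jogging).
#' @param ramp_duration Transition ramp for static poses, seconds
#'   (default 0.5).
#' @param sampling_rate Sweep repetition rate, Hz (default 70).
#' @return An object of class `activity_protocol`.
#' @export
activity_protocol <- function(activity_name,
                              mode = c("static", "dynamic"),
                              n_cycles = 10,
                              strain_amplitudes,
                              hold_duration = 4,
                              stand_duration = 4,
                              cycle_period = 2,
                              ramp_duration = 0.5,
                              sampling_rate = 70) {
  mode <- match.arg(mode)
  activity_name <- match.arg(activity_name, .activity_names)
  if (n_cycles < 1 || n_cycles != round(n_cycles)) {
    stop("'n_cycles' must be a positive integer", call. = FALSE)
  }
  if (length(strain_amplitudes) != 2L || any(strain_amplitudes < 0) ||
      any(strain_amplitudes > 0.3)) {
    stop("'strain_amplitudes' must be two strains in [0, 0.3]", call. = FALSE)
  }
  .check_positive(sampling_rate, "sampling_rate")
  structure(
    list(activity_name = activity_name, mode = mode,
         n_cycles = as.integer(n_cycles),
         strain_amplitudes = as.numeric(strain_amplitudes),
         hold_duration = hold_duration, stand_duration = stand_duration,
         cycle_period = cycle_period, ramp_duration = ramp_duration,
         sampling_rate = sampling_rate),
    class = "activity_protocol")
}

.activity_names <- c("squat", "deep_squat", "foot_to_glute", "knee_drive",
                     "hip_flexion", "hip_abduction", "lunge", "walk", "jog",
                     "stand")

#' Sensor artifact model
#'
#' Imperfections of fabric capacitive sensors injected on top of the clean
#' gauge-model capacitance: Gaussian measurement noise whose standard
#' deviation depends on the phase (standing phases are noisier because the
#' unloaded fabric sags and readjusts), a per-cycle baseline drift toward
#' lower capacitance as the fabric relaxes, and stretch-release hysteresis
#' modelled as a first-order capacitance deficit that builds up while strain
#' is released and decays with a relaxation time, so that at matched strain
#' the release phase sits below the stretch phase.
#'
#' @param noise_sd_stand Noise SD in standing phases, expressed in hertz of
#'   equivalent resonance deviation (default 0.33 MHz, the observed
#'   cycle-to-cycle variability scale of this class of system).
#' @param noise_sd_active Noise SD in activity/transition phases, Hz
#'   equivalent (default 0.15 MHz); must not exceed `noise_sd_stand`.
#' @param baseline_drift_rate Fractional baseline capacitance lost per
#'   completed cycle (default 1e-3).
#' @param hysteresis_offset Fraction of released capacitance change
#'   temporarily withheld during release (default 0.15).
#' @param relaxation_time Recovery time constant of the hysteresis deficit,
#'   seconds (default 3).
#' @return An object of class `artifact_model`.
#' @export
artifact_model <- function(noise_sd_stand = 0.33e6,
                           noise_sd_active = 0.15e6,
                           baseline_drift_rate = 1e-3,
                           hysteresis_offset = 0.15,
                           relaxation_time = 3) {
  .check_nonneg(noise_sd_stand, "noise_sd_stand")
  .check_nonneg(noise_sd_active, "noise_sd_active")
  .check_nonneg(baseline_drift_rate, "baseline_drift_rate")
  .check_nonneg(hysteresis_offset, "hysteresis_offset")
  .check_nonneg(relaxation_time, "relaxation_time")
  if (noise_sd_active > noise_sd_stand) {
    stop("standing phases must be at least as noisy as activity phases",
         call. = FALSE)
  }
  structure(
    list(noise_sd_stand = noise_sd_stand, noise_sd_active = noise_sd_active,
         baseline_drift_rate = baseline_drift_rate,
         hysteresis_offset = hysteresis_offset,
         relaxation_time = relaxation_time),
    class = "artifact_model")
}

#' Inter-session variability model
#'
#' Donning and doffing the garment between sessions changes each sensor's
#' rest stretch state (baseline capacitance shift) and how far it is
#' stretched by the same movement (amplitude scaling). One shift and one
#' scale are drawn per (session, sensor) and held constant within the
#' session.
#'
#' @param n_sessions Number of independent sessions (>= 1).
#' @param baseline_shift_sd SD of the fractional baseline capacitance shift
#'   (default 0.05).
#' @param amplitude_scale_sd SD of the fractional multiplicative amplitude
#'   scaling (default 0.15).
#' @return An object of class `session_effects`.
#' @export
session_effects <- function(n_sessions = 1, baseline_shift_sd = 0.05,
                            amplitude_scale_sd = 0.15) {
  if (n_sessions < 1 || n_sessions != round(n_sessions)) {
    stop("'n_sessions' must be a positive integer", call. = FALSE)
  }
  .check_nonneg(baseline_shift_sd, "baseline_shift_sd")
  .check_nonneg(amplitude_scale_sd, "amplitude_scale_sd")
  structure(
    list(n_sessions = as.integer(n_sessions),
         baseline_shift_sd = baseline_shift_sd,
         amplitude_scale_sd = amplitude_scale_sd),
    class = "session_effects")
}

# Deterministic child seeds: a polynomial rolling hash of the key strings,
# folded into [1, 2^31 - 2]. Keying streams by name means adding an activity
# or session never shifts another trace's noise.
.child_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character,
                                            character(1))), collapse = "|")
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% 2147483587
  as.integer(h + 1)
}

#' Two-channel strain profile for an activity protocol
#'
#' Builds the ground-truth strain time series for both sensors. Static
#' protocols are trapezoidal (linear ramps, flat holds, flat stands);
#' dynamic protocols are raised-cosine cycles. Ground-truth phases come from
#' the generating waveform: ramp segments are `transition`; for dynamic
#' cycles samples above 70% of the normalised waveform are `activity` and
#' the rest of the cycling block `transition`, with the bounding stands
#' labelled `stand`. A protocol with zero amplitude on both sensors is all
#' `stand`.
#'
#' @param protocol An [activity_protocol()].
#' @param amplitude_scale Optional length-2 multiplicative scaling of the
#'   protocol amplitudes (session effect); results are clipped to 0.3.
#' @return A data.frame with columns `time`, `strain1`, `strain2`,
#'   `gt_phase` (factor: stand/activity/transition) and `gt_cycle`
#'   (0 before the first cycle, then the index of the current or most
#'   recently completed cycle).
#' @export
strain_profile <- function(protocol, amplitude_scale = c(1, 1)) {
  stopifnot(inherits(protocol, "activity_protocol"))
  fs <- protocol$sampling_rate
  amps <- pmin(protocol$strain_amplitudes * amplitude_scale, 0.3)
  nseg <- function(dur) max(1L, round(dur * fs))

  if (protocol$mode == "static") {
    shape <- numeric(0); phase <- character(0); cyc <- integer(0)
    add <- function(values, ph, k) {
      shape <<- c(shape, values); phase <<- c(phase, rep(ph, length(values)))
      cyc <<- c(cyc, rep(k, length(values)))
    }
    add(rep(0, nseg(protocol$stand_duration)), "stand", 0L)
    n_ramp <- nseg(protocol$ramp_duration)
    for (k in seq_len(protocol$n_cycles)) {
      add(seq(0, 1, length.out = n_ramp + 1L)[-1L], "transition", k)
      add(rep(1, nseg(protocol$hold_duration)), "activity", k)
      add(seq(1, 0, length.out = n_ramp + 1L)[-1L], "transition", k)
      add(rep(0, nseg(protocol$stand_duration)), "stand", k)
    }
  } else {
    n_stand <- nseg(protocol$stand_duration)
    n_block <- nseg(protocol$cycle_period * protocol$n_cycles)
    t_block <- (seq_len(n_block) - 0.5) / fs
    u <- (1 - cos(2 * pi * t_block / protocol$cycle_period)) / 2
    cyc_block <- pmin(floor(t_block / protocol$cycle_period) + 1L,
                      protocol$n_cycles)
    shape <- c(rep(0, n_stand), u, rep(0, n_stand))
    phase <- c(rep("stand", n_stand),
               ifelse(u >= 0.7, "activity", "transition"),
               rep("stand", n_stand))
    cyc <- c(rep(0L, n_stand), as.integer(cyc_block),
             rep(protocol$n_cycles, n_stand))
  }
  if (max(amps) == 0) phase <- rep("stand", length(shape))
  n <- length(shape)
  data.frame(
    time = (seq_len(n) - 1L) / fs,
    strain1 = amps[1] * shape,
    strain2 = amps[2] * shape,
    gt_phase = factor(phase, levels = c("stand", "activity", "transition")),
    gt_cycle = as.integer(cyc)
  )
}

#' Corrupt a strain profile into a capacitance series
#'
#' Converts each sensor's strain to capacitance through the linear gauge
#' model and injects the artifacts: hysteresis deficit (first-order
#' recursion on the released capacitance), per-cycle baseline drift toward
#' lower capacitance, and phase-dependent Gaussian noise. The noise SDs are
#' specified in hertz of equivalent resonance deviation and converted per
#' sensor with the small-shift relation `sd_C / C = 2 sd_f / f` at the
#' sensor's baseline resonance. Fully deterministic under a fixed seed.
#'
#' @param profile A data.frame from [strain_profile()].
#' @param sensors List of two [strain_sensor()] objects.
#' @param artifacts An [artifact_model()].
#' @param f_baselines Length-2 baseline resonance frequencies (Hz) used for
#'   the noise conversion.
#' @param seed Integer seed for the noise stream.
#' @param baseline_shift Optional length-2 fractional baseline capacitance
#'   shift (session effect), default `c(0, 0)`.
#' @return The profile with added columns `C1`, `C2` (farads).
#' @export
apply_artifacts <- function(profile, sensors, artifacts, f_baselines, seed = 1,
                            baseline_shift = c(0, 0)) {
  stopifnot(inherits(artifacts, "artifact_model"), length(sensors) == 2L)
  fs <- 1 / diff(profile$time[1:2])
  n <- nrow(profile)
  noise_sd <- ifelse(profile$gt_phase == "stand",
                     artifacts$noise_sd_stand, artifacts$noise_sd_active)
  out <- profile
  for (j in 1:2) {
    sensor <- sensors[[j]]
    c0 <- plate_capacitance(sensor) * (1 + baseline_shift[j])
    strain <- profile[[paste0("strain", j)]]
    cap <- c0 * (1 + sensor$gauge_factor * strain)
    # hysteresis: deficit builds while strain is being released, relaxes
    # exponentially; the release phase therefore sits below the stretch
    # phase at matched strain
    if (artifacts$hysteresis_offset > 0 && artifacts$relaxation_time > 0) {
      released <- pmax(0, -c(0, diff(strain))) * sensor$gauge_factor * c0
      alpha <- exp(-1 / (fs * artifacts$relaxation_time))
      deficit <- as.numeric(stats::filter(artifacts$hysteresis_offset * released,
                                          alpha, method = "recursive"))
      cap <- cap - deficit
    }
    # baseline relaxation drift, per completed cycle
    cap <- cap - c0 * artifacts$baseline_drift_rate * profile$gt_cycle
    # phase-dependent measurement noise
    sd_frac <- 2 * noise_sd / f_baselines[j]
    rng <- .with_seed(.child_seed(seed, "noise", j), stats::rnorm(n))
    cap <- cap + c0 * sd_frac * rng
    out[[paste0("C", j)]] <- cap
  }
  out
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Render a capacitance series into a resonance-frequency trace
#'
#' Fast mode maps each sensor's capacitance through the closed-form series
#' resonance `f = 1 / (2 pi sqrt(L C))` with its sub-inductance. Full mode
#' synthesises an S11 sweep per sample on the tracking grid and locates both
#' dips with [find_resonances()]; at the default coupling the two modes
#' agree within one grid step. Full-mode "peak lost" errors propagate.
#'
#' @param caps A data.frame from [apply_artifacts()] (columns `C1`, `C2`).
#' @param circuit A [circuit_spec()] with one sub-circuit per sensor.
#' @param mode `"fast"` (default) or `"full"`.
#' @param grid Tracking grid for full mode (default 20-60 MHz at 200 kHz).
#' @param activity,session Metadata stamped on the trace.
#' @return A `resonance_trace` data.frame with columns `time`, `f1_hz`,
#'   `f2_hz`, `gt_phase`, `gt_cycle`, `session`, `activity`, and attribute
#'   `sampling_rate`.
#' @export
render_resonance_trace <- function(caps, circuit, mode = c("fast", "full"),
                                   grid = default_tracking_grid(),
                                   activity = "unknown", session = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(circuit, "circuit_spec"),
            length(circuit$sub_circuits) == 2L,
            all(c("C1", "C2") %in% names(caps)))
  l1 <- circuit$sub_circuits[[1]]$L_sub
  l2 <- circuit$sub_circuits[[2]]$L_sub
  if (mode == "fast") {
    f1 <- resonance_frequency(l1, caps$C1)
    f2 <- resonance_frequency(l2, caps$C2)
  } else {
    n <- nrow(caps)
    f1 <- numeric(n); f2 <- numeric(n)
    for (i in seq_len(n)) {
      circ_i <- circuit
      circ_i$sub_circuits[[1]]$C_sensor <- caps$C1[i]
      circ_i$sub_circuits[[2]]$C_sensor <- caps$C2[i]
      dips <- find_resonances(s11_sweep(circ_i, grid), 2L)
      f1[i] <- dips[1]; f2[i] <- dips[2]
    }
  }
  out <- data.frame(
    time = caps$time, f1_hz = f1, f2_hz = f2,
    gt_phase = caps$gt_phase, gt_cycle = caps$gt_cycle,
    session = as.integer(session), activity = caps$activity %||% activity,
    stringsAsFactors = FALSE
  )
  fs <- 1 / diff(caps$time[1:2])
  structure(out, sampling_rate = fs,
            class = c("resonance_trace", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a multi-activity, multi-session synthetic dataset
#'
#' For each session, per-sensor baseline shifts and amplitude scalings are
#' drawn once and held fixed; each protocol is then turned into a strain
#' profile, corrupted with the artifact model, and rendered into a
#' resonance trace. Random streams are keyed by (session, activity, sensor,
#' component), so generation is bit-reproducible and adding an activity
#' does not perturb the others.
#'
#' @param protocols List of [activity_protocol()] objects.
#' @param sensors List of two [strain_sensor()] objects.
#' @param circuit A [circuit_spec()] with two sub-circuits.
#' @param artifacts An [artifact_model()].
#' @param sessions A [session_effects()].
#' @param seed Master integer seed.
#' @param mode Rendering mode, `"fast"` or `"full"`.
#' @return A list of `resonance_trace` objects with a `"manifest"` attribute
#'   recording parameters and derived seeds.
#' @export
synth_dataset <- function(protocols, sensors, circuit,
                          artifacts = artifact_model(),
                          sessions = session_effects(1),
                          seed = 1, mode = "fast") {
  stopifnot(inherits(sessions, "session_effects"))
  f_base <- c(
    resonance_frequency(circuit$sub_circuits[[1]]$L_sub, plate_capacitance(sensors[[1]])),
    resonance_frequency(circuit$sub_circuits[[2]]$L_sub, plate_capacitance(sensors[[2]]))
  )
  traces <- list()
  manifest <- list(seed = seed, n_sessions = sessions$n_sessions,
                   sessions = list())
  for (s in seq_len(sessions$n_sessions)) {
    draw <- .with_seed(.child_seed(seed, "session", s), {
      list(shift = stats::rnorm(2, 0, sessions$baseline_shift_sd),
           scale = 1 + stats::rnorm(2, 0, sessions$amplitude_scale_sd))
    })
    manifest$sessions[[s]] <- draw
    for (p in protocols) {
      prof <- strain_profile(p, amplitude_scale = pmax(draw$scale, 0))
      trace_seed <- .child_seed(seed, "trace", s, p$activity_name, p$mode)
      caps <- apply_artifacts(prof, sensors, artifacts, f_base,
                              seed = trace_seed,
                              baseline_shift = draw$shift)
      caps$activity <- p$activity_name
      tr <- render_resonance_trace(caps, circuit, mode = mode,
                                   activity = p$activity_name, session = s)
      traces[[length(traces) + 1L]] <- tr
    }
  }
  attr(traces, "manifest") <- manifest
  traces
}
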