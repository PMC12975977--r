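# Shared fixtures, all generated in code.

# the reference tapped coil used throughout: 40 mm, 3 turns, 2 mm gap,
# sensors on the first and third turn
reference_inductor <- function(gap = "2 mm") {
  spiral_inductor("40 mm", 3, "0.23 mm", gap, tap_turns = list(1, 3))
}

# single-sensor reader-coupled circuit for oracle comparisons
single_sensor_circuit <- function(k = 0.35, L_sub = 1.28e-6, R_sub = 1.3,
                                  C = 22e-12, L_reader = 0.092e-6,
                                  R_reader = 0.1) {
  circuit_spec(L_reader, R_reader,
               list(sub_circuit(L_sub, R_sub, C,
                                mutual_inductance(k, L_reader, L_sub))))
}

# two-mesh closed form for the single-sensor circuit: reader branch with the
# sub-circuit reflected through (wM)^2 / Z_sub, in parallel with the load
closed_form_zin <- function(circuit, f) {
  w <- 2 * pi * f
  sc <- circuit$sub_circuits[[1]]
  z_sub <- sc$R_sub + 1i * w * sc$L_sub + 1 / (1i * w * sc$C_sensor)
  z_branch <- circuit$reader_resistance +
    1i * w * circuit$reader_inductance + (w * sc$M)^2 / z_sub
  zl <- circuit$load_impedance
  z_branch * zl / (z_branch + zl)
}

# short clean two-sensor recording rendered through the default circuit
small_trace <- function(activity = "squat", mode = "static", n_cycles = 3,
                        amps = c(0.18, 0.11), seed = 11,
                        artifacts = artifact_model(), stand_duration = 4) {
  p <- activity_protocol(activity, mode, n_cycles, amps,
                         stand_duration = stand_duration)
  prof <- strain_profile(p)
  sensors <- default_sensors()
  fb <- c(resonance_frequency(1.28e-6, 22e-12),
          resonance_frequency(0.45e-6, 17e-12))
  caps <- apply_artifacts(prof, sensors, artifacts, fb, seed = seed)
  render_resonance_trace(caps, default_circuit(), "fast",
                         activity = activity)
}

# bare labelled trace built directly from frequency vectors (bypasses the
# generator) for labeler unit tests
trace_from_freqs <- function(f1, f2, fs = 70) {
  n <- length(f1)
  structure(
    data.frame(time = (seq_len(n) - 1) / fs, f1_hz = f1, f2_hz = f2,
               gt_phase = factor(rep("stand", n),
                                 levels = c("stand", "activity", "transition")),
               gt_cycle = 0L, session = 1L, activity = "synthetic"),
    sampling_rate = fs, class = c("resonance_trace", "data.frame"))
}
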