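# Synthetic activity generator: strain profiles, sensor artifacts,
# rendering and dataset assembly.

test_that("static profiles alternate holds and stands with ramps", {
  p <- activity_protocol("squat", "static", 10, c(0.18, 0.11))
  prof <- strain_profile(p)
  runs <- rle(as.character(prof$gt_phase))
  expect_equal(sum(runs$values == "activity"), 10)
  expect_equal(sum(runs$values == "stand"), 11)
  expect_equal(runs$values[1], "stand")
  expect_equal(runs$values[length(runs$values)], "stand")
  expect_equal(max(prof$strain1), 0.18)
  expect_equal(max(prof$gt_cycle), 10L)
  # timestamps uniform at the sampling rate
  expect_equal(unique(round(diff(prof$time), 10)), 1 / 70)
})

test_that("zero-amplitude protocols are all standing", {
  p <- activity_protocol("stand", "dynamic", 5, c(0, 0))
  prof <- strain_profile(p)
  expect_true(all(prof$strain1 == 0 & prof$strain2 == 0))
  expect_true(all(prof$gt_phase == "stand"))
})

test_that("gait protocols carry 20 ground-truth cycles", {
  p <- activity_protocol("walk", "dynamic", 20, c(0.07, 0.03),
                         cycle_period = 1.0)
  prof <- strain_profile(p)
  expect_equal(max(prof$gt_cycle), 20L)
  runs <- rle(as.character(prof$gt_phase))
  expect_equal(sum(runs$values == "activity"), 20)
})

test_that("phase labels partition every profile", {
  for (mode in c("static", "dynamic")) {
    prof <- strain_profile(activity_protocol("lunge", mode, 4, c(0.25, 0.14)))
    counts <- table(prof$gt_phase)
    expect_equal(sum(counts), nrow(prof))
  }
})

test_that("artifact-free conversion equals the clean gauge series", {
  p <- activity_protocol("squat", "static", 3, c(0.18, 0.11))
  prof <- strain_profile(p)
  sensors <- default_sensors()
  fb <- c(30e6, 57.5e6)
  caps <- apply_artifacts(prof, sensors, artifact_model(0, 0, 0, 0, 0), fb)
  expect_equal(caps$C1, 22e-12 * (1 + prof$strain1), tolerance = 1e-12)
  expect_equal(caps$C2, 17e-12 * (1 + prof$strain2), tolerance = 1e-12)
})

test_that("artifact injection is deterministic under a fixed seed", {
  p <- activity_protocol("squat", "dynamic", 3, c(0.18, 0.11))
  prof <- strain_profile(p)
  sensors <- default_sensors()
  a <- apply_artifacts(prof, sensors, artifact_model(), c(30e6, 57.5e6), seed = 9)
  b <- apply_artifacts(prof, sensors, artifact_model(), c(30e6, 57.5e6), seed = 9)
  d <- apply_artifacts(prof, sensors, artifact_model(), c(30e6, 57.5e6), seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$C1, d$C1))
})

test_that("release phase sits below the stretch phase at matched strain", {
  # symmetric triangular stretch-release with no noise or drift
  fs <- 70
  up <- seq(0, 0.2, length.out = 4 * fs)
  tri <- c(up, rev(up))
  prof <- data.frame(
    time = (seq_along(tri) - 1) / fs,
    strain1 = tri, strain2 = tri,
    gt_phase = factor(rep("activity", length(tri)),
                      levels = c("stand", "activity", "transition")),
    gt_cycle = 1L)
  caps <- apply_artifacts(prof, default_sensors(),
                          artifact_model(0, 0, 0, hysteresis_offset = 0.15,
                                         relaxation_time = 3),
                          c(30e6, 57.5e6))
  n <- length(up)
  # compare at the same nominal strain: sample i on stretch vs mirror on release
  mid <- round(n / 2)
  expect_lt(caps$C1[2 * n + 1 - mid], caps$C1[mid])
})

test_that("standing phases are noisier than activity phases", {
  p <- activity_protocol("squat", "static", 8, c(0.18, 0.11))
  prof <- strain_profile(p)
  caps <- apply_artifacts(prof, default_sensors(),
                          artifact_model(noise_sd_stand = 0.33e6,
                                         noise_sd_active = 0.1e6,
                                         baseline_drift_rate = 0,
                                         hysteresis_offset = 0),
                          c(30e6, 57.5e6), seed = 3)
  tr <- render_resonance_trace(caps, default_circuit(), "fast")
  sd_stand <- sd(tr$f1_hz[prof$gt_phase == "stand"])
  sd_act <- sd(tr$f1_hz[prof$gt_phase == "activity"])
  expect_gt(sd_stand, sd_act)
  expect_error(artifact_model(noise_sd_stand = 0.1e6, noise_sd_active = 0.2e6),
               "noisy")
})

test_that("fast rendering maps capacitance through the series resonance", {
  caps <- data.frame(time = (0:9) / 70, C1 = rep(22e-12, 10),
                     C2 = rep(17e-12, 10),
                     gt_phase = factor(rep("stand", 10),
                                       levels = c("stand", "activity", "transition")),
                     gt_cycle = 0L)
  tr <- render_resonance_trace(caps, default_circuit(), "fast")
  expect_equal(unique(tr$f1_hz), resonance_frequency(1.28e-6, 22e-12))
  expect_equal(unique(tr$f2_hz), resonance_frequency(0.45e-6, 17e-12))
})

test_that("a 60 s protocol at 70 Hz renders 4200 samples", {
  p <- activity_protocol("squat", "dynamic", 26, c(0.18, 0.11),
                         stand_duration = 4, cycle_period = 2)
  prof <- strain_profile(p)   # 4 + 52 + 4 seconds
  expect_equal(nrow(prof), 4200)
})

test_that("fast and full rendering agree within one grid step", {
  p <- activity_protocol("squat", "dynamic", 1, c(0.18, 0.11),
                         stand_duration = 0.5, cycle_period = 2,
                         sampling_rate = 20)
  prof <- strain_profile(p)
  caps <- apply_artifacts(prof, default_sensors(), artifact_model(0, 0, 0, 0, 0),
                          c(30e6, 57.5e6))
  fast <- render_resonance_trace(caps, default_circuit(), "fast")
  full <- render_resonance_trace(caps, default_circuit(), "full")
  expect_lt(max(abs(fast$f1_hz - full$f1_hz)), 0.2e6)
  expect_lt(max(abs(fast$f2_hz - full$f2_hz)), 0.2e6)
})

test_that("inverting the rendering recovers the input strain", {
  p <- activity_protocol("lunge", "static", 3, c(0.25, 0.14))
  prof <- strain_profile(p)
  caps <- apply_artifacts(prof, default_sensors(), artifact_model(0, 0, 0, 0, 0),
                          c(30e6, 57.5e6))
  tr <- render_resonance_trace(caps, default_circuit(), "fast")
  c_rec <- 1 / ((2 * pi * tr$f1_hz)^2 * 1.28e-6)
  strain_rec <- c_rec / 22e-12 - 1
  expect_lt(abs(max(strain_rec) - 0.25) / 0.25, 0.01)
  c_rec2 <- 1 / ((2 * pi * tr$f2_hz)^2 * 0.45e-6)
  expect_lt(abs(max(c_rec2 / 17e-12 - 1) - 0.14) / 0.14, 0.01)
})

test_that("datasets are reproducible and session shifts move baselines", {
  protos <- list(activity_protocol("squat", "dynamic", 3, c(0.18, 0.11)))
  sensors <- default_sensors(); circ <- default_circuit()
  d1 <- synth_dataset(protos, sensors, circ, sessions = session_effects(1, 0, 0),
                      seed = 21)
  d2 <- synth_dataset(protos, sensors, circ, sessions = session_effects(1, 0, 0),
                      seed = 21)
  expect_identical(d1[[1]]$f1_hz, d2[[1]]$f1_hz)
  d3 <- synth_dataset(protos, sensors, circ,
                      sessions = session_effects(3, 0.05, 0.15), seed = 21)
  expect_length(d3, 3)
  base_means <- vapply(d3, function(tr)
    mean(tr$f1_hz[tr$gt_phase == "stand"]), numeric(1))
  expect_gt(max(base_means) - min(base_means), 1e5)
  expect_equal(vapply(d3, function(tr) tr$session[1], integer(1)), 1:3)
})
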