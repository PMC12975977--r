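# Small-signal S11 simulation: grids, solver, dip detection and the
# capacitor design-space search.

test_that("linear grids use the interval-count convention", {
  g <- frequency_grid("20 MHz", "60 MHz", "linear", "200 kHz")
  expect_length(g$frequencies, 200)
  expect_equal(g$frequencies[1], 20e6)
  expect_equal(diff(g$frequencies)[1], 200e3)
  glog <- frequency_grid("10 MHz", "100 MHz", "log", 200)
  expect_length(glog$frequencies, 200)
  expect_error(frequency_grid("60 MHz", "20 MHz", "linear", "200 kHz"),
               "f_start must be below f_stop")
})

test_that("mesh solver matches the hand-derived two-mesh closed form", {
  circ <- single_sensor_circuit()
  f <- default_tracking_grid()$frequencies
  zin <- input_impedance(circ, f)
  zref <- closed_form_zin(circ, f)
  expect_lt(max(Mod(zin - zref) / Mod(zref)), 1e-9)
})

test_that("decoupled sensors leave the reader trace dipless", {
  circ <- circuit_spec(0.092e-6, 0.1,
                       list(sub_circuit(1.28e-6, 1.3, 22e-12, 0),
                            sub_circuit(0.45e-6, 1.0, 17e-12, 0)))
  f <- default_tracking_grid()$frequencies
  zin <- input_impedance(circ, f)
  # equals reader branch alone in parallel with the load
  w <- 2 * pi * f
  zb <- 0.1 + 1i * w * 0.092e-6
  expect_equal(zin, zb * 50 / (zb + 50), tolerance = 1e-12)
  sw <- s11_sweep(circ, default_tracking_grid())
  expect_error(find_resonances(sw, 2), "peak lost")
})

test_that("S11 sweeps stay passive for random passive circuits", {
  set.seed(7)
  for (i in 1:20) {
    lr <- 10^runif(1, -8, -6)
    ls <- 10^runif(1, -7, -5)
    k <- runif(1, 0.01, 0.99)
    circ <- circuit_spec(lr, runif(1, 0.05, 2),
                         list(sub_circuit(ls, runif(1, 0.2, 5),
                                          10^runif(1, -12, -10),
                                          mutual_inductance(k, lr, ls))))
    sw <- s11_sweep(circ, frequency_grid(1e6, 200e6, "linear", 1e6))
    expect_true(all(Mod(sw$reflection) <= 1 + 1e-12))
  }
})

test_that("the default two-sensor design shows exactly two prominent dips", {
  sw <- s11_sweep(default_circuit(), default_tracking_grid())
  dips <- find_resonances(sw, 2)
  expect_length(dips, 2)
  expect_lt(dips[1], dips[2])
  f1 <- resonance_frequency(1.28e-6, 22e-12)
  f2 <- resonance_frequency(0.45e-6, 17e-12)
  expect_lt(abs(dips[1] - f1), 200e3)
  expect_lt(abs(dips[2] - f2), 200e3)
})

test_that("dip detection recovers constructed Lorentzian dips to a grid step", {
  g <- default_tracking_grid()
  f <- g$frequencies
  lorentz <- function(f0, width) 1 / (1 + ((f - f0) / width)^2)
  mag_db <- -12 * lorentz(30e6, 1e6) - 9 * lorentz(52e6, 1.5e6)
  sweep <- list(frequencies = f, magnitude_db = mag_db)
  dips <- find_resonances(sweep, 2)
  expect_lt(abs(dips[1] - 30e6), 200e3)
  expect_lt(abs(dips[2] - 52e6), 200e3)
  # frequency bands take precedence and pick the in-band minimum
  banded <- find_resonances(sweep, 2, bands = list(c(25e6, 40e6), c(45e6, 58e6)))
  expect_lt(abs(banded[1] - 30e6), 200e3)
  expect_error(find_resonances(sweep, 3), "peak lost")
})

test_that("at weak coupling each dip lies within a grid step of the series prediction", {
  g <- default_tracking_grid()
  for (k in c(0.05, 0.1)) {
    circ <- default_circuit(k = k)
    dips <- find_resonances(s11_sweep(circ, g), 2)
    expect_lt(abs(dips[1] - resonance_frequency(1.28e-6, 22e-12)), 200e3)
    expect_lt(abs(dips[2] - resonance_frequency(0.45e-6, 17e-12)), 200e3)
  }
})

test_that("stretching one sensor leaves the other's dip in place", {
  g <- default_tracking_grid()
  rest <- find_resonances(s11_sweep(default_circuit(), g), 2)
  for (strain in c(0.05, 0.1, 0.2)) {
    moved <- find_resonances(
      s11_sweep(default_circuit(C1 = 22e-12 * (1 + strain)), g), 2)
    expect_lt(moved[1], rest[1])                  # own dip moves down
    expect_lt(abs(moved[2] - rest[2]), 0.5e6)     # other dip < 0.5 MHz
  }
})

test_that("each sensor's dip is non-increasing in its own strain", {
  g <- default_tracking_grid()
  strains <- seq(0, 0.3, by = 0.05)
  f1s <- vapply(strains, function(e) find_resonances(
    s11_sweep(default_circuit(C1 = 22e-12 * (1 + e)), g), 2)[1], numeric(1))
  f2s <- vapply(strains, function(e) find_resonances(
    s11_sweep(default_circuit(C2 = 17e-12 * (1 + e)), g), 2)[2], numeric(1))
  expect_true(all(diff(f1s) <= 0))
  expect_true(all(diff(f2s) <= 0))
})

test_that("design-space search enforces the separation rule over the strain envelope", {
  ds <- design_space_search(c(1.28e-6, 0.45e-6))
  expect_true(all(ds$C1 > ds$C2))
  ret <- ds[ds$retained, ]
  expect_gt(nrow(ret), 0)
  expect_true(all(ret$separation > 20e6))
  expect_true(all(ret$worst_separation > 20e6))
  # the shipped design point survives the filter
  at_design <- ds[abs(ds$C1 - 22e-12) < 1e-15 & abs(ds$C2 - 17e-12) < 1e-15, ]
  expect_true(at_design$retained)
  # no separation requirement retains every enumerated pair
  ds0 <- design_space_search(c(1.28e-6, 0.45e-6), min_separation = 0)
  expect_true(all(ds0$retained))
  # widening the C1-C2 gap widens the resonance separation
  fixed_c2 <- ds[abs(ds$C2 - 15e-12) < 1e-15, ]
  expect_true(all(diff(fixed_c2$separation[order(fixed_c2$C1)]) > 0))
})
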