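# Closed-form design formulas for the tapped spiral inductor, the
# parallel-plate strain sensors and the inductive reader link.

test_that("inner diameter follows the spiral geometry relation", {
  # zero-width degenerate case of the bare relation
  expect_equal(wearlc:::.inner_diameter(40e-3, 3, 0, 0), 40e-3)
  ind <- reference_inductor()
  expect_equal(inner_diameter(ind), 30.16e-3, tolerance = 1e-12)
  # infeasible: 10 mm coil with 5 wide turns
  expect_error(spiral_inductor("10 mm", 5, "1 mm", "2 mm"),
               "inner diameter")
})

test_that("fill factor is bounded and matches hand arithmetic", {
  expect_equal(fill_factor(40e-3, 40e-3), 0)
  expect_equal(fill_factor(40e-3, 30.16e-3), 0.1403, tolerance = 1e-3)
  expect_gt(1 - fill_factor(40e-3, 1e-9), 0)          # d_in -> 0 limit
  expect_equal(fill_factor(40e-3, 1e-12), 1, tolerance = 1e-9)
  expect_error(fill_factor(30e-3, 40e-3), "d_in exceeds d_out")
})

test_that("Wheeler inductance matches hand evaluation and scalings", {
  ind <- reference_inductor()
  expect_equal(wheeler_inductance(ind), 0.568e-6, tolerance = 1e-3)
  # N^2 scaling at fixed diameters and fill factor
  l1 <- wearlc:::.wheeler(3, 30.16e-3, 40e-3)
  l2 <- wearlc:::.wheeler(6, 30.16e-3, 40e-3)
  expect_equal(l2 / l1, 4)
  # inductance increases as the gap shrinks
  gaps <- c("1 mm", "1.5 mm", "2 mm", "2.5 mm", "3 mm")
  ls <- vapply(gaps, function(g)
    wheeler_inductance(spiral_inductor("40 mm", 3, "0.23 mm", g)), numeric(1))
  expect_true(all(diff(ls) < 0))
})

test_that("sub-inductances decrease outward-in and reduce to the whole coil", {
  ind <- reference_inductor()
  ls <- sub_inductances(ind)
  expect_length(ls, 2)
  expect_gt(ls[1], ls[2])
  # a single tap spanning every turn is the whole coil
  whole <- spiral_inductor("40 mm", 3, "0.23 mm", "2 mm", tap_turns = list(1:3))
  expect_equal(sub_inductances(whole), wheeler_inductance(whole))
  # per-turn taps: mutual terms are excluded, so segments under-add
  per_turn <- spiral_inductor("40 mm", 3, "0.23 mm", "2 mm",
                              tap_turns = list(1, 2, 3))
  expect_lt(sum(sub_inductances(per_turn)), wheeler_inductance(per_turn))
  expect_true(all(diff(sub_inductances(per_turn)) < 0))
  # overlapping taps are rejected
  expect_error(spiral_inductor("40 mm", 3, "0.23 mm", "2 mm",
                               tap_turns = list(1:2, 2:3)), "overlap")
})

test_that("plate capacitance reproduces the two reference sensors", {
  c1 <- plate_capacitance(strain_sensor("70 mm", "15 mm", "0.8 mm"))
  c2 <- plate_capacitance(strain_sensor("80 mm", "10 mm", "0.8 mm"))
  expect_equal(c1 * 1e12, 20.57, tolerance = 5e-4)
  expect_equal(c2 * 1e12, 15.67, tolerance = 5e-4)
  expect_equal(plate_capacitance(strain_sensor(0, "10 mm", "0.8 mm")), 0)
})

test_that("gauge model is linear and affine in strain", {
  s <- strain_sensor("70 mm", "15 mm", "0.8 mm", gauge_factor = 1,
                     baseline_capacitance = 22e-12)
  expect_equal(strain_to_capacitance(s, 0), 22e-12)
  expect_equal(strain_to_capacitance(s, 0.30), 1.30 * 22e-12)
  expect_equal(strain_to_capacitance(s, 0.10), 24.2e-12)
  expect_error(strain_to_capacitance(s, -0.1), "negative strain")
  expect_warning(strain_to_capacitance(s, 0.35), "30%")
  # affine: C(e1) + C(e2) - C0 = C(e1 + e2)
  e1 <- 0.07; e2 <- 0.12
  expect_equal(strain_to_capacitance(s, e1) + strain_to_capacitance(s, e2) -
                 22e-12, strain_to_capacitance(s, e1 + e2))
})

test_that("series resonance formula and its inverse are exact", {
  expect_equal(resonance_frequency(0.5e-6, 22e-12) / 1e6, 48.0,
               tolerance = 1e-3)
  f0 <- resonance_frequency(1e-6, 10e-12)
  expect_equal(resonance_frequency(1e-6, 40e-12), f0 / 2)
  set.seed(42)
  L <- 10^runif(50, -8, -4); C <- 10^runif(50, -13, -9)
  expect_equal(resonance_frequency(L, C) * 2 * pi * sqrt(L * C),
               rep(1, 50), tolerance = 1e-12)
  expect_error(resonance_frequency(0, 1e-12), "positive")
})

test_that("quality factor scales as 1/R and sqrt(L/C)", {
  expect_equal(quality_factor(5, 0.5e-6, 5e-12), 63.2, tolerance = 1e-2)
  expect_equal(quality_factor(10, 1e-6, 1e-12),
               quality_factor(5, 1e-6, 1e-12) / 2)
  expect_equal(quality_factor(5, 4e-6, 1e-12),
               2 * quality_factor(5, 1e-6, 1e-12))
  expect_error(quality_factor(0, 1e-6, 1e-12), "positive")
})

test_that("effective radius is the arithmetic mean", {
  expect_equal(effective_radius(10e-3, 10e-3), 10e-3)
  expect_equal(effective_radius(15.08e-3, 20e-3), 17.54e-3)
  expect_equal(effective_radius(0, 20e-3), 10e-3)
  expect_error(effective_radius(30e-3, 20e-3), "r_in <= r_out")
})

test_that("coupling coefficient is 1 at contact and decays with distance", {
  spec0 <- coupling_spec(0, "15.08 mm", "20 mm")
  expect_equal(coupling_coefficient(spec0, 17.54e-3), 1)
  # closed-form inversion: d = sqrt(r1 r2) 2^(-1/3) gives k = 2^(-3/2)
  r1 <- effective_radius(15.08e-3, 20e-3); r2 <- 17.54e-3
  d_half <- sqrt(r1 * r2) * 2^(-1 / 3)
  expect_equal(coupling_coefficient(
    coupling_spec(d_half, "15.08 mm", "20 mm"), r2), 2^(-3 / 2),
    tolerance = 1e-12)
  # strictly decreasing, vanishing at large distance
  ds <- seq(0, 50e-3, by = 1e-3)
  ks <- vapply(ds, function(d) coupling_coefficient(
    coupling_spec(d, "15.08 mm", "20 mm"), r2), numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_lt(coupling_coefficient(coupling_spec(10, "15.08 mm", "20 mm"), r2),
            1e-6)
  # the shipped pipeline value enters as an override
  ov <- coupling_spec("1.5 mm", coupling_override = 0.35)
  expect_equal(coupling_coefficient(ov, r2), 0.35)
})

test_that("mutual inductance follows k sqrt(L1 L2)", {
  expect_equal(mutual_inductance(0, 1e-6, 1e-6), 0)
  expect_equal(mutual_inductance(1, 1e-6, 1e-6), 1e-6)
  expect_equal(mutual_inductance(0.35, 0.5e-6, 0.2e-6) * 1e6, 0.1107,
               tolerance = 1e-3)
  expect_error(mutual_inductance(1.2, 1e-6, 1e-6), "\\[0, 1\\]")
})

test_that("quantities with unit suffixes parse to SI", {
  expect_equal(parse_quantity("40 mm"), 0.04)
  expect_equal(parse_quantity("22 pF"), 22e-12)
  expect_equal(parse_quantity("0.45 uH"), 0.45e-6)
  expect_equal(parse_quantity("200 kHz"), 2e5)
  expect_equal(parse_quantity(3.3), 3.3)
  expect_error(parse_quantity("40 furlong"), "unknown unit")
})
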