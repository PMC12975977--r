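# Closed-form design model of the textile sensing circuit: a planar spiral
# inductor tapped into sub-inductors, parallel-plate capacitive strain
# sensors, and inductive coupling to an external reader loop.

.mu0  <- 4 * pi * 1e-7          # vacuum permeability, H/m
.eps0 <- 8.8541878128e-12       # vacuum permittivity, F/m

#' Planar spiral textile inductor
#'
#' Describes a circular planar spiral inductor embroidered with conductive
#' yarn, optionally tapped at individual turns so that each capacitive sensor
#' connects across its own sub-inductor. Geometry follows the usual spiral
#' parameterisation: outer diameter, number of turns, trace (yarn) width and
#' turn-to-turn gap.
#'
#' @param outer_diameter Outer diameter in metres (or a unit string,
#'   e.g. `"40 mm"`).
#' @param n_turns Number of turns (positive integer).
#' @param trace_width Width of the conductive trace in metres.
#' @param gap Spacing between adjacent turns in metres. Must be at least
#'   `min_gap`, the manufacturing floor below which adjacent turns short.
#' @param resistance_per_length Series resistance of the conductive yarn,
#'   ohm/m. Default 3.3 ohm/m (silver-plated Vectran yarn).
#' @param parasitic_capacitance Lumped parasitic capacitance of the coil in
#'   farads; sets the self-resonance of the whole inductor.
#' @param tap_turns List of integer vectors, each a contiguous run of turn
#'   indices (1 = outermost) forming one sub-inductor. Segments must not
#'   overlap and must be given outermost first. `NULL` for an untapped coil.
#' @param lead_inductance Additive inductance of the connection leads per
#'   segment, in henries. Connection yarns add measurable inductance on top
#'   of the Wheeler estimate; default 0.
#' @param min_gap Manufacturing lower bound on `gap`, metres (default 1 mm).
#' @return An object of class `spiral_inductor`.
#' @examples
#' ind <- spiral_inductor("40 mm", 3, "0.23 mm", "2 mm", tap_turns = list(1, 3))
#' wheeler_inductance(ind)
#' sub_inductances(ind)
#' @export
spiral_inductor <- function(outer_diameter, n_turns, trace_width, gap,
                            resistance_per_length = 3.3,
                            parasitic_capacitance = 2e-12,
                            tap_turns = NULL,
                            lead_inductance = 0,
                            min_gap = 1e-3) {
  outer_diameter <- parse_quantity(outer_diameter)
  trace_width <- parse_quantity(trace_width)
  gap <- parse_quantity(gap)
  .check_positive(outer_diameter, "outer_diameter")
  if (!is.numeric(n_turns) || length(n_turns) != 1L || n_turns < 1 ||
      n_turns != round(n_turns)) {
    stop("'n_turns' must be a positive integer", call. = FALSE)
  }
  .check_positive(trace_width, "trace_width")
  .check_positive(gap, "gap")
  .check_nonneg(lead_inductance, "lead_inductance")
  if (!is.null(tap_turns) && is.atomic(tap_turns)) {
    # a bare vector is shorthand for single-turn taps
    tap_turns <- as.list(as.integer(tap_turns))
  }
  if (gap < min_gap) {
    stop(sprintf("gap %.3g mm is below the manufacturing floor of %.3g mm",
                 gap * 1e3, min_gap * 1e3), call. = FALSE)
  }
  .check_positive(resistance_per_length, "resistance_per_length")
  .check_positive(parasitic_capacitance, "parasitic_capacitance")

  obj <- structure(
    list(outer_diameter = outer_diameter,
         n_turns = as.integer(n_turns),
         trace_width = trace_width,
         gap = gap,
         resistance_per_length = resistance_per_length,
         parasitic_capacitance = parasitic_capacitance,
         tap_turns = tap_turns,
         lead_inductance = lead_inductance),
    class = "spiral_inductor")

  d_in <- inner_diameter(obj)     # errors on infeasible geometry
  p <- fill_factor(outer_diameter, d_in)
  if (p <= 0 || p >= 1) {
    stop("derived fill factor must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.null(tap_turns)) {
    .validate_taps(tap_turns, obj$n_turns)
    ls <- sub_inductances(obj)
    if (length(ls) > 1L && any(diff(ls) >= 0)) {
      stop("sub-inductances must decrease strictly from the outermost tap inward",
           call. = FALSE)
    }
  }
  obj
}

#' @export
print.spiral_inductor <- function(x, ...) {
  cat(sprintf("Spiral inductor: d_out = %.1f mm, N = %d, w = %.2f mm, s = %.2f mm\n",
              x$outer_diameter * 1e3, x$n_turns, x$trace_width * 1e3, x$gap * 1e3))
  cat(sprintf("  d_in = %.2f mm, fill factor = %.4f, L = %.3f uH\n",
              inner_diameter(x) * 1e3,
              fill_factor(x$outer_diameter, inner_diameter(x)),
              wheeler_inductance(x) * 1e6))
  if (!is.null(x$tap_turns)) {
    cat(sprintf("  sub-inductors (turns %s): %s uH\n",
                paste(vapply(x$tap_turns, function(t) paste(range(t), collapse = "-"),
                             character(1)), collapse = ", "),
                paste(sprintf("%.3f", sub_inductances(x) * 1e6), collapse = ", ")))
  }
  invisible(x)
}

.validate_taps <- function(tap_turns, n_turns) {
  if (!is.list(tap_turns) || length(tap_turns) < 1L) {
    stop("'tap_turns' must be a non-empty list of turn-index vectors", call. = FALSE)
  }
  all_turns <- integer(0)
  last_max <- 0L
  for (seg in tap_turns) {
    seg <- as.integer(seg)
    if (any(seg < 1L) || any(seg > n_turns)) {
      stop("tap turn indices must lie in 1..n_turns", call. = FALSE)
    }
    if (!identical(seg, seq(min(seg), max(seg)))) {
      stop("each tap segment must be a contiguous run of turns", call. = FALSE)
    }
    if (min(seg) <= last_max) {
      stop("tap segments overlap or are not ordered outermost-first", call. = FALSE)
    }
    last_max <- max(seg)
    all_turns <- c(all_turns, seg)
  }
  invisible(TRUE)
}

#' Inner diameter of a planar spiral
#'
#' The inner diameter is fixed by the outer diameter, turn count, trace
#' width and gap: `d_in = d_out - 2(N+1) w - 2(N-1) s`.
#'
#' @param inductor A [spiral_inductor()].
#' @return Inner diameter in metres; errors if the geometry is infeasible
#'   (non-positive result).
#' @export
inner_diameter <- function(inductor) {
  stopifnot(inherits(inductor, "spiral_inductor"))
  d_in <- .inner_diameter(inductor$outer_diameter, inductor$n_turns,
                          inductor$trace_width, inductor$gap)
  if (d_in <= 0) {
    stop("infeasible spiral geometry: derived inner diameter is not positive",
         call. = FALSE)
  }
  d_in
}

.inner_diameter <- function(d_out, n, w, s) {
  d_out - 2 * (n + 1) * w - 2 * (n - 1) * s
}

#' Fill factor of a planar spiral
#'
#' `p = (d_out - d_in) / (d_out + d_in)`, a dimensionless measure of how
#' completely the spiral fills its annulus (0 = single thin loop, -> 1 =
#' filled to the centre).
#'
#' @param d_out Outer diameter, metres.
#' @param d_in Inner diameter, metres; must satisfy `0 < d_in <= d_out`.
#' @return Fill factor in `[0, 1)`.
#' @export
fill_factor <- function(d_out, d_in) {
  d_out <- parse_quantity(d_out)
  d_in <- parse_quantity(d_in)
  .check_positive(d_out, "d_out")
  if (d_in <= 0) stop("'d_in' must be positive", call. = FALSE)
  if (d_in > d_out) stop("invalid geometry: d_in exceeds d_out", call. = FALSE)
  (d_out - d_in) / (d_out + d_in)
}

#' Wheeler inductance of a circular planar spiral
#'
#' Modified simplified Wheeler formula for circular planar spirals:
#' `L = (mu0 / 4) N^2 (d_in + d_out) ln(2.46 / p + 0.20 p^2)`,
#' with `p` the fill factor. Any configured lead inductance is added.
#'
#' @param inductor A [spiral_inductor()].
#' @return Inductance in henries.
#' @export
wheeler_inductance <- function(inductor) {
  stopifnot(inherits(inductor, "spiral_inductor"))
  d_in <- inner_diameter(inductor)
  .wheeler(inductor$n_turns, d_in, inductor$outer_diameter) +
    inductor$lead_inductance
}

.wheeler <- function(n, d_in, d_out) {
  p <- (d_out - d_in) / (d_out + d_in)
  if (p <= 0) {
    stop("degenerate geometry: fill factor is zero (logarithm diverges)",
         call. = FALSE)
  }
  0.25 * .mu0 * n^2 * (d_in + d_out) * log(2.46 / p + 0.20 * p^2)
}

#' Inductances of the tapped sub-inductors
#'
#' Each tap segment (a contiguous run of turns) is modelled as an
#' independent spiral on its own annulus and its inductance computed with
#' the Wheeler formula; mutual inductance between segments is neglected,
#' treating each sensor sub-circuit as a separable resonator. Segment `k`
#' starting at turn `a` has outer diameter `d_out - 2 (a-1) (w + s)`.
#'
#' @param inductor A [spiral_inductor()] with `tap_turns` set.
#' @return Numeric vector of inductances (H), outermost segment first.
#'   For a tapped coil these decrease strictly from the outermost segment
#'   (largest enclosed area) inward.
#' @export
sub_inductances <- function(inductor) {
  stopifnot(inherits(inductor, "spiral_inductor"))
  if (is.null(inductor$tap_turns)) {
    stop("inductor has no tap_turns; use wheeler_inductance() for the whole coil",
         call. = FALSE)
  }
  .validate_taps(inductor$tap_turns, inductor$n_turns)
  pitch <- inductor$trace_width + inductor$gap
  vapply(inductor$tap_turns, function(seg) {
    seg <- as.integer(seg)
    a <- min(seg)
    n_seg <- length(seg)
    d_out_seg <- inductor$outer_diameter - 2 * (a - 1L) * pitch
    d_in_seg <- .inner_diameter(d_out_seg, n_seg, inductor$trace_width,
                                inductor$gap)
    if (d_in_seg <= 0) {
      stop("infeasible tap segment: non-positive inner diameter", call. = FALSE)
    }
    .wheeler(n_seg, d_in_seg, d_out_seg) + inductor$lead_inductance
  }, numeric(1))
}

#' Series resistance of tapped sub-inductor segments
#'
#' Approximates each segment's conductor length as the sum over its turns of
#' the turn circumference at the turn's mean radius, times the yarn
#' resistance per unit length.
#'
#' @param inductor A [spiral_inductor()] with `tap_turns` set.
#' @param lead_length Extra conductor length per segment for connection
#'   leads, metres (default 0).
#' @return Numeric vector of resistances (ohm), outermost segment first.
#' @export
sub_resistances <- function(inductor, lead_length = 0) {
  stopifnot(inherits(inductor, "spiral_inductor"))
  if (is.null(inductor$tap_turns)) stop("inductor has no tap_turns", call. = FALSE)
  pitch <- inductor$trace_width + inductor$gap
  vapply(inductor$tap_turns, function(seg) {
    seg <- as.integer(seg)
    r_mean <- inductor$outer_diameter / 2 - (seg - 1L) * pitch -
      inductor$trace_width / 2
    arc <- sum(2 * pi * r_mean)
    (arc + lead_length) * inductor$resistance_per_length
  }, numeric(1))
}

#' Parallel-plate capacitive strain sensor
#'
#' A textile strain sensor made of two stretchable conductive plates
#' separated by a fabric dielectric. Baseline capacitance follows the
#' parallel-plate formula unless a measured override is supplied; response
#' to strain is linear with a constant gauge factor.
#'
#' @param plate_length,plate_width Plate dimensions, metres.
#' @param dielectric_thickness Plate separation, metres.
#' @param relative_permittivity Relative permittivity of the fabric
#'   dielectric (default 1.77; spandex measures about 1.75 in the tens of
#'   MHz).
#' @param gauge_factor Relative capacitance change per unit strain
#'   (default 1, typical for parallel-plate capacitive strain sensors).
#' @param baseline_capacitance Optional measured baseline capacitance (F)
#'   overriding the parallel-plate estimate.
#' @return An object of class `strain_sensor`.
#' @examples
#' s <- strain_sensor("70 mm", "15 mm", "0.8 mm")
#' plate_capacitance(s) * 1e12   # pF
#' @export
strain_sensor <- function(plate_length, plate_width, dielectric_thickness,
                          relative_permittivity = 1.77,
                          gauge_factor = 1,
                          baseline_capacitance = NULL) {
  plate_length <- parse_quantity(plate_length)
  plate_width <- parse_quantity(plate_width)
  dielectric_thickness <- parse_quantity(dielectric_thickness)
  .check_nonneg(plate_length, "plate_length")
  .check_nonneg(plate_width, "plate_width")
  .check_positive(dielectric_thickness, "dielectric_thickness")
  .check_positive(relative_permittivity, "relative_permittivity")
  if (!is.null(baseline_capacitance)) {
    baseline_capacitance <- parse_quantity(baseline_capacitance)
    .check_positive(baseline_capacitance, "baseline_capacitance")
  }
  structure(
    list(plate_length = plate_length,
         plate_width = plate_width,
         dielectric_thickness = dielectric_thickness,
         relative_permittivity = relative_permittivity,
         gauge_factor = gauge_factor,
         baseline_capacitance = baseline_capacitance),
    class = "strain_sensor")
}

#' @export
print.strain_sensor <- function(x, ...) {
  cat(sprintf("Strain sensor: %.0f x %.0f mm plates, d = %.2f mm, er = %.2f, GF = %.2f\n",
              x$plate_length * 1e3, x$plate_width * 1e3,
              x$dielectric_thickness * 1e3, x$relative_permittivity,
              x$gauge_factor))
  cat(sprintf("  baseline C = %.2f pF%s\n", plate_capacitance(x) * 1e12,
              if (!is.null(x$baseline_capacitance)) " (measured override)" else ""))
  invisible(x)
}

#' Baseline capacitance of a parallel-plate sensor
#'
#' `C = eps0 epsr A / d` with `A = plate_length * plate_width`, unless the
#' sensor carries a measured override, which is returned as-is.
#'
#' @param sensor A [strain_sensor()].
#' @return Capacitance in farads.
#' @export
plate_capacitance <- function(sensor) {
  stopifnot(inherits(sensor, "strain_sensor"))
  if (!is.null(sensor$baseline_capacitance)) return(sensor$baseline_capacitance)
  area <- sensor$plate_length * sensor$plate_width
  .eps0 * sensor$relative_permittivity * area / sensor$dielectric_thickness
}

#' Capacitance under applied strain
#'
#' Linear gauge model `C(strain) = C0 (1 + GF * strain)`. The linear regime
#' of these fabric sensors extends to about 30% strain; larger strains are
#' accepted with a warning.
#'
#' @param sensor A [strain_sensor()].
#' @param strain Engineering strain (dimensionless), `>= 0`. Vectorised.
#' @return Capacitance in farads, same length as `strain`.
#' @export
strain_to_capacitance <- function(sensor, strain) {
  stopifnot(inherits(sensor, "strain_sensor"))
  if (any(strain < 0)) stop("negative strain is not supported", call. = FALSE)
  if (any(strain > 0.3)) {
    warning("strain above 30% is outside the sensor's characterised linear range")
  }
  c0 <- plate_capacitance(sensor)
  c0 * (1 + sensor$gauge_factor * strain)
}

#' Resonance frequency of a series LC sub-circuit
#'
#' `f = 1 / (2 pi sqrt(L C))`. Stretching a sensor raises its capacitance
#' and therefore lowers its sub-circuit's resonance.
#'
#' @param L Inductance, henries (vectorised).
#' @param C Capacitance, farads (vectorised).
#' @return Frequency in hertz.
#' @export
resonance_frequency <- function(L, C) {
  if (any(L <= 0) || any(C <= 0)) {
    stop("L and C must be positive", call. = FALSE)
  }
  1 / (2 * pi * sqrt(L * C))
}

#' Quality factor of a series RLC resonator
#'
#' `Q = (1 / R) sqrt(L / C)`. Higher Q gives narrower, deeper reflection
#' dips, easier to locate precisely.
#'
#' @param R Series resistance, ohms; must be strictly positive (an ideal
#'   lossless resonator has no finite Q).
#' @param L Inductance, henries.
#' @param C Capacitance, farads.
#' @return Dimensionless quality factor.
#' @export
quality_factor <- function(R, L, C) {
  if (any(R <= 0)) stop("R must be strictly positive", call. = FALSE)
  if (any(L <= 0) || any(C <= 0)) stop("L and C must be positive", call. = FALSE)
  (1 / R) * sqrt(L / C)
}

#' Effective radius of a planar spiral
#'
#' Arithmetic mean of inner and outer radii, used in the coaxial-loop
#' coupling approximation.
#'
#' @param r_in,r_out Inner and outer radii, metres, `0 <= r_in <= r_out`,
#'   `r_out > 0`.
#' @return Effective radius in metres.
#' @export
effective_radius <- function(r_in, r_out) {
  r_in <- parse_quantity(r_in)
  r_out <- parse_quantity(r_out)
  if (r_in < 0 || r_out <= 0 || r_in > r_out) {
    stop("radii must satisfy 0 <= r_in <= r_out with r_out > 0", call. = FALSE)
  }
  (r_in + r_out) / 2
}

#' Reader-to-textile coupling specification
#'
#' Geometry of the inductive link between the external reader loop and the
#' textile inductor. The coupling coefficient is computed from the axial
#' separation with the standard coaxial-loop approximation; a measured or
#' chosen override may be supplied instead (the shipped defaults use
#' `k = 0.35`, representative of a reader loop pressed against the textile
#' coil in a garment pocket).
#'
#' @param axial_distance Axial separation of the two coils, metres (>= 0).
#' @param reader_inner_radius,reader_outer_radius Reader loop radii, metres.
#' @param coupling_override Optional fixed coupling coefficient in (0, 1]
#'   used instead of the distance formula.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(axial_distance,
                          reader_inner_radius = "19 mm",
                          reader_outer_radius = "20 mm",
                          coupling_override = NULL) {
  axial_distance <- parse_quantity(axial_distance)
  reader_inner_radius <- parse_quantity(reader_inner_radius)
  reader_outer_radius <- parse_quantity(reader_outer_radius)
  .check_nonneg(axial_distance, "axial_distance")
  .check_positive(reader_inner_radius, "reader_inner_radius")
  .check_positive(reader_outer_radius, "reader_outer_radius")
  if (reader_inner_radius > reader_outer_radius) {
    stop("reader_inner_radius must not exceed reader_outer_radius", call. = FALSE)
  }
  if (!is.null(coupling_override)) {
    if (coupling_override <= 0 || coupling_override > 1) {
      stop("coupling_override must lie in (0, 1]", call. = FALSE)
    }
  }
  structure(
    list(axial_distance = axial_distance,
         reader_inner_radius = reader_inner_radius,
         reader_outer_radius = reader_outer_radius,
         coupling_override = coupling_override),
    class = "coupling_spec")
}

#' Coupling coefficient between coaxial circular coils
#'
#' Coaxial-loop approximation
#' `k(d) = (1 + 2^(2/3) (d / sqrt(r1 r2))^2)^(-3/2)`, where `r1` is the
#' reader's effective radius, `r2` the textile coil's, and `d` the axial
#' separation. `k(0) = 1` and `k` decreases strictly with distance. If the
#' spec carries a `coupling_override` it is returned unchanged.
#'
#' @param spec A [coupling_spec()].
#' @param textile_r_eff Effective radius of the textile (sub-)inductor,
#'   metres.
#' @return Coupling coefficient in (0, 1].
#' @export
coupling_coefficient <- function(spec, textile_r_eff) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (!is.null(spec$coupling_override)) return(spec$coupling_override)
  textile_r_eff <- parse_quantity(textile_r_eff)
  .check_positive(textile_r_eff, "textile_r_eff")
  r1 <- effective_radius(spec$reader_inner_radius, spec$reader_outer_radius)
  d <- spec$axial_distance
  (1 + 2^(2 / 3) * (d / sqrt(r1 * textile_r_eff))^2)^(-3 / 2)
}

#' Mutual inductance of two coupled inductors
#'
#' `M = k sqrt(L_reader L_sub)` for coupling coefficient `k` in `[0, 1]`.
#'
#' @param k Coupling coefficient.
#' @param L_reader,L_sub Inductances of the two coils, henries.
#' @return Mutual inductance in henries.
#' @export
mutual_inductance <- function(k, L_reader, L_sub) {
  if (any(k < 0) || any(k > 1)) stop("k must lie in [0, 1]", call. = FALSE)
  if (any(L_reader <= 0) || any(L_sub <= 0)) {
    stop("inductances must be positive", call. = FALSE)
  }
  k * sqrt(L_reader * L_sub)
}
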