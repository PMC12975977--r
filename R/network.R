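# Small-signal AC analysis of the reader-coupled multi-sensor circuit.
#
# Topology: an AC source with 50 ohm series impedance drives a port formed
# by a 50 ohm load in parallel with the reader branch (reader loop R_R +
# jwL_R). Each sensor sub-circuit is a series R-L-C loop coupled to the
# reader loop only through its mutual inductance M_i; sub-circuits do not
# couple to each other (an untapped isolation turn between taps keeps
# inter-sensor coupling negligible). The branch impedances are obtained
# from a mesh-current solve of the coupled loops.

#' One sensor sub-circuit of the tapped coil
#'
#' @param L_sub Sub-inductor inductance, henries.
#' @param R_sub Series resistance of the segment and its leads, ohms;
#'   must be strictly positive (guards against singular lossless branches).
#' @param C_sensor Sensor capacitance, farads.
#' @param M Mutual inductance to the reader loop, henries.
#' @return A list of class `sub_circuit`.
#' @export
sub_circuit <- function(L_sub, R_sub, C_sensor, M) {
  L_sub <- parse_quantity(L_sub); R_sub <- parse_quantity(R_sub)
  C_sensor <- parse_quantity(C_sensor); M <- parse_quantity(M)
  .check_positive(L_sub, "L_sub")
  .check_positive(R_sub, "R_sub")
  .check_positive(C_sensor, "C_sensor")
  .check_nonneg(M, "M")
  structure(list(L_sub = L_sub, R_sub = R_sub, C_sensor = C_sensor, M = M),
            class = "sub_circuit")
}

#' Reader-coupled multi-sensor circuit specification
#'
#' @param reader_inductance Reader loop inductance, henries.
#' @param reader_resistance Reader loop series resistance, ohms.
#' @param sub_circuits List of [sub_circuit()] objects, one per sensor,
#'   ordered by ascending design resonance (largest capacitor first).
#' @param source_impedance Source (VNA) impedance, ohms; default 50.
#' @param load_impedance Load placed in parallel with the reader port,
#'   ohms; default 50.
#' @param isolation_inductance Inductance of the untapped turn(s) left
#'   between sensor taps, henries. Recorded for bookkeeping; in this model
#'   its role is to justify neglecting inter-sub-circuit coupling.
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(reader_inductance, reader_resistance, sub_circuits,
                         source_impedance = 50, load_impedance = 50,
                         isolation_inductance = 0) {
  reader_inductance <- parse_quantity(reader_inductance)
  reader_resistance <- parse_quantity(reader_resistance)
  .check_positive(reader_inductance, "reader_inductance")
  .check_nonneg(reader_resistance, "reader_resistance")
  .check_positive(source_impedance, "source_impedance")
  .check_positive(load_impedance, "load_impedance")
  .check_nonneg(isolation_inductance, "isolation_inductance")
  if (!is.list(sub_circuits) || length(sub_circuits) < 1L) {
    stop("at least one sub-circuit is required", call. = FALSE)
  }
  for (sc in sub_circuits) {
    if (!inherits(sc, "sub_circuit")) {
      stop("'sub_circuits' must be a list of sub_circuit objects", call. = FALSE)
    }
    if (sc$M > sqrt(reader_inductance * sc$L_sub) + 1e-15) {
      stop("mutual inductance exceeds sqrt(L_reader * L_sub) (k > 1)",
           call. = FALSE)
    }
  }
  structure(
    list(reader_inductance = reader_inductance,
         reader_resistance = reader_resistance,
         sub_circuits = sub_circuits,
         source_impedance = source_impedance,
         load_impedance = load_impedance,
         isolation_inductance = isolation_inductance),
    class = "circuit_spec")
}

#' @export
print.circuit_spec <- function(x, ...) {
  cat(sprintf("Reader-coupled circuit: L_R = %.3f uH, R_R = %.2f ohm, %d sensor sub-circuit(s)\n",
              x$reader_inductance * 1e6, x$reader_resistance,
              length(x$sub_circuits)))
  for (i in seq_along(x$sub_circuits)) {
    sc <- x$sub_circuits[[i]]
    cat(sprintf("  [%d] L = %.3f uH, R = %.2f ohm, C = %.2f pF, M = %.4f uH -> f_res = %.2f MHz\n",
                i, sc$L_sub * 1e6, sc$R_sub, sc$C_sensor * 1e12, sc$M * 1e6,
                resonance_frequency(sc$L_sub, sc$C_sensor) / 1e6))
  }
  invisible(x)
}

#' Frequency sweep grid
#'
#' Linear grids use the interval-count convention: the number of points is
#' `(f_stop - f_start) / resolution`, with points at
#' `f_start + (0:(n-1)) * resolution` (a 20-60 MHz sweep at 200 kHz
#' resolution has 200 points). Log grids place `resolution` points per
#' decade starting at `f_start`.
#'
#' @param f_start,f_stop Sweep limits, hertz; `f_start < f_stop`.
#' @param spacing_mode `"linear"` or `"log"`.
#' @param resolution Step in hertz (linear) or points per decade (log).
#' @return An object of class `frequency_grid` with a `frequencies` field.
#' @examples
#' length(frequency_grid("20 MHz", "60 MHz", resolution = "200 kHz")$frequencies)
#' @export
frequency_grid <- function(f_start, f_stop, spacing_mode = c("linear", "log"),
                           resolution) {
  f_start <- parse_quantity(f_start); f_stop <- parse_quantity(f_stop)
  spacing_mode <- match.arg(spacing_mode)
  .check_positive(f_start, "f_start")
  if (f_stop <= f_start) stop("f_start must be below f_stop", call. = FALSE)
  if (spacing_mode == "linear") {
    resolution <- parse_quantity(resolution)
    .check_positive(resolution, "resolution")
    n <- round((f_stop - f_start) / resolution)
    if (n < 2) stop("grid must contain at least 2 points", call. = FALSE)
    freqs <- f_start + (seq_len(n) - 1L) * resolution
  } else {
    .check_positive(resolution, "points per decade")
    n <- max(2L, round(log10(f_stop / f_start) * resolution))
    freqs <- f_start * 10^((seq_len(n) - 1L) / resolution)
  }
  structure(
    list(f_start = f_start, f_stop = f_stop, spacing_mode = spacing_mode,
         resolution = resolution, frequencies = freqs),
    class = "frequency_grid")
}

# Mesh-current solve: loop 1 is the reader, loops 2..(m+1) the sensor
# sub-circuits; coupling enters as jwM off-diagonal terms. Returns the
# impedance of the reader branch seen at its terminals.
.reader_branch_impedance <- function(circuit, f) {
  w <- 2 * pi * f
  m <- length(circuit$sub_circuits)
  Z <- matrix(0 + 0i, nrow = m + 1L, ncol = m + 1L)
  Z[1L, 1L] <- circuit$reader_resistance + 1i * w * circuit$reader_inductance
  for (i in seq_len(m)) {
    sc <- circuit$sub_circuits[[i]]
    Z[i + 1L, i + 1L] <- sc$R_sub + 1i * w * sc$L_sub + 1 / (1i * w * sc$C_sensor)
    Z[1L, i + 1L] <- 1i * w * sc$M
    Z[i + 1L, 1L] <- 1i * w * sc$M
  }
  rhs <- c(1 + 0i, rep(0 + 0i, m))
  currents <- solve(Z, rhs)
  1 / currents[1L]
}

#' Input impedance of the reader-coupled circuit
#'
#' Impedance seen by the source at frequency `f`: the reader branch (with
#' every sensor sub-circuit reflected into it through its mutual
#' inductance, obtained from a mesh-current solve) in parallel with the
#' load.
#'
#' @param circuit A [circuit_spec()].
#' @param f Frequency in hertz (vectorised).
#' @return Complex impedance, same length as `f`.
#' @export
input_impedance <- function(circuit, f) {
  stopifnot(inherits(circuit, "circuit_spec"))
  if (any(f <= 0)) stop("frequencies must be positive", call. = FALSE)
  zl <- circuit$load_impedance
  vapply(f, function(fi) {
    zb <- .reader_branch_impedance(circuit, fi)
    (zb * zl) / (zb + zl)
  }, complex(1))
}

#' Simulate an S11 reflection sweep
#'
#' Computes the complex reflection coefficient
#' `S11(f) = (Z_in(f) - Z0) / (Z_in(f) + Z0)` over a frequency grid, with
#' `Z0` the source impedance. For passive circuits `|S11| <= 1` everywhere;
#' each sensor sub-circuit produces a dip near its series resonance.
#'
#' @param circuit A [circuit_spec()].
#' @param grid A [frequency_grid()].
#' @return An object of class `s11_sweep` with fields `grid`, `frequencies`,
#'   `reflection` (complex) and `magnitude_db`.
#' @export
s11_sweep <- function(circuit, grid) {
  stopifnot(inherits(circuit, "circuit_spec"), inherits(grid, "frequency_grid"))
  z0 <- circuit$source_impedance
  zin <- input_impedance(circuit, grid$frequencies)
  s11 <- (zin - z0) / (zin + z0)
  structure(
    list(grid = grid,
         frequencies = grid$frequencies,
         reflection = s11,
         magnitude_db = 20 * log10(Mod(s11))),
    class = "s11_sweep")
}

#' @export
print.s11_sweep <- function(x, ...) {
  cat(sprintf("S11 sweep: %d points, %.2f-%.2f MHz, min |S11| = %.2f dB at %.2f MHz\n",
              length(x$frequencies), min(x$frequencies) / 1e6,
              max(x$frequencies) / 1e6, min(x$magnitude_db),
              x$frequencies[which.min(x$magnitude_db)] / 1e6))
  invisible(x)
}

#' Locate resonance dips in an S11 sweep
#'
#' Without bands, finds local minima of `|S11|` in dB with prominence of at
#' least `min_prominence_db`, refines each by 3-point parabolic
#' interpolation, and returns the `n_expected` most prominent, ascending in
#' frequency. When per-sensor frequency `bands` are supplied they take
#' precedence: the global `|S11|` minimum within each band is returned.
#'
#' @param sweep An [s11_sweep()] (or any list with `frequencies` and
#'   `magnitude_db`).
#' @param n_expected Number of resonances that must be found.
#' @param bands Optional list of `c(f_lo, f_hi)` intervals (Hz), one per
#'   expected resonance.
#' @param min_prominence_db Prominence threshold for dip detection
#'   (default 1 dB).
#' @param refine If `TRUE` (default) apply parabolic refinement to the dip
#'   position; the refined value is clamped to within one grid step.
#' @return Numeric vector of `n_expected` resonance frequencies (Hz),
#'   ascending. Raises a "peak lost" error when fewer dips are found,
#'   modelling reader misalignment or merged peaks.
#' @export
find_resonances <- function(sweep, n_expected, bands = NULL,
                            min_prominence_db = 1, refine = TRUE) {
  stopifnot(n_expected >= 1)
  f <- sweep$frequencies
  mag <- sweep$magnitude_db
  n <- length(f)
  if (!is.null(bands)) {
    if (length(bands) != n_expected) {
      stop("'bands' must supply one interval per expected resonance", call. = FALSE)
    }
    out <- vapply(bands, function(b) {
      sel <- which(f >= b[1] & f <= b[2])
      if (length(sel) == 0L) stop("peak lost: empty frequency band", call. = FALSE)
      i <- sel[which.min(mag[sel])]
      .refine_dip(f, mag, i, refine)
    }, numeric(1))
    return(sort(out))
  }
  # interior local minima
  if (n < 3L) stop("peak lost: sweep too short for dip detection", call. = FALSE)
  is_min <- which(diff(sign(diff(mag))) > 0) + 1L
  if (length(is_min) == 0L) stop("peak lost: no S11 dip found", call. = FALSE)
  prom <- vapply(is_min, function(i) {
    left_max <- max(mag[1:i])
    right_max <- max(mag[i:n])
    min(left_max, right_max) - mag[i]
  }, numeric(1))
  keep <- is_min[prom >= min_prominence_db]
  if (length(keep) < n_expected) {
    stop(sprintf("peak lost: found %d dip(s), expected %d",
                 length(keep), n_expected), call. = FALSE)
  }
  ord <- keep[order(prom[prom >= min_prominence_db], decreasing = TRUE)]
  sel <- sort(ord[seq_len(n_expected)])
  sort(vapply(sel, function(i) .refine_dip(f, mag, i, refine), numeric(1)))
}

.refine_dip <- function(f, mag, i, refine) {
  n <- length(f)
  if (!refine || i <= 1L || i >= n) return(f[i])
  y1 <- mag[i - 1L]; y2 <- mag[i]; y3 <- mag[i + 1L]
  denom <- (y1 - 2 * y2 + y3)
  if (denom <= 0) return(f[i])
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-1, min(1, delta))
  step <- if (i < n) f[i + 1L] - f[i] else f[i] - f[i - 1L]
  f[i] + delta * step
}

#' Capacitor design-space search with a separation constraint
#'
#' Enumerates sensor capacitor pairs `(C1, C2)` with `C1 > C2` over the
#' given ranges and retains those whose two sub-circuit resonances stay
#' separated by more than `min_separation` both at rest and across the full
#' strain envelope (either sensor stretched up to `max_strain`, which
#' raises its capacitance by the gauge model and lowers its resonance).
#' The worst case for separation is the upper resonance's sensor at full
#' stretch against the lower resonance's sensor at rest.
#'
#' @param L_subs Numeric vector of two sub-inductances (H), outermost
#'   (larger, paired with `C1`) first.
#' @param C1_range,C2_range Length-2 numeric vectors (F) giving the
#'   enumeration ranges.
#' @param step Enumeration step, farads (default 0.5 pF).
#' @param min_separation Required resonance separation, hertz
#'   (default 20 MHz).
#' @param max_strain Strain envelope bound (default 0.30).
#' @param gauge_factor Gauge factor used for the strain envelope (default 1).
#' @return A data.frame with columns `C1`, `C2` (F), `f1`, `f2` (baseline
#'   resonances, Hz), `separation` (baseline `f2 - f1`, Hz),
#'   `worst_separation` (minimum over the strain envelope, Hz) and
#'   `retained` (logical). An empty retained set is reported, not an error.
#' @export
design_space_search <- function(L_subs,
                                C1_range = c(15e-12, 30e-12),
                                C2_range = c(10e-12, 25e-12),
                                step = 0.5e-12,
                                min_separation = 20e6,
                                max_strain = 0.30,
                                gauge_factor = 1) {
  stopifnot(length(L_subs) == 2L, all(L_subs > 0))
  if (any(C1_range <= 0) || any(C2_range <= 0)) {
    stop("capacitance ranges must be positive", call. = FALSE)
  }
  c1s <- seq(C1_range[1], C1_range[2], by = step)
  c2s <- seq(C2_range[1], C2_range[2], by = step)
  grid <- expand.grid(C1 = c1s, C2 = c2s, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[grid$C1 > grid$C2, , drop = FALSE]
  stretch <- 1 + gauge_factor * max_strain
  f1 <- resonance_frequency(L_subs[1], grid$C1)
  f2 <- resonance_frequency(L_subs[2], grid$C2)
  # f2 falls as sensor 2 stretches; f1 is highest at rest
  f2_min <- resonance_frequency(L_subs[2], grid$C2 * stretch)
  out <- data.frame(
    C1 = grid$C1, C2 = grid$C2, f1 = f1, f2 = f2,
    separation = f2 - f1,
    worst_separation = f2_min - f1
  )
  out$retained <- out$separation > min_separation &
    out$worst_separation > min_separation
  rownames(out) <- NULL
  out[order(out$C1, out$C2), ]
}

#' Shipped default sensing circuit
#'
#' A two-sensor reference design: reader loop of 40 mm outer diameter
#' (single-turn Wheeler limit, about 0.09 uH, 0.1 ohm), coupling
#' coefficient fixed at 0.35 (reader pressed against the textile coil),
#' and two sub-circuits with inductances representative of a tapped
#' three-turn textile coil including its connection leads
#' (`L1 = 1.28 uH`, `L2 = 0.45 uH`) so that the measured-baseline sensors
#' (22 pF kneecap, 17 pF glute) resonate near 30 and 58 MHz — separated by
#' more than 20 MHz across the full strain envelope.
#'
#' @param C1,C2 Sensor capacitances, farads (defaults 22 pF and 17 pF).
#' @param k Coupling coefficient (default 0.35).
#' @param L_subs Sub-inductances, henries (default `c(1.28e-6, 0.45e-6)`).
#' @param R_subs Sub-circuit series resistances, ohms
#'   (default `c(1.3, 1.0)`, spiral arc plus leads at 3.3 ohm/m).
#' @return A [circuit_spec()].
#' @export
default_circuit <- function(C1 = 22e-12, C2 = 17e-12, k = 0.35,
                            L_subs = c(1.28e-6, 0.45e-6),
                            R_subs = c(1.3, 1.0)) {
  l_reader <- .wheeler(1, 36e-3, 40e-3)   # single 40 mm loop, 1 mm trace
  subs <- list(
    sub_circuit(L_subs[1], R_subs[1], C1, mutual_inductance(k, l_reader, L_subs[1])),
    sub_circuit(L_subs[2], R_subs[2], C2, mutual_inductance(k, l_reader, L_subs[2]))
  )
  circuit_spec(reader_inductance = l_reader, reader_resistance = 0.1,
               sub_circuits = subs)
}

#' Default tracking grid (20-60 MHz at 200 kHz)
#'
#' The minimal sweep window containing both sensors' dips in rest and
#' stretched states, at the resolution used for resonance tracking.
#'
#' @return A [frequency_grid()].
#' @export
default_tracking_grid <- function() {
  frequency_grid(20e6, 60e6, "linear", 200e3)
}
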