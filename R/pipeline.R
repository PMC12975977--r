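# Processing chain for two-sensor resonance traces: zero-phase low-pass
# filtering, range-relative threshold phase labeling with two-sensor
# reconciliation, cycle accounting, overlapping-window feature extraction,
# and cycle-based partitioning.

.trace_fs <- function(trace) {
  fs <- attr(trace, "sampling_rate")
  if (is.null(fs)) fs <- 1 / diff(trace$time[1:2])
  fs
}

#' Zero-phase low-pass filter a resonance trace
#'
#' Applies a 4th-order Butterworth filter forward and backward (zero phase,
#' unit DC gain) to both sensor channels. Static recordings are typically
#' filtered at 1 Hz and dynamic recordings at 5 Hz.
#'
#' @param trace A `resonance_trace` data.frame (columns `f1_hz`, `f2_hz`).
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist rate.
#' @param order Filter order (default 4).
#' @return The trace with filtered `f1_hz`, `f2_hz`.
#' @export
lowpass <- function(trace, cutoff, order = 4) {
  fs <- .trace_fs(trace)
  cutoff <- parse_quantity(cutoff)
  if (cutoff >= fs / 2) {
    stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # demean and odd-reflect both ends so the filter's zero initial conditions
  # do not leak transients into the trace
  n <- nrow(trace)
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(3 * fs / cutoff)))
  for (col in c("f1_hz", "f2_hz")) {
    x <- trace[[col]]
    mu <- mean(x)
    x <- x - mu
    ext <- c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- as.numeric(signal::filtfilt(bf, ext))
    trace[[col]] <- y[(pad + 1L):(pad + n)] + mu
  }
  trace
}

#' Threshold labeler configuration
#'
#' Range-relative thresholds: samples with resonance at or above
#' `max(f) - stand_tolerance * range` are standing; samples at or below
#' `min(f) + activity_tolerance * range` are activity; everything between
#' is transition.
#'
#' @param stand_tolerance Fraction of the full range below the maximum
#'   accepted as standing (default 0.20).
#' @param activity_tolerance Fraction of the full range above the minimum
#'   accepted as activity (default 0.15).
#' @param min_range Minimum per-sensor frequency range (Hz) below which the
#'   trace is degenerate (default 0.1 MHz).
#' @return An object of class `labeler_config`.
#' @export
labeler_config <- function(stand_tolerance = 0.20, activity_tolerance = 0.15,
                           min_range = 1e5) {
  if (stand_tolerance <= 0 || stand_tolerance >= 0.5 ||
      activity_tolerance <= 0 || activity_tolerance >= 0.5) {
    stop("tolerances must lie strictly in (0, 0.5)", call. = FALSE)
  }
  .check_positive(min_range, "min_range")
  structure(list(stand_tolerance = stand_tolerance,
                 activity_tolerance = activity_tolerance,
                 min_range = min_range),
            class = "labeler_config")
}

#' Phase thresholds for one channel
#'
#' @param f Numeric vector of resonance frequencies (Hz).
#' @param cfg A [labeler_config()].
#' @return Named list with `stand` and `activity` thresholds (Hz).
#' @export
phase_thresholds <- function(f, cfg = labeler_config()) {
  rng <- max(f) - min(f)
  if (rng < cfg$min_range) {
    stop("degenerate trace: frequency range below min_range", call. = FALSE)
  }
  thr <- list(stand = max(f) - cfg$stand_tolerance * rng,
              activity = min(f) + cfg$activity_tolerance * rng)
  if (thr$stand <= thr$activity) {
    stop("labeler configuration error: stand and activity thresholds cross",
         call. = FALSE)
  }
  thr
}

.label_channel <- function(f, thr) {
  ifelse(f >= thr$stand, "stand",
         ifelse(f <= thr$activity, "activity", "transition"))
}

#' Label standing/activity/transition phases of a trace
#'
#' Each sensor channel is labelled independently with range-relative
#' thresholds, then the two labels are reconciled per timestamp: agreement
#' is kept; a definite label (stand or activity) on one sensor overrides a
#' transition on the other; a stand-versus-activity conflict is resolved
#' conservatively to transition. Detected cycles are the maximal runs of
#' the merged activity label; `det_cycle` carries, for every sample, the
#' index of the current or most recently completed detected cycle.
#'
#' @param trace A `resonance_trace` data.frame.
#' @param cfg A [labeler_config()].
#' @return The trace with added `assigned_phase` and `det_cycle` columns and
#'   a `"thresholds"` attribute.
#' @export
label_phases <- function(trace, cfg = labeler_config()) {
  thr1 <- phase_thresholds(trace$f1_hz, cfg)
  thr2 <- phase_thresholds(trace$f2_hz, cfg)
  lab1 <- .label_channel(trace$f1_hz, thr1)
  lab2 <- .label_channel(trace$f2_hz, thr2)
  merged <- ifelse(lab1 == lab2, lab1,
                   ifelse(lab1 == "transition", lab2,
                          ifelse(lab2 == "transition", lab1, "transition")))
  trace$assigned_phase <- factor(merged,
                                 levels = c("stand", "activity", "transition"))
  trace$det_cycle <- .cycles_from_labels(merged)
  attr(trace, "thresholds") <- list(sensor1 = thr1, sensor2 = thr2)
  attr(trace, "labeler_config") <- cfg
  trace
}

# cycle index per sample: activity runs numbered 1..K; other samples carry
# the most recent run index (0 before the first run)
.cycles_from_labels <- function(labels) {
  is_act <- labels == "activity"
  starts <- which(is_act & !c(FALSE, is_act[-length(is_act)]))
  run_id <- cumsum(seq_along(labels) %in% starts)
  as.integer(run_id)
}

#' Compare detected and expected cycle counts
#'
#' Real deployments occasionally lose cycles to noisy labeling; rather than
#' silently relabeling, this reports the mismatch and can optionally fall
#' back to the ground-truth phases (available for synthetic traces) when
#' the detected count is wrong, replacing a manual relabeling step.
#'
#' @param labeled A trace from [label_phases()].
#' @param expected Expected number of activity cycles.
#' @param fallback If `TRUE` and the count mismatches and `gt_phase` is
#'   present, relabel from ground truth.
#' @return A list with `detected`, `expected`, `flag` (logical mismatch),
#'   `used_fallback`, and `trace` (possibly relabeled).
#' @export
validate_cycles <- function(labeled, expected, fallback = FALSE) {
  detected <- max(labeled$det_cycle)
  flag <- detected != expected
  used_fallback <- FALSE
  if (flag && fallback && "gt_phase" %in% names(labeled)) {
    labeled$assigned_phase <- labeled$gt_phase
    labeled$det_cycle <- .cycles_from_labels(as.character(labeled$gt_phase))
    used_fallback <- TRUE
    detected <- max(labeled$det_cycle)
    flag <- detected != expected
  }
  list(detected = detected, expected = expected, flag = flag,
       used_fallback = used_fallback, trace = labeled)
}

#' Cut a labelled trace into overlapping windows
#'
#' Windows of `length` seconds advance with a stride of
#' `length * (1 - overlap_fraction)` (at least one sample). Each window
#' receives the majority assigned phase over its samples; windows whose
#' majority is transition are discarded. Activity windows are labelled with
#' the trace's activity name, standing windows with `"stand"`. The window's
#' cycle index is the detected cycle at its centre sample, which keeps
#' every window attached to a single cycle for splitting.
#'
#' @param labeled A trace from [label_phases()].
#' @param length Window length in seconds (>= 2 samples).
#' @param overlap_fraction Overlap between successive windows in `[0, 1)`
#'   (default 0.8).
#' @return A data.frame of window shells: `start`, `end` (sample indices),
#'   `start_s`, `end_s`, `label`, `cycle`, `session`, `activity`.
#' @export
make_windows <- function(labeled, length, overlap_fraction = 0.8) {
  fs <- .trace_fs(labeled)
  len <- round(length * fs)
  if (len < 2) stop("window must span at least 2 samples", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)", call. = FALSE)
  }
  n <- nrow(labeled)
  if (n < len) stop("trace shorter than one window", call. = FALSE)
  stride <- max(1L, round(len * (1 - overlap_fraction)))
  starts <- seq(1L, n - len + 1L, by = stride)
  phases <- as.character(labeled$assigned_phase)
  activity <- labeled$activity[1]
  session <- labeled$session[1] %||% 1L
  rows <- lapply(starts, function(s0) {
    idx <- s0:(s0 + len - 1L)
    counts <- c(stand = sum(phases[idx] == "stand"),
                activity = sum(phases[idx] == "activity"),
                transition = sum(phases[idx] == "transition"))
    maj <- names(counts)[which.max(counts)]
    if (maj == "transition") return(NULL)
    centre <- idx[ceiling(len / 2)]
    data.frame(start = s0, end = s0 + len - 1L,
               start_s = labeled$time[s0], end_s = labeled$time[s0 + len - 1L],
               label = if (maj == "stand") "stand" else activity,
               cycle = labeled$det_cycle[centre],
               session = session, activity = activity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      start_s = numeric(0), end_s = numeric(0),
                      label = character(0), cycle = integer(0),
                      session = integer(0), activity = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Eleven-feature vector for one two-sensor window
#'
#' Per sensor: mean, population standard deviation, RMS, range, and Shannon
#' entropy of a 10-equal-width-bin histogram of the window's values
#' (natural log; 0 for a constant window), plus the Pearson correlation
#' between the two sensors (0 when either channel is constant).
#'
#' @param x1,x2 Numeric vectors, the two sensors' samples in the window
#'   (same length, >= 2).
#' @return Named numeric vector of length 11.
#' @export
extract_features <- function(x1, x2) {
  stopifnot(length(x1) == length(x2), length(x1) >= 2)
  feats <- c(.channel_features(x1, "s1"), .channel_features(x2, "s2"))
  sd1 <- stats::sd(x1); sd2 <- stats::sd(x2)
  corr <- if (sd1 == 0 || sd2 == 0) 0 else stats::cor(x1, x2)
  c(feats, corr = corr)
}

.channel_features <- function(x, prefix) {
  n <- length(x)
  mu <- mean(x)
  sd_pop <- sqrt(sum((x - mu)^2) / n)
  rms <- sqrt(mean(x^2))
  rng <- max(x) - min(x)
  ent <- if (rng == 0) 0 else {
    counts <- tabulate(pmin(10L, 1L + floor(10 * (x - min(x)) / rng)), 10L)
    p <- counts[counts > 0] / n
    -sum(p * log(p))
  }
  stats::setNames(c(mu, sd_pop, rms, rng, ent),
                  paste0(prefix, "_", c("mean", "sd", "rms", "range", "entropy")))
}

#' Feature table for all windows of a labelled trace
#'
#' @param labeled A trace from [label_phases()].
#' @param windows Window shells from [make_windows()].
#' @return The window data.frame with the 11 feature columns appended.
#' @export
window_features <- function(labeled, windows) {
  if (nrow(windows) == 0L) return(windows)
  feats <- t(vapply(seq_len(nrow(windows)), function(i) {
    idx <- windows$start[i]:windows$end[i]
    extract_features(labeled$f1_hz[idx], labeled$f2_hz[idx])
  }, numeric(11)))
  cbind(windows, as.data.frame(feats))
}

.feature_names <- c("s1_mean", "s1_sd", "s1_rms", "s1_range", "s1_entropy",
                    "s2_mean", "s2_sd", "s2_rms", "s2_range", "s2_entropy",
                    "corr")

#' Fit a z-score feature scaler on training windows
#'
#' @param train A data.frame containing the 11 feature columns (the
#'   training partition only, to avoid leakage); needs >= 2 rows.
#' @return An object of class `feature_scaler` with per-feature centre and
#'   scale (scale 1 for zero-variance features).
#' @export
feature_scaler <- function(train) {
  stopifnot(nrow(train) >= 2)
  x <- as.matrix(train[, .feature_names, drop = FALSE])
  centre <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  structure(list(centre = centre, scale = scale), class = "feature_scaler")
}

#' Apply a fitted feature scaler
#'
#' @param scaler A [feature_scaler()].
#' @param df Data.frame with the 11 feature columns.
#' @return `df` with standardized feature columns.
#' @export
scale_features <- function(scaler, df) {
  stopifnot(inherits(scaler, "feature_scaler"))
  for (f in .feature_names) {
    df[[f]] <- (df[[f]] - scaler$centre[[f]]) / scaler$scale[[f]]
  }
  df
}

#' Assign windows to train/validation/test by whole cycles
#'
#' Within each (activity, session) trace, whole cycles are assigned
#' contiguously in temporal order: the earliest cycles to training, then
#' validation, then test, using floor allocation with at least one cycle
#' each for validation and test (10 cycles at 80-10-10 give 8/1/1;
#' 20 give 16/2/2). Windows preceding the first cycle (cycle 0) join the
#' training partition. No window ever straddles partitions because every
#' window carries a single cycle index.
#'
#' @param windows A window/feature data.frame (needs `activity`, `session`,
#'   `cycle`).
#' @param ratios Length-3 train/validation/test proportions summing to 1
#'   (default `c(0.8, 0.1, 0.1)`).
#' @return `windows` with a `partition` factor column, plus a `"split_plan"`
#'   attribute (data.frame of activity, session, cycle, partition).
#' @export
split_by_cycles <- function(windows, ratios = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  windows$partition <- NA_character_
  plan <- list()
  for (key in unique(paste(windows$activity, windows$session, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sel <- windows$activity == parts[1] & windows$session == as.integer(parts[2])
    cycles <- sort(unique(windows$cycle[sel & windows$cycle > 0]))
    n <- length(cycles)
    if (n < 3) {
      stop("need at least 3 cycles per activity and session to split",
           call. = FALSE)
    }
    alloc <- cycle_allocation(n, ratios)
    part_of <- stats::setNames(
      rep(c("train", "validation", "test"), alloc), NULL)
    cyc_part <- stats::setNames(part_of, cycles)
    windows$partition[sel] <- ifelse(
      windows$cycle[sel] == 0, "train", cyc_part[as.character(windows$cycle[sel])])
    plan[[key]] <- data.frame(activity = parts[1],
                              session = as.integer(parts[2]),
                              cycle = cycles,
                              partition = unname(cyc_part),
                              stringsAsFactors = FALSE)
  }
  windows$partition <- factor(windows$partition,
                              levels = c("train", "validation", "test"))
  attr(windows, "split_plan") <- do.call(rbind, c(plan, make.row.names = FALSE))
  windows
}

#' Cycle counts per partition under the floor-with-minimum-one rule
#'
#' @param n Number of cycles (>= 3).
#' @param ratios Train/validation/test proportions.
#' @return Integer vector `c(train, validation, test)` summing to `n`.
#' @export
cycle_allocation <- function(n, ratios = c(0.8, 0.1, 0.1)) {
  n_val <- max(1L, floor(n * ratios[2]))
  n_test <- max(1L, floor(n * ratios[3]))
  n_train <- n - n_val - n_test
  if (n_train < 1L) stop("too few cycles to split", call. = FALSE)
  c(train = n_train, validation = n_val, test = n_test)
}
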