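---
title: "Modelling and processing passive wireless multi-sensor textile recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and processing passive wireless multi-sensor textile recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearlc)
```

## The system being modelled

A garment carries several capacitive textile strain sensors, all wired to a
single embroidered spiral inductor. Each sensor taps its own contiguous run
of turns — a *sub-inductor* — so each sensor forms a series RLC loop that
resonates at `f = 1/(2π√(LC))`. An external reader loop, pressed against
the textile coil, is inductively coupled to every sub-inductor; each
sub-circuit appears as a dip in the reader's S11 reflection trace.
Stretching a sensor raises its plate capacitance (gauge factor ≈ 1) and
lowers its dip frequency, so sweeping the reader repeatedly turns the
garment into a passive, battery-free movement monitor.

`wearlc` models this chain end to end: closed-form design formulas, a
small-signal sweep simulator, a synthetic-recording generator, and the
processing/classification pipeline. Everything runs on synthetic data; no
instrument access is required.

## Circuit model and its assumptions

**Geometry.** For a circular planar spiral with outer diameter `d_out`,
`N` turns, trace width `w` and gap `s`, the inner diameter is
`d_in = d_out − 2(N+1)w − 2(N−1)s`, the fill factor
`p = (d_out − d_in)/(d_out + d_in)`, and the inductance follows the
modified simplified Wheeler formula
`L = ¼ μ₀ N² (d_in + d_out) ln(2.46/p + 0.20 p²)`. A tap segment starting
at turn `a` with `n` turns is treated as its own spiral with outer
diameter `d_out − 2(a−1)(w+s)`; mutual inductance *between* segments is
neglected, treating each sensor loop as a separable resonator. This
matches the design practice of tuning each sub-circuit independently
through `1/(2π√(LC))`, and numerically the segment inductances then
under-add relative to the whole coil (the mutual terms are the
difference).

**Coupling.** The reader link uses the coaxial-loop approximation
`k(d) = (1 + 2^{2/3}(d/√(r₁r₂))²)^{−3/2}` on the coils' effective radii
(arithmetic mean of inner and outer). This expression is exact in its two
limits (`k(0)=1`, `k→0`), but at millimetre separations between
40 mm coils it predicts `k ≈ 1`, much higher than the `k = 0.35` that a
physical reader-in-pocket arrangement actually achieves (losses,
misalignment and fabric spacing are not in the formula). Both routes are
therefore exposed: `coupling_coefficient()` computes the formula, and a
`coupling_override` carries a chosen/measured value. The shipped defaults
use the override `k = 0.35`.

**Network solve.** The sweep simulator is a mesh-current solver: loop 1 is
the reader (`R_R + jωL_R`), loops 2… are the sensor RLC branches, and
coupling enters as `jωM` off-diagonal terms; the solved reader-branch
impedance is placed in parallel with a 50 Ω load and reflected against the
50 Ω source, `S11 = (Z_in − Z₀)/(Z_in + Z₀)`. For one sensor this reduces
analytically to the reflected-impedance form
`Z_R + (ωM)²/Z_sub`, which the test suite uses as an independent oracle
(agreement to better than 1e−9 relative). Requiring `R_sub > 0` keeps
every branch non-singular on the grid.

**Default design.** The shipped two-sensor circuit uses sub-inductances
`L₁ = 1.28 µH` and `L₂ = 0.45 µH` — representative of a tapped three-turn
textile coil *including its connection leads*, which add substantially to
the bare Wheeler segment values (0.13 µH and 0.10 µH for naked turns 1 and
3) — with measured-style sensor baselines of 22 pF (kneecap) and 17 pF
(glute). That places the rest resonances near 30.0 and 57.5 MHz inside the
20–60 MHz tracking window and keeps them more than 20 MHz apart over the
whole 0–30% strain envelope. Lead inductance is also available as an
additive `lead_inductance` term on `spiral_inductor()` (default 0).

## Sweep grids and dip detection

Linear grids use the interval-count convention `n = span/resolution`
(20–60 MHz at 200 kHz → 200 points, starting at `f_start`); log grids
place a fixed number of points per decade (the design-stage default is
10–100 MHz at 200/decade). Dips are local minima of `|S11|` in dB with
prominence ≥ 1 dB, refined by three-point parabolic interpolation and
clamped to one grid step; explicit per-sensor frequency bands, when
given, take precedence (in-band global minimum). If fewer dips than
sensors survive the prominence rule the detector raises a *peak lost*
error rather than splitting a merged dip — modelling what a real reader
misalignment looks like downstream.

## The capacitor design-space search

`design_space_search()` enumerates `(C1, C2)` pairs (0.5 pF steps,
`C1 > C2` only, defaults C1 ∈ [15, 30] pF, C2 ∈ [10, 25] pF) and predicts
both resonances per pair. A pair is retained only if `f2 − f1` exceeds the
separation threshold both at rest **and** in the worst corner of the
strain envelope (upper-resonance sensor stretched 30%, lower one at
rest), because release-phase frequency elevation must never let the dips
collide. The shipped threshold is 20 MHz — the conservative rule that
keeps clearly distinguishable peaks on real, broader-than-simulated dips —
while 1 MHz is the bare distinguishability floor; the threshold is a
plain argument, not hard-coded.

## What the synthetic generator emulates

Protocols follow the bench protocol of this class of system: recordings at
70 Hz; static activities as 4 s hold / 4 s stand cycles with 0.5 s linear
ramps, 10 cycles, starting and ending standing; dynamic activities as
continuous raised-cosine cycles (2 s default period) and gait as 20 steps
at 1.0 s (walk) or 0.6 s (jog).

Artifacts, applied on capacitance before rendering:

* **Phase-dependent noise** — Gaussian, SD 0.33 MHz-equivalent in
  standing phases and 0.15 MHz-equivalent in activity phases (standing is
  noisier: the unloaded fabric sags and readjusts). The MHz values are
  converted per sensor via `sd_C/C = 2·sd_f/f` at its baseline resonance;
  0.33 MHz anchors the order of magnitude of observed cycle-to-cycle
  variability for this class of sensor.
* **Hysteresis** — a capacitance *deficit* that accumulates in proportion
  (default 0.15) to the capacitance being released and relaxes with a 3 s
  time constant, so at matched strain the release phase sits below the
  stretch phase, and standing baselines recover within a few seconds.
* **Baseline drift** — 0.1% of baseline capacitance lost per completed
  cycle (fabric relaxation).
* **Session effects** — per (session, sensor) draws: baseline shift
  (SD 5%) and amplitude scaling (SD 15%), held constant within a session,
  emulating donning/doffing between days.

Per-activity peak strain pairs (kneecap, glute) are generator *fixtures*,
not measurements: no quantitative per-activity strain table exists for
this setup, so the defaults (see `activity_amplitudes()`) were chosen once
to respect the qualitative ordering the garment geometry implies (deep
squat largest on both sensors; foot-to-glute mostly kneecap; hip
flexion/abduction mostly glute; shallow gait strains) and to keep every
pair of activities at least three standing-noise standard deviations
apart in strain-equivalent units. Consequences for interpretation: the
benchmark shows that *under those separations* the pipeline recovers the
labels almost perfectly; it does not certify real-garment accuracy, where
amplitudes may overlap, strains drift with fit, and movements vary
cycle-to-cycle in ways the generator does not model (no biomechanics, no
garment-fit simulation, no inter-participant variability).

Every random stream is keyed by `(seed, session, activity, sensor,
component)` through a rolling-hash child seed, so datasets are
bit-reproducible and adding an activity never perturbs another trace's
noise.

Rendering is closed-form (`fast`, the default) or through per-sample S11
sweeps plus dip detection (`full`); at the default coupling the two agree
within one 200 kHz grid step, which is also a regression test.

## Processing pipeline choices

* **Filtering.** 4th-order Butterworth, applied forward–backward for zero
  phase (1 Hz cutoff for static, 5 Hz for dynamic recordings). The input
  is demeaned and odd-reflected at both ends before `filtfilt` so the
  filter's zero initial conditions cannot leak multi-MHz transients into
  a ~30 MHz-offset signal; padding length is `3·fs/cutoff` samples.
* **Labeling.** Per sensor, `f ≥ max f − 0.20·range` is standing and
  `f ≤ min f + 0.15·range` is activity (the standing tolerance is wider
  because standing is noisier); everything between is transition. The
  two sensors are then reconciled per timestamp: a definite label
  overrides a transition; a stand-versus-activity conflict — a case the
  single-sensor rules do not define — resolves conservatively to
  transition. Detected cycles are maximal runs of the merged activity
  label. Traces whose per-sensor range falls below `min_range`
  (default 0.1 MHz) are rejected as degenerate rather than labelled from
  noise.
* **Cycle validation.** When the detected cycle count disagrees with the
  protocol, `validate_cycles()` flags the trace and can relabel it from
  the generator's ground truth — the software stand-in for the manual
  relabeling a human operator performs on real recordings when a cycle is
  lost (in the shipped benchmark this typically triggers for the
  lowest-amplitude activities and gait).
* **Windows and features.** 1 s (static) or 0.2 s (dynamic) windows at
  80% overlap; each window takes the majority phase and is discarded if
  that majority is transition; the window's cycle is the detected cycle
  at its centre sample, so no window straddles partitions. Features per
  sensor: mean, population SD, RMS, range, and Shannon entropy of a
  10-equal-width-bin histogram of the window's values (natural log,
  0 for constant windows — entropy has no canonical definition for short
  real-valued windows, so the simplest reproducible binning was fixed);
  plus the Pearson correlation between the sensors (0 if either is
  constant): 11 features for two sensors.
* **Splits.** Whole cycles, contiguous in time, earliest to training:
  floor allocation with at least one cycle each for validation and test
  (10 → 8/1/1, 20 → 16/2/2). Pre-first-cycle standing windows join
  training. Temporal-order assignment was fixed for reproducibility;
  random cycle assignment is the obvious alternative and would leak
  nothing either.
* **Classifiers.** KNN, multinomial logistic regression, SVM (RBF),
  decision tree, random forest and gradient-boosted trees, each tuned by
  4-fold stratified cross-validation over the pooled train+validation
  windows on small conventional grids (see `default_grids()`), then
  refitted and scored once on the test cycles. Feature standardization
  uses training-partition statistics only. The boosted trees use the
  exact greedy splitter: on small, widely separated tabular classes the
  histogram splitter can place a boundary at the edge of a training
  cluster and misclassify marginal test points with high confidence.
  Standing is kept as its own class by default
  (`include_stand_class = FALSE` drops it); accuracy and weighted F1 are
  both reported since threshold labeling makes class sizes uneven.
* **Multi-session evaluation.** The default pools all sessions and
  re-applies the per-trace cycle split, so every session contributes to
  every partition; this is one reasonable reading of a multi-session
  protocol, not a claim about any particular one. A leave-one-session-out
  comparison can be run by filtering the window table on `session` before
  `train_and_evaluate()`.

## Problem sizes and runtime

The shipped benchmarks generate 7 static traces (≈ 6 600 samples each)
or 9 dynamic traces (≈ 1 400–2 800 samples each) per session at 70 Hz,
yielding roughly 2 800–3 000 feature windows per benchmark; the full
bank with tuning evaluates in well under a minute per benchmark on one
CPU. These sizes mirror a realistic single-participant protocol (10
cycles per activity, 20 gait steps) rather than being scaled down.

## Known limitations

* The circuit model has no inter-segment mutual inductance, no
  frequency-dependent (skin-effect) resistance, and no self-resonance
  beyond a lumped parasitic capacitance; it reproduces dip positions and
  independence well, not absolute dip depths of a physical bench.
* The coupling formula and a pocket-mounted reader disagree at millimetre
  distances; defaults rely on the override value.
* The generator's strain amplitudes are declared fixtures; benchmark
  scores quantify pipeline correctness under stated separations, not
  field performance.
* Labeling is range-relative per trace, so a recording containing no
  activity at all is (deliberately) rejected as degenerate rather than
  labelled all-standing.
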