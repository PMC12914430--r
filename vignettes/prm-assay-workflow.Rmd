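---
title: "Building and validating multiplex PRM assays with prmflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating multiplex PRM assays with prmflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prmflow)
```

## The problem

A targeted PRM assay trades breadth for precision: each precursor in the
target list receives a scheduled acquisition window around its expected
retention time, and the instrument cycles through whichever windows are
open. Multiplexing is limited by a hard identity,

$$\text{cycle time} = \frac{\text{expected peak width}}{\text{points per peak}},$$

because a quantifiable chromatographic peak needs a minimum number of
samples (six is the working standard), and every concurrent target
consumes one scan per cycle. On a linear ion trap scanning 200–1500 Th at
125 kTh/s with a 15 ms injection floor, one scan takes roughly 27 ms, so a
2.15 s cycle (12.9 s peaks, six points) supports at most ~78 concurrent
targets. Everything in this package exists to push as many precursors as
possible through that bottleneck without losing them to retention-time
drift or to poor chromatography.

`prmflow` covers the full chain: library bookkeeping and peptide
uniqueness, precursor refinement, cycle-time-constrained scheduling,
an emulation of adaptive real-time alignment, matrix-matched calibration
figures of merit, and downstream differential abundance. A synthetic
chromatogram generator with complete ground truth makes each stage
testable in isolation and end to end.

## The synthetic generator

`simulate_library()` draws, per precursor, an elution apex, a base width,
a tail factor, an apex intensity, and 4–8 transitions with shared shape
and distinct fragment m/z. Peaks are exponentially modified Gaussians: the
Gaussian core width and exponential tail give realistic asymmetry while
keeping a closed-form trace to sample on the acquisition grid. Two
conventions matter and are fixed deliberately:

* **Base width** is the span at 1% of apex height — the same definition
  the peak detector measures as its integration-boundary width — and the
  generator rescales the EMG time axis so the realized 1% span equals the
  drawn width exactly. Defaults of 8–20 s give the ~14 s average of a
  30-min gradient on this instrument class.
* **Ground-truth area** is the trapezoidal area inside that 1% base, not
  the full analytic tail, again to match what boundary-limited integration
  can see.

Interfered transitions receive an added contaminant peak at 0.3–0.6 base
widths offset with 1–2× comparable intensity: close enough to
co-integrate with the peak (a farther contaminant resolves into a separate
peak that boundary detection simply excludes), far enough to decorrelate
the trace shape. Point noise is multiplicative with a configurable CV, and
an optional additive baseline floor.

What the generator does **not** emulate: isotope envelopes, charge-state
cross-talk at MS1, detector saturation, or correlated (batch-like) noise
across runs. Tests passing on this generator therefore demonstrate the
logic of the workflow, not instrument-level performance.

## Peak detection and refinement

`detect_peak()` smooths the summed transition trace with a 3-point moving
average, takes local maxima at ≥10% of the global maximum as apex
candidates, and picks the candidate nearest the library retention time
(ties go to the taller one). Choosing by proximity rather than by global
maximum is intentional: a library entry's identification anchors its
retention time, and a taller unrelated peak elsewhere in the window is
exactly the situation a targeted assay must not follow. Boundaries walk
outward on the smoothed trace until it drops below 1% of the apex (or a
local minimum below 10%), and the final boundary is interpolated at the 1%
crossing of the *raw* sum — smoothing alone would inflate the measured
width by about one grid step per side. Area is the raw-sum trapezoid
between boundaries; on a 2.15 s grid, narrow peaks carry a discretization
error of a few percent, which the tests account for.

"Interference-free" is operationalized as two conditions: the transition's
Pearson correlation against the median transition profile inside the
boundaries must reach the coelution threshold (default 0.9), and no other
library precursor within the isolation width (default 1 Th) may place a
fragment within the fragment tolerance (default 0.7 Th, unit-resolution
trap) while its peak overlaps. Acceptance requires area, width, and
interference-free transition count thresholds simultaneously; rejection
reports name the *first* failing criterion in the fixed order area, width,
transitions, so reports are deterministic.

## Scheduling

Windows start at `max(min_window, 2 * rt_uncertainty + peak width)`
centered on the library retention time. If the concurrency profile (checked
on a 0.01-min grid) exceeds the cycle capacity anywhere, the widest window
covering the worst time is trimmed symmetrically — never below the floor,
and always still containing the retention time. The trim-to-capacity
scheme is this package's own defined stand-in for proprietary window
optimizers; it is simple, monotone, and independently checkable by the
interval-stabbing oracle in the test suite. Targets that cannot fit even
at the window floor go to an overflow set, and `split_injections()`
assigns all targets greedily, in retention-time order, to the lowest
injection whose concurrency stays within capacity. Greedy first-fit is not
optimal, but on exhaustively enumerable instances (≤12 targets) it stays
within one injection of the optimum, which the suite asserts.

The per-scan model adds a 2 ms inter-scan overhead by default; dynamic
(AGC-driven) injection times are modeled at the configured minimum, a
worst-case-optimistic choice — real AGC behavior is out of scope.

## Adaptive alignment, emulated

The reference is a wide-window DIA acquisition compressed to a time × m/z
grid (default 0.05-min bins × twelve 50-Th windows over 400–1000), each
time slice normalized to unit sum so the map is intensity-scale-free; it
serializes to a versioned JSON container. During an emulated run the clock
advances in cycle-time steps; five times per peak width the recent scans
(1 min lookback) are binned the same way and compared against the
reference over a grid of candidate shifts, with cosine similarity over the
flattened window. Three choices keep the estimator honest:

* **Lock-on vs tracking.** The first estimate searches ±1.5 min; once
  locked, updates search only ±0.25 min around the prior. Drift is slow
  relative to the 2.6 s update cadence, and a permanently wide search
  invites spurious matches in sparse gradient regions.
* **Confidence gate.** Estimates whose best cosine similarity falls below
  0.5 are discarded (prior kept, no anchor laid). Without it, stretches of
  near-empty signal let the estimate random-walk away.
* **Causality.** An update at clock time *t* sees only events acquired
  before *t*; anchors are therefore monotone in run time, which the tests
  assert.

Anchors feed an isotonic regression (run time as a non-decreasing function
of estimated reference time) joined piecewise-linearly; the end segments
are padded with the whole-span slope because grid-quantized neighboring
anchors make literal two-point end slopes degenerate (flat or wildly
steep), which would collapse upcoming windows under extrapolation. Target
windows are re-mapped through the current warp each cycle.

Coverage is defined as collecting at least `points_per_peak` acquisitions
inside the true (warped) peak base. That definition has a sampling
precondition — a peak narrower than `points_per_peak × cycle_time`
(12.9 s at the defaults) can never be covered — so the alignment
simulations use 15–22 s peaks, wide enough that six points remain
attainable even under the ~0.92× local time compression of the piecewise
warps exercised. Targets are also restricted to precursors eluting at
least 1.5 min after the first library peptide: alignment needs some signal
before the first scheduled window opens, and in real matrices the earliest
eluters play exactly that anchor role.

## Calibration figures of merit

Matrix-matched curves dilute the analyte matrix into a matched background
(human into chicken, in the motivating application); peptides whose
sequences exist in both species are removed beforehand
(`shared_peptides`). For each precursor the summed transition area versus
dilution fraction is fit with a two-segment model — a flat noise level
below a changepoint and a straight line above it — by exhaustive least
squares over the measured fractions, ties to the lower changepoint. LOD is
the changepoint fraction, snapped to measured fractions because reported
LOQ distributions are quoted at dilution-series points. LOQ is the
smallest measured fraction at or above the LOD whose bootstrap CV
(replicates resampled within each point, 100 draws, model refit per draw)
of the fitted prediction stays at or below 20%.

Two deliberate additions to that rule:

* **Quantifiability gate.** A fraction-independent (fully
  background-dominated) response satisfies the changepoint fit trivially —
  a zero-slope line fits it as well as a flat noise model, and the
  tie-break would report the lowest fraction. The fit therefore requires a
  positive linear-segment slope *and* a fitted response at the 100% point
  at least 1.5× the fitted noise level; otherwise the curve is flagged
  not quantifiable with LOD = LOQ = 1.
* **Background models.** The calibration generator's default expectation
  is `f·A + B + floor` (additive background). That curve is globally
  linear in `f`, so a changepoint is structurally unidentifiable on it —
  any LOD estimator would be fitting noise. The `background_model =
  "floor"` option (`max(f·A, B) + floor`) emulates detection-limited
  integration, where below the crossover the integrated signal is matrix
  background only; the LOD-recovery studies use it with `B/A = 0.05`, and
  recovery is assessed against the known crossover.

Transition optimization is greedy backward elimination: drop the
transition whose removal most lowers the LOQ (ties drop the lower-area
transition), never below three transitions, stopping when no removal
helps; the final LOQ can therefore never exceed the full-set LOQ. The
bootstrap seed is derived from the peptide identity, so per-peptide
results are reproducible regardless of processing order. An alternative
LOQ definition via prediction-interval crossing exists in the literature;
the bootstrap-CV rule is the one implemented here.

## Downstream statistics

Differential abundance uses Welch's t-test on `log2(area + pseudocount)`
with a pseudocount of half the smallest nonzero value, and
Benjamini–Hochberg control at 0.05 across all tested precursors;
precursors constant in both groups receive p = 1 by convention. The test
statistic is configurable in principle but Welch-on-log2 is the field
default and the one validated in the suite (spike recovery with
sensitivity ≥ 0.9 and empirical FDR ≤ 0.1). TIC normalization equalizes
column sums while preserving the overall magnitude; note that normalizing
a matrix with a one-sided spike-in introduces a small compositional bias
in the unspiked precursors, which is why the spike-recovery studies test
the unnormalized path. Allele frequencies are
`100 · k / (2n)` rounded to 0.1.

## Numerical conventions and problem sizes

* Concurrency checks and window trims use a 0.01-min grid; shift search
  uses the reference time-bin (0.05 min).
* CV thresholds are strict (`<`); the curve-performance ratio tolerance is
  inclusive (`≤`); the LOQ bootstrap-CV ceiling is inclusive.
* All generators, the bootstrap, and the pipeline commands are
  deterministic under a fixed seed; pipeline outputs embed the seed and a
  hash of the scientific configuration, and reruns are byte-identical.
* The validation studies in the test suite and acceptance script use
  libraries of 200 precursors, 30-min gradients, triplicate 9-point
  dilution series, and 1000-precursor / 10-vs-10 spike matrices — sizes
  chosen so each study exercises the estimators well away from their
  small-sample edges while remaining comfortable on a laptop.

## Known limitations

* The alignment emulation validates the algorithm, not on-instrument
  timing; the vendor binary reference format is replaced by a documented
  JSON container.
* Window trimming is symmetric; trimming asymmetrically toward sparse
  regions could in principle retain more width at equal capacity.
* The refinement area criterion applies to the summed transition trace;
  whether a per-best-transition variant is preferable is left as a
  sensitivity question.
* Search scores carried by library files are parsed and preserved but do
  not influence scheduling priority.
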