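---
title: "Detecting atrial fibrillation from inter-beat intervals with the Lorenz plot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation from inter-beat intervals with the Lorenz plot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmonitor)
```

## The problem

Atrial fibrillation (AF) is the most common sustained cardiac arrhythmia:
the atria stop contracting in a coordinated way and the ventricles respond
irregularly, so the time between successive heart beats — the RR interval —
loses its short-range structure. AF episodes are often transient and
asymptomatic, which is why long-term ambulatory monitoring matters, and why
a detector that needs only the *sequence of inter-beat intervals* (a few
hundred bytes per 2-minute window) rather than the raw ECG is attractive
for wearable, battery-powered devices: the wearable measures beats, and a
remote service classifies the compressed interval stream.

`afmonitor` implements that cloud-side detector together with everything
needed to exercise it end to end without any external data: a software
model of the wearable front end (band-pass conditioning plus Pan-Tompkins
R-peak detection), a seeded synthetic rhythm generator, the interval packet
codec, and a windowed evaluation harness.

## The detector

The detector operates on non-overlapping 2-minute windows of RR intervals.
Within a window it forms the successive differences

$$\delta RR(i) = RR(i) - RR(i-1)$$

and scatter-plots each pair $(\delta RR(i), \delta RR(i-1))$ — the Lorenz
(Poincaré) plot of the differenced tachogram. Under normal sinus rhythm
(NSR) the beat-to-beat variability is small and serially correlated, so the
points pile up near the origin. Under AF the ventricular response is
irregular and serially uncorrelated, so points spread sparsely over the
whole plane. Premature atrial contractions (PACs) form a third, structured
pattern: a short coupling interval followed by a compensatory pause puts
repeated points into specific off-origin lobes.

The plane is quantized into a 31×31 grid of 40 ms bins spanning roughly
±600 ms, and the grid is segmented into 13 regions: region 0 is the square
of bins whose centers lie within 80 ms of the origin (the spread of normal
sinus variability), regions 1–12 tile the rest. From the per-region counts
— `BinCount` (number of distinct populated bins) and `PointCount` (number
of points) — three integer indices are computed:

* **IrregularityEvidence** $= \sum_{n=1}^{12} \mathrm{BinCount}_n$: how many
  distinct off-origin bins are populated; a sparsity measure, high in AF.
* **PACEvidence** $= \sum_{n \in \{1..4,5,6,10\}} (\mathrm{PointCount}_n -
  \mathrm{BinCount}_n) - \sum_{n \in \{7,8,12\}} (\mathrm{PointCount}_n -
  \mathrm{BinCount}_n)$: points stacking repeatedly in the same bins of the
  PAC-typical regions, evidence of compensatory-pause structure rather than
  fibrillation.
* **AFEvidence** $= \mathrm{IrregularityEvidence} - \mathrm{OriginCount} -
  2\times\mathrm{PACEvidence}$, where OriginCount is the number of points
  in region 0.

A window is called **AF** when AFEvidence reaches a fixed threshold of 50,
**NSR** otherwise. All of this is exact integer arithmetic — there is no
floating point anywhere in the decision path, so results are
bit-reproducible across platforms.

```{r}
af <- gen_af_rr(mean_rr_ms = 800, spread_ms = 400, duration_s = 120, seed = 1)
classify_window(af)
nsr <- gen_nsr_rr(mean_rr_ms = 800, sdnn_ms = 30, duration_s = 120, seed = 1)
classify_window(nsr)
```

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `window_s` | 120 s | analysis window; windows tile the record from $t=0$ |
| `bin_width_ms` | 40 ms | Lorenz grid resolution (31 bins per axis, centers at multiples of 40 ms, domain $[-620, 620)$ ms) |
| `origin_radius_ms` | 80 ms | Chebyshev radius of region 0 |
| `af_threshold` | 50 | AF is declared when AFEvidence $\ge$ 50 |
| `min_intervals` | 4 | windows with fewer intervals are `undetermined` and excluded from scoring |

Decisions that the published description of the algorithm leaves open, and
how this package resolves them:

* **Window alignment.** Windows are clock-aligned to the record start
  (0, 120, 240, … s), non-overlapping, and δRR pairs never straddle a
  window boundary: each window is classified from its own intervals only.
  This mirrors a device that batches and transmits each 2-minute window
  independently.
* **Out-of-range pairs** (|δRR| beyond the grid) are *saturated* into the
  edge bins rather than dropped, so the total point count of a window is
  always the number of pairs formed — conservation that the tests rely on.
* **Region geometry.** Only region 0 has a printed, quantitative
  definition (the 80 ms radius). The built-in mask for regions 1–12 uses
  quadrant blocks and axis corridors split at 340 ms into near/far halves —
  a documented reconstruction. Because the exact published segment drawing
  is only available graphically, the mask is a *loadable data resource*
  (`load_segment_mask()`, a plain-text 31×31 grid): an alternative geometry
  can be swapped in without touching the algorithm, and
  `validate_segment_mask()` enforces the invariants any mask must satisfy
  (shape, label range, full coverage, the 80 ms region-0 rule).
* **Tie at the threshold.** AFEvidence exactly 50 is classified AF
  (`>=`); the comparison direction is exposed via `af_threshold` in
  `detector_config()`.
* **OriginCount** counts all points of region 0 (the full 80 ms square),
  reconciling the "bin containing the origin" phrasing with the region-0
  radius.

## The front end

The wearable side is emulated in software: `condition_ecg()` applies the
front end's 0.5–40 Hz band limit (zero-phase Butterworth: 2nd-order
high-pass, 5th-order low-pass; the forward–backward pass squares the
magnitude response, putting 50 Hz mains interference more than 20 dB down),
and `detect_rpeaks()` runs a Pan-Tompkins chain — five-point derivative,
squaring, 96 ms moving-window integration, dual adaptive thresholds with a
200 ms refractory period and search-back at 1.66× the running mean RR.
Zero-phase filtering is used even though a real device filters causally:
only beat *times* matter downstream, and a fixed group delay cancels in the
RR differences anyway. The classic threshold-adaptation constants are kept
(0.125/0.875 running mixes); they are recorded in `frontend_config()`.

On clean synthetic ECG the chain recovers beat times to within two samples
at 250 sps across 40–180 bpm. Equivalence with any particular commercial
R-to-R chip is not claimed — those state machines are proprietary — only
with the published Pan-Tompkins recipe.

## The synthetic generator

The generator is the package's stand-in for a patient simulator: it
produces RR streams, matching ground-truth annotations, and (optionally)
rendered ECG, all deterministic under a fixed seed.

* **NSR**: a stationary Gaussian AR(1) process (defaults mean 800 ms, SDNN
  30 ms, lag-1 correlation 0.9). With SDNN ≤ 30 ms the successive
  differences concentrate well inside the 80 ms origin region. These
  defaults sit in the middle of textbook short-term heart-rate-variability
  ranges for resting adults.
* **AF**: serially uncorrelated RR drawn uniformly on mean ± spread
  (defaults 800 ± 400 ms). The published description does not specify an AF
  interval model; an uncorrelated uniform stream maximizes Lorenz scatter
  sparsity, which is the qualitative signature the detector keys on.
* **PAC**: `insert_pac()` shortens one interval by a prematurity factor
  `c` and stretches the next to `(2 − c)` times the original — a full
  compensatory pause that preserves the local two-beat time.
* All intervals are clipped to a physiological 300–2000 ms, which keeps
  δRR mostly inside the ±620 ms grid while still exercising edge-bin
  saturation occasionally.
* **ECG**: Gaussian-kernel P-QRS-T complexes at the scheduled beat times
  (P omitted during AF), plus optional white noise. P and T waves are
  placed as fractions of the local RR so complexes stay separated at high
  heart rates.

What the generator does *not* emulate: fibrillatory f-waves, ectopic
morphology, motion artifacts, electrode noise, or drifting baselines. A
detector that separates these synthetic rhythms perfectly has demonstrated
the algorithm's mechanics — histogram, segmentation, indices, threshold —
not clinical performance. Real-data behavior additionally depends on the
exact region geometry of the published mask and on beat-detection quality
under noise, which is why whole-database results are reproduced through
the `evaluate` path on a user-supplied copy of the public AF database
rather than asserted from synthetic data (see the README).

## Evaluation protocol

Scoring is window-level: each 2-minute window's truth is **AF** when AFIB
annotation tracts overlap at least half of it (the overlap fraction is
configurable; annotations leave no other workable interpretation of
window-level scoring), `OTHER` rhythms count as non-AF, and undetermined
windows are excluded. From the pooled confusion counts,

$$\mathrm{accuracy} = \frac{TP+TN}{TP+TN+FP+FN},\qquad
\mathrm{sensitivity} = \frac{TP}{TP+FN},\qquad
\mathrm{specificity} = \frac{TN}{TN+FP},$$

with zero-denominator cases reported as undefined and printed `//`. The
pooled row sums confusion counts across records rather than averaging
per-record metrics; the per-record rows are reported alongside, in the
conventional per-patient table layout. The roster helper `afdb_roster()`
carries the public database's 23 record names and drops the one record
whose AF is atypically regular (07859) by default — a configuration entry,
not a hard-coded rule.

## Numerical and degenerate-input choices

* Binning is `round(δ/40)` with indices clamped to the grid — integer
  throughout.
* Windows with fewer than 4 intervals (fewer than 2 Lorenz points) are
  `undetermined`, never an error; `build_histogram()` refuses fewer than
  two δ values with an "insufficient data" signal that the classifier
  converts into that verdict.
* An empty record yields zero windows and zero packets, not an error.
* Packet encoding rounds to integer milliseconds into unsigned 16-bit
  little-endian — covering RR up to 65.5 s — and decoding inverts it
  exactly; the byte order and rounding are this package's documented
  dialect, since only the 2-bytes-per-interval size is externally fixed.
* The first beat a detector emits has no preceding R peak; its interval is
  back-filled with the first measured RR so no detected beat is lost.

## Problem sizes in the test suite

The shipped tests run the oracle-equivalence check on 1000 random windows
against an independent nested-loop reference, the separation check on 200
NSR and 200 AF seeded windows, and the beat-detector sweep at five rates
between 40 and 180 bpm with 60 s of ECG each; the whole suite completes in
well under a minute on a single core.

## Known limitations

* The exact published drawing of regions 1–12 could not be transcribed
  from text; the built-in mask is a faithful-by-construction reconstruction
  and replaceable as data. Whole-database metrics depend on it.
* Only AF versus non-AF is decided; atrial tachycardia, group beating and
  ventricular ectopy patterns, though visible in the same plot, are out of
  scope, as is any P-wave/morphology analysis.
* The WFDB codec covers headers, format 212/16 signals, and rhythm-change
  annotations — the subset this pipeline needs — not the full format
  family.
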