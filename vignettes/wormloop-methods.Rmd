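---
title: "Methods: quantifying exploratory locomotion with wormloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying exploratory locomotion with wormloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormloop)
```

wormloop quantifies the exploratory crawling behaviour of *C. elegans*
from centroid tracks recorded by a multi-worm tracker (nominally one
frame per second, coordinates in mm), together with head-landmark series
(every 0.5 s) and photobleach-and-recovery fluorescence records. This
vignette explains the estimators, the choices behind their numerical
details, what the synthetic-data generators do and do not emulate, and
the limits of what the test suite can establish about real data.

## Trajectory preprocessing

A trajectory is a time-ordered table of `(animal_id, t_s, x_mm, y_mm)`
with two pieces of metadata: `ventral_is_left`, a tri-state flag saying
whether the animal's ventral side lies to the left of its heading
(worms crawl on their lateral side, so this is constant within a
track), and `excluded`, set by `flag_crossings()` when two animals'
centroids approach within one body width (default 1 mm — the threshold
is an analysis choice, configurable, since centroid tracking is
unreliable through contacts and both partners are discarded).
Timestamps must be strictly increasing; duplicated frames keep the
first observation rather than aborting, because tracker glitches should
not invalidate a 20-minute recording. Sampling-interval drift is
reported but tolerated.

Fixed-distance analyses use `truncate_by_path_length()`: the track is
cut at the arc length where its cumulative chord length reaches L₀,
with the final point linearly interpolated along the last segment.
Interpolation on the polyline (rather than snapping to the nearest
sample) makes the truncated length exact and the operation idempotent.

## Curving rate

The curving rate is the change in direction of locomotion per unit
length of advancement, in deg/mm. Headings are directions of
displacements between consecutive *retained* samples: steps shorter
than `min_step_mm` (default 0.05 mm) are merged into their successors
first, because at 1 s sampling a nearly stationary animal produces
sub-pixel displacements whose headings are dominated by localisation
jitter. The rate at an interior sample is the wrapped heading
difference divided by the mean of the two adjacent step lengths — a
centred estimate; the divisor convention is recorded in the output so
downstream consumers know which was used.

Angular differences are wrapped to (−180°, 180°] with the tie at an
exact reversal broken toward +180°, so repeated analyses of the same
degenerate geometry are deterministic. Sign convention: mathematically,
counter-clockwise turns are positive; when the ventral side is known
the sign is flipped (if needed) so that ventral-ward curves are
positive, and the output records `ventral_positive` versus
`ccw_positive` so unsigned-biology data are never silently
misinterpreted.

Two summaries mirror the two standard presentations: a
path-length-weighted mean over a fixed time window (default 1200 s,
anchored at the track's first sample) and over a fixed initial distance
(default 30 mm). Weighting by step length, not by sample, keeps the
estimate per unit of advancement when speed varies. Histograms pool
path-length weights into half-open bins aligned so that zero is a bin
edge, which keeps ventral and dorsal mass strictly separated; the bin
width has no canonical default and is user-set.

## Coarse-grained path statistics

For step size δ the coarse-grained trajectory connects dividing points
placed every δ of arc length along the first L₀ = 30 mm of track; its
length L_δ is the summed chord length and L_δ/L₀ is dimensionless.
Because trajectory length, not elapsed time, parameterises the
division, animals of different speeds are comparable. Numerical
choices:

* The final partial sub-trajectory (arc length < δ when δ does not
  divide L₀) contributes one closing chord to the point at arc L₀, so
  L_δ always spans the full analysed length; dropping the remainder
  would make L_δ discontinuous in δ.
* Dividing points are interpolated on the polyline, never snapped to
  samples.
* The default δ grid is 10 points logarithmically spaced from 0.5 to
  30 mm, matching the log–log presentation of the ratio curves; it is
  an analysis choice, not canonical, and any strictly increasing grid
  in (0, L₀] is accepted.
* Cohort summaries report the per-δ median of log₁₀(L_δ/L₀) with first
  and third quartiles by linear interpolation (the type-7 definition,
  R's default); single-animal cohorts report q1 = q3 = median.

For a circle of radius R the ratio has the closed form
(⌊L₀/δ⌋·2R·sin(δ/2R) + closing chord)/L₀, which the test suite uses as
an oracle; straight tracks give exactly 1 at every δ, and the chord
bounds |end − start| ≤ L_δ ≤ L₀ are asserted as invariants on random
tracks.

## Loop detection and circular-locomotion classification

Loopy segments are parts of tracks forming closed circles with a
diameter under 1 cm. Two of the classifier's thresholds come from that
definition: `max_loop_diameter_mm = 10` and, for calling the animal's
phenotype, `loopy_fraction_threshold = 0.30` — an animal is CL when
loopy segments cover at least 30% of its track. The threshold is
inclusive (≥ 30%). "Covering 30% of the track" is read as track
*length*, not time, which matches the arc-length parameterisation of
the detector and is insensitive to pauses.

The remaining knobs operationalise "closed circle" for automated
scoring of sampled centroid tracks, where by-eye judgment is not
available; all are configurable and reported:

* `closure_eps_mm = 0.5`: a closure is a return to within half a body
  width of an earlier point. Tighter values miss noisy loops, looser
  ones accept near-misses.
* `min_loop_path_mm = 3`: a closure must enclose at least a short
  path, excluding jitter-scale returns.
* `min_net_turn_deg = 330`: the closed sub-path must have accumulated
  nearly a full turn of net signed heading change, which distinguishes
  loops from incidental track crossings (an out-and-back excursion
  closes spatially with net turn near 0 or ±180).
* `strong_fraction_threshold = 0.95`: "continuously only loopy" is
  scored as ≥ 95% rather than 100%, tolerating the small closure gaps
  between consecutive circuits of a real (or simulated) spiral.

The sub-path diameter is the exact minimal enclosing circle of its
samples, computed with the randomized incremental (Welzl) algorithm;
`diameter_method = "max_pairwise"` offers the cheaper largest pairwise
distance, which can under-estimate the true enclosing diameter by up to
a factor 2/√3 on acute configurations (a 12 mm-wide equilateral
sub-path would pass the 10 mm bound under `max_pairwise` but fail under
`"mec"`). The scan is greedy earliest-closure-first; after a detected
loop it resumes at the closure point, and overlapping or touching
intervals merge into maximal loopy stretches so that a three-circuit
spiral is a single interval. Assay summaries report percent CL out of
10 worms per assay (mean across assays and pooled), following the
standard assay layout.

## Head-bend kinematics

The head angle is the angle at the pharynx terminal bulb between the
centroid→bulb and bulb→nose-tip vectors, signed by cross-product
orientation and mapped to ventral-positive when the ventral side is
known. The estimator is invariant under rigid motion and uniform
scaling and negates under mirror reflection — properties the suite
asserts directly. Frames with coincident landmarks are dropped with a
warning rather than failing the series, since single-frame tracking
failures are common; actual timestamps are used without resampling to
an exact 0.5 s grid.

A *bend* is a prominent local extremum of the angle series: positive
maxima are ventral bends, negative minima dorsal bends, and topographic
prominence (peak height above the higher of the two flanking valley
minima, with series edges acting as boundaries) must reach
`prominence_deg`, default 10°. "Bend" has no standard operational
definition at this sampling rate; prominence was chosen over a plain
local-extremum rule because small oscillations riding on a large bend
should not count as separate bends, and the default is reported with
results.

## Fluorescence recovery and puncta

Every ROI intensity is corrected by subtracting the mean of three
background points *before* any ratio is formed; this ordering is the
only one under which a camera offset common to ROI and background
cancels from all terms, and the corresponding offset invariance is
asserted for random records. The per-animal rate of change is
(after − bleached)/(intact − bleached) on corrected values. Records
whose corrected bleach depth is below 1% of the corrected intact
intensity (`eps_fraction`) carry no usable signal and error out;
records where bleaching failed outright (bleached ≥ intact) are flagged
invalid; measured retention outside the expected 50–70% band is warned
about but tolerated, as is a rate outside [0, 1] (flagged, since noise
can overshoot). The recovery ratio of a heat-shocked animal is its rate
minus the mean *corrected* control rate plus 1 (control rates are
averaged after background correction). Puncta tables from external
segmentation are background-corrected the same way, clipped at zero
with a warning when background exceeds a punctum, and an empty table is
a valid "no puncta detected" result, not an error.

## The synthetic-data generators

`simulate_trajectory()` is a correlated random walk: constant speed
(default 0.15 mm/s — a typical crawling speed, configurable since real
speed distributions vary), with the heading turned each step by
(regime bias + Gaussian noise) × step advancement. Expressing bias and
noise per unit path length (deg/mm) rather than per time matches the
per-length definition of the curving rate and makes the walk's
geometry speed-invariant: a constant bias b closes onto a circle of
diameter 360/(π|b|) mm, an exact relation the suite uses as an oracle.
A two-state Markov chain toggles between the normal and loopy regimes
with probability `bout_switch_prob` per step, emulating animals that
alternate normal and loopy locomotion in bouts. A walker that can
never switch but has a loopy bias set starts in the loopy regime — it
models a permanently loopy mutant — while all other walkers start
normal; `start_regime` overrides the rule. The simulated animal's
ventral side is on the left, so positive bias means ventral-ward
curving. All generators are pure functions of their configuration
(seed included), restore the caller's RNG state, and are bitwise
reproducible.

For cohort studies the symmetric regime chain's occupancy varies
widely between animals, so `simulate_trajectories()` can condition on
a minimum realised loopy coverage, discarding runs below the bound.
The packaged cohort demonstration uses loopy bias −12 deg/mm (loop
diameter ≈ 9.5 mm, just under the 1 cm bound), switch probability
0.0015 (mean bout ≈ 667 steps ≈ 3 loop circumferences, so bouts
sustain whole circuits — detection only credits closed circuits, so
much shorter bouts would be invisible), heading noise 1.5 deg/mm in
both groups (small enough that drift does not push 9.5 mm loops over
the 1 cm diameter bound), 3600 s tracks (classification-style
one-hour crawls; tracker-style quantification defaults to 1200 s), and
mutants conditioned on ≥ 40% bout coverage.

`simulate_head_wave()` programs an asymmetric oscillation — positive
half-cycles scaled to the ventral amplitude, negative to the dorsal —
and builds landmark frames that invert *exactly* under `head_angle()`
(centroid at origin, bulb 1 mm along the body axis, nose 0.5 mm from
the bulb rotated by the programmed angle). The default 2 s period puts
the 0.5 s samples exactly on the extrema, so programmed amplitudes are
recovered without interpolation error. `simulate_fluorescence()` draws
intact intensities around a mean, retains a uniform 50–70% fraction
after bleaching, recovers a programmed fraction of the lost signal,
and adds a constant camera background to every reading so that the
correction path is exercised; at zero noise every rate of change
equals the programmed recovery fraction exactly.

What the generators do **not** emulate — and hence what green tests do
not establish about real data: no body-posture model (centroid only),
no speed variation, pauses or reversals, no plate-edge interactions,
no tracking dropouts or outliers, and head-wave landmarks with rigid
geometry rather than a deforming body. The generators validate the
estimators' mathematics, not the biology of any particular strain.

## Problem sizes and determinism

The shipped tests and the acceptance script use cohorts of 30 animals
per group, 300–3600 s tracks, 10-point δ grids, and 100-track invariant
sweeps — sizes chosen so the full suite completes in a few minutes on a
single core while keeping Monte-Carlo error well inside the asserted
tolerances (e.g. a −5 deg/mm bias is recovered to ±10% with ~0.02
deg/mm standard error across 30 animals). Every stochastic step takes
an explicit seed; per-animal seeds are derived deterministically from a
master seed, so cohorts are reproducible end to end.

## Known limitations

* Ventral-side orientation must be supplied as metadata; it cannot be
  inferred from centroid tracks, and unsigned data are only reported in
  the mathematical convention.
* The loop detector scans sample points; loops traversed faster than
  the sampling rate (not realistic at 1 Hz and normal crawling speeds)
  or closures falling between samples by more than `closure_eps_mm`
  are missed.
* Chemotaxis indices and any odorant-gradient logistics are out of
  scope, as are image segmentation and landmark detection upstream of
  the tables this package reads.
* The final partial circuit of a loopy bout (after the last closure)
  is not counted as loopy path, so detected loopy fractions slightly
  under-estimate regime occupancy in bout-structured walks.
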