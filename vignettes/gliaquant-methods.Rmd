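---
title: "gliaquant: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gliaquant: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliaquant)
```

# What the package quantifies

Microglia — the brain's resident macrophages — report on neuronal distress
through their shape and behaviour. In a healthy larval zebrafish brain most
microglia are *branched*: a small soma with several long, ramified
processes. Under sustained neuronal hyperactivity (as in `scn1lab`
loss-of-function models of Dravet syndrome) a growing fraction retract
their processes and round up into *amoeboid* cells, move their cell bodies
more, and the brain shows more seizure-like events in both calcium imaging
and local field potential (LFP) recordings, while the larvae swim longer
distances. `gliaquant` implements the full quantification chain behind
those readouts:

1. **3D morphometrics** of segmented microglia (volume, surface area,
   sphericity, process number and lengths, ramification index, Sholl
   profiles);
2. **rule-based classification** of activation state
   (branched / amoeboid / transitional);
3. **cell-body motility** metrics from time-lapse centroids;
4. **calcium event detection** on ΔF/F₀ traces;
5. **LFP event detection** on band-pass-filtered voltage traces;
6. **locomotor scoring** into distance and speed-state times;
7. group statistics and an **end-to-end synthetic experiment**.

Because raw imaging data of this kind are rarely shareable, every stage is
paired with a synthetic generator that produces inputs with known ground
truth; the test suite and the acceptance script validate the chain against
that truth rather than against irreproducible recordings.

# Morphometrics

## Measured quantities

For a cell given as a binary voxel mask with physical voxel sizes
(micrometres, possibly anisotropic):

* **Volume** V: voxel count × voxel volume (µm³).
* **Surface area** A (µm²): the 0.5-isosurface area, estimated by summing
  exposed voxel faces, each weighted by $1/(|n_x|+|n_y|+|n_z|)$ where
  $\hat n$ is the unit surface normal obtained from the gradient of a
  Gaussian-smoothed copy of the mask (σ = 0.45 × the smallest voxel
  dimension). The weight corrects the staircase bias of the voxel surface:
  it is exact for axis-aligned boxes and converges to the true area for
  smooth surfaces. On a digitized ball of radius 20 voxels the estimate is
  within ~1% of $4\pi r^2$; on a 30-voxel cube within ~5% of $6s^2$
  (sharp edges are the worst case for any local estimator).
* **Sphericity** S: Wadell's definition
  $S = \pi^{1/3}(6V)^{2/3}/A$, 1 for a perfect sphere. This is the
  standard definition used by commercial 3D cell-analysis software.
* **Process statistics**: from the skeleton (below), NP = number of
  primary processes (skeleton edges incident to the soma), TL = summed
  arc length of all processes outside the soma (µm), mean length = TL/NP,
  and the **ramification index** RI = terminals / NP — 1 for an unbranched
  cell, growing with branching, 0 when NP = 0. RI has no universally
  agreed definition; terminals-per-primary was chosen because it is
  scale-free and matches the qualitative usage (branched cells score
  higher).
* **Sholl profile**: for concentric spheres centred on the soma, the
  number of skeleton segments crossing each sphere; a segment crossing k
  times counts k, and a crossing that lands exactly on a segment endpoint
  is counted once (half-open interval test).

## Skeletonization

The skeleton is traced as a **shortest-path tree** over the foreground
voxel graph (26-connectivity, edge weights = physical distances between
voxel centres), in the TEASAR family of centreline tracers:

1. *Depth*: multi-source Dijkstra from all boundary voxels gives each
   voxel's distance to the background; the deepest voxel is the soma
   centre and its depth the soma radius.
2. *Tips*: iteratively, the voxel farthest (geodesically) from the current
   skeleton becomes a new branch tip, and its path back to the skeleton is
   added. A voxel is only eligible as a tip if its distance to the
   skeleton exceeds `max(tip_margin, 2·depth + 2·voxel diagonals)` — a
   voxel inside an already-traced tube sits within one tube radius plus a
   voxel diagonal of the centreline, so this gate rejects tube-wall
   artifacts at any voxel size. The gate bounds the shortest detectable
   process at roughly twice the tube radius plus two voxel diagonals
   (≈ 7 µm at 1 µm voxels).
3. *Routing*: paths are routed with Dijkstra on depth-penalized weights
   (`w · (1 + 1/(0.5 + depth))`); 26-connected shortest paths tie on
   length and otherwise hug the tube wall, and the penalty breaks ties
   toward the centreline. All *reported* lengths are measured on the
   resulting geometry in physical µm, never in penalized units.
4. *Lengths*: chain coordinates are smoothed (two passes of 3-point
   averaging on chain-interior voxels) and arc lengths are computed on
   chains resampled at every third voxel, which cancels the residual
   staircase zigzag of a discrete path. Terminal edges are trimmed by the
   estimated tube radius (median centreline depth outside the soma),
   because the farthest-point tip lies on the end-cap surface, one tube
   radius beyond the true process end. With these corrections, total
   process length on synthetic cells is recovered with a bias of about
   +2% (and always within the 15% acceptance band).
5. *Pruning*: terminal chains shorter than `prune_len` (default 2 µm) are
   removed.
6. *Soma delimitation*: skeleton voxels within the measured soma radius of
   the soma centre collapse into a single soma node; primary processes
   are the tree edges crossing that boundary, and process length excludes
   the soma interior.

Anisotropic voxels need no resampling step: all edge weights and reported
quantities are physical, so geodesics are already in µm. Scale
equivariance (double the voxel size ⇒ TL×2, A×4, V×8, S and NP unchanged)
is regression-tested.

# Activation-state classification

Five morphological parameters are carried per cell (S, NP, TL, A, V); the
rule uses four of them. A cell is **branched** when at least 3 of
{S < 0.5, NP > 7, TL > 140 µm, A > 2400 µm²} hold, **amoeboid** when at
least 3 of {S > 0.7, NP < 3, TL < 60 µm, A < 1500 µm²} hold, otherwise
**transitional**. All comparisons are strict, taking the rule's notation
literally; sitting exactly on a threshold satisfies nothing (this boundary
semantics is regression-tested). Volume appears in the parameter list of
the source protocol but in neither criterion list; the implementation
follows the criterion lists and carries V for reporting only.

Because each parameter's branched and amoeboid intervals are disjoint, a
vector can satisfy at most 4 predicates in total, so no cell can reach 3
on both sides: the classes are mutually exclusive by construction. This
is verified both by exhaustive enumeration over per-parameter states and
on 10⁶ random vectors, and the whole classifier is checked exactly
against an independent literal-predicate-counting oracle.

# Motility

Cell-body centroids are linked frame-to-frame by greedy mutual-nearest-
neighbour assignment; candidate links longer than `max_step` (default
20 µm, half a microglial diameter per 40 s frame) are rejected, and
unmatched centroids start or end tracks. There is no gap closing: at tens
of seconds per frame, identity across a disappearance is not reliable, so
a vanishing cell simply ends its track. Per track: displacement
(first→last straight line), path length (summed steps; always ≥
displacement), and mean speed = path length / elapsed time (µm/min),
elapsed time taken from timestamps rather than frame counts. Group
summaries keep only tracks spanning ≥ 80% of the recording (configurable)
to avoid the speed bias of short fragments. The "speed" reported for a
cell body is deliberately the path-based mean speed — the only
interpretation of a cell-body "speed displacement" metric that is
well-defined for an arbitrary track.

# Calcium events

The whole-field trace is the per-frame mean gray value. ΔF/F₀ uses the
global mean as F₀:
$\mathrm{dff}(t) = (F(t) - \bar F)/\bar F$ — dimensionless, invariant to
multiplicative gain, and summing to zero over frames (both properties are
tested exactly). Slow drift is removed *before* normalization by
subtracting a running low-percentile baseline (default: 10th percentile
over a sliding 60 s window, evaluated on a quarter-window grid and
interpolated, then re-zeroed at the corrected trace's median). A linear
ramp on an event-free noiseless trace leaves a residual |dff| < 0.005,
well under half the event threshold.

An **event** is a maximal run of frames with dff strictly above the 0.04
threshold; its amplitude is the run maximum and its duration the run
length. No minimum duration is imposed. Runs separated by fewer than
`min_separation_frames` merge; the default is 1 (no merging), and noisy
analyses use 5 frames (half the default transient decay constant) as a
debounce, because near-threshold noise can split a single transient's
crossing. Strict threshold-count monotonicity holds for unimodal
(noise-free) excursions and is tested on that domain.

The synthetic generator injects transients with instant rise and
exponential decay (τ = 10 frames by default — a generic sensor-scale
decay; only the threshold crossing matters to the detector), with peak
amplitude specified as ΔF/F₀ relative to the local noiseless baseline;
overlapping transients sum, and negative intensities clip at zero with a
warning.

# LFP events

Recordings are band-pass filtered with zero-phase (forward–backward)
second-order Butterworth high-pass (0.1 Hz) and low-pass (1 kHz) filters
in cascade — two named corner frequencies, minimal waveform distortion,
and DC rejection that makes every detection invariant to a constant
offset of the raw trace (tested). An **event** is a maximal segment with
the filtered signal strictly below −0.3 mV lasting strictly more than
100 ms; its amplitude is the segment minimum (relative to the filtered
zero baseline, i.e. threshold-crossing semantics). Segments closer than
`merge_gap_ms` merge before the duration test; the default is 0, and
noisy analyses use 20 ms, since a noise excursion above threshold
mid-event would otherwise split one deflection into two sub-100 ms
fragments. Amplitude measured from a local baseline instead of zero is
available as a flag but is not the default.

Synthetic deflections have half-cosine onset/offset ramps (5 ms) so they
pass the band-pass without ringing. The generator's sampling interval is
a parameter; synthetic suites run at 1.25 kHz and the end-to-end
experiment at 250 Hz with a 100 Hz low-pass (the low-pass corner must stay
below Nyquist), which leaves 100-ms-scale events untouched. The detector
itself is sampling-rate-agnostic.

# Locomotor scoring

Per-step speed is step length over the step interval. The two printed
thresholds (4 and 8 mm) carry no explicit time base in tracking-software
convention; they are interpreted as mm/s (distance per second at 1 s
re-integration), and the configuration also accepts changed values. The
two thresholds cannot separate "immobile" from "slow swimming", so a
motion floor of 0.1 mm/s (configurable) defines immobility. Each
inter-sample interval is assigned to exactly one state — immobile
(< 0.1 mm/s), low (< 4), medium ([4, 8)), high (≥ 8) — so state times sum
to the recording duration exactly (tested to 1e−9); totals are also
reported per one-minute integration bin. Habituation is an acquisition
step, not a computation: summaries start at t = 0 of the provided trace.

# Group statistics

`compare_two_groups()` mirrors standard practice in this literature:
Shapiro–Wilk normality per group (α = 0.05); if both pass, Student's
unpaired t-test, switching to Welch when a Brown–Forsythe (median-centred
Levene) test rejects equal variances (α = 0.05); otherwise Mann–Whitney.
The normality and variance tests themselves are conventional choices and
configurable. `compare_factorial()` fits a two-way ANOVA with interaction
and returns the Tukey HSD table. All tests are delegated to the standard
R routines (`stats`, `car`); the module's contract is the selection
logic. No multiple-testing correction is applied across metrics (matching
field practice); the report logs how many comparisons were made, along
with every operative threshold, for provenance.

# The synthetic experiment

`run_synthetic_experiment()` mirrors the full study on synthetic data: a
2 × 2 design of genotype (wild type vs `scn1lab` knockdown) × microglia
(present vs depleted). Default condition means follow the study system:
amoeboid fraction 10.4% vs 29.1% (branched 27.8% vs 10.2%), calcium
events 16.5 vs 32.2 per hour, LFP events 4.8 vs 28.2 per hour, 30-min
swim distance 212 vs 355 mm, with further increases in the
microglia-depleted epileptic condition. Everything is deterministic per
seed (sub-stream seeds are derived per stage and larva), and per-stage
outputs equal what the standalone modules produce on the same inputs
(tested).

Problem sizes are chosen for desk-scale runs with adequate power: 200
cells per genotype at 1.25 µm voxels for the morphology arm (the
two-proportion comparison of a 10% vs 29% amoeboid fraction then has
>99% power per run), 8 larvae × 40 min at 1 Hz for calcium, 5 larvae ×
30 min at 250 Hz for LFP, and 16 larvae × 30 min at 1 Hz for swimming.
With a zero-effect configuration every condition uses wild-type
parameters, which is used to check the type-I error of the whole chain.

# What the generators do and do not emulate

The generators produce exactly the statistical structure the detectors
and estimators key on: tube-like branched geometry with known process
counts/lengths, transients and deflections of known time, amplitude and
duration on noisy drifting baselines, and piecewise-constant-speed
trajectories. They deliberately do **not** simulate microscope optics
(PSF, shot noise, depth attenuation), touching or overlapping cells,
movement artifacts, electrode drift beyond a linear/dc component, or
photobleaching beyond linear drift. Passing tests therefore demonstrate
that the quantification chain is correct and well-calibrated on data
whose ground truth is known — not that segmentation of low-contrast real
stacks is solved, which is out of scope (real-use inputs are assumed
segmented, as produced by any standard imaging pipeline).

# Numerical and degenerate-input choices

* Surface smoothing σ = 0.45 × min voxel; balances the sharp-edge
  (cube) and curved-surface (ball) regimes of the area estimator.
* Tube rasterization radius 1.5 voxels; thinner tubes fragment under
  voxelization.
* A cell mask thinner than one voxel everywhere yields a degenerate
  single-node skeleton with NP = 0 rather than an error; an empty
  segmentation produces an empty labelling with a warning.
* Event detectors return zero-row tables, and summary statistics report
  an absent (`NA`) mean amplitude rather than 0 when no events exist.
* All generator seeds are single integers; derived sub-streams are split
  deterministically and kept below 2³¹.

# Known limitations

* NP can undercount by 1 when two processes attach to the soma within a
  couple of tube radii of each other (their shafts merge before leaving
  the soma neighbourhood); the acceptance band (±1 for ≥90% of cells)
  reflects this.
* The area estimator's sharp-edge bias (≈ −4% on a 30-voxel cube) is
  inherent to local surface estimation on binary masks.
* Very short processes (below ~2 tube radii + 2 voxel diagonals) are
  indistinguishable from surface roughness and are not traced.
* The LFP amplitude of a noisy event is the segment minimum and therefore
  includes the expected minimum of the noise (~3σ for long events).
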