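---
title: "Quantifying pulsatile apical constriction: models, parameters, and design choices"
author: "placodyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulsatile apical constriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

During tube formation, epithelial placode cells constrict their apical
surfaces in pulses driven by a medial actomyosin network: myosin intensity
rises and falls with a cycle length on the order of 120–180 s, each pulse
correlating with a constriction of the apical area, and part of each
constriction is retained afterwards (a ratchet). Quantifying this from
two-channel confocal time-lapse data requires a chain of image-analysis
steps — finding the curved apical surface in each z-stack, projecting a thin
layer beneath it, segmenting and tracking the cell apices, partitioning
fluorescence into medial and junctional pools, detrending the per-cell
traces, detecting fluctuation cycles, classifying activity against
thresholds, and estimating the phase relation between myosin and cell
radius — and every step can silently distort the result. `placodyn`
implements the full chain together with a ground-truthed synthetic movie
generator, so each stage is tested against data whose right answer is known.

## The synthetic tissue and what it emulates

`generate_epithelium()` builds a conforming polygonal tiling as the Voronoi
diagram of a jittered hexagonal lattice (150 cells on an 80 × 80 µm field by
default, matching a typical placodal field of view), with an invagination-pit
center placed off-center the way the real pit sits in the dorsal-posterior
corner, and a placodal ellipse surrounded by margin cells that play the role
of the adjacent epidermis.

`simulate_dynamics()` gives each placodal cell a raised-cosine myosin
oscillation: per-cell period drawn from N(150 s, 10 s²), random initial
phase, amplitude 5 grayscale units over a baseline of 10, all scaled down
with radial distance from the pit (`radial_gradient = 0.5`). The apical area
is modulated in proportion to the *lagged* myosin oscillation —
`lag_cycles = 0.125` by default, so the inverse apical radius trails myosin
by exactly one-eighth of a cycle — plus a ratchet that retains 30% of each
pulse per elapsed cycle. We deliberately model area as the quasi-static
response of tension to lagged myosin rather than integrating a rate equation:
the former makes the generated myosin-to-inverse-radius phase difference
exactly the configured lag (which is what the phase analysis must recover),
while integrating a lagged forcing would silently add a quarter-cycle. The
`constriction_gain` parameter (0.5 µm² per grayscale unit per min) sets the
peak constriction rate of the oscillatory component, capped at 20% of the
cell's own area so small apices cannot be driven below zero. Since the
ratchet removes placodal area, the margin cells absorb it: frame totals are
conserved exactly, as a tiling must.

Polygon realization works on the shared-vertex mesh: each cell proposes an
isotropic rescaling about its centroid, vertices move toward the mean of
their cells' proposals with an annealed Laplacian smoothing term and a
per-vertex displacement cap tied to the local edge length (which prevents
edge crossings). Realized areas track their analytic targets to ~1% mean
(~4% worst-case) while the tiling remains a strict partition of the domain.
The truth tables carry the analytic areas; the polygons realize them.

`render_movie()` paints the membrane skeleton and the per-cell medial myosin
in a one-slice shell at the height of a smooth dome surface (a pit-centered
bump, gradient ≤ 0.1 µm/µm, well within the 1 µm/µm fitting bound), applies
a Gaussian point-spread (σ = 0.3 µm laterally and axially) and scaled-Poisson
photon noise plus Gaussian read noise. The noise scale (0.5) and the
baseline-to-amplitude ratio (10:5) are generator conventions, not biological
claims; both are exposed as configuration. What the generator does *not*
emulate: sub-cellular myosin foci and flows (the medial pool is uniform per
cell), genuine 3D cell shape, tissue-scale flows, bleaching, or segmentation
ambiguities from weak membrane signal. Passing the recovery tests therefore
shows the analysis is correct under the stated signal model, not that it is
robust to every pathology of real embryo movies.

## Surface extraction and projection

The apical surface ("blanket") is fitted per frame: each slice of the
membrane channel is Gaussian-smoothed, the per-column best slice taken, a
3 × 3 median filter removes isolated outliers, and a min-plus (Lipschitz)
projection enforces the smoothness bound of 1 µm/µm — yielding the largest
surface below the per-column optimum with bounded gradient, contiguous by
construction. A bound of zero degenerates to the single globally best
plane. Frames are fitted independently; the median frame-to-frame surface
displacement is logged so drift in the fit is visible. Projection takes the
per-pixel maximum over the slab from the surface down to 1 µm below it
(inclusive slice endpoints after rounding; with a 1 µm z-step that is
exactly two slices). No sub-slice interpolation is performed.

## Segmentation, tracking, QC

Segmentation is a seeded watershed on the locally contrast-normalized
membrane image (block 15 µm), which makes the labeling invariant to global
intensity rescaling. Seeds are distance-transform maxima of the interior
mask with a 2.5 µm minimum separation; basins grow by intensity-weighted
propagation, and adjacent basins whose shared boundary carries less than one
local standard deviation of membrane evidence are merged — so featureless
regions are not split by spurious seeds. The final skeleton (pixels where
basins meet) carries label 0. On rendered scenes, 95–100% of truth cells are
recovered at IoU ≥ 0.8 without noise, and ≥ 90% at default noise.

Tracking links consecutive frames by greedy maximal-overlap matching (a pair
links iff the overlap covers ≥ 50% of the smaller region); identities are
never reused. QC flags — never deletes — instances violating size
(2–150 µm²), relative speed to neighbors (> 5 µm/min), relative area-change
rate (|d ln A/dt| > 3 min⁻¹), short lineages (< 6 frames), or field-of-view
contact. Relative speed is measured against the *median* neighbor velocity:
with the mean, one mis-tracked cell also condemns all of its well-tracked
neighbors.

## Fluctuation analysis

Per-cell medial intensity is the mean of the projected myosin channel over
pixels deeper than 0.6 µm from the membrane skeleton, minus the per-frame
mean over an epidermal (extra-placodal) baseline mask, floored at zero;
empty medial regions yield missing values, not zeros. Detrending subtracts a
centered boxcar mean (360 s window, longer than any expected cycle,
truncated at trace ends so trend + detrended always reconstructs the raw
trace exactly).

Cycles run trough-to-trough for myosin and peak-to-peak for radius. Extrema
are alternating turning points with prominence ≥ 0.3 × the trace standard
deviation, located on a 5-point moving average of the detrended trace;
amplitudes (max − min within the cycle) are measured on a lighter 3-point
average. This split is deliberate: with ~7–8 samples per cycle, per-sample
shot noise otherwise creates spurious turning points that cut genuine cycles
short (biasing the mean cycle length from 150 s down to ~110 s in our
recovery experiments) and inflates the max − min amplitude by the noise
envelope (which misclassified ~44% of instances as fluctuating in a control
whose amplitude was scaled to 10%). With the split, recovery gives a mean
cycle length within one frame of truth and the low-amplitude control
classifies < 5% of instances as fluctuating. Setting both smoothing
parameters to 1 recovers the plain textbook definition, which the unit tests
exercise on noise-free sinusoids.

Activity is amplitude × frequency (frequency in min⁻¹); instances inside a
cycle are fluctuating iff activity meets the threshold — 0.5 for myosin
(grayscale/min) and 0.005 for radius (µm/min), the standard values for this
assay — and instances outside any cycle are non-fluctuating. Pooled
fractions report the percentage of instances with myosin fluctuations and,
of those, the percentage also fluctuating in radius.

Phase averaging assigns each instance its myosin-cycle phase (0 at the
opening trough, advancing linearly), bins [0, 1) into 20 bins, and reports
per-bin means with 1.96 SEM confidence intervals for both detrended myosin
and detrended inverse radius. The myosin lead is the circular difference of
the two curves' first-harmonic phases, *weighted by bin occupancy*: phase
sampling is quantized (cycles contain ~7–8 frames), so some bins hold very
few instances and an unweighted estimator is dominated by them. Before
pooling, instances beyond 5 robust standard deviations of their own trace
are masked — transient segmentation faults that slip through QC otherwise
put single multi-sigma spikes into one phase bin. On default movies the
estimated lead is 0.112–0.137 cycles across seeds against a truth of 0.125.

## Spatial statistics

Neighbor dispersion is the mean absolute apical-area difference between a
cell and its edge-sharing neighbors — low when constriction is spatially
clustered, high when scattered. On the two fixed-tissue patterns (identical
area multisets, different arrangements) the pipeline measures a median
dispersion of ~6 µm² for the clustered pattern versus ~10 µm² for the
dispersed one. Radial profiles pool cell instances into 5 µm bins of
pit-centered distance with normal-approximation 95% CIs. One measurement
effect is worth knowing: strongly constricted apices near the pit lose
medial area to the fixed-width junctional band, which damps their measured
medial amplitude — the innermost activity bins sit below the imposed
gradient. Cell radius is the equivalent-circle radius sqrt(area/π) by
default; the centroid-to-vertex mean is available behind a switch, as the
field uses both conventions.

## Statistical tests

`ks_two_sample()` (two-sided, asymptotic p) and `t_test_two_sample()`
(Student pooled-variance by default, Welch optional) wrap the standard R
implementations; `g_test()` implements G = 2 Σ O ln(O/E) with chi-square
reference, since base R provides no G test. Degenerate zero-variance t-test
inputs return the limiting statistic explicitly. No multiple-testing
correction is applied anywhere; p-values are reported individually.

## Numerical conventions and degenerate inputs

Polygons are open rings in µm, areas by the shoelace formula;
self-intersecting polygons are rejected. Voronoi cells are built by
half-plane clipping against the domain rectangle, so boundary cells are
exact; slivers below vertex-welding tolerance (10⁻⁶ µm) count as empty and
their sites are replaced. Label images use 0 for the skeleton; all
calibrations ride along in µm. Single-slice stacks project to themselves;
all-zero stacks, constant images, empty baselines, zero margins, and
non-positive thresholds raise errors rather than propagating nonsense.

## Problem sizes

The shipped configuration analyses one 150-cell, 46-frame movie at
0.4 µm/pixel (200 × 200 × 10 voxels per channel per frame). These sizes give
~400–600 pooled myosin cycles per movie — enough that the recovery bands
(± one frame on cycle length, ± 0.03 cycles on lead) are comfortably
resolved — while a full simulate-measure-analyze round trip stays in the
low minutes on a single CPU. All sizes scale through ordinary function
arguments.

## Known limitations

Each blanket is fitted per frame with no temporal regularization; the
published analyses may have smoothed in time (unstated), so we log
frame-to-frame displacement instead. Manual correction of outlines is out of
scope: QC flags suspect instances rather than repairing them. The strain-rate
decomposition of tissue deformation into cell-shape and intercalation terms
is not implemented; "rate of tissue area change" is the pooled per-cell
d ln A/dt, which suffices for radial profiles. Whether published fraction
denominators excluded instances near trace ends is unknowable from the text;
we count every instance of every analyzable trace and report the counts
alongside the percentages.
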