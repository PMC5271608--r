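---
title: "Reference-frame analysis of grid cells on a movable platform: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-frame analysis of grid cells on a movable platform: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gridframes)
```

## The scientific problem

Medial entorhinal grid cells fire at the vertices of a hexagonal lattice
tiling the environment. When a square foraging platform is rotated or
translated inside a cue-rich room, each grid must "choose" what to stay
anchored to: the room's distal landmarks, the physical platform, or the
platform's *geometric* structure (its square symmetry class, which is
indistinguishable from the physical platform under 90° rotations).
`gridframes` implements the full measurement chain that turns raw tracking
and spike trains into that three-way attribution: rate maps, autocorrelogram
geometry, a bootstrap grid-cell classifier, rotation/phase decomposition per
reference frame, pairwise coupling statistics, and 60°-symmetric circular
statistics — together with a synthetic-session generator that makes every
stage testable by parameter recovery.

All angles in the package are degrees, clockwise-positive (matching the
convention in which a "20° CW" platform rotation is +20); the analysis frame
is room-axis-aligned with its origin at the platform center, which follows
the platform when it is translated (the recording camera was re-centered the
same way).

## Rate maps

Running speed is estimated on a trajectory smoothed with a clipped Gaussian.
The temporal mask is specified by its width in time; we read the stated
"variance = 300 ms" as σ = 300 ms, because a literal variance of 300 ms²
(σ ≈ 17 ms) is shorter than one 30-Hz frame and could not smooth anything.
The mask is clipped at ±2σ (the clipping extent is not specified upstream;
±2σ keeps 95% of the mass) and renormalized where it overhangs the series
ends. Epochs *strictly longer* than 500 ms in which the smoothed speed stays
*strictly below* 3 cm/s are expunged from the unsmoothed trajectory and the
spike train.

Retained positions are binned at 3 × 3 cm; rate = spikes/dwell per bin; bins
under 50 ms of dwell are missing. Smoothing uses a 5 × 5-bin Gaussian with
variance 2 bin² (here the literal reading is plausible: σ ≈ 1.4 bins for a
5 × 5 clipped mask), renormalized over the occupied bins under the mask at
each step; an output bin is missing when fewer than five occupied bins fall
under the mask. Both convolutions are tested against explicit
loop-summation oracles at 10⁻⁹ tolerance.

Bin edges are anchored to the platform's bounding box in the analysis frame
(declared per day), so maps from differently rotated sessions share a grid —
a prerequisite for crosscorrelograms between sessions.

## Correlogram geometry

The crosscorrelogram holds the Pearson correlation of two maps at every
integer bin displacement, computed over co-occupied bins, and only where the
overlap has ≥ 100 bins. It is computed via masked FFT cross-correlation of
the five moment sums (the bin counts are rounded back to integers, which
removes FFT round-off from the validity mask) and agrees with brute-force
loops to ~10⁻¹³. Autocorrelograms are symmetrized under point reflection,
which holds exactly in exact arithmetic.

Correlation fields are 8-connected components of ≥ 20 bins with r > 0.1;
8-connectivity tolerates single-bin diagonal bridges at 3-cm resolution.
A field's center of mass is computed over its core — bins at or above the
midpoint between the detection threshold and the field's peak — weighted
by the correlation excess over the threshold. Centering on the core keeps
the estimate independent of how far the field's low-correlation skirt
happens to stay above threshold (which varies with overlap size and
neighboring correlogram structure, and would otherwise bias large-scale
grids outward), and excess weighting makes the estimator continuous as
noise moves boundary bins in and out of the component. Canonical axes: AX0 is
the semi-axis closest to +x (the exact ±30° tie goes to the CCW candidate),
AX1/AX2 the first semi-axes CCW/CW of it. Orientation is their circular
mean after mapping into the 60°-periodic axis space, which avoids ±60°
wrap-around artifacts; scale is the mean center distance of the three axis
fields; the elliptical index is 1 − B/A of a direct least-squares conic fit
(deterministic, no iteration) to the six inner fields.

## Gridness and classification

If the elliptical index exceeds 0.05 the map is stretched along the
ellipse's short axis by A/B and all geometry is recomputed. We implement the
stretch as an NA-aware affine resampling of the rate-map image rather than
re-binning rescaled coordinates: it keeps the operation a map→map transform
(so bootstrap replicates reuse it without re-threading raw data) and is
equivalent up to bilinear interpolation at 3-cm bins.

The annulus containing the six inner vertices (radii D ± 1.2·cR, where cR is
the radius of the circle with the central field's area) is correlated with
rotated copies of itself (bilinear interpolation, correlations over bins
valid in both). The published description of the gridness contrast is
internally inconsistent (the same 30° offset appears on both sides, which
would score ideal grids strongly negative while the same source reports
accepted-map gridness ≈ 1.26); we use the standard contrast
min(r60, r120) − max(r30, r90, r150), with both offset sets exposed in
`gf_config()`.

A map is a grid cell when all seven criteria hold: gridness ≥ 0.1; six
annulus fields found; adjacent semi-axis separations strictly between 30°
and 90°; elliptical index < 0.5; no vertex farther from the fitted ellipse
than 20% of its center distance (radial distance approximation); scale
< 125 cm; and gridness ≥ 0.1 in ≥ 95 of 100 bootstrap replicates, each
built by resampling the spike train with replacement to equal size and
re-running the full pipeline. Criteria after an unevaluable step are
reported as `NA`, and the bootstrap stage is skipped when an earlier
criterion already fails (the conjunction cannot pass).

On simulated 20-minute sessions (15 Hz peak), the classifier accepts ideal
grids and rejects uniform-rate Poisson cells at ≥ 95% each, with
orientation recovered within 2° and scale within 5% — these checks run in
the test suite. One caveat worth knowing: a rotationally *symmetric*
pattern (concentric rings) scores near zero but not exactly zero, because
the square platform aperture leaves a residual 4-fold component in the
autocorrelogram.

## Reference-frame decomposition

Grid rotations live in the circular range [−30°, +30°) (60° lattice
symmetry). The platform frame of a manipulation maps to
`to_grid_angle(ρ)` (70° → +10°, 45° → −15°); the geometric frame is the
minimal rotation congruent to ρ modulo 90°, in grid space
(`geometric_frame_angle`: 70° → −20°, 45° → +15°, with the exact 45° tie
resolved toward the rotation opposite in sign to the physical one). A
frame-relative rotation is the wrapped difference from the measured room
rotation; phase shifts are read off the crosscorrelogram after rotating the
STD map by the frame's physical rotation plus the residual rotation in that
frame, as the center-of-mass displacement of the most central correlation
field (nearest (0,0); ties to the larger area).

For SHIFT (platform translated by half its side, 68.5 cm, both maps
platform-centered), the room/platform dissociation uses the 1-D phase
algebra: α = 2π·68.5/(scale·cos θ) wrapped to (−π, π] is the platform-frame
phase a perfectly room-anchored grid must show; β is the observed
platform-frame phase, γ = β − α the room-frame phase, converted back to cm.
Two conventions are worth stating. First, our correlogram displacement is
"manipulated pattern relative to STD", the opposite sign to the algebra's
convention, so the wiring flips sign on entry and exit. Second, the algebra
is one-dimensional: its y-component is taken from the platform-frame shift
unchanged, so when no lattice axis aligns with the translation the reducing
lattice vector leaves a y-residue even for a perfectly room-anchored grid
(at orientation 0 the algebra is exact). The projected period is
scale·cos(orientation) as published, without first reducing the orientation
to the axis nearest the translation; the reduced variant is a one-line
sensitivity change.

## Pair coupling

Pairs of simultaneously recorded grids enter the analysis when both pass
classification in both sessions and their STD maps correlate below 0.5.
Rotation difference is the wrapped absolute difference (in [0°, 30°]).
The joint correlation stacks the two mean-centered, unit-norm STD maps,
applies one shared rigid transform — the pair's circular-mean rotation (in
the 60°-expanded space) and mean phase-shift vector, each grid contributing
its own phase shift even across scales — and takes the cosine against the
stacked manipulated maps over bins defined in both. Controls perturb each
STD map by a uniform (−30°, 30°) rotation and each manipulated map by a
uniform-direction shift of uniform (0, scale) length, then *re-run the
measurement pipeline* on the perturbed maps (rather than perturbing measured
parameters), which is the more faithful reading of the procedure.

## Circular statistics

Rotations are linearly expanded ×6 onto the full circle for testing and
contracted for description. Rao's spacing test requires n > 7; because no
circular-statistics library is available as a dependency, its null
distribution is simulated once per sample size (memoized Monte Carlo,
10,000 draws, fixed internal seed) — this reproduces what the published
critical-value tables tabulate without committing to a table edition, and
the test's type-I error at nominal 0.05 is verified to lie in [0.02, 0.09]
in the suite. Hypothesis tests on mean directions use mean-direction
confidence intervals (Zar's formulation, with the high-concentration branch
at r̄ > 0.9) at 95/99/99.9/99.99%, reporting the largest interval that
excludes the hypothesis. Thinning removes same-tetrode units recorded on
different days within 150 µm of anatomical depth, per manipulation,
deterministically (earliest day, then lowest cluster id, is retained — the
upstream description says only that the procedure was automated).

## The synthetic-session generator

The generator is the package's study-condition stand-in for the undeposited
recordings. Trajectories are a smoothed random walk: per-epoch target speeds
(mean 27 cm/s, s.d. 5, redrawn every ~3 s, relaxation τ = 0.5 s), heading
diffusion (40°/√s), reflective walls (1 cm margin), and explicit pauses
(0.03 s⁻¹, ≥ 600 ms) that the immobility filter must catch. These defaults
were chosen once as plausible brisk foraging on a familiar 137-cm platform
and produce ≥ 95% bin coverage at ≥ 50 ms and a dwell coefficient of
variation below 0.5 in 20 minutes. Real foraging differs in ways the model
does not emulate — wall-following, thigmotaxis early in sessions,
inhomogeneous sampling — so passing recovery tests shows the *measurement
chain* is correct, not that it is robust to every behavioral pathology.

Grid cells are rectified sums of three plane-wave cosines 60° apart
(analytic lattice control; peak rate at vertices). The rectification level
(default 1.25 of the sum's [−1.5, 3] range) sets the firing-field width;
the default gives fields covering roughly a fifth of the platform, as in
real grid cells — rectifying at zero produces fields so broad that at
large grid scale the correlogram's inter-field troughs leave the valid
region and field centers can no longer be localized, which is also why the
generator's noise-free recovery contract (scale within one bin) pins this
default down. A Gaussian-bumps-on-lattice alternative is selectable for
robustness checks; elliptical
distortion is injected by an affine compression of position before rate
evaluation; spikes come from inhomogeneous-Poisson thinning of a bounded
candidate stream (oracle-tested against a 1-ms Bernoulli discretization).
Anchoring policies transform the ground truth per session: room-anchored
lattices are fixed in room coordinates (the SHIFT camera re-centering makes
them appear translated); platform/geometry-anchored lattices rotate about
the platform center by the anchor's rotation minus a configured
under-rotation (applied toward zero, and only when the anchor actually
moves), plus a configured phase lag. Under-rotation and lag are
deterministic offsets, not per-session noise, mirroring the day-to-day
reproducibility of the real responses. Spiking noise aside, the generator
is noise-free; no head-direction, conjunctive, or learning dynamics are
modeled.

## Numerical choices and limitations

* Problem sizes in the suite: 20-minute sessions at 30 Hz, 46×46-bin maps,
  100 bootstrap replicates, 100 cells per classifier-calibration arm —
  sizes at which every stage is exercised end to end on one CPU.
* Degenerate inputs: geometry functions return a flagged degenerate result
  (reason string) instead of erroring inside the pipeline; `run_day` logs
  per-unit failures and continues.
* Ties are deterministic everywhere (axis ±30°, central-field selection,
  thinning retention, the 45° congruence tie).
* The gridness of very large-scale grids (> ~120 cm on a 137-cm platform)
  is ill-posed because vertices fall off the aperture — the 125-cm scale
  criterion exists for exactly this reason.
* `run_day` derives per-stage seeds from one master seed by a stable string
  hash, so adding a unit does not shift any other unit's stream.

## Repository shape

The package exposes everything as functions; the `analysis/` directory
holds numbered driver scripts (simulate → rate maps → classification →
frame responses → coupling → statistics) that run the same functions over a
packaged synthetic day and write tables under `results/`. They are the
workflow interface; no shell CLI is shipped.
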