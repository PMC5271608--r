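# gridframes

Reference-frame analysis of grid-cell recordings on a movable platform.

Grid cells of the medial entorhinal cortex fire on the vertices of a
hexagonal lattice. When the square platform an animal forages on is rotated
or translated inside a cue-rich room, each grid's lattice must re-anchor —
to the room's distal landmarks, to the physical platform, or to the
platform's *geometric* frame (the square's 90°-symmetry class that implies
the smallest rotation). `gridframes` is an R package plus analysis workflow
that takes tracked trajectories and spike trains through the full
measurement chain of that question:

* speed-filtered, occupancy-normalized, smoothed **rate maps** (3-cm bins,
  3 cm/s / 500 ms immobility rule, 50 ms dwell minimum) and split-half
  stability;
* spatial auto/crosscorrelograms, correlation fields, canonical axes, grid
  **orientation / scale / elliptical index**, and a **gridness score** with
  elliptical correction;
* the **seven-criterion bootstrap grid-cell classifier** (100 spike-train
  resamples, ≥ 95 must clear gridness 0.1);
* **rotation and phase-shift decomposition** against the room, platform and
  geometric reference frames, on the 60°-symmetric circular range
  [−30°, +30°), including the closed-form α/β/γ phase algebra for the
  half-platform (68.5 cm) translation;
* **pairwise geometric coupling** (rotation difference and stacked-map
  joint correlation) with randomized perturbation controls;
* **circular statistics** in the 6×-expanded angle space (Rao spacing test,
  mean vectors, confidence-interval tests) and anatomical thinning of
  putative duplicate units (150 µm rule);
* a **synthetic-session generator** — foraging trajectories,
  inhomogeneous-Poisson grid and boundary cells, configurable anchoring
  policies with under-rotation and phase lag — so that every stage is
  validated by parameter recovery against known ground truth.

Key angular identities, as implemented: a 70° CW platform rotation is
`to_grid_angle(70) = +10°` in grid angular space; its geometric frame is
`geometric_frame_angle(70) = −20°` (20° CCW); a 45° CW rotation maps to
−15° with geometric frame +15°.

## Worked example

The `analysis/` directory is a numbered workflow over one simulated
experiment day — eight platform-anchored grids (scales 52–78 cm) with a 6°
rotational undershoot, run through STD → ROT20 → ROT70 → SHIFT sessions of
20 minutes each:

```sh
Rscript analysis/01_simulate_day.R      # writes results/data/ (CSV + YAML manifest)
Rscript analysis/02_rate_maps.R
Rscript analysis/03_classification.R
Rscript analysis/04_frame_responses.R
Rscript analysis/05_coupling.R
Rscript analysis/06_population_stats.R
```

Output printed by the run (abridged):

```
Median split-half stability: 0.94
32/32 maps classified as grid cells; mean gridness of accepted maps 1.51.
ROT20: mean room-frame rotation 14.1 deg, mean shift 0.4 cm (n = 8)
ROT70: mean room-frame rotation 4 deg, mean shift 19.6 cm (n = 8)
SHIFT: mean room-frame rotation 0.1 deg, mean shift 9.6 cm (n = 8)
84 pairs; 100% with rotation difference < 5 deg; 75% with joint correlation > 0.7.
Control medians: rotation difference 14.4 deg vs 0.5 intact; joint correlation 0.2 vs 0.96 intact.
 manipulation n mean_rotation vector_length rao_level
        ROT20 8    14.0618547     0.9989751   p<0.001
        ROT70 8     3.9850562     0.9991578   p<0.001
        SHIFT 8     0.1404155     0.9994938   p<0.001
```

Reading these numbers: a platform-anchored population with a configured 6°
undershoot must rotate 20° − 6° = 14° in the room after ROT20 (measured
14.1°, with negligible phase shift), and 70° − 6° = 64° ≡ +4° after ROT70
(measured 4.0°). In SHIFT the grids move with the platform, so the
platform-centered maps show no rotation and small shifts. Pairs rotate
together (rotation differences < 5°, joint correlations near 1), and
randomly perturbing each pair's alignment destroys both measures — the
control medians. The circular statistics reject uniformity of every
rotation sample (Rao p < 0.001) with mean vector lengths ≈ 1.

The same functions run on real data via `load_day()` over a YAML manifest
pointing at tracking and spike CSVs (see `?read_tracking`, `?read_spikes`,
`?run_day`).

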