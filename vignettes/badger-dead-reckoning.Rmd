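---
title: "GPS-enabled dead-reckoning of badger movement: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GPS-enabled dead-reckoning of badger movement: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Hourly GPS fixes describe a nocturnal, semi-fossorial animal like the
European badger (*Meles meles*) as a handful of points joined by straight
lines. Everything between the fixes — the tortuosity of foraging paths,
time spent working along a hedgerow, repeated use of a corridor — is
invisible. Collar-mounted tri-axial accelerometers and magnetometers
sample orientation and body dynamics hundreds of times per second, and
dead-reckoning turns those streams into a continuous track: per time step
a speed estimate is laid along a compass heading and the steps are summed
from an anchor point. Uncorrected, such tracks drift; anchored to sparse
GPS fixes, they combine the absolute accuracy of GPS with the resolution
of the motion sensors.

`badgerdr` implements this pipeline end to end for badger-style data —
40 Hz acceleration and magnetometry, 7 Hz collar temperature, hourly
fixes between 21:00 and 04:00 — together with the downstream space-use
analyses (nightly path lengths, MCP95/KD95 home ranges, habitat-proximity
time budgets) and the statistical comparisons between GPS-only and
dead-reckoned estimates. Because no raw collar data of this kind are
publicly deposited, the package carries a first-class synthetic-data
module: every stage can be exercised, and its error quantified, against a
simulated badger whose true track is known exactly.

# Sensor models

## VeDBA as a speed proxy

Raw acceleration is split into a *static* component (gravity, posture) —
a centred running mean per axis — and a *dynamic* remainder. The vector
magnitude of the dynamic triplets is VeDBA (vectorial dynamic body
acceleration), which scales approximately linearly with locomotion speed:
`speed = max(0, m * VeDBA + c)`. The gradient `m` (m s⁻¹ per g) is not
assumed: a nominal value starts the integration and `m` is then rescaled
so the dead-reckoned displacement between consecutive GPS fixes matches
the GPS-derived displacement in the least-squares sense over the night's
segments. The intercept `c` defaults to 0 (only a gradient is
calibrated); both are exposed.

The static window is 2 s (81 samples at 40 Hz), the common biologging
convention: long against the 2–8 Hz locomotor band, short against
postural change. A test verifies that a sinusoid spanning an integer
number of periods of the window averages out to below 1e-6.

## Tilt-compensated heading

Body axes are x forward, y left, z up; a level, motionless collar reads
(0, 0, 1) g. Pitch and roll are estimated from the normalised static
vector (`pitch = asin(sx)`, `roll = atan2(sy, sz)`), the magnetometer
triplet is de-rotated into the horizontal plane, and heading is the angle
of the horizontal field clockwise from magnetic north, in [0, 360). Under
this frame a collar facing east carries magnetic north on its **+y**
(left) side. The convention is exercised by a round-trip test: an
explicit rotation matrix (yaw 137°, pitch 20°, roll 10°) applied to a
fixed Earth field is inverted to within 0.1°. Heading is invariant to
uniform magnetometer scaling, so no intensity calibration is required; a
hard/soft-iron hook (3×3 matrix plus offset) is available for real
collars. Declination defaults to 0 (magnetic = geographic north), as no
declination correction is part of the method.

## Sett occupancy

Underground, movement is restricted by the sett tunnels and VeDBA drops
from the active ~0.25 g to below 0.1 g; the sett is also warmer than the
night air, so collar temperature climbs by about 4 °C within ~30 min of
entry. Detection is VeDBA-led (the temperature sensor lags): a
below-ground bout is a maximal run of 30 s-smoothed VeDBA below 0.1 g
lasting at least 5 min. Sub-minimum quiet runs are ordinary above-ground
rests and do not qualify; brief active pops inside a long quiet spell are
merged into the surrounding bout. This directional rule is deliberate: at
realistic nightly travel rates the *mean* above-ground VeDBA sits near
the threshold, so any symmetric majority-vote merging of short runs is
unstable, while "sustained quiet only" cleanly separates sett occupancy
(hours of quiet) from resting (tens of seconds). Each below-ground bout
is tagged with corroborating evidence (`both`) when the temperature rises
by ≥ 3 °C within 30 min of entry, and detection degrades gracefully to
VeDBA-only when temperature is missing.

# Dead-reckoning and correction

Per above-ground bout: speed from the calibrated model is integrated
along heading in the projected plane (UTM 29N by default; at sub-10-km
scales projection distortion is far below GPS error). Below-ground
samples contribute zero displacement. The residual between each
time-matched fix and the dead-reckoned position is then interpolated
linearly in time across each inter-fix segment and added to the track —
the simplest current-style correction that passes through every fix
(anchoring error ~1e-9 m) while preserving the dead-reckoned turn
structure between fixes. Before the first and after the last fix the
nearest residual is carried flat. Bouts without any usable fix are
translated to continue from the previous bout's endpoint and the track is
tagged `dead_reckoned_unanchored` when no bout had a fix.

Calibration fits one global gradient per bout (the method alters "the"
gradient, not one per segment); with a zero intercept each inter-fix
displacement is exactly linear in `m`, so the iteration converges in one
update and the loop (tolerance 1e-4, cap 50) only guards clamped or
non-zero-intercept configurations. All-zero VeDBA against non-zero GPS
displacement raises a calibration error rather than returning a
meaningless gradient.

# Space use

*Path length* sums WGS84 ellipsoidal geodesics between consecutive
coordinates (via `geosphere::distGeo`; an independent hand-written
haversine agrees within 0.5% at < 50 km). *Trimming* removes the
outermost 5% of locations by distance from the centroid — the canonical
MCP95 convention; the same trimmed set feeds the kernel estimate so
GPS/DR comparisons are like-for-like. *MCP95* is the convex hull of the
trimmed points (shoelace area, km²). *KD95* is a binned bivariate
Gaussian kernel density on a 200×200 grid padded by 4 bandwidths, with
the volume contour enclosing 95% of the integrated mass, polygonised via
`contourLines`; the default bandwidth is the reference rule
`h = σ̂ n^(-1/6)` (σ̂ = mean marginal SD), and fixed bandwidths are
accepted. Grid-doubling changes areas by under 2%, and the mass inside
the contour is verified to sit in [0.945, 0.955].

With 40 Hz dead-reckoned input the reference rule shrinks `h` by
`n^(-1/6)`, tightening the kernel estimate around genuinely used
corridors — this, not any change in the estimator, is why kernel ranges
come out smaller for dead-reckoned than for sparse GPS data while convex
polygons come out larger (the dead-reckoned track visits hull-expanding
excursions between fixes).

*Proximity budgets*: a position is within a feature class when it lies
≤ 20 m from any polygon of that class (inside = 0 m). Distances are
computed exactly (point-in-polygon plus point-to-segment), which is
equivalent to testing against dissolved per-class buffers, so stacked
hedges never double-count. Classes are non-exclusive — a point in a field
15 m from a hedge counts towards both — so proportions need not sum to 1.
Time weighting follows the sampling regime: 1/40 s per dead-reckoned
position, 1 h per hourly GPS fix. Missing (withheld) fixes contribute no
time anywhere; this under-counts GPS-side totals on nights with
underground gaps and is a documented limitation of the hourly-fix
regime, not of the estimator.

# The synthetic badger

The generator is the package's ground truth and its defaults are the
study conditions; they were fixed from the field regime before any
end-to-end results were inspected and are not tuned per run:

* **Schedule**: nights simulated 20:00–05:00; emergence ≈ 20:50 and
  return ≈ 03:45 (±15 min), with a mid-night below-ground bout (~25 min)
  on 70% of nights. GPS hourly 21:00–04:00, σ = 10 m per axis, fixes
  withheld underground (no sky view in the sett).
* **Behaviour**: a three-state chain (stationary / forage / travel) with
  mean dwells of 40/70/40 s. Speeds 0, 0.26 and 0.44 m s⁻¹ (with 25%
  second-to-second variation) give nightly true paths of ~4–5.5 km and
  make locomotion the majority of above-ground time — badgers emerge to
  forage — so the VeDBA stream is bimodal around the 0.1 g occupancy
  threshold rather than hovering at it.
* **Heading**: a wrapped-normal random walk (σ = 0.5° per 40 Hz sample,
  decorrelating over ~5 min) produces tortuosity in the regime where
  dead-reckoned paths are 2–3× the GPS polyline. While the animal is not
  locomoting the *collar* heading wanders much faster (σ = 6° per
  sample): head movement during grooming and on-the-spot foraging points
  the collar nowhere in particular, so resting VeDBA carries no coherent
  travel direction. Without this, resting noise integrates along the last
  travel heading and biases the gradient calibration low.
* **Speed~VeDBA truth**: m = 2.0 m s⁻¹ per g, c = 0. Target VeDBA is
  `(speed − c)/m` plus context noise: a small positive floor underground
  (0.005 g + |N(0, 0.008)|, restricted movement) and at rest above ground
  (0.01 g + |N(0, 0.012)|, fidgeting), zero-mean jitter (SD 0.02 g) while
  moving. Dynamic acceleration is 2–8 Hz band-limited vector noise scaled
  per sample to that magnitude; gravity is rotated by slowly varying
  pitch/roll (±15° bound, 5° posture offset). The magnetometer sees a
  fixed Earth field at 67° inclination (Irish latitudes), rotated by the
  full collar orientation.
* **Temperature**: ambient 8 °C; below ground the 7 Hz channel relaxes
  first-order towards ambient + 4 °C with τ = 600 s, so the recorded
  change over 30 min is ≈ the full offset. The channel is held
  sample-and-hold on the 40 Hz grid with validity flags.
* **Landscape**: a 5×5 grid of 160 m fields separated by 4 m hedge
  strips, one road and one building beyond the eastern edge; the sett at
  the centre and the track confined to the block by reflection. Geometry
  is deterministic per configuration and serialises to GeoJSON
  (WGS84 coordinates, projected CRS recorded in properties).

What the generator does **not** emulate: sett-homing at dawn (the animal
simply stops where it is), social interactions between the two simulated
animals, terrain and elevation, GPS fix failure above ground,
magnetometer distortion, diurnal temperature cycles. Passing tests
therefore demonstrate the pipeline's internal consistency and its error
behaviour under known noise — not field performance on real collars,
where hard/soft-iron effects and behaviour-dependent VeDBA–speed
relations add error sources the hooks (`calibration`, per-bout models)
are designed to absorb.

# Numerical choices and degenerate inputs

* Sub-seeds for each animal-night and stage are derived deterministically
  from one root seed, so any night can be regenerated in isolation and
  whole studies are bit-reproducible.
* Reflection at the landscape boundary re-derives per-sample speed and
  heading from the realised positions, so the published invariant —
  positions equal the cumulative integral of speed·Δt along heading —
  holds to machine precision even at folded steps.
* The running mean shrinks its window symmetrically at record edges (no
  NA padding); the static filter rejects windows longer than the record.
* Zero static magnitude flags the sample and interpolates heading from
  neighbours; all-identical points flag degenerate home ranges; collinear
  points give a zero-area MCP with a `degenerate` flag rather than an
  error; hedge width 0 degrades to 1 m strips with a warning.
* Paired/Welch tests with zero-variance input return explicit
  infinite-statistic degenerate results (p → 0) or t = 0, p = 1 for
  identical series, instead of erroring mid-pipeline.
* The KDE threshold is the smallest density whose superlevel set holds
  95% of the mass; contour rings are closed if they terminate on the
  (padded) grid boundary, and even-odd ring nesting subtracts holes.

# Problem sizes

The default study — 2 animals × 7 nights × 9 h at 40 Hz (~1.3 M samples
per night) — runs in a few minutes on one core, and the test suite
exercises the full study once plus 20 single-night calibration
replicates. Unit tests use a 2.5 h night with half-hourly fixes, which
preserves every code path at a fraction of the cost.

# Known limitations

* The speed~VeDBA relation is linear with a global per-bout gradient;
  gait-dependent (state-specific) gradients are not fitted, matching the
  method being reproduced. Per-segment overrides exist in the model
  object but are not used by the default pipeline.
* GPS error is modelled as isotropic Gaussian without fix-to-fix
  correlation or terrain-dependent degradation.
* The land-use models treat badger-nights as independent observations
  (no random effects), and the four per-class paired comparisons carry no
  multiple-testing correction — both deliberate matches to the analysis
  being reproduced, noted here as caveats.
* Proximity proportions for GPS tracks rest on the "1 h per fix"
  assumption; with withheld fixes the GPS-side denominators shrink.
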