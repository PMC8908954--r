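# badgerdr

GPS-enabled dead-reckoning of European badger (*Meles meles*) movement
from collar sensor streams, with the space-use and statistical analyses
that compare what hourly GPS alone sees against what the reconstructed
40 Hz track reveals.

## The problem

A nocturnal, semi-fossorial animal tracked with hourly GPS fixes is
reduced to a handful of points joined by straight lines; the tortuous
foraging paths, hedgerow-following and core-area use between fixes are
invisible. Collar accelerometers and magnetometers sample 40 times per
second, and *dead-reckoning* integrates them into a continuous track:

* **Speed proxy** — VeDBA (vectorial dynamic body acceleration), the
  magnitude of the gravity-removed acceleration vector, mapped to speed
  by `v = max(0, m · VeDBA + c)`;
* **Heading** — tilt-compensated compass bearing: pitch/roll from the
  static (gravity) acceleration, magnetometer de-rotated to the
  horizontal, heading clockwise from north;
* **Integration** — per 1/40 s step, displacement `v·Δt` along the
  heading, summed in the projected plane (UTM 29N);
* **GPS anchoring** — the gradient `m` is calibrated so dead-reckoned
  displacements between consecutive fixes match the GPS displacements
  (least squares per night), then the residual at each fix is
  distributed linearly over the inter-fix samples so the track passes
  through every fix exactly while keeping its turn structure.

Around that core: sett-occupancy detection (VeDBA collapses below
0.1 g underground while collar temperature rises ~4 °C within 30 min),
per-night geodesic path lengths, MCP95 and KD95 home ranges, 20 m
habitat-proximity time budgets over a field/hedge/building/road
landscape, and paired-t / Welch-t / Tukey-HSD comparisons.

Because no raw collar data of this kind are publicly deposited, the
package includes a first-class synthetic-data module: a seeded
ground-truth badger (correlated random walk with behavioural states and
below-ground bouts) from which sensor streams, GPS fixes and the
landscape are generated with known parameters, so every pipeline stage
is testable against truth.

## Worked example

```r
library(badgerdr)

cfg <- study_config(seed = 1)          # 2 badgers x 7 nights, hourly GPS
night <- simulate_night(cfg, animal = 1, night = 1)
an <- analyse_night(night$stream, night$fixes, cfg,
                    landscape = generate_landscape(cfg$sim),
                    truth = night$truth)
an$metrics
#>   animal night n_fixes  above_h path_km_dr path_km_gps m_fitted anchor_max_m
#> 1      1     1       7 6.655100   4.760365    1.896074 1.963013            0
#>   dr_rmse_m gps_interp_rmse_m sett_agreement true_path_km
#> 1  13.22691          117.2167      0.9901794     4.461598
```

One night, read off the row: the badger was above ground 6.66 h and
truly walked 4.46 km. The dead-reckoned track measures 4.76 km against
1.90 km for the straight-line GPS polyline; the calibrated speed~VeDBA
gradient (1.96) recovers the generating value of 2.0; the corrected
track sits 13 m RMS from the truth where GPS interpolation is off by
117 m; and sett-occupancy detection agrees with the generating mask on
99.0% of samples.

The full study and its statistics:

```r
st <- run_study(study_config(seed = 1))
st
#> <badger_study> 14 badger-night(s)
#>   path length (km): DR 4.82 +/- 0.57, GPS 1.69 +/- 0.45 (ratio 2.84)
#>   MCP95 (km^2): DR 0.651, GPS 0.474
#>   KD95 (km^2): DR 0.514, GPS 0.921
st$tests$path_paired
#> <badger_test> paired t-test: t = 22.85, df = 13, p = 7.045e-12
```

The three qualitative signatures of GPS-enabled dead-reckoning all
appear: nightly paths are ~2.8× the GPS polyline (the tortuosity GPS
cannot see), kernel (KD95) home ranges shrink (dense 40 Hz points
tighten the kernel estimate onto genuinely used corridors) while convex
polygons (MCP95) grow (the track explores beyond the fixes), and the
land-use models rank fields first and hedges second with buildings and
roads far behind.

## The analysis workflow

The numbered drivers under `analysis/` run the file-based version of
the same study (bulky raw bundles under `scratch/`, tables under
`results/`):

```sh
Rscript analysis/01_simulate.R        # sensor CSVs, GPS CSV/GPX, landscape GeoJSON
Rscript analysis/02_sett_use.R        # occupancy bouts per night
Rscript analysis/03_dead_reckoning.R  # tracks, path lengths, home ranges, proximity
Rscript analysis/04_stats.R           # paired/Welch tests, land-use models + Tukey
```

`BADGERDR_SEED` overrides the root seed. See
`vignettes/badger-dead-reckoning.Rmd` for the models, parameter
defaults and the design decisions behind them.

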