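# ivpharm

Semi-automated single-cell pharmacokinetics from intravital fluorescence
microscopy.

Intravital imaging of fluorophore-labeled drugs can resolve, cell by
cell, how much drug reaches tumor nuclei in a living animal. Turning such
movies into numbers is hard: cell fields are dense and multi-layered,
nuclear brightness varies several-fold within one frame, and both the
animal and the cells move. `ivpharm` is an R package for analysts of such
data. It segments the nuclear-marker channel, converts per-cell drug
fluorescence to concentration through a dilution-series calibration line,
and links cells across frames into identity-preserving tracks — with a
fully ground-truthed synthetic movie generator so every stage is
verifiable without animal data.

## What is inside

* **Thresholding** — Otsu (between-class variance), Huang (minimal
  fuzziness entropy), and an iterative *locally-adaptive* thresholder
  that refines a per-pixel surface `T(x, y)` from windowed class
  statistics: `T = (w_F m_F + w_B m_B)/(w_F + w_B)` with
  `w_F = f^power`, `w_B = (1-f)^power`, where `f`, `m_F`, `m_B` are the
  local foreground fraction and class means, smoothed each iteration and
  stopped when the mean surface change drops below `epsilon`. Local
  adaptation recovers dim nuclei that any single global threshold must
  sacrifice.
* **Segmentation** — gamma adjustment, thresholding, rough-pass speckle
  removal (disk opening), 8-connected labeling with centroids/borders,
  size filtering; per-frame, per-Z-slice, and scriptable preview
  overlays.
* **Quality metrics** — misclassification error
  `ME = 1 - (|B_o∩B_T| + |F_o∩F_T|)/(|B_o|+|F_o|)`, region-number
  nonuniformity `TRNU = |R_T - R_o|/R_o`, variance nonuniformity
  `VNU = |σ_T - σ_M|/σ_M`, with Friedman rank-sums and gated pairwise
  Wilcoxon tests across methods and images.
* **Pharmacokinetics** — OLS calibration (fluorescence → µM), per-cell
  nuclear concentration time courses with per-frame mean ± SD, vessel-ROI
  input curves, subtherapeutic fractions (default threshold 1.5 µM),
  nuclear-vs-cytosol partitioning via a dilated ring, and closed-form
  one-compartment uptake fitting (`dC/dt = k_in C_v - k_out C`).
* **Tracking** — optimal one-to-one frame linking (shortest augmenting
  path) within a search radius (default 10 px), plus CSV export for
  external linkers.
* **Synthetic data** — seeded, bit-reproducible two-channel movies and
  Z-stacks with exact per-cell ground truth (positions, masks,
  concentration curves, vessel kinetics, drift).

## Worked example

```r
library(ivpharm)

spec <- scene_spec(n_frames = 30, seed = 1)        # 50 cells, 256 px field
mv <- generate_movie(spec)
mv$stack
#> ChannelStack: 2 channel(s) [nuclear, drug] x 30 frame(s), 256x256 px, axis=time

seg    <- segment_stack(mv$stack, segmentation_params(), "nuclear")
curve  <- calibration_curve(spec$calibration$slope, spec$calibration$intercept)
series <- cell_concentrations(seg$frames, mv$stack, "drug", curve)
series$per_frame[c(1, 10, 20, 30), c("frame", "time_s", "n_cells", "mean_uM", "sd_uM")]
#>    frame time_s n_cells     mean_uM       sd_uM
#> 1      1      0      50 0.001749234 0.009475107
#> 10    10    675      48 1.021025750 0.087817807
#> 20    20   1425      46 1.753270344 0.152049274
#> 30    30   2175      47 2.182523515 0.190573032

vessel <- vessel_curve(mv$stack, "drug", mv$truth$vessel_roi, curve)
vfit <- fit_vessel_decay(vessel$time_s, vessel$vessel_uM)
ufit <- fit_uptake(series$per_frame$time_s, series$per_frame$mean_uM,
                   vfit$peak, vfit$k_decay)
#> vessel fit: peak 10.00 uM, k_decay 5.552e-04 /s
#> uptake fit: k_in 1.842e-04 /s (true 2.0e-04), k_out 4.775e-05 /s (true 5.0e-05)

tracks <- attach_concentrations(
  link_tracks(regions_to_detections(seg$frames), max_radius = 10), series)
length(unique(tracks$track_id))
#> [1] 53

nuclear_fraction(seg$frames[[30]], get_frame(mv$stack, "drug", 30), ring_radius = 5)
#> [1] 0.8040515
```

Reading the numbers: nearly all of the 50 simulated nuclei are segmented
in every frame; the mean nuclear concentration rises from 0 towards its
plateau as the vessel bolus decays; the re-fitted uptake/efflux constants
land within ~10 % of the generating values from a 30-frame movie (a
100-frame movie brings them within ~2 %); 53 tracks for 50 cells reflects
a few track restarts where a detection was briefly lost; and ~80 % of the
cellular drug signal sits in the nuclear compartment in this simulation,
the remainder being ring background.

Batch processing uses `run_config()` + `run_pipeline()` (regions,
per-frame, per-cell and track CSVs, 16-bit label maps, JSON manifest, log)
or the `inst/cli/ivpharm` command-line front-end
(`simulate`, `preview`, `threshold`, `segment`, `evaluate`, `track`,
`run`).

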