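# mitomotion

Quantification of mitochondrial motility and morphology in time-lapse
fluorescence microscopy of neuronal tissue.

## The problem

In live-imaged brain-slice cultures, neuronal mitochondria appear as
small elongated fluorescent blobs (≈ 0.2–5 µm²).  Most are stationary; a
minority moves along neurites at ≈ 0.2–0.3 µm/s.  Oxidative stress and
neuroprotective drugs change both the organelles' shape and the fraction
that moves, so a typical experiment compares several treatment
conditions, each imaged as a set of 2-minute sequences (31 frames, one
every 4 s, ≈ 0.2 µm/px).

`mitomotion` is a semi-automated analysis pipeline for such data:

* **registration** — translation-only drift correction of each stack
  (phase correlation + robust masked Gauss–Newton refinement);
* **detection** — per-frame Laplacian-of-Gaussian spot detection at a
  nominal blob diameter *d* (default 1.5 µm), quality-thresholded, with
  sub-pixel localization;
* **tracking** — exact optimal frame-to-frame assignment with a hard
  link radius (default 2 µm), no gap closing; per-track displacement
  ‖x_last − x_first‖ and mean speed (path length / duration); a track is
  *motile* when its displacement exceeds 1.5 µm;
* **morphometry** — first-frame segmentation and per-particle area,
  Feret (caliper) diameter and moment-ellipse aspect ratio, gated to
  [0.2, 5] µm²;
* **metrics** — per-ROI summaries including the *motile fraction*
  (motile tracks / segmented particles);
* **stats** — tie-corrected Kruskal–Wallis
  H = [12/(N(N+1)) Σ nᵢR̄ᵢ² − 3(N+1)] / (1 − Σ(t³−t)/(N³−N)),
  then Dunn's post hoc z on preselected condition pairs with Bonferroni
  over those pairs only; star tiers \*, \*\*, \*\*\*, \*\*\*\*;
* **simulator** — a synthetic-movie generator with exact ground truth
  (blob shapes, trajectories, drift, bleaching, noise), used to validate
  every stage end to end.

## Worked example

Simulate one ROI in the default acquisition regime (31 frames / 4 s /
0.2 µm/px, 40 mitochondria, 30 % motile at 0.25 µm/s, SNR 10) and run
the full pipeline on it:

```r
library(mitomotion)

scene <- scene_config(seed = 7)
sim   <- simulate_movie(scene)
cfg   <- scene_matched_config(scene)   # thresholds on the scene's intensity scale
res   <- run_roi(sim$movie, cfg, roi_id = "dg_roi_01",
                 condition = "neg_ctrl", verbose = TRUE)
#> [dg_roi_01] drift corrected: max |offset| 0.29 px
#> [dg_roi_01] detected 1240 spots over 31 frame(s) (40.0/frame)
#> [dg_roi_01] 40 tracks, 12 motile (displacement > 1.5 um)
#> [dg_roi_01] 40 particles gated in, 3 components excluded by the 0.2-5 um^2 gate

res$summary[, c("n_particles", "n_motile_tracks", "motile_fraction",
                "mean_area_um2", "mean_feret_um", "mean_aspect_ratio")]
#>   n_particles n_motile_tracks motile_fraction mean_area_um2 mean_feret_um mean_aspect_ratio
#> 1          40              12             0.3          0.99      1.882826          2.366807
```

All 40 simulated mitochondria were detected in every frame (detection
F1 = 1.000 against the ground truth), the 12 truly motile blobs were the
12 motile tracks, and the recovered motile fraction 0.30 equals the
generated one.  Mean area (0.99 µm²) and Feret diameter (1.88 µm) are
the averages over the 40 gated first-frame particles, in the range
typical of neuronal mitochondria.

A multi-condition study runs from a manifest (`path, roi_id, condition`)
with `run_batch()`, which writes per-ROI CSVs (`spots.csv`, `tracks.csv`,
`morphology.csv`, `drift.csv`, a JSON run manifest) plus combined
`roi_summary.csv` and `stats.csv` with one row per metric and
preselected pair (z, raw and adjusted p, significance tier).

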