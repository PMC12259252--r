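# mcctrack

Quantification of mucociliary clearance (MCC) from fluorescent-bead
tracking, for researchers running the ex vivo bead-transport assay on
airway epithelium (and for validating its analysis chain on simulated
data). In the assay, fluorescent beads are applied to the opened luminal
surface of an isolated trachea and imaged by time-lapse confocal
microscopy (136 ms intervals, 258.33 × 64.20 μm field, 300–600 beads per
recording). A healthy epithelium transports beads fast and coherently;
an injured one produces slow, erratic, spatially inconsistent motion.

The package provides, end to end:

* a **ground-truthed simulator** of bead transport (patchwise advection +
  Brownian diffusion, detection dropout, frame rendering with a Gaussian
  PSF) whose coherent vs. erratic regimes emulate healthy vs. injured
  epithelium;
* **spot detection** (difference-of-Gaussians, robust MAD threshold,
  sub-pixel centroids) and **frame-to-frame linking** (gated
  minimum-squared-displacement assignment, no gap closing), plus
  TrackMate-compatible CSV import/export;
* the two **transport statistics** under the assay's sampling protocol.
  For each selected bead, a 7-frame window (6 intervals = 0.816 s) gives
  the displacement α, path length β and trajectory vector φ:

  * traveling linearity = α / β ∈ [0, 1] (per bead; 1 = perfectly straight),
  * directional uniformity = |Φ| / mean(|φᵢ|) ∈ [0, 1], with Φ the mean of
    the 10 selected beads' trajectory vectors (per recording; 1 = all
    beads co-directional).

  Tracks need more than 6 continuous inter-frame intervals to be
  eligible; 10 eligible beads are selected at random (seeded); two
  recordings are averaged per animal;
* **confocal morphometry**: per-cell cilia height (junction plane to the
  top of the cilia-marker signal), ciliated-surface fraction along an
  epithelial trace, positive-area fraction of projection images,
  positive-cell density per 40,000 μm² reference area, and rectangular-ROI
  total flux;
* **group comparison** (Student's t / one-way ANOVA + Tukey HSD) and a
  reproducible `run_pipeline()` with config files, manifests and logs.

## Worked example

```r
library(mcctrack)

flow  <- flow_field_spec(patch_direction_sd = 0.1)   # coherent "healthy" flow
acq   <- acquisition_spec(seed = 42)                 # protocol defaults
truth <- simulate_tracks(flow, acq)                  # ground-truth trajectories

det    <- truth_detections(truth)                    # detection table
tracks <- link_detections(det, max_disp = 4)         # frame-to-frame linking

sel   <- selection_spec(seed = 42)                   # >6 intervals, pick 10
beads <- select_beads(eligible_tracks(tracks, sel), sel)
record_metrics(beads, record_id = "trachea1_rec1")
#> Recording trachea1_rec1 - 10 beads
#>   directional uniformity: 0.9841
#>   traveling linearity: mean 0.904 range 0.643-0.996
```

A uniformity of 0.98 means the 10 sampled beads moved almost perfectly
co-directionally, and the mean linearity of 0.90 means their 0.816 s
paths were nearly straight — the signature of intact mucociliary
transport. The full two-group demo study (3 animals × 2 recordings per
group) runs in seconds:

```r
res <- run_pipeline(default_config(seed = 42), "demo_out")
res$comparisons$uniformity
#> Two-tailed Student's t test: t = 4.786 , p = 0.008738 (significant at 0.05)
#> Group means:
#> healthy injured
#>  0.9835  0.5244
```

The injured configuration (erratic patchwork flow) roughly halves
directional uniformity, and the per-animal comparison flags the
difference. `demo_out/` then contains `per_bead.csv`, `per_record.csv`,
`per_animal.csv`, `comparisons.csv`, a JSON manifest and a stage log;
re-running with the same config reproduces them byte-for-byte.

A thin CLI wraps the same functions:

```sh
exec/mcctrack run --seed 42 --out-dir demo_out
exec/mcctrack metrics --tracks exported_tracks.csv --seed 1
```

## Documentation

`vignettes/mcc-quantification.Rmd` describes the transport statistics and
their edge cases, the simulator's model and defaults, the detection and
linking algorithms, the morphometry procedures, and known limitations.
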