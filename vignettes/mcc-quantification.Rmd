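---
title: "Quantifying mucociliary transport from bead tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mucociliary transport from bead tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcctrack)
```

## The measurement problem

Mucociliary clearance (MCC) — the directed transport of mucus and entrapped
particles along the airway surface by coordinated ciliary beating — is
routinely assayed ex vivo by dropping fluorescent beads onto the opened
luminal surface of an isolated trachea and recording their motion by
time-lapse confocal microscopy. A healthy epithelium moves beads rapidly
and coherently in one direction; an injured epithelium produces slow,
erratic, spatially inconsistent motion. `mcctrack` implements the full
quantification chain for this assay: a ground-truthed simulator of bead
transport, spot detection and frame-to-frame linking, the two transport
statistics (traveling linearity and directional uniformity) computed under
the assay's sampling protocol, the accompanying confocal morphometry
measurements, and group-comparison reporting.

## The transport statistics

Each analysed bead contributes a seven-frame window (6 inter-frame
intervals; at the protocol's 136 ms interval this spans exactly 0.816 s).
Writing $p_0,\dots,p_6$ for the window positions:

* displacement $\alpha = \lVert p_6 - p_0 \rVert$ (straight-line distance),
* path length $\beta = \sum_{t=1}^{6} \lVert p_t - p_{t-1} \rVert$,
* trajectory vector $\varphi = p_6 - p_0$ (so $|\varphi| = \alpha$).

**Traveling linearity** is the per-bead ratio $\alpha/\beta \in [0,1]$: 1
for perfectly straight motion, small for wandering or oscillating motion.
By the triangle inequality $\alpha \le \beta$ always, with equality exactly
when every segment points along the net displacement.

**Directional uniformity** is a per-recording statistic over the $n$
selected beads (10 under the protocol):

$$ U = \frac{\lVert \tfrac1n \sum_i \varphi_i \rVert}{\tfrac1n \sum_i \lVert \varphi_i \rVert} \in [0,1], $$

the length of the mean trajectory vector $\Phi$ over the mean trajectory
length. $U = 1$ iff all beads move in one direction; exact cancellation
gives 0. $U$ is invariant under global rotation and global positive
rescaling of the $\varphi_i$ — it measures directional coherence only. It
is the vector order parameter familiar from collective-motion analysis,
applied to per-bead displacement vectors.

The sampling protocol is part of the definition: per recording, 300–600
beads are detected in a 258.33 × 64.20 μm field, tracks with more than 6
continuous inter-frame intervals (≥ 7 consecutive frame observations) are
eligible, and 10 eligible beads are selected uniformly at random
(seeded here, so selections are reproducible). Two recordings are made per
animal; the animal-level uniformity is the unweighted mean of the two
record uniformities, and per-bead linearities are kept both per record and
pooled per animal so either plotting convention can be used.

### Numerical edge cases

* A perfectly stationary bead has $\beta = 0$ and an undefined ratio. Such
  beads are excluded from both statistics, with the exclusion counted,
  messaged, and reported in the output tables (`n_excluded`) — exclusion is
  conservative and auditable, whereas assigning 0 would silently distort
  the record mean. A record needs at least 2 usable beads.
* $U$ is clipped to $[0,1]$ only to absorb representational round-off
  (≤ 1e−12), never to mask a logic error.
* For tracks longer than 7 frames, the window is the **first** 7 frames of
  the longest consecutive run: the earliest-window rule is deterministic
  and avoids biasing selection toward fast late segments.

## The simulator and what it emulates

`simulate_tracks()` generates trajectories under patchwise advection plus
Brownian diffusion:

$$ x_{t+1} = x_t + v(x_t)\,\Delta t + \eta_t, \qquad
   \eta_t \sim \mathcal N(0,\, 2D\,\Delta t\, I), $$

where the advective speed is `base_speed` (zero for an `immobile_fraction`
of beads, emulating beads trapped in static mucus) and the direction is
the fixed direction of the square flow patch containing the bead plus
per-step jitter $\mathcal N(0, \texttt{angular\_jitter\_sd})$. Patch
directions are drawn once per simulation around `base_direction` with
spread `patch_direction_sd`; `patch_direction_sd ≈ 0` reproduces the
coherent transport of a healthy epithelium, large values the spatially
heterogeneous, erratic transport over an injured one. Fixed square patches
(rather than a continuous random vector field) are the simplest structure
that reproduces erratic, spatially inconsistent flow while admitting exact
ground truth. Beads that leave the field are censored (invisible
thereafter, as in open-field imaging, not reflected); each visible bead is
additionally hidden i.i.d. per frame with `dropout_prob`, which is what
breaks tracks and exercises the continuous-frames eligibility filter.

Default parameter choices (all geometry in μm, time in s):

| parameter | default | rationale |
|---|---|---|
| `frame_interval` | 0.136 s | the recording protocol |
| field | 258.33 × 64.20 μm | the recording protocol |
| `n_beads` | drawn uniformly in [300, 600] | the protocol's per-record detection count |
| `base_speed` | 15 μm/s (healthy), 8 (injured demo) | ex vivo tracheal bead transport is of order 1 mm/min; gives several-μm displacements per 0.816 s window |
| `diffusion_coeff` | 0.2 μm²/s | hindered Brownian motion of a 0.5 μm bead in mucus (free-water D ≈ 0.9 μm²/s, reduced by mucus viscosity) |
| `patch_direction_sd` | 0.1 rad (healthy) / 1.5 (injured demo) | near-coherent vs. effectively random patch directions |
| `dropout_prob` | 0.1 | enough broken tracks to exercise eligibility while keeping ≥ 10 eligible beads per record |
| `localization_noise_sd` | 0.05 μm | sub-pixel centroid accuracy at 0.2523 μm/px |
| `psf_sigma` | 0.4 μm | slightly above the diffraction limit for a 0.5 μm bead at ×20 |

All randomness flows from one integer seed through named sub-streams
(patch layout, motion, dropout, rendering, selection), so each component
is independently reproducible and identical seeds give bit-identical
output.

The simulator targets the *statistical structure* of recorded
trajectories only. It does not model hydrodynamic coupling between beads,
mucus rheology, metachronal wave structure, or cilia beat frequency; nor
correlated blinking, uneven illumination, or motion blur. Passing tests
therefore certify the measurement chain (detection, linking, windowing,
statistics) against a known transport field — they do not certify detector
performance on real image artefacts.

## Detection and linking

`detect_beads()` mirrors standard particle-tracking spot detection:
difference-of-Gaussians band-pass (centre sigma = expected spot sigma,
surround = 2×), strict 8-neighbourhood local maxima, a robust threshold
(median + k × scaled MAD of the filtered frame, so the threshold is
invariant to background level), and sub-pixel localization by
intensity-weighted centroid over a $(2\lceil\sigma_{px}\rceil+1)^2$
window.

`link_detections()` performs frame-to-frame linking with no gap closing,
splitting, or merging. Per consecutive frame pair it minimizes the total
squared displacement over one-to-one assignments among pairs closer than
`max_disp`, with "leave unmatched" available at cost `max_disp²/2` per
endpoint; this is solved exactly as a maximum-weight bipartite matching
with weight `max_disp² − d²` per admissible pair. A broken detection
therefore ends its track and starts a new one — deliberately, because the
eligibility rule ("continuous frames") is defined on unbroken tracks. The
published assays in this field use interactive trackers whose linking
parameters are rarely reported; this linker is a fully specified,
deterministic stand-in, validated against ground-truth identities on
fields satisfying a separation condition (minimum inter-bead distance
exceeding twice the largest per-frame displacement), where the assignment
is provably unambiguous.

## Morphometry

* **Cilia height** (`cilia_heights()`): per labelled cell footprint, the
  apical reference plane is the z-plane of maximal tight-junction signal;
  the ciliary top is the *highest* z-plane whose cilia-marker signal in
  the footprint exceeds the robust background threshold ("top of the
  signal", not an intensity centroid). Height is the difference, floored
  at 0 and quantized to the z-step. On noise-free synthetic volumes the
  recovery error is bounded by one z-step. Cell segmentation itself is out
  of scope: footprints come from the synthetic generator or user-supplied
  label masks.
* **Ciliated-surface fraction** (`ciliated_fraction()`): length-weighted
  share of ciliated segments along an epithelial polyline, invariant under
  re-parameterization.
* **Positive-area fraction** (`positive_area_fraction()`): share of pixels
  above median + k·MAD of the image. The median-based background estimate
  presumes the positive area is a minority (< 50%) of the image; at
  exactly half coverage the estimate sits between the modes and the
  measure degenerates — a documented limitation of relative thresholds.
  Manual absolute thresholds from interactive analysis are unreported in
  typical published workflows, which is why the configurable relative rule
  is used.
* **Positive-cell density** (`positive_cell_density()`): counts scaled to
  the 200 × 200 μm (40,000 μm²) reference area.
* **ROI total flux** (`roi_total_flux()` / `roi_flux_table()`): summed
  intensity in rectangular ROIs, with identical ROI dimensions enforced
  across any comparison set.

## Reporting

`compare_groups()` uses a two-tailed Student's t test (equal variances)
for two groups and one-way ANOVA with Tukey HSD all-pairs comparisons for
three or more, flagging significance at 0.05 (a presentation flag;
p-values are kept at full precision). Both per-animal and per-bead tables
are emitted so the unit-of-analysis choice is explicit. `run_pipeline()`
orchestrates simulate → detect/ingest → link → select → metrics → compare,
writes every table as CSV with units in the column names, and emits a
machine-readable manifest (config + seeds + version) plus a stage-level
log carrying per-stage seeds and exclusion counts, so every reported n is
auditable and any output is reproducible bit-for-bit from the manifest.

## Problem sizes used in the test-suite studies

The packaged studies run at desk scale, chosen to give stable Monte-Carlo
estimates: the linking audit uses 300 beads × 20 frames on a separated
grid; the coherence study uses the protocol's 300–600 beads over a
patch-spread grid with 12 replicates per level and 50 paired
healthy-vs-injured replicates; the brute-force uniformity oracle uses
10⁵ replicates (oracle) against 2×10⁴ (implementation). Morphometry
round-trips use 50–200 cells and 256² projections.

## Known limitations

* The linker is a stand-in for unreported interactive-tracker settings;
  with dense fields and fast flow (inter-bead spacing comparable to the
  per-frame displacement) mis-links occur, as they would for any gated
  nearest-assignment tracker.
* Directional uniformity from 10 beads is a high-variance estimator
  (sampling noise alone gives E[U] ≈ 0.28 for isotropic motion, not 0);
  comparisons should always be made against matched sampling, as the
  pipeline does.
* The morphometry validations are against synthetic ground truth; no
  claim is made of agreement with manual line-tool or interactive
  measurements on real tissue.
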