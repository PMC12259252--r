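Package: mcctrack
Title: Quantification of Mucociliary Clearance from Fluorescent Bead Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and quantification of mucociliary transport assays.
    Generates ground-truthed fluorescent-bead trajectories over ciliated
    epithelium, renders time-lapse image stacks, detects and links beads into
    tracks, and computes per-bead traveling linearity (net displacement over
    path length in a seven-frame window) and per-recording directional
    uniformity (length of the mean trajectory vector over the mean trajectory
    vector length). Also implements confocal morphometry measurements (per-cell
    cilia height from junction marker to cilia-marker top, ciliated-surface
    fraction along an epithelial trace, positive-area fraction on projections,
    positive-cell density per reference area, rectangular-ROI total flux) and
    group-comparison reporting with a reproducible run pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    yaml,
    jsonlite,
    tiff,
    EBImage,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
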