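Package: chromdyn
Title: Chromatin Mobility Analysis from Live-Cell Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of chromatin dynamics in live-cell
    time-lapse fluorescence microscopy. Detects sub-resolution chromatin
    foci with a spot-enhancing (Laplacian-of-Gaussian) filter, links them
    into trajectories with a Kalman-filter tracker using gated optimal
    assignment, computes mean-squared-displacement curves and fits the
    two-dimensional anomalous diffusion model MSD = 4*D*dt^alpha, groups
    trajectories by center-to-center distance to replication (PCNA) foci,
    converts DAPI intensity fractions of labeled foci to DNA base pairs
    with cell-cycle correction factors, computes coefficient-of-variation
    accumulation statistics, and performs high-content nuclei and foci
    analysis with EdU-based S-phase gating. A synthetic-data module
    simulates Brownian, fractional-Brownian, confined and static motion,
    and renders ground-truthed movies and population images, so every
    stage of the pipeline is testable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
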