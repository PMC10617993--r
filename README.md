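# chromdyn

Quantitative analysis of chromatin mobility in live-cell fluorescence
microscopy, for researchers studying chromatin dynamics through the cell
cycle and around DNA replication.

Replication-labeled chromatin domains appear as sub-resolution fluorescent
foci whose local diffusion reports the physical state of chromatin.
`chromdyn` implements the full measurement chain:

* **Detection** — spot-enhancing filter (Laplacian-of-Gaussian, threshold
  `mean(|response|) + c·sd(response)`, sub-pixel refinement).
* **Tracking** — constant-velocity Kalman prediction with gated
  minimum-cost (Hungarian) assignment and a past-displacement cost term;
  optional drift correction by composed frame-to-frame registration
  (phase correlation + matched-detection refinement, translation or
  affine).
* **Motion analysis** — time-averaged MSD per trajectory, ensemble
  averaging with SEM, and the two-dimensional anomalous diffusion fit
  `MSD(Δt) = 4·D·Δt^α`, with motion classes confined (α ≤ 0.1),
  obstructed (0.1 < α < 0.9), normal (0.9 ≤ α ≤ 1.1) and super (α > 1.1).
  Trajectories shorter than 10 s (20 steps at 0.5 s) are excluded.
* **Replisome proximity** — k-d-tree center-to-center distances (CCD) from
  chromatin trajectories to the nearest PCNA focus; per-radius
  within/outside mobility comparison.
* **DNA quantification** — per-focus DNA content
  `dna_bp = (I_RFi / I_DNA_total) · C · GS` with cell-cycle correction
  factors C = 1.0/1.05/1.25/1.77/2.0 (G1/early-S/mid-S/late-S/G2) and
  genome sizes (`genome_sizes`: HeLa 9.682 Gbp, IMR90 6.37 Gbp).
* **Accumulation statistic** — coefficient of variation `cV = σ/μ` per
  time point, normalized to the pre-treatment time point and to a control
  condition.
* **High-content stage** — watershed nucleus segmentation with
  area/circularity filters, à-trous wavelet foci segmentation, S-phase
  gating by EdU focus count (≥ 50 control / ≥ 55 treated), EdU-positive
  fractions, and Wilcoxon rank-sum condition comparisons (exact
  enumeration for small samples, tie-corrected normal approximation
  otherwise).
* **Synthetic data** — ground-truthed trajectory simulation (Brownian,
  fractional-Brownian subdiffusion with MSD exactly `4·D·Δt^α`, confined,
  static + localization noise), movie rendering (Gaussian PSF, Poisson
  noise), two-channel chromatin+PCNA proximity scenes with planned
  distances, and cell-population images/records with controlled S-phase
  fractions, EdU focus counts and protein totals.

## Worked example

Three synthetic conditions — a mobile G1/G2-like population
(D = 1.3e-3 µm²/s, α = 0.7), a constrained S-like population
(D = 0.5e-3 µm²/s, α = 0.45) and a fixed-cell control (static emitters
with 20 nm localization noise) — each simulated, rendered to movies,
detected, tracked and fitted:

```r
library(chromdyn)

cfg <- mobility_config(
  conditions = list(
    g1g2_like = list(motion = motion_spec("fbm_subdiffusive", D = 1.3e-3,
                                          alpha = 0.7), n_scenes = 5),
    s_like    = list(motion = motion_spec("fbm_subdiffusive", D = 0.5e-3,
                                          alpha = 0.45), n_scenes = 5),
    fixed     = list(motion = motion_spec("static", loc_noise_sd = 0.02),
                     n_scenes = 5)),
  seed = 1)
res <- run_mobility_pipeline(cfg)
res$summary
#>   condition n_trajectories   D_um2_s D_um2_s_1e5     alpha motion_class
#> 1 g1g2_like             50 0.0013115      131.15  0.663508   obstructed
#> 2    s_like             50 0.0005077       50.77  0.442003   obstructed
#> 3     fixed             50 0.0004025       40.25 -0.005091     confined
```

Fifty trajectories per condition pass the 10 s duration filter. The fitted
diffusion coefficients (reported both in µm²/s and in the µm²/s × 10⁻⁵
convention common for chromatin) and anomalous exponents recover the
generating parameters within a few percent, reproduce the expected
ordering (G1/G2-like more mobile than S-like), and classify both moving
conditions as obstructed subdiffusion. The fixed-cell control shows an
essentially flat MSD (α ≈ 0, class confined) whose plateau reflects pure
localization noise (4σ² = 1.6e-3 µm²) — the imaging-stability control.
Individual fits print their full context:

```r
res$results$g1g2_like$fit
#> <diffusion_fit> D = 0.001312 um^2/s (131.2 x 1e-5), alpha = 0.664 (obstructed)
#>   fitted over lags 0.5-5 s (10 points, loglog)
```

A thin command-line wrapper for the same steps (simulate / detect / track /
msd / proximity / run) is installed at `inst/cli/chromdyn.R`.

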