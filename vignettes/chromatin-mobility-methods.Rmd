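---
title: "Quantifying chromatin mobility: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin mobility: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
```

## The problem

Replication-labeled chromatin domains (Cy3-dUTP pulse labeling) appear in
live-cell fluorescence microscopy as sub-resolution foci that jiggle inside
the nucleus. Their local diffusion carries information about the physical
state of chromatin: in S-phase, and particularly near active replisomes
(PCNA foci), this motion is constrained. Measuring the effect requires a
chain of image-analysis steps — background adjustment, spot detection,
frame-to-frame linking, mean-squared-displacement (MSD) analysis, and
anomalous-diffusion model fitting — plus population-level assays
(DNA content per labeled focus, protein-accumulation contrast, high-content
EdU gating). `chromdyn` implements that chain end to end, together with a
synthetic-data generator that produces ground-truthed inputs for every
stage, so the pipeline's accuracy is measurable without any raw microscopy
data.

## The motion model

For a 2D trajectory the time-averaged MSD at lag $\Delta t$ is fitted with
the anomalous diffusion model

$$\mathrm{MSD}(\Delta t) = 4\,D\,\Delta t^{\alpha},$$

where $D$ (µm²/s) is the diffusion coefficient and $\alpha$ the anomalous
exponent. The prefactor 4 is the two-dimensional convention
($2d\,D\,\Delta t^\alpha$ with $d = 2$) appropriate for single-focal-plane
imaging; it is applied consistently in both the simulator and the fit, and
is the main convention a user must keep in mind when comparing values to
other software. Motion classes follow the exponent:
confined ($\alpha \le 0.1$), obstructed ($0.1 < \alpha < 0.9$), normal
($0.9 \le \alpha \le 1.1$) and super ($\alpha > 1.1$). The boundaries 0.1
and 0.9 are the conventional limits of the obstructed-diffusion regime; the
neighborhood of 1 is reported as normal since a finite-sample slope is
never exactly 1.

The fit is linear least squares in $\log \mathrm{MSD}$ versus
$\log \Delta t$: the slope is $\alpha$ and $D = e^{\mathrm{intercept}}/4$.
The default fit window runs from the first lag to
$\min(5\,\mathrm{s},\ 25\%\ \mathrm{of\ the\ longest\ lag})$: short lags
carry the most displacement pairs, while long lags of a time-averaged MSD
are dominated by a handful of overlapping windows and are strongly
correlated. Both the window and the fitting space are arguments
(`fit_lag_range`, `method = "nls"` refits on the linear scale).
`analyze_motion()` can either fit the ensemble-averaged curve (default) or
fit each trajectory and average the parameters (`fit_mode =
"per_trajectory"`); the two agree for homogeneous populations, and the
ensemble route is numerically more stable for short tracks.

## Synthetic ground truth

`simulate_trajectories()` provides four motion models:

* **brownian** — i.i.d. Gaussian increments, per-axis variance $2D\,dt$;
* **fbm_subdiffusive** — per-axis fractional Brownian motion with Hurst
  index $H = \alpha/2$, scaled so the ensemble MSD is exactly
  $4D\,\Delta t^{\alpha}$. fBm is used because it reproduces precisely the
  power-law MSD the fitted model assumes (a continuous-time random walk
  would add aging effects the estimator does not model). Increments are
  generated by a Cholesky factorization of the exact fractional-Gaussian-noise
  covariance — at the series lengths used here (tens of frames) this is
  both exact and cheap;
* **confined** — Brownian steps with radial reflection at a confinement
  radius;
* **static** — constant position, the fixed-cell control.

Localization noise is additive Gaussian per coordinate per frame
(`loc_noise_sd`), independent across frames, the standard single-particle-
tracking error model. It produces the known flat MSD offset of
$4\sigma_{loc}^2$, which is exactly how the fixed-cell control behaves; the
localization precision of a given microscope is a free parameter here, not
a constant of the method.

`render_movie()` converts true positions to images: isotropic Gaussian
spots of width `psf_sigma_um` on a constant background with Poisson (or
Gaussian) noise. The default scene — 10 particles per nucleus, 41 frames at
0.5 s, 0.1 µm pixels, PSF σ = 0.13 µm, amplitude 500 counts over background
20 with Poisson noise (peak SNR ≈ 22), minimum particle separation 1.2 µm —
was chosen once as a realistic spinning-disk-like acquisition and is used
as the standard condition throughout the tests. What the generator does
*not* emulate: out-of-focus light and 3D defocus, photobleaching, spot
shape heterogeneity, vesicle-like directed transport, and spot density
heterogeneity of real nuclei. Passing the pipeline's recovery tests on
these scenes therefore demonstrates correctness of the algorithms under the
stated model, not performance on arbitrary real data.

Every generator takes an explicit seed and restores the caller's RNG state;
identical (spec, seed) pairs give bit-identical outputs.

## Detection

The spot-enhancing filter is a Laplacian-of-Gaussian (sign-corrected so
bright blobs give positive peaks, zero-sum so constant offsets vanish)
followed by thresholding at

$$T = \mathrm{mean}(|\mathrm{response}|) + c \cdot \mathrm{sd}(\mathrm{response}),$$

and 8-neighborhood local-maxima extraction. The threshold factor $c$
(default 3, a common choice for this filter family) is held constant across
all frames of a sequence. The LoG scale (default 1.5 px) should match the
rendered spot width. Maxima are admitted with `>=` comparisons so that a
spot centered exactly on a pixel boundary (a two-pixel plateau) is not
lost; the minimum-separation suppression then keeps a single peak per
plateau. Sub-pixel positions come from the intensity-weighted centroid of
the positive LoG response in a $(2\lceil 2\sigma\rceil + 1)^2$ window — the
response is background-free, which keeps the centroid unbiased; on the
default scenes the localization error is ~0.1 px RMS.

Nucleus segmentation for the live-cell stage mirrors the classic
threshold / fill-holes / close / label / size-filter recipe. The original
3D volume cutoff becomes a 2D area parameter (`min_area_um2`, default
50 µm²) because the time series analyzed here are single-plane.

## Tracking

Each live track carries a constant-velocity Kalman filter. Per frame,
predictions and detections are matched by minimum-total-cost assignment
(an $O(n^3)$ Hungarian solver, written in-package and tested against
brute-force permutation enumeration) with:

* a hard gate: candidate pairs farther than `gate_radius_um` (default
  0.5 µm, several times the expected per-step displacement of chromatin
  foci at 0.5 s intervals) are infeasible;
* cost = Mahalanobis innovation distance + `memory_weight` × the deviation
  of the candidate step from the mean of the last `motion_memory`
  displacements. The memory term implements the idea of exploiting past
  displacements in the correspondence cost.

Unmatched detections found new tracks; a track unmatched for more than
`max_missed_frames` (default 0 — no gap closing, since the analyzed foci do
not blink) terminates. Detections are put into a canonical within-frame
order before assignment, so results are independent of input order;
equal-cost ties resolve deterministically. This tracker deliberately
replaces a published multi-sensor particle-filter design with a simpler
estimator that satisfies the same contract (prediction, gated assignment,
motion memory); it is not a numerical reproduction of that tracker.

**Drift correction.** `register_affine()` estimates frame-to-frame
transforms — translation by regularized phase correlation with parabolic
sub-pixel interpolation, refined on nearest-neighbor-matched detections
(translation-restricted least squares by default, full affine with
`mode = "affine"`) — and composes them into frame-to-reference transforms.
Two numerical choices matter. First, consecutive-frame estimation:
matching each frame directly to frame 1 breaks down once accumulated
particle diffusion exceeds the match gate, whereas consecutive frames
differ by only one small step. Second, the phase-correlation whitening is
regularized with a relative epsilon, because on smooth low-noise images
exact whitening amplifies numerical noise at near-zero spectral
magnitudes. Registration on a scene of diffusing particles necessarily
absorbs the common-mode component of the true motion, deflating the MSD by
a factor $(1 - 1/n)$ for $n$ particles; with the ~20 particles per nucleus
used in the drift tests this is a ~5% effect, within the tolerance used.
Translation-only refinement is the default because a full 6-parameter
affine fit on few, mobile landmarks absorbs part of their diffusion.

## MSD computation and filtering

`compute_msd()` uses all overlapping start times (time-averaged MSD);
`ensemble_msd()` averages curves per lag with SEM across curves. Only
trajectories of duration ≥ 10 s (20 steps at 0.5 s) enter the analysis by
default — short tracks make noisy MSDs — and the boundary is inclusive (a
track of exactly 20 steps is kept, consistent with equating the 10 s
minimum with 20 time steps). Lags where fewer than two trajectories
contribute are dropped from ensemble curves.

## Proximity analysis

Chromatin trajectories are grouped by the center-to-center distance (CCD)
from their first-time-point position to the nearest PCNA focus of the
reference frame, computed with an in-package k-d tree (exact agreement
with brute force is part of the test suite). Eligibility: present at the
sequence's first time point and ≥ 10 s long. The boundary is inclusive —
distance = R classifies as within — a choice this package fixes and
asserts in its tests (the comparison convention is not otherwise pinned
down). The PCNA reference is a single frame acquired before the chromatin
series; PCNA foci are not tracked. `msd_by_group()` repeats the ensemble
fit per group over a grid of radii; empty or unfittable groups are
reported as missing rather than failing.

## DNA content per labeled focus

For a fixed, DAPI-stained nucleus,
$\mathrm{DNA}_{\mathrm{focus}} = \frac{I_{RFi}}{I_{DNA,total}} \cdot C \cdot GS$
with the stage-dependent correction factor $C$ (1.0 G1, 1.05 early S,
1.25 mid S, 1.77 late S, 2.0 G2 — accounting for genome duplication through
S-phase) and the genome size $GS$ (9.682 Gbp for HeLa, 6.37 Gbp for IMR90,
available as `genome_sizes`). The ratio makes the result invariant to
global intensity scaling, and foci tiling a nucleus sum exactly to
$C \cdot GS$. DAPI images should be background-adjusted first
(`adjust_background()`); intensity ratios are background-sensitive, so the
package treats this as a required preprocessing step. The histogram
utility `dna_content_mode()` reports the modal bin and its right neighbor
("mode + 1 bin"); the bin width (default 100 kbp) is a free parameter.

## Accumulation statistic

Protein accumulation at replication sites is measured as the coefficient of
variation $c_V = \sigma/\mu$ of pixel intensities within the segmented
signal, per time point; $\sigma$ is the *population* standard deviation
(divisor $N$) — a convention that must be pinned for reproducibility and is
asserted against a hand-computed case. Series are normalized to the first
time point ($c_V(t)/c_V(t_0) = 1$ at $t_0$ exactly) and optionally divided
by a control condition at matched times. An all-constant image has
$c_V = 0$ and is flagged degenerate rather than normalized through a zero.

## High-content stage

Nuclei: manual (or Otsu) intensity threshold, watershed on the distance
transform to split touching nuclei, then area and circularity filters.
Circularity is $4\pi A / P^2$ with the perimeter from a four-direction
Crofton estimate (boundary crossings along rows, columns and both
diagonals) — pixel-edge counting overestimates perimeters and would push
circular nuclei visibly below 1, while the Crofton estimate is within a few
percent for disks.

Foci: B3-spline à-trous (stationary) wavelet decomposition; the detail
plane at the chosen `level` is thresholded at `k_sigma` × a robust noise
scale (1.4826 × MAD of the first detail plane), connected components inside
the nuclear mask become foci. Because the threshold is noise-relative,
counts are invariant to global multiplicative intensity changes. `level`
selects the spot scale (level 1 for ~1 px spots, level 2 for ~2–3 px); the
per-channel parameters are free, but the pipeline keeps them identical
between control and treated samples — the one constraint that matters for
comparability. Merged foci are a known limitation: two spots closer than
about 3 px at their scale segment as one component.

Gating: a nucleus is S-phase iff its EdU focus count ≥ 50 (control) or
≥ 55 (aphidicolin-treated). The boundary is inclusive by this package's
choice, asserted in tests. The EdU-positive call uses a strict `>`
comparison against the background level measured on an EdU-free stained
control. Condition comparisons use the two-sided Wilcoxon rank-sum test
with midranks: exact enumeration of the rank-sum distribution over group
assignments when $\binom{n}{n_a}$ is small (ties handled correctly),
otherwise the tie-corrected normal approximation with continuity
correction; both paths are cross-checked against enumeration and
`stats::wilcox.test`.

## Problem sizes and statistical checks

The package's property tests run the full chain — simulate, render,
detect, track, filter, MSD, fit — on 500 trajectories per condition
(50 scenes × 10 particles, 41 frames at 0.5 s), the scale at which the
recovered $\alpha$ is within a few hundredths and $D$ within a few percent
of truth, and on smaller scenes for the focused per-module checks. The
drift-correction check uses 22 particles in a 449 µm² nucleus
(0.049 spots/µm²). The Wilcoxon power check (+0.5 SD shift, 200 nuclei per
compared group) is asserted on the median p over replicate simulations,
since a single draw estimates power with substantial noise; type-I
calibration checks uniformity of null p-values over 200 replicates at
n = 200 per group, where the normal-approximation p is effectively
continuous.

## Degenerate inputs and edge cases

Constant frames yield empty detection lists (not errors); blank frames
make registration fail with the frame named; zero total DAPI intensity,
empty masks, empty samples and empty PCNA sets raise parameter errors;
all-static groups in `msd_by_group()` (zero MSD, unfittable in log space)
are reported as missing estimates with their trajectory counts. Pipeline
stage failures halt with the stage named. Seeds are explicit everywhere;
reruns of one configuration are bit-identical.

## Known limitations

* 2D only: no 3D detection, tracking or rendering.
* No gap closing by default; blinking emitters would fragment.
* The tracker is a contract-level stand-in for the published probabilistic
  multi-sensor tracker, not a reproduction; measured diffusion values on
  real recordings will not numerically match results of that software.
* The wavelet foci counter undercounts once spots merge below its scale.
* Real-data effects excluded from the generator (defocus, bleaching,
  motion blur) are exactly the ones most likely to degrade detection on
  microscope data; parameters (`log_sigma_px`, `threshold_factor`,
  wavelet `level`, `k_sigma`) are exposed for tuning per dataset.
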