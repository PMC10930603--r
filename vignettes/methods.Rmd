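---
title: "Quantifying cerebellar microglia and Purkinje cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebellar microglia and Purkinje cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gliaquant quantifies cerebellar microglia and Purkinje cells from
two-channel fluorescence imaging: in-vivo two-photon time-lapse stacks of
the molecular layer (ML) and Purkinje cell layer (PCL), and fixed-tissue
confocal sections spanning ML+PCL, granule layer (GL), and white matter
(WM). This vignette documents the models, the tunable parameters, the
synthetic-data generator that drives all testing, and the numerical choices
behind each stage.

## The measurement pipeline

An in-vivo dataset is a 5-D stack indexed (time, z, channel, y, x): twelve
timepoints at 5-minute intervals, 101 z-slices at a 1 µm step, a microglia
(GFP) channel and a Purkinje (tdTomato) channel. The analysis chain is:

1. **Blinding** — file identities are replaced by opaque ids
   (`blindDataset`), with a key table for unblinding after measurement.
2. **Drift correction** (`correctDrift`) — a per-timepoint integer (y, x)
   translation is estimated by FFT cross-correlation of the
   microglia-channel maximum projection against timepoint 1 and undone with
   zero padding. Integer resolution was chosen because all downstream
   statistics are pixel-set operations; sub-pixel interpolation would blur
   the binarized masks it aims to protect.
3. **Bleed-through subtraction** (`estimateBleedthrough`,
   `subtractBleedthrough`) — tdTomato signal leaks into the GFP channel by
   a single multiplicative fraction α, estimated as the least-squares slope
   of microglia-channel vs Purkinje-channel intensity over Purkinje-only
   pixels (the intercept absorbs background). Each frame is first
   background-corrected by its modal intensity, then
   `max(0, microglia − α · purkinje)` is taken. α is estimated per stack.
4. **Temporal PCA denoising** (`pcaDenoise`) — timepoints are observations
   and voxels variables; the stack is rebuilt from the mean image plus the
   top-k temporal components. The temporal axis is the denoising-relevant
   one for a time-lapse: structure persists across frames, shot noise does
   not. k equal to the number of timepoints reproduces the input.
5. **Layer substacks** (`splitLayers`) — the PCL starts at an explicitly
   supplied z-slice (soma monolayer identification is a manual call in
   practice); both substacks take the same number of slices, as half-open
   intervals below and above the boundary.
6. **Segmentation surrogates** (`binarizeObjects`, `detectSomas`,
   `classifySubcomponents`, `classifyPurkinjeComponents`) — learned pixel
   classifiers are replaced by deterministic threshold + morphology
   operators so the pipeline is self-contained and reproducible:
   intensity threshold, connected-component size exclusion
   (8-connectivity in 2-D, 26 in 3-D), morphological opening with a disc of
   radius `rSoma` (default 3 px) to split somas from processes, and
   Zhang–Suen thinning with junction detection for dendritic branch points.
   Thresholds and size bounds are configuration, not estimates.

## Metrics

**Motility index** (`motilityIndex`): for consecutive binarized frames
(A, B), extended = |B∖A|, retracted = |A∖B|, stable = |A∩B|, and
M.I. = (extended + retracted) / stable, averaged over the 11 transitions.
The masks are already thresholded; no further change-magnitude threshold is
applied (none is defined for these data). "Stable" is the intersection, the
reading consistent with the prior-work formula; pairs without stable pixels
are excluded with a warning. Both the mean-of-transitions (default) and the
pooled-pixel variant are reported.

**Surveillance ratio** (`surveillanceRatio`): pixels in the union of all
timepoints over pixels at timepoint 1; ≥ 1 by construction.

**Injury convergence** (`detectFront`, `injuryConvergence`): after a focal
laser ablation, the microglia front is the boundary of the microglia-free
connected region containing the core centroid (the autofluorescent core
itself is excluded from the microglia mask first). Normalized proximity at
time t is (A_front(t) − A_core)/(A_front(1) − A_core), with shoelace
polygon areas. Manual front polygons can be supplied instead of the
automated contour.

**Sholl curves** (`shollIntersections`): for rings at 2 µm intervals (out
to 70 µm in vivo, 100 µm in fixed tissue), the intersection count is the
number of maximal foreground runs along the angularly ordered Bresenham
circle, joined circularly. On 1-px-wide diagonal structures a rasterized
ring can miss a crossing — an inherent raster artifact shared by standard
plug-in implementations; binarized masks in practice are ≥ 2 px wide.

**Sholl change-point model** (`fitShollCurve`, `fitShollModel`): the
expected curve is piecewise log-linear and continuous at the change-point
γ: E[I(r)] = exp(τ + α₁(r − γ)) for r ≤ γ and exp(τ + α₂(r − γ)) beyond,
so the branch maximum e^τ is attained at γ. Counts are Poisson — the
natural count likelihood, and the one the simulation-based tests verify.
The hierarchy has cell-level parameters drawn from animal-level normals and
animal-level means given by a linear predictor (intercept + treatment +
sex + interaction, as available). Priors are weakly informative normals
(τ ~ N(0, 3²); slopes ~ N(0, 1); γ centered mid-range with SD ≈ 30 µm) and
uniform hierarchical SDs; γ is truncated to the observed radius range at
the cell level. Posterior sampling uses JAGS with fixed per-chain seeds;
convergence is checked by split-R̂ < 1.05. With α₁ ≈ α₂ the change-point is
unidentifiable; the fit then flags `gammaWide` (the 95% interval of the γ
intercept exceeds a third of the radius range) rather than failing.
`fitShollCurve` provides a per-curve maximum-likelihood fit profiling γ
over the ring grid (a Poisson GLM per candidate), used for initialization
and for single-cell summaries.

**Spatial statistics** (`somaDensity`, `spacingIndex`, `linearFrequency`):
density is somas per µm² inside a layer polygon (even-odd rule);
the spacing index is (mean nearest-neighbor distance)² × density —
1 for a perfect grid, 0.25 in expectation for a 2-D Poisson process
(E[NN] = 1/(2√λ)), below 0.25 for clustering. No edge correction is
applied; for small ROIs this biases nearest-neighbor distances slightly
downward, a documented limitation. Purkinje linear frequency is somas
within ± one soma diameter (16 µm) of the PCL polyline divided by the
polyline length; three sections are averaged per animal with equal weight.

**Interactions** (`interactionOverlap`, `normalizedInteraction`,
`dynamicInteractionIndex`, `coverageIndex`): the interaction mask is the
voxelwise AND of the binarized channels, computed in 3-D per timepoint (or
per 51-slice fixed substack); normalized interaction is overlap voxels over
microglia voxels, averaged across timepoints or sections; subcomponent
variants use the exact soma/process and dendrite/branch partitions. The
dynamic interaction index applies the motility formula to max-projected
interaction masks, and the coverage index is their temporal union over the
frame area — following the convention that dynamics are assessed on
projections while occupancy is assessed in 3-D. The GL is excluded from
interaction analysis (Purkinje axon density there is too low). Timepoints
with empty microglia masks are dropped with a warning rather than
zero-filled.

## The synthetic-data generator

No public raw imaging accompanies this problem domain, so every stage is
validated against `generateTimelapse`, `generateFixedSection`,
`generateInjurySeries`, and `generateOccupancyRegion`, which emit images
*and* their exact ground truth (masks, coordinates, realized parameters).
Emission intensities are fixed (microglia 100, Purkinje 120 with ±25%
per-voxel brightness variation so the bleed slope is identifiable);
thresholding the noise-free image at the emission floor reproduces the
ground-truth mask exactly, and identical config + seed gives bit-identical
output (one RNG stream per stack).

Microglia are soma spheres with 1-px-wide process walks confined to a
z-band around the layer boundary. Process dynamics are modeled as random
tip retraction and extension with the total turnover controlled so that
the ground-truth motility index equals the configured `processTurnover`
(k = m·n/(2 + m) tip pixels per transition, stochastically rounded so the
mean stays on target even for small cells). This is an artifact of
testability, not a biological claim: it makes M.I. and S.R. analytically
controllable. Re-extension into pixels vacated in the same transition is
forbidden so the pixel bookkeeping is exact.

Fixed sections stack three wavy layer bands (ML+PCL, GL, WM); Purkinje
somas (radius 8 µm) sit on a curved PCL polyline at the configured spacing
with a random phase, so the expected count is path length / spacing without
quantization bias; dendrite trunks fork once per soma in the ML; microglia
somas are placed by a perturbed grid (default, for spacing-index tests) or
a Poisson process (null tests) at per-layer densities. Group effects are
named multiplier sets keyed by treatment or treatment.sex — e.g. a 0.92
multiplier on PCL linear density yields an exact 8% reduction in
ground-truth linear frequency.

Injury series place a fixed autofluorescent core with a microglia annulus
whose inner radius shrinks linearly, giving an analytic proximity series.
Occupancy regions fill a volume with process-like segments (or slabs, when
dense) to an exact voxel count, reproducing the sparse microglia
volume-fraction regime (~0.005 PCL, ~0.02 WM) and the dense Purkinje one
(~0.25–0.30).

Defaults chosen once for realism at desk scale: microglia density
1.5 × 10⁻⁴ /µm² (in-plane), process turnover ML 0.07 / PCL 0.10 (the PCL >
ML ordering mirrors the layer contrast reported in vivo), Purkinje soma
spacing 30 µm, bleed α 0.15, Gaussian noise SD 3 on background 5 (clipped
at zero; no photon-noise model — additive noise suffices to exercise
thresholding). The in-vivo default frame is 96 × 96 px (with the full
101-slice, 12-timepoint geometry); the acquisition frame size of real
hardware is not a generator condition, and this size keeps a stack at
desk-scale memory. What the generator does *not* emulate — optical PSF,
photobleaching, Bergmann glia, nonrigid motion, realistic arbor
morphometry — bounds what passing tests show about real data: they validate
the *computations*, not robustness to unmodeled optics.

## Verification strategy and problem sizes

Every metric is tested against an independent brute-force oracle (direct
set operations, ray casting, shoelace areas, flood-fill labeling, rle ring
walks, closed-form spatial limits) on ≥ 100 random instances, and the
pipeline end-to-end against generator ground truth: turnover ∈
{0, 0.05, 0.1, 0.2} recovered within ±0.02 by the measured motility index
with strictly monotone surveillance; injected integer drift recovered
exactly; bleed α = 0.2 recovered within ±0.01; injected 8% (pooled) and
12% (female-specific) linear-frequency reductions recovered within ±2
percentage points over 8–10 sections per group; sparse volume fractions
within ±10% relative. The hierarchical Sholl model is validated by
simulation: parameter recovery on 10 cells × 5 animals × 2 groups, and
null-effect calibration (95% intervals covering zero ≥ 90% of the time)
on 12 replicate fits of 6 cells × 4 animals × 2 groups with rings to
60 µm — sizes chosen to keep full-suite runs fast while leaving the
calibration property, which does not depend on them, intact.

## Known limitations

- Drift correction is integer-pixel and rigid; nonrigid motion is out of
  scope.
- Bleed-through is a single global α per stack; no spectral unmixing.
- Nearest-neighbor statistics carry small-ROI edge bias (no correction).
- Sholl rings are 2-D on maximum projections; no 3-D spheres.
- The segmentation surrogates are deliberate simplifications of learned
  classifiers; on real data their thresholds and size bounds must be tuned
  per dataset, and results will differ from trained-model output.
- Priors for the Sholl model are the package's own documented defaults;
  the published parameterization does not specify them.
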