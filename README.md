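# gliaquant

Quantification of cerebellar microglia and Purkinje cells from two-channel
fluorescence imaging: in-vivo two-photon time-lapse stacks of the molecular
layer (ML) and Purkinje cell layer (PCL), and fixed-tissue confocal
sections of a whole lobule (ML+PCL, granule layer, white matter). The
package is aimed at imaging labs measuring how microglia — the motile
immune cells of the brain — survey the cerebellar cortex and physically
interact with Purkinje cells, its sole output neurons, and how group
factors (treatment, sex) shift those measurements.

It implements, as tested and reusable code:

- **Preprocessing**: dataset blinding, integer drift correction by FFT
  cross-correlation, channel bleed-through estimation and subtraction,
  temporal PCA denoising, layer substacks, maximum projections.
- **Segmentation surrogates**: threshold + connected-component size
  exclusion (8/26-connectivity), soma detection by morphological opening,
  soma/process and dendrite/branch-point classification (Zhang–Suen
  thinning) — deterministic stand-ins for trained pixel classifiers.
- **Microglia dynamics**: motility index
  M.I. = (extended + retracted) / stable pixels between consecutive
  binarized timepoints, surveillance ratio
  S.R. = |∪ₜ maskₜ| / |mask₁|, and laser-ablation injury convergence,
  proximity(t) = (A_front(t) − A_core)/(A_front(1) − A_core).
- **Sholl analysis**: ring-intersection curves (2 µm rings) and a
  hierarchical Bayesian change-point model
  E[I(r)] = exp(τ + α₁(r − γ)) for r ≤ γ, exp(τ + α₂(r − γ)) beyond —
  slopes α₁/α₂ before and after the change-point γ, branch maximum e^τ —
  with Poisson counts, cell-within-animal-within-group hierarchy, and
  treatment/sex effect credible intervals (JAGS).
- **Spatial statistics**: per-layer soma density, nearest-neighbor spacing
  index (NN̄² × density; 1 on a grid, 0.25 for Poisson), and Purkinje cell
  linear frequency along the PCL path.
- **3-D interactions**: microglia–Purkinje overlap (voxelwise AND),
  normalized interaction (overlap / microglia voxels), dynamic interaction
  index, and coverage index, including subcomponent variants.
- **A synthetic-data generator** with exact ground truth (masks,
  coordinates, realized parameters, injected group effects) that makes
  every stage testable without external data.

## Worked example

Simulate one in-vivo animal with layer-specific process turnover (ML 0.05,
PCL 0.15), 1-px drift, 15% channel bleed-through, and noise — then run the
full pipeline (drift correction → bleed subtraction → layer substacks →
binarization → metrics):

```r
library(gliaquant)
cfg <- synthConfig(imageShape = c(y = 80L, x = 80L, z = 30L),
                   nTimepoints = 12L,
                   processTurnover = c(ML = 0.05, PCL = 0.15),
                   drift = 1, noiseSd = 3, bleedAlpha = 0.15, seed = 3)
res <- runInvivo(cfg)
res$alpha
#> [1] 0.1438578
subset(res$table, metric %in% c("motility_index", "surveillance_ratio",
                                "normalized_interaction"))
#>  layer                 metric  value
#>     ML         motility_index 0.0523
#>     ML     surveillance_ratio 1.2400
#>     ML normalized_interaction 0.3726
#>    PCL         motility_index 0.1508
#>    PCL     surveillance_ratio 1.5422
#>    PCL normalized_interaction 0.1630
```

The estimated bleed fraction recovers the injected 0.15; the measured
motility indices recover the configured turnover per layer (0.05 and 0.15);
the more motile PCL microglia also survey more area (S.R. 1.54 vs 1.24);
and the normalized interaction is the fraction of microglia voxels touching
Purkinje signal in each layer.

For fixed tissue, `runFixed()` measures density, spacing index, linear
frequency, volume fractions and interactions over a design of animals ×
sections, and `groupSummary()` reports group means ± SEM and percent
differences; `fitShollModel()` fits the change-point model across animals.

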