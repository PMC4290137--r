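# lhvessel

Segmentation of 3D vascular structures from angiographic volumes (MRA /
CTA) with a **localized hybrid level-set** active contour.

Vessel intensity decreases from the root of a vascular tree toward its thin
branches, so no single global intensity threshold can delineate a whole
vasculature: high thresholds lose dim branches, low thresholds swallow
background. This package evolves a level-set contour φ under two forces —

- a **region force** `α δ_ε(φ) (I − μ)`, where `μ(u) = k (K_σ ∗ I)(u)` is a
  spatially varying lower-bound threshold (the k-scaled Gaussian local mean
  of the image), and
- a **geodesic edge force** `β δ_ε(φ) div(g(|∇I|) ∇φ)` with edge indicator
  `g(h) = 1/(1 + c h²)`,

with exact signed-distance reinitialization every iteration. The
**original hybrid model** — the same evolution with a preset global
threshold `μ` — is available through the same code path
(`seg_config(global_mu = ...)`), so comparisons isolate exactly the effect
of localization. Default parameters are the reference set
`Δt = 4.0, α = 0.01, β = 0.5, σ = 3.0, ε = 1.0, k = 0.9`.

The package also provides:

- a synthetic branching-vessel **phantom generator** with exact ground
  truth, branch-wise intensity dimming (inhomogeneity) and seeded Gaussian
  noise on the normalized intensity scale;
- **Dice / segmentation-error** validation and a benchmark runner
  (`run_benchmark()`) comparing models across noise levels;
- 3D volume I/O (NIfTI-1, NRRD, single-series DICOM directories), binary
  mask I/O, and maximum-intensity-projection rendering;
- a command-line interface (`exec/lhvessel`) with `segment`, `phantom`,
  `benchmark` and `metrics` subcommands, each writing a reproducibility
  manifest.

## Worked example

Build a phantom, corrupt it with noise, segment it, and score the result:

```r
library(lhvessel)

spec    <- phantom_spec(shape = c(64, 48, 64))   # branching tree, one dim branch
phantom <- generate_phantom(spec)
print(phantom)
#> vessel_phantom: 64x48x64 voxels, 5 branches, 2778 vessel voxels, peak 500

noisy <- add_gaussian_noise(phantom$volume, variance = 0.001, rng_seed = 1)
phi0  <- initialize_phi(spec$shape, seed_spec(trunk_seed(phantom)))
fit   <- evolve(noisy, phi0, seg_config())
print(fit)
#> vessel_segmentation: 72 iterations (converged), 3358 interior voxels

dice_coefficient(phantom$mask, fit$mask)      # 0.902
segmentation_error(phantom$mask, fit$mask)    # 9.84 (percent, lower is better)
head(fit$trace, 3)
#>   iteration interior_voxels changed_voxels band_mean_abs_diff
#> 1         1             229            106           176.9035
#> 2         2             373            144           163.0265
#> 3         3             519            146           155.6029
```

The phantom's 2778 ground-truth voxels include a branch dimmed to 45%
intensity; the localized model recovers it, while the same run with
`seg_config(global_mu = 250)` (the original hybrid baseline) loses it
entirely — `run_benchmark()` tabulates this comparison across noise
variances and writes a CSV report, a text table and MIP snapshots.

From a shell, the same pipeline is:

```sh
lhvessel phantom  --output-dir out/ph --shape 64,48,64 --variances 0.001
lhvessel segment  --input out/ph/noisy_v0.001.nii.gz --output-dir out/seg \
                  --seed-ball 32,24,14,3
lhvessel metrics  --mask-a out/ph/ground_truth_mask.nii.gz \
                  --mask-b out/seg/mask.nii.gz
```

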