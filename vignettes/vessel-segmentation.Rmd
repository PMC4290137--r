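---
title: "Localized hybrid level-set segmentation of 3D vessel images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized hybrid level-set segmentation of 3D vessel images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Vessels in MRA/CTA angiography are bright tubular structures whose intensity
falls from the root of the tree toward its thin branches. A single global
intensity threshold therefore cannot delineate a whole vasculature: set high
it loses dim branches, set low it swallows background. `lhvessel` implements
a hybrid region+edge level-set active contour whose region force compares
each voxel against a *spatially varying* lower-bound threshold computed from
the image itself.

The contour is the zero level set of a scalar field $\phi$ over the image
domain $\Omega$, positive inside. The energy being minimized combines a
region term and a geodesic (edge) term,

$$E(\phi) = -\alpha \int_\Omega (I(\mathbf{u}) - \mu(\mathbf{u}))\,
H(\phi)\, d\mathbf{u} \;+\; \beta \int_\Omega g(|\nabla I|)\,
|\nabla H(\phi)|\, d\mathbf{u},$$

where $H$ is the Heaviside function, $g(h) = 1/(1 + c\,h^2)$ is a
decreasing edge indicator, and

$$\mu(\mathbf{u}) = k \,(K_\sigma * I)(\mathbf{u})$$

is the local threshold map: the Gaussian-weighted local mean of the image,
scaled by an adjustment coefficient $k \in [0.5, 1]$. Where
$I > \mu$ the contour grows; where $I < \mu$ it shrinks; the geodesic term
regularizes the surface and stops it at strong edges. The *original* hybrid
model is the special case $\mu(\mathbf{u}) \equiv \mu_0$ with a preset
global constant; in this package it is literally the same code path with a
constant threshold map (`seg_config(global_mu = ...)`), so model comparisons
isolate exactly the effect of localization.

In practice $H$ and its derivative are smoothed:
$H_\varepsilon(s) = \tfrac12\left(1 + \tfrac{2}{\pi}\arctan(s/\varepsilon)\right)$
and $\delta_\varepsilon(s) = \tfrac{1}{\pi}\,
\varepsilon/(\varepsilon^2 + s^2)$, which restrict updates to a band of
width $\sim\varepsilon$ around the contour.

Each iteration of `evolve()` performs:

1. reinitialize $\phi$ to a signed distance function (SDF);
2. the local threshold map $\mu$ (computed once up front — it depends only
   on the image, so per-iteration recomputation would return identical
   values);
3. the region force $\delta_\varepsilon(\phi)\,(I - \mu)$;
4. $\phi' = \phi + \Delta t\,\alpha\,\delta_\varepsilon(\phi)(I - \mu)$;
5. reinitialize $\phi'$;
6. $\phi \leftarrow \phi' + \Delta t\,\beta\,\delta_\varepsilon(\cdot)\,
   \mathrm{div}(g\,\nabla \cdot)$.

## Parameters

All defaults are the fixed set used across every experiment in this
package; all lengths are in voxels (anisotropic spacing is carried as
metadata only and never enters the PDE).

| parameter | default | meaning |
|---|---|---|
| `dt` | 4.0 | explicit time step |
| `alpha` | 0.01 | region-force weight (per intensity unit) |
| `beta` | 0.5 | geodesic/curvature weight |
| `sigma` | 3.0 | Gaussian scale of the local threshold map |
| `eps` | 1.0 | Heaviside/Dirac band width |
| `k` | 0.9 | threshold adjustment coefficient |
| `c` | 1.0 | edge-indicator scope |
| `sigma_edge` | 1.0 | pre-smoothing for the edge map |

`alpha` multiplies raw intensity differences, so its default presumes
intensities on the scale of hundreds (vessel peak around 500); volumes on
other scales can either be left raw with rescaled `alpha` or normalized
explicitly (`normalize = TRUE`, which puts thresholds on the unit scale).
`k` below 1 keeps the contour from stalling inside the object before the
boundary: the local mean near a boundary mixes object and background, and
scaling it down biases the threshold toward the lower bound of the object.

The edge map is always computed on the unit-normalized image so that the
default `c = 1` is scale-free across modalities. We also evaluated much
larger `c` (stronger edge response, `g` down to about 0.3 at a vessel
wall): it *weakens* the curvature containment of the contour faster than
its ridge attraction improves localization, and segmentation accuracy on
the phantom degrades monotonically with `c`; the scale-free default is kept.

## Numerical choices

**Reinitialization.** The method requires $|\nabla\phi| = 1$; we
reinitialize by a signed Euclidean distance transform at *every* iteration
(steps 1 and 5) rather than by iterative PDE relaxation: it is exact,
deterministic, and unconditionally stable. Two details matter:

* *Sub-voxel interface seeding.* The zero level set is located to first
  order by linear interpolation of $\phi$ along grid edges with a sign
  change; interface-adjacent voxels are seeded with that fractional
  distance and one exact distance transform propagates the far field. A
  plain distance transform of the binarized field would snap every front
  voxel back to integer distances each iteration, freezing any front that
  moves slower than one voxel per iteration — with the paper-scale forces
  that includes exactly the dim thin branches the method exists to capture.
  With sub-voxel seeding, slow fronts accumulate progress across
  iterations. Far-field values follow the Pythagorean composition of seed
  offsets, accurate to about half a voxel — immaterial, since
  $\delta_\varepsilon$ confines the dynamics to the interface band.
* *Step-6 field.* The printed update sequence can be read as evaluating
  step 6's Dirac weight and gradient on the *pre*-region-update field. We
  evaluate both on the freshly reinitialized field from step 5 (that
  reinitialization exists precisely to precondition step 6); the literal
  reading is available as `strict_paper_steps = TRUE`. In A/B runs the
  committed ordering converges while the literal one oscillates
  indefinitely at thin-branch tips without changing the qualitative result.

**Seeds.** `initialize_phi()` builds the SDF of the seed union: analytic
sphere distance for ball seeds (exact), distance transform for mask seeds,
combined by pointwise maximum.

**Stopping.** The evolution stops when the inside/outside labelling changes
at no more than `tol_voxels` voxels (default 0) for 3 consecutive
iterations, or at `max_iters` (default 500). With sub-voxel reinitialization
a front creeping slower than about a third of a voxel per iteration can
produce three label-quiet iterations and stop while the field still moves;
in every phantom experiment here this truncation occurs only after branch
recovery is complete (it clips the last fraction of the boundary halo
discussed below), but runs that must settle to the exact discrete
equilibrium should set `max_iters` explicitly and `tol_voxels = 0` remains
the default.

**Stability.** With the defaults the explicit curvature step has diffusion
number $\Delta t\,\beta\,\delta_\varepsilon(0) = \Delta t\,\beta/\pi
\approx 0.64$; per-iteration exact reinitialization keeps the scheme stable
there, and `seg_config()` warns only above 1, the hard bound for the
centered scheme.

**Discretization.** All differential operators use central differences in
the interior and one-sided differences at the volume faces; Gaussian
convolutions use reflective boundary handling (truncated at $4\sigma$) so
thresholds are not artificially lowered at the borders, which would
spuriously grow the contour there.

## The synthetic phantom

No deposited validation volume exists, so `phantom_spec()` /
`generate_phantom()` emulate the validation dataset: a branching tubular
tree rasterized into a 100×70×106 grid (configurable), vessel peak
intensity 500, boundary intensity 250 at the tube surface, background 0.
The default tree has a radius-4 trunk, two generations of branches leaving
at roughly 40° with radius ratio 0.75, tapering to 1.5-voxel tips, and one
first-generation branch dimmed to 45% intensity — emulating the intensity
inhomogeneity that makes part of a real tree look disconnected in a maximum
intensity projection. Intensities ramp linearly from full value one voxel
inside the surface through the boundary value at the surface to background
one voxel outside (a 1-voxel partial-volume skirt); the ground-truth mask is
exactly the set of voxels within the tube radius. Gaussian noise is defined
on the intensity-normalized scale (variances of 0.001–0.015 on raw units of
hundreds would be invisible), clipped to [0, 1.2] so overshoot above the
vessel peak is not half-truncated, and the same seed at different variances
reuses the same underlying draws, so noise levels are perfectly comparable.

What the phantom does *not* emulate: nonzero/textured background tissue, MR
bias fields, Rician noise statistics, and point-spread functions wider than
the 1-voxel ramp. Passing the phantom benchmark therefore demonstrates the
mechanism — local thresholds following dim branches where a global
threshold fails — not clinical-grade accuracy on any particular scanner's
data.

## Behavior, limitations, and the boundary halo

Two reproducible consequences of the phantom's construction are worth
understanding before reading benchmark numbers:

* *Sub-voxel boundary halo.* Around thin branches the Gaussian local mean
  is diluted by background, so $\mu$ falls well below the boundary
  isovalue and the equilibrium front rests a fraction of a voxel *outside*
  the true radius, inside the partial-volume skirt. On the default phantom
  every false-positive voxel lies within 0.75 voxels of the true surface —
  excellent localization by segmentation standards — but for a thin tree
  the skirt is a large fraction of the vessel volume, which caps the Dice
  coefficient near 0.9 at the 64×48×64 scale regardless of how well the
  branches are recovered.
* *Noise direction.* Clipping noisy intensities at zero lifts the mean
  background level, which raises the local thresholds and trims that same
  halo; over the benchmark's variance range this effect slightly
  *decreases* the localized model's segmentation error as noise grows,
  before noise damage takes over. The comparison against the global-hybrid
  baseline is unaffected (the localized model is more accurate at every
  variance, by a wide margin, and is the only one to recover the dimmed
  branch).

## Problem sizes

The test suite exercises the numerics on 16³–48³ grids, clean-phantom
recovery on 64×48×64, and the noise benchmark and inhomogeneity comparison
on the full 100×70×106 phantom; `scripts/acceptance.R` recomputes the
clean-recovery, benchmark, coverage and connectivity quantities at those
same sizes. These sizes keep a full run in the minutes range on a single
CPU while spanning the regime (thin, dim, branching tubes) the method is
about.
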