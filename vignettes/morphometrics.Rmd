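---
title: "Quantifying irregular 3D plant morphology with convex-hull descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying irregular 3D plant morphology with convex-hull descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoct)
```

## The problem and the model

Thalloid plants such as the liverwort *Marchantia polymorpha* grow as thin,
flat sheets. Mutants of morphogenesis genes often twist or undulate along
the growth axis, and because the deformation differs between individuals of
the same genotype, it resists classical landmark-based morphometrics.
`morphoct` implements a landmark-free alternative built on two global 3D
shape descriptors of the segmented plant body:

* **convexity** \(C = A_C / A\), the convex-hull surface area over the
  object surface area, and
* **solidity** \(S = V / V_C\), the object volume over the convex-hull
  volume.

A flat convex sheet has \(C \approx S \approx 1\). As the body curls away
from its hull, \(V_C\) grows while \(V\) does not, so \(S\) drops steeply
— it is the workhorse descriptor for twist and curl. As the *surface*
wrinkles at a scale smaller than the body envelope, \(A\) grows while
\(A_C\) does not, so \(C\) drops — it responds to surface undulation.
Two-class linear discriminant analysis (LDA) in the \((S, C)\) plane, with
Cohen's kappa as the chance-corrected score, separates morphological
groups.

One geometric subtlety is documented rather than hidden: \(C\) is **not**
bounded by 1. For flat objects with in-plane concavities the hull area can
exceed the object area; the plus-pentomino prism (`make_body()` shape
`"plus_prism"`) has analytically \(C = (18 + 4\sqrt2)/22 \approx 1.075\).
More consequentially, *pure twist* of a sheet is a nearly isometric
deformation: the sheet's own area barely grows while the hull inflates, so
\(C\) *increases* with twist (measured on the bundled slab phantom:
\(C = 1.00, 1.11, 1.18, 1.18\) at twist \(0°, 90°, 180°, 270°\)) even as
\(S\) falls monotonically \((1.00, 0.47, 0.34, 0.31)\). A claim that both
descriptors decrease under pure twist is therefore geometrically
untenable; in this package's test suite the solidity half of that sweep is
asserted and the convexity half is left as a deliberately failing
assertion with this explanation. What *does* lower \(C\) is surface
undulation at fixed envelope, which is also a phenotype of twisted
mutants; the mutant-like phantom therefore combines twist (drives \(S\))
with sinusoidal undulation (drives \(A\), hence \(C\)).

## The extraction pipeline

A micro-CT scene contains, in decreasing intensity: the tube-case wall,
the pedestal block the sample rests on, the plant, and background.
`extract_plant()` isolates the binary plant body in five stages:

1. **Mask1** (`build_pedestal_mask()`): binarize at the high threshold,
   optionally dilate, AND with the scene's nonzero support. This captures
   the pedestal and case wall.
2. **Subtraction** (`subtract_mask()`): zero those voxels.
3. **Binarization** at the plant threshold.
4. **Mask2** (`build_edge_mask()`): the binarized image retains the
   pedestal's partial-volume *rim* — a one-voxel shell at plant-like
   intensity that touches the plant where it meets the pedestal, welding
   noise to the body. Mask2 marks foreground that (a) survives no 3×3×3
   morphological opening (no interior, i.e. thin), (b) lies in the
   dilated zone of binarized gradient-magnitude edges, and (c) is in the
   1-voxel neighbourhood of Mask1 — so only the *pedestal's* edge is
   flagged and thin parts of the plant far from the pedestal are spared.
   Components smaller than `min_component_size` are dropped from the mask
   (component selection removes them anyway).
5. **Flood fill** (`select_plant_component()`): keep one connected
   component under the configured connectivity (default 26, which keeps
   thin sheets connected across voxel staircases) — the largest, or the
   one containing a seed voxel. If the surviving component is smaller
   than `min_component_size`, the pipeline fails with
   `"no plant component found"` rather than returning debris.

**Automatic thresholds.** The plant class is a small fraction of the
scene, so plain two-class Otsu lands between the background and the
*pedestal* — above the plant. When both thresholds are `"auto"` the
pipeline instead uses three-class Otsu (`multi_otsu3()`): the lower
threshold separates background from plant-like material, the upper
separates it from pedestal/case. Both are config-overridable
(`extraction_config()`), since any real deployment will want to pin them
per scanner protocol.

On the bundled phantom scenes (noise sd 5 on intensity steps of 100) the
pipeline recovers the plant with Jaccard 1.00 (flat) and 0.99 (twisted),
degrades monotonically with noise, and fails cleanly on a plant-free
scene.

## Meshing and hull: numerical choices

`V` and `A` are measured on an iso-surface mesh, not by voxel counting:
voxel-face area does not converge to the true area (about +50% on
spheres) and would corrupt \(C\). The mesher is **marching tetrahedra**
on the Kuhn 6-tetrahedron cell decomposition. That decomposition is
face-consistent across cells and every case is unambiguous, so the mesh
is watertight and consistently oriented *by construction* — `mesh_volume()`
verifies closure (every edge on exactly two faces) before integrating
signed tetrahedra.

Meshing the raw binary field at level 0.5 overestimates curved areas
severely (staircase jaggies; +28% on a radius-20 ball with this mesher),
while heavy Gaussian smoothing of the field rounds away true edges and
corners. The default is therefore a *combination*, chosen once against
analytic solids and then frozen:

* Gaussian field smoothing, `smooth_sigma = 0.6` voxels;
* shrink-free Taubin mesh smoothing, 10 iterations,
  \(\lambda = 0.5, \mu = -0.53\).

With these defaults a 10-voxel cube is within 3.3% / 9.5% of its analytic
volume / area, and a radius-20 ball within 0.2% / 2.3%. Objects so thin
that field smoothing erases them fall back to the raw field with a
warning. One honest limitation: the residual staircase area bias is fixed
in *voxel* units, so \(|C-1|\) on a ball does **not** shrink as the
radius grows (it stays below 2%), whereas \(|S-1|\) does converge. The
test suite asserts exactly that.

The convex hull is computed over the **mesh vertices** (quickhull in C++,
with tolerance-escalation retry and a closure check on the facet
surface). Because the hull of the mesh vertices contains the mesh region,
\(V \le V_C\) and hence \(S \le 1\) holds as a theorem under this
convention — up to the hull's facet tolerance (1e-10 of the bounding-box
diagonal), which can exclude vertices grazing the boundary and undershoot
\(V_C\) by up to (tolerance × hull area). `measure()` treats an excess of
\(V\) over \(V_C\) within that explained slack as "numerically convex"
(\(S = 1\)) and errors beyond it. Degenerate (coplanar) point sets are
rejected, never silently reduced to a 2D hull. Ties on the LDA boundary
classify as the positive (higher-convexity, wild-type-like) label — an
arbitrary but documented rule, overridable via the exposed
`positive_label`.

## What the phantoms emulate — and what they do not

`make_scene()` rebuilds the *engineered* contrast regime of the original
imaging setup: background 0, plant 100, pedestal 200 (the plastic-eraser
trick that makes the pedestal much brighter than the sample), tube wall
230, additive Gaussian noise (sd 5 by default), and a one-voxel
partial-volume rim at plant intensity on the pedestal's air-exposed
boundary — without the rim, Mask2 would have nothing to do and the
pipeline's hardest failure mode (rim welded to the plant) would go
untested. Plant bodies are voxelized by center inclusion (a voxel is
foreground iff its center is inside the analytic solid), the simplest
rule whose measurements converge to the attached analytic ground truth
with resolution. `sample_population()` jitters all size parameters (and
twist/undulation when present) with mean-preserving lognormal noise,
relative sd 0.1 — about the size scatter one sees between same-age
gemmalings — with n = 18 per line, matching the study design the package
mirrors.

The phantoms deliberately do **not** model CT physics (beam hardening,
ring artifacts, partial-volume blur beyond the 1-voxel rim), dichotomous
thallus branching, gemma cups, or multi-plant scenes. A green test
therefore establishes that the *pipeline machinery* — masking,
flood-fill, meshing, hull, descriptors, LDA — is correct on bodies of
known geometry in the stated contrast regime; it does not establish
segmentation robustness on real scanner data, where thresholds will need
per-protocol tuning.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `plant_threshold`, `high_threshold` | `"auto"` (3-class Otsu) | intensity | The published macro's values are not recoverable; auto matches the engineered contrast and is overridable. |
| `edge_threshold` | 0.25 | gradient magnitude | A binary interface has gradient 0.5; 0.25 marks every interface voxel. |
| `min_component_size` | 27 | voxels | A 3×3×3 cube: anything smaller is a speck. |
| `connectivity` | 26 (plant), 6 (specks) | — | 26 keeps thin sheets connected; 6 keeps speck components small. |
| `mask_dilation_radius` | 0 | voxels | Dilation eats the plant's contact layer; the rim it would remove is Mask2's job. |
| `smooth_sigma` | 0.6 | voxels | See meshing section. |
| `taubin_iters` | 10 | — | See meshing section. |
| hull `tol` | 1e-10 | × bbox diagonal | Facet-plane slack; escalated ×100 on the rare closure failure. |
| `jitter` | 0.1 | relative sd | Population size scatter. |
| `noise_sd` | 5 | intensity | 5% of the plant-background contrast. |

## Known limitations

* TIFF support is a minimal baseline codec (uncompressed grayscale
  strips, 8/16-bit unsigned or 32-bit float, both byte orders on read);
  compressed or tiled files from vendor software must be re-exported.
* Spacing is isotropic; anisotropic voxels are out of scope.
* \(C\) depends on the meshing convention at the ~2% level; comparisons
  are meaningful within one pipeline, not across packages.
* Training-set accuracy is reported, as in the study mirrored here;
  no cross-validation is implemented.
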