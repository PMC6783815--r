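# morphoct

3D morphometrics of irregular plant bodies from micro-CT volumes.

Thalloid plants such as the liverwort *Marchantia polymorpha* grow as
thin sheets; mutants of morphogenesis genes twist and undulate in ways
that differ between individuals of the same genotype, defeating
landmark-based shape analysis. `morphoct` implements a landmark-free
pipeline for exactly this regime:

1. **Extraction** — isolate the binary plant body from a micro-CT scene
   containing a high-intensity pedestal and tube-case wall: high-intensity
   masking (Mask1), subtraction, binarization, edge/rim noise masking
   (Mask2), and 3D flood-fill component selection.
2. **Descriptors** — mesh the body's iso-surface (marching tetrahedra,
   watertight by construction), compute its 3D convex hull (quickhull),
   and evaluate

   $$C = \frac{A_C}{A} \qquad S = \frac{V}{V_C}$$

   where $V, A$ are the body's volume and surface area and $V_C, A_C$
   those of its convex hull. Flat convex sheets have $C \approx S
   \approx 1$; curling drives $S$ down, surface undulation drives $C$
   down.
3. **Classification** — two-class linear discriminant analysis in the
   $(S, C)$ plane with pooled covariance and equal priors, reported as a
   boundary line $y = a x + b$, with accuracy and Cohen's kappa
   $\kappa = (p_o - p_e)/(1 - p_e)$; for a balanced design
   $\kappa = 2\,\mathrm{accuracy} - 1$.
4. **Phantoms** — synthetic flat (wild-type-like) and twisted/undulating
   (mutant-like) thallus sheets with analytic ground truth, plus full
   synthetic scenes (pedestal, tube wall, partial-volume rim, Gaussian
   noise), so the whole pipeline is testable without scanner data.

Volumes are multi-page TIFF stacks (voxel spacing in the resolution
tags); descriptor tables are CSV; hulls export as ASCII PLY.

## Worked example

Measure a flat sheet and a twisted, undulating one:

```r
library(morphoct)
flat <- measure(make_twisted_slab(60, 24, 5, twist = 0), label = "WT")
mut  <- measure(make_twisted_slab(60, 24, 5, twist = 180,
                                  undulation_amplitude = 2,
                                  undulation_period = 20), label = "mutant")
rbind(flat, mut)
#>                name    V    Vc    A   Ac     C      S  label
#> 1   twisted_slab_t0 5662  5695 3390 3393 1.001 0.9942     WT
#> 2 twisted_slab_t180 7048 20886 3966 4501 1.135 0.3374 mutant
```

The flat sheet is its own convex hull ($S = 0.99$). The twisted sheet
sweeps out a hull three times its volume ($S = 0.34$) — solidity is the
workhorse separator for twist.

Run the bundled end-to-end demo (two populations of 18 phantoms, scene
simulation, extraction, measurement, LDA; about 15 s):

```r
run_all(system.file("extdata/demo_config.yaml", package = "morphoct"))
#> group 'WT': 18 bodies
#> group 'mutant': 18 bodies
#> wrote demo_out/descriptors.csv (36 records)
#> LDA: y = -2.023 x + 2.44; accuracy 1.000, kappa 1.000
#> wrote demo_out/report.json
```

The report contains the discriminant line, the confusion matrix,
training accuracy and kappa, and per-sample predictions. The synthetic
groups are cleanly separable (accuracy 1.0); the original study's real
populations overlap more (accuracy 0.917, kappa 0.834 for N = 18 + 18).

The same pipeline is scriptable from the shell:

```sh
Rscript -e 'morphoct::morphoct_cli()' simulate --spec scene.yaml --out-dir sim/
Rscript -e 'morphoct::morphoct_cli()' extract  --in sim/scene.tif --out plant.tif
Rscript -e 'morphoct::morphoct_cli()' measure  --in plant.tif --out descriptors.csv --hull-out hull.ply
Rscript -e 'morphoct::morphoct_cli()' classify --train train.csv --test test.csv --out report.json
Rscript -e 'morphoct::morphoct_cli()' compare  --in descriptors.csv --reference WT --out compare.json
Rscript -e 'morphoct::morphoct_cli()' run-all  --config run.yaml
```

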