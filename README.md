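# tomosgp

Model-based iterative reconstruction for **digital breast tomosynthesis
(DBT)** in R.

DBT images the compressed breast from a handful of X-ray views (typically
11 over a ±15° arc), so the tomographic system `A x = b` is severely
under-determined and analytic inversion produces noisy, artifact-ridden
slices. `tomosgp` reconstructs the attenuation volume as the solution of
the convex constrained program

```
min_{x >= 0}  f(x) = 1/2 ||A x - b||^2 + lambda * sum_j sqrt(||grad x_j||^2 + beta^2)
```

— nonnegative least squares with a smoothed total-variation (TV) prior —
solved by the **Scaled Gradient Projection (SGP)** algorithm: projected
gradient descent with a diagonal scaling matrix built from a
positive/negative gradient splitting, adaptive Barzilai–Borwein
steplengths, and Armijo backtracking. The forward model is a matrix-free
**distance-driven** cone-beam projector (compiled, double precision) with
an exactly matched adjoint; rows of `A` are recomputed on the fly and
never stored. The package is for researchers prototyping limited-angle
reconstruction methods and for teaching the model-based reconstruction
chain end to end at desk scale.

What is in the box:

* S4 data classes (`ScanGeometry`, `VolumeGrid`, `Volume`,
  `ProjectionStack`) with validity checking and accessors;
* `forwardProject()` / `backProject()` — matched distance-driven
  projectors, with Z-chunked evaluation (halo slices for TV) certified
  equal to the unchunked result;
* `tvValue()` / `tvGradient()` / `objectiveGradient()` — the smoothed-TV
  objective and its analytic gradient;
* `sgpSolve()` — the SGP solver with iteration log, checkpoint
  snapshots, and bitwise-reproducible runs;
* `d3Preset()` / `makePhantom()` / `addNoise()` — a scalable digital
  breast phantom (0.300 mm microcalcification bead cluster, mass, fiber
  in an adipose-like slab) with an SNR-exact Gaussian noise model;
* `roiStats()`, `lineProfile()`, `contrast()`, `recoveryError()` —
  reconstruction quality metrics;
* raw+JSON / TIFF volume I/O, YAML geometry configs, and a small CLI
  (`inst/cli/tomosgp`: `simulate`, `reconstruct`, `analyze`).

## Worked example

Simulate the desk-scale phantom study (a 150 × 50 × 5 volume at
0.1/0.1/1.0 mm voxels, 11 views, SNR 50 dB noise) and reconstruct it:

```r
library(tomosgp)

ds    <- d3Preset(scale = 0.05, snrDb = 50, seed = 1)
truth <- makePhantom(ds$phantom)
b     <- addNoise(simulateProjections(truth, ds$geometry), ds$noise)

fit <- sgpSolve(b, ds$grid, objectiveConfig(lambda = 0.01),
                solverConfig(maxiter = 30, tol = 1e-10),
                checkpoints = c(4, 12, 30))
fit$x
#> Volume: 150 x 50 x 5 voxels; range [ 0.04484 , 0.1957 ] 1/mm

vapply(fit$state$checkpoints, recoveryError, numeric(1), truth = truth)
#>      iter4     iter12     iter30
#> 0.05453639 0.03567720 0.02950101

head(fit$state$log[, c("iteration", "f", "ls", "tv", "eta")], 3)
#>   iteration         f        ls       tv    eta
#> 1         1 6.3318695 5.3558437 97.60258 0.0256
#> 2         2 1.9094830 1.0704934 83.89896 1.0000
#> 3         3 1.2569718 0.4672766 78.96952 1.0000
```

The relative recovery error falls from 5.5 % after 4 iterations to 3.0 %
after 30, and the objective `f` shows the sharp early drop characteristic
of the scaled iteration (most of the decrease happens in the first few
steps). Quality metrics on the central slice:

```r
roiStats(fit$x, roi(3, 5:30, 5:15))            # background uniformity
#>    mean  stddev
#> 5.0e-02 3.1e-05
contrast(fit$x, roi(3, 75:77, 25:27), roi(3, 5:30, 5:15))
#> [1] 2.447182
```

The background is recovered at its true attenuation (0.05/mm) with noise
suppressed by the TV prior, and the central 0.300 mm bead — three voxels
wide at this pitch — stands out at contrast 2.45, far above the
5-standard-deviation detection threshold. `lineProfile()` extracts the
in-plane profile through the bead for overlay plots across checkpoints;
`writeVolumeTiff()` exports slices for visual inspection.

The regularization weight has no universal default; `tuneLambda()` sweeps
candidates against a known phantom (for this preset the sweep selects
`lambda = 0.01`).

The same pipeline runs from a shell:

```sh
Rscript inst/cli/tomosgp simulate --preset d3 --scale 0.05 --seed 1 --out sim/
Rscript inst/cli/tomosgp reconstruct --input sim/ --lambda 0.01 \
    --iters 30 --checkpoints 4,12,30 --out rec/
Rscript inst/cli/tomosgp analyze --recon rec/recon --truth sim/truth --out metrics.csv
```

## Scope

The package models a monochromatic beam and an ideal detector (no
scatter, blur or dose model), reconstructs on one CPU (chunked evaluation
certifies partitioned correctness; there is no GPU path), and leaves the
choice of `lambda` to the user. See the methods vignette
(`vignettes/dbt-sgp-methods.Rmd`) for the model, algorithm, parameter
semantics and design decisions.
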