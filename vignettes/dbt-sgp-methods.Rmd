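---
title: "Model-based DBT reconstruction with scaled gradient projection: methods and design"
author: "tomosgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based DBT reconstruction with scaled gradient projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomosgp)
```

## The reconstruction problem

Digital breast tomosynthesis (DBT) acquires a small number of cone-beam
X-ray projections — typically around eleven views over a narrow arc of
±15° — of a compressed breast resting on a flat detector. The data are
severely incomplete: the number of measured detector values $N_d$ is
smaller than the number of unknown voxels $N_v$, so the linear system
$Ax = b$ relating the attenuation volume $x$ to the log-transformed
projections $b$ is under-determined, and analytic inversion (filtered back
projection) amplifies noise and limited-angle artifacts.

`tomosgp` implements the model-based alternative: reconstruct $x$ as the
solution of the convex, constrained program

$$
\min_{x \ge 0}\; f(x) = \tfrac{1}{2}\,\lVert Ax - b \rVert_2^2
  + \lambda \sum_{j=1}^{N_v} \sqrt{\lVert \nabla x_j \rVert_2^2 + \beta^2},
$$

a nonnegative least-squares fit with a smoothed total-variation (TV)
prior. The voxelwise gradient $\nabla x_j$ uses forward differences along
the three Cartesian directions; $\beta > 0$ removes the kink of the TV
seminorm at zero gradient so $f$ is differentiable everywhere, and
$\lambda > 0$ balances data fidelity against the edge-preserving prior.
Nonnegativity reflects the physics: $x$ is a map of linear attenuation
coefficients (1/mm).

## The system model

### Geometry

The acquisition frame is right-handed with the detector in the plane
$Z = 0$, $X$ along detector columns, $Y$ along the source-motion
direction and $Z$ up toward the source. The source rotates on a C-arc in
the $YZ$ plane about a configurable `arcCenter`; the detector stays fixed.
The packaged `giottoGeometry()` preset encodes a representative clinical
unit: 11 views from −15° to +15°, source 690 mm above the detector at the
central position, and a 3580 × 2812 detector with 0.085 mm pixels. The
rotation-center location is not fixed by the hardware description we
model, so it is an explicit field (defaulting to the detector-plane point
below the central source) rather than a hidden assumption.

All user-facing indices in the R interface are 1-based; cell corners
anchor voxels and pixels, and cells are half-open boxes
$[\text{corner}, \text{corner} + \text{pitch})$, so boundary ties never
count twice.

### Distance-driven projectors

The matrix $A$ is far too large to store ($N_d \times N_v$ reaches
$10^{15}$ entries at clinical scale with a nonzero density of order
$10^{-7}$), so both projectors are matrix-free: every row is recomputed
on demand, in compiled code. Weights follow the distance-driven model:
for each slice, the four X/Y boundaries of a detector pixel are centrally
projected from the source onto the slice mid-plane, and each voxel
receives the fractional footprint overlap times $dz / \cos\varphi$, where
$\varphi$ is the angle between the central pixel ray and the Z axis.

Two design points deserve note:

* **Weight normalization.** Weights are *effective path lengths in mm*
  (footprint overlap fraction × slab traversal), so $Ax$ approximates the
  Beer–Lambert line integral and the data term is physically
  interpretable. A uniform slab of attenuation $\mu$ projects to
  $\mu \times \text{thickness}$ under a vertical ray.
* **Mid-plane footprints.** The footprint is evaluated on each slice's
  mid-plane rather than by exact 3D polytope intersection. This is the
  standard distance-driven simplification; `oracleRow()` — an independent
  brute-force reference that casts a stratified grid of sub-rays through
  the pixel and accumulates exact ray–box intersection lengths — bounds
  the approximation error, which stays well below 2 % per row on the test
  geometries.

The backward projector reuses the identical weight computation, making it
the *exact* adjoint of the forward projector; the test suite verifies
$\langle Ax, y\rangle = \langle x, A^T y\rangle$ to $10^{-10}$ relative on
randomized acquisitions. All arithmetic is double precision (single
precision is known to be insufficient for this objective), loop orders are
fixed, and no threading is used internally, so results are bitwise
reproducible.

### Chunked evaluation

Clinical-scale volumes do not fit accelerator memory, so the operators
support partitioned evaluation along Z. Chunking is implemented here as a
*correctness contract* rather than a performance feature: forward
projection accumulates per-chunk partial sums (exact by linearity),
backward projection writes disjoint slice blocks, and the TV value and
gradient extend each chunk by one halo slice so border finite differences
are exact. The suite checks that every operator agrees with its unchunked
result to $10^{-12}$ relative for chunk sizes 1, 2 and $N_z$; the TV
gradient agrees bitwise.

## The solver

`sgpSolve()` implements scaled gradient projection (SGP): projected
gradient descent whose descent direction is premultiplied by a diagonal
scaling matrix $D_k$, with Barzilai–Borwein (BB) steplengths and Armijo
backtracking. Each iteration:

1. $d^{(k)} = P_+(x^{(k)} - \alpha_k D_k \nabla f(x^{(k)})) - x^{(k)}$,
   with $P_+$ the Euclidean projection onto $x \ge 0$;
2. backtracking from $\eta = 1$, shrinking by $\gamma$ until
   $f(x^{(k)} + \eta d^{(k)}) \le f(x^{(k)}) + \sigma\eta\,\nabla f(x^{(k)})^T d^{(k)}$;
3. $x^{(k+1)} = x^{(k)} + \eta d^{(k)}$;
4. $\rho_{k+1} = \sqrt{1 + 10^{15}/(k+1)^{2.1}}$ and
   $D_{k+1} = \mathrm{clip}(x_j / V_j,\; 1/\rho_{k+1},\; \rho_{k+1})$,
   where $V$ is the positive part of the gradient splitting
   $\nabla f = V - U$ ($V = A^T A x + \lambda V_{TV} \ge 0$ for
   $x \ge 0$); entries with $x_j = 0$ or $V_j = 0$ default to 1;
5. an adaptive alternation of the two scaled BB rules updates
   $\alpha_{k+1} \in [\alpha_{\min}, \alpha_{\max}]$.

Iterations stop when $|f(x^{(k)}) - f(x^{(k-1)})| < 10^{-6} |f(x^{(k)})|$
(configurable) or the iteration cap is reached. The $\rho$ schedule
leaves the scaling essentially unconstrained early — where it acts as a
cheap diagonal preconditioner — and drives $D_k$ to the identity, which
the method's convergence theory requires.

Design choices the method statement leaves open, fixed here once:

* **Defaults** $\sigma = 10^{-4}$, $\gamma = 0.4$,
  $\alpha_{\min} = 10^{-10}$, $\alpha_{\max} = 10^{5}$,
  $\alpha_0 = 1.3$, BB switching threshold $0.5$ with memory 2 (smallest
  remembered BB2 on the small-step branch, threshold shrunk by 0.9 /
  grown by 1.1). These are the canonical settings of the SGP literature
  lineage; all are `solverConfig()` fields.
* **Initialization** $x^{(0)} = P_+(A^T b)$, rescaled so
  $\lVert A x^{(0)} \rVert = \lVert b \rVert$: deterministic and
  geometry-aware. Only nonnegativity of $x^{(0)}$ is required by the
  method, so iteration-indexed comparisons against other implementations
  are not meaningful unless they share this choice.
* **Per-iteration cost.** One forward and one backward projection:
  $A^T b$ is precomputed, $A d$ serves both the line search and the
  running update $Ax^{(k+1)} = Ax^{(k)} + \eta A d$, and each extra
  backtracking trial re-evaluates only vector arithmetic and the TV term.
  $V = A^T A x$ is recovered as $A^T(Ax - b) + A^T b$ (clipped at zero
  against roundoff) instead of a third projection.
* **Degeneracies.** A zero direction, or a directional derivative at
  roundoff level relative to $f$, stops the iteration as numerically
  stationary; more than 60 backtracking shrinks raises an error, since
  that indicates an inconsistent gradient rather than a hard line search.
  After the update the iterate is re-projected onto $x \ge 0$ so
  feasibility is exact, not merely up to roundoff.

### Objective parameters

* `beta` defaults to $10^{-3}$ in attenuation units (1/mm): small against
  typical tissue gradients (~$10^{-2}$–$10^{-1}$), large enough to keep
  $f$ smooth near flat regions. The TV floor $\lambda N_v \beta$ is an
  exact lower bound on $f$ used as a sanity check in the tests.
* `lambda` has no universal value and depends on noise level, geometry
  and discretization; the field's practice is trial and error.
  `tuneLambda()` makes that explicit: it sweeps candidates and reports
  recovery error against a known phantom. For the packaged desk-scale
  simulation (below), a sweep over $10^{-4}$–$10^{-1}$ selected
  $\lambda = 0.01$ (recovery error 0.030 at 30 iterations, vs 0.041 and
  0.045 at the sweep ends); that value is used by the worked examples.
* `anisotropy` optionally weights the Z difference inside
  $\lVert \nabla x_j \rVert$. DBT voxels are strongly anisotropic
  (e.g. 0.1 mm in-plane vs 1 mm slices), and whether the prior should
  compensate is genuinely open; the default treats the three differences
  equally, matching the plain forward-difference formulation.
* **Boundary rule.** Forward differences use replicate (Neumann)
  boundaries: the difference at the far face is zero. This makes constant
  volumes TV-stationary (no spurious boundary forces) and gives the exact
  identities $TV(\text{const}) = N_v\beta$ and
  $\sum_j [\nabla TV]_j = 0$ that the tests pin down.

## The simulation study

`d3Preset()` emulates a simulated microcalcification-detection study: a
uniform adipose-like slab (0.05/mm, a representative soft-tissue
attenuation at mammographic energies) holding a cluster of five 0.300 mm
beads — three voxels wide at the 0.100 mm in-plane pitch, the canonical
medium microcalcification surrogate — plus a larger low-contrast mass and
a fiber, projected under an 11-view ±15° geometry onto a 0.100 mm-pitch
detector and corrupted by white Gaussian noise at SNR 50 dB. Object
attenuations (beads 10×, masses 1.5×, fibers 2× background) are surrogate
values standing in for a physical phantom's materials; they are fields of
the returned spec, not constants.

Two conventions are worth spelling out:

* **The SNR definition** puts the *noisy* projections in the numerator:
  the noise scale solves
  $20\log_{10}(\lVert b+\varepsilon\rVert / \lVert\varepsilon\rVert) =
  \text{SNR}$ analytically (a quadratic in the scale), so the measured
  ratio matches the request to $10^{-9}$ and a fixed seed reproduces the
  stack bitwise. The conventional $\lVert b \rVert$ numerator is
  available as `convention = "clean"`.
* **Scaling.** At full scale the volume is 3000 × 1000 × 50 at
  0.100/1.000 mm and the detector 3200 × 1100. In-plane counts scale
  proportionally with `scale`; the slice count scales by
  $\min(1, 2\,\text{scale})$ so that desk-scale configurations keep a
  meaningful slice stack (at `scale = 0.05`: a 150 × 50 × 5 volume and
  160 × 55 detector — the problem size used throughout the tests and the
  acceptance script, reconstructable in seconds on one CPU core).

Rasterization uses fixed 3³ stratified sub-voxel sampling for partial
volume weighting — deterministic, mass-conserving to ~1 % for objects a
few voxels across, and refinement-consistent.

What the simulator does *not* emulate: anatomical texture, detector blur
and MTF, scatter, polychromatic beam hardening (the forward model is
monochromatic), and dose. Passing the recovery tests therefore
demonstrates the *algorithmic* chain — model, projectors, solver — under
a controlled forward model, not clinical image quality.

## What the package verifies about itself

The test suite is organized around independent oracles rather than
regression values: a ray-casting reference for the projector, a naive
triple-loop for TV, central differences for every gradient, explicit
row-assembly double loops for adjointness, a slow fixed-step projected
gradient run for the solver's optimum (agreement to $10^{-14}$ observed,
$10^{-6}$ required), and a permutation-system geometry in which the exact
constrained minimizer $\max(b, 0)$ is known in closed form. The
desk-scale study asserts the qualitative claims that matter clinically:
recovery error strictly decreases across checkpoints 4 → 12 → 30, and at
30 iterations the bead cluster stands more than five background standard
deviations above the background mean, while the objective shows the
characteristic sharp drop of the scaled iteration within the first few
steps.

`scripts/acceptance.R` re-derives all of these quantities from scratch
against the installed package and writes them to JSON; see the README for
invocation.

## Known limitations

* The distance-driven footprint uses slice mid-planes and a per-pixel
  central-ray obliquity factor; highly oblique geometries (beyond the
  ±15° DBT arc) would stress both approximations.
* No acceleration beyond the diagonal scaling: optimal $O(1/k^2)$
  first-order variants and ordered-subset schemes are out of scope, as is
  GPU execution — chunking here certifies partitioned correctness only.
* `lambda` must be chosen by the user (with `tuneLambda()` support);
  no automatic selection is attempted.
* Line profiles are axis-aligned; oblique profiles require resampling the
  volume externally.
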