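---
title: "Comparative cranial FEA with craniofem: model, protocols, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative cranial FEA with craniofem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(craniofem)
```

## The question the pipeline answers

Comparative cranial finite-element analysis asks how well different cranial
*shapes* resist feeding loads, independent of absolute size and of absolute
muscle strength. The inputs are tetrahedral volume meshes of crania (here,
either synthetic test geometry or meshes imported from an Abaqus-INP
dialect), and the outputs are stress and strain-energy summaries that are
deliberately constructed to be size-comparable. Everything downstream —
which taxon is "stronger", where the stress concentrates — is read off
those summaries and the exported contour fields.

## The mechanical model and its assumptions

The solver implements small-strain linear elasticity on four-noded
tetrahedra (the constant-strain tetrahedron, CST). Each element carries a
single strain and stress tensor; the element stiffness is

$$K_e = V \, B^\mathsf{T} D B,$$

with $B$ the constant 6×12 strain–displacement matrix from the linear
shape-function gradients and $D$ the isotropic constitutive matrix built
from Young's modulus $E$ and Poisson's ratio $\nu$ (Voigt order
xx, yy, zz, xy, yz, zx; engineering shear strains). The modelling
assumptions are the standard ones of this kind of comparative analysis:

- **isotropic, homogeneous materials** per tissue: bone
  $E = 20.49\,\mathrm{GPa}, \nu = 0.40$ and teeth
  $E = 60.40\,\mathrm{GPa}, \nu = 0.31$ by default (alligator mandible and
  crocodile tooth data); keratin has *no* default — rhamphotheca runs must
  supply their constants explicitly, because published values vary widely;
- **linear kinematics**: displacements are small relative to the cranium;
  this makes every solution exactly linear in the loads (doubling forces
  doubles stress and quadruples strain energy), which the test suite
  exploits;
- **no sutures, no contact, no kinesis**: the cranium is one fused elastic
  body; regions that were flexibly connected in life will read as stiffer
  and may concentrate stress;
- **rigid supports**: constraints prescribe zero displacement exactly.

Units are mm / N / MPa internally, so stresses come out in MPa with no
conversion; configuration files accept GPa and convert by 1000 on load.

### Constraint handling and the solver

Constraints are imposed by *eliminating* the constrained degrees of freedom
and solving the reduced symmetric positive-definite system with a sparse
Cholesky factorisation (a Jacobi-preconditioned conjugate-gradient fallback
with relative residual $10^{-10}$ is available; both are deterministic).
Penalty methods were rejected deliberately: a penalty spring injects large
artificial stiffness at exactly the nodes whose neighbourhood feeds the
peak-stress statistic, which the trimming step is trying to protect. If the
reduced system is singular (an unsuppressed rigid-body mode) the solve
fails with a diagnostic rather than returning garbage; a load case must
constrain at least 6 degrees of freedom before it is even accepted.

Strain energy is computed as $U = \tfrac12 f^\mathsf{T} u$ over the applied
loads; reaction work vanishes because all constraints are homogeneous.

### Stress reporting

Commercial solvers export "von Mises stress at every element node". For a
CST element the stress is constant, so the element-nodal report is realised
as each element's value replicated at its four corners — a multiset of
exactly $4 n_\text{el}$ values per model. This replication is an
approximation to whatever nodal extrapolation a commercial code performs;
it is the conservative choice because it introduces no smoothing. A
node-averaged field is also computed, but only for contour export — never
for statistics.

## The comparative protocols

### Area-scaled bending

Stress scales with area, so to compare crania of different sizes at equal
*relative* load, each model's total palatal force is
$F_i = 100\,\mathrm{N} \cdot A_i / A_\min$: the smallest cranium receives
exactly 100 N (an arbitrary but realistic bite-scale force) and larger ones
proportionally more. Loads act dorsally (+z, "perpendicular to the palate"
with the cranium in standard orientation — a global-axis reading of that
phrase; per-node surface normals were considered and rejected as
mesh-resolution-sensitive), split *equally* over the palate nodes of the
chosen position. Whether the original protocol split loads across several
nodes per side or used a single node is not documented; the equal split is
this package's choice and is recorded here. Unilateral means left side, and
three positions (anterior tip, lateral mid-palate margin, posterior palate)
× two lateralities give the six bending scenarios per model. Constraints
are always 4 fully fixed nodes per quadrate articular patch plus 3 on the
occipital condyle.

### Muscle-driven biting

Each jaw adductor contributes its contraction force divided across **eight
nodes** of its origin node set, each nodal force aimed from its node at the
muscle's insertion point. The insertion point is an *input*: the force
vectors descend from volumetric muscle reconstructions, so the pipeline
must not invent them. How the original eight nodes were chosen is not
documented; here they are the eight set members nearest the set centroid
(ties broken by node index), a rule chosen purely so scenario construction
is deterministic. Note that with a fanned origin patch the vector resultant
is slightly below the scalar force sum; the per-muscle *magnitude* sum is
what equals the contraction force. Bite points are constrained in the
vertical (z) axis only — one node for a unilateral (left) bite, two for a
bilateral bite — and the summed vertical reaction at those nodes is the
modelled bite force (`bite_reaction()`).

### Extrinsic movements and the rhamphotheca

Head-pull (posterior −y), head-shake (lateral +x) and head-twist (equal and
opposite z loads on the left/right beak-tip groups: a pure couple) act on
the beak-tip node sets under the standard posterior constraints. Their
magnitudes are configuration inputs with no asserted defaults — the
reference magnitudes for such scenarios live in supplementary material that
varies between studies. The rhamphotheca overlay re-labels beak-region
elements to a keratin material; geometry and mesh are untouched, so
overlaid and bone-only runs are element-by-element comparable.

## The statistics

- **Top-5% trim**: `floor(0.05 · n)` of the largest element-nodal values
  are removed before any statistic is computed. The floor is deliberate:
  it never removes more than the stated fraction, and it makes the retained
  count exactly `ceiling(0.95 · n)`. Ties at the cut are resolved by count,
  not by value, so the operation is a pure function of the sorted multiset.
- **Quartiles** are computed on the trimmed multiset by linear
  interpolation between order statistics (`stats::quantile` type 7). The
  original protocol does not say whether its quartiles were trimmed;
  trimming them keeps every reported statistic a function of one multiset.
- **Peak** is the maximum of the retained values (equivalently the value
  just below the 95th percentile). Reporting the 95th percentile itself was
  the alternative; the two differ by at most one order statistic.
- **Strain-energy size correction**: reported as
  $U_\text{corr} = U \cdot V_\text{ref} / V$. When loads are pre-scaled by
  surface area, stress — hence energy density — is size-invariant for
  geometrically similar shapes, so $U \propto V$ and dividing by volume
  (times a common reference volume, by convention the smallest model in the
  run) is the unique linear correction that makes $U$ comparable across
  sizes. The acceptance suite verifies this operationally: a scale-1 and a
  scale-2 copy of the same cranium under area-scaled loads agree in
  corrected energy to better than $10^{-5}$ relative.

## Synthetic geometry: what it does and does not emulate

`make_toy_skull()` generates a rostrally tapering box carrying every
landmark node set the protocols need (palate bite points at three positions
× two sides, 4-node quadrate patches, a 3-node occipital patch, 8-node
adductor origin patches, beak tips, and optional beak/tooth element
regions). Its purpose is *contractual*, not anatomical: the pipeline's
guarantees — symmetry, scaling laws, determinism, protocol constants — are
geometric and statistical, so they can be tested exactly on geometry whose
ground truth is known. Defaults (60 × 30 × 24 mm, 50% rostral taper,
8 × 12 × 6 grid cells ≈ 3.5k elements) give a small-oviraptorid-scale
cranium that solves in well under a second.

Two generator details matter for testing. First, the grid is
tetrahedralised with a Kuhn 6-tet split that is *mirrored cell-by-cell*
about the midsagittal plane, so a bilaterally loaded model produces an
exactly mirror-symmetric element-level stress field — the symmetry checks
hold to ~1e-13, not just to mesh-asymmetry error. Second, generation is
seed-deterministic (the seed only matters if node jitter is enabled;
jitter deliberately breaks symmetry and is off by default). An optional
internal cavity ("fenestra" toggle) exercises non-convex topology; by
default cavity walls count toward the load-scaling surface area, with
`surface_area(mesh, outer_only = TRUE)` restricting to the outermost shell
— whether enclosed pneumatic surfaces should count is genuinely ambiguous,
so both are offered and the inclusive reading is the default.

What the toy skull does **not** emulate: real cranial topology (fenestrae,
struts, thin laminae), heterogeneous bone, sutures, or realistic muscle
fibre architecture. Passing tests on it demonstrates that the *pipeline*
is correct — solver, protocols, statistics — not that any biological
conclusion transfers; conclusions about real crania require real meshes,
which the INP reader ingests.

`make_beam()` provides the analytic validation geometry: a slender
cantilever whose Euler–Bernoulli tip deflection $PL^3/3EI$ the solver must
approach from below (CST elements are stiff in bending and converge slowly;
that is a property of the element, not a defect of the implementation).

## Numerical choices and problem sizes

- Patch test: a 2 × 1 × 1 block, 48 elements, uniform traction by
  consistent nodal loads — constant stress is recovered to machine
  precision (~1e-15 MPa), the defining correctness property of a conforming
  displacement element.
- Beam convergence: slenderness 10, refinement levels 20×2×2, 40×4×4 and
  80×8×8 cells (up to ~31k elements); the tip-deflection error falls
  monotonically to ≈4.6%, within the 10% band expected of CST at this
  refinement. These sizes were chosen as the coarsest ladder that shows
  clean monotone convergence.
- Dense-solve cross-check: meshes up to 300 DOFs, sparse vs dense direct
  solution agreeing to 1e-9 relative.
- Degenerate (zero-volume) tets are a validation *failure*, never silently
  dropped — dropping an element changes the stiffness of everything around
  it. Inverted elements, by contrast, are auto-repaired at construction by
  a node swap (orientation is a bookkeeping property, volume is not).
- Scenario tolerances: load-magnitude bookkeeping to 1e-9 relative;
  symmetry and multiset comparisons to 1e-6 relative; similarity-family
  statistics to 1e-6 (stress) and 1e-5 (corrected energy) relative.

## Known limitations

- CST elements underestimate bending compliance at coarse resolution; all
  cross-model comparisons should use comparable mesh densities (the
  area-scaled protocol shares one mesh across the similarity family, which
  sidesteps this entirely).
- The element-nodal replication of stress is one of several defensible
  readings of a commercial element-nodal export; absolute trimmed peaks may
  differ slightly from a solver that extrapolates and averages.
- Muscle wrapping, pennation and activation dynamics are out of scope; a
  muscle is eight straight lines of action.
- No contact at the bite point: the vertical constraint can in principle
  pull as well as push; interpreting its reaction as bite force assumes the
  load system compresses the bite point, which holds for jaw-adductor
  geometries.
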