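---
title: "Designing functionally graded lattice implants with fglattice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing functionally graded lattice implants with fglattice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fglattice)
```

## The design problem

Solid-metal orthopedic implants such as acetabular reinforcement cages are
five to twenty times stiffer than the bone they replace. The stiff implant
takes over load transfer ("stress shielding"), the surrounding bone is
under-stimulated and resorbs, and the implant eventually loosens. A lattice
implant whose local relative density varies in space can be tuned so that
its stiffness distribution carries the joint load efficiently while staying
porous enough for bone to grow into it.

`fglattice` implements the full design chain for such functionally graded
truss-lattice implants:

1. **Unit-cell morphology** — parametric octet-truss (also body- and
   face-centred) cells, with the density-strut relation and a clinical /
   manufacturing design window.
2. **Numerical homogenization** — the effective elasticity tensor of the
   periodic lattice at a given relative density, from six unit-test-strain
   cell problems on a voxelized representative volume element (RVE).
3. **Surrogate modelling** — a quadratic polynomial for the relative
   modulus and a cubic for the relative Poisson ratio, fitted to the
   homogenization sweep, so that macro-scale element stiffness is a cheap
   function of density.
4. **Bone material mapping** — CT Hounsfield values to tissue density and
   Young's modulus by the standard three-branch piecewise law.
5. **Genetic optimization** — element-wise binary-coded densities evolved
   to minimize structural compliance under a volume constraint.
6. **Lattice building** — mapping the optimized density field to a graded
   strut lattice and exporting printable STL geometry.

The unit system is mm-N-MPa throughout.

## Unit-cell morphology

The octet-truss cell combines an octahedral core (6 nodes, 12 struts
between the face centres of the cube) with corner tetrahedra (24 struts in
the face planes, each shared between two neighbouring cells). All 36 struts
have the same length $l = a/\sqrt{2}$, where $a$ is the cubic cell edge.
For circular struts of radius $t$ the relative density follows the
stretching-dominated closed form

$$\rho \;=\; 6\sqrt{2}\,\pi\,(t/l)^2 ,$$

with porosity $p = 1 - \rho$. A note on symbols: $l$ in this relation is
the **strut length**, not the cell edge — with the cell edge in the
denominator the prefactor would be $12\sqrt{2}\pi$. `unit_cell_spec()`
stores the cell edge and converts internally, so any two of
$\{t, l, \rho\}$ determine the third.

The closed form sums strut volumes and ignores the overlap where struts
meet. That is accurate for slender struts, but at $\rho = 0.5$ the struts
have an aspect ratio of only about 7 and the true boolean-union solid
fraction is about 0.36 — 28% below the nominal value (we verified this with
an independent Monte-Carlo point-membership oracle). Throughout the
pipeline the **nominal** density is the bookkeeping quantity: it sizes the
struts, parameterizes the surrogate and is the GA design variable. The
junction-overlap deficit is therefore a property of the geometry the
equations describe, not an inconsistency of the pipeline.

The design window couples two constraints that both bite at low density:
additive manufacturing cannot print struts thinner than `t_min` (0.2 mm,
compared against the strut **diameter**), and bone ingrowth requires pores
no larger than `pore_max` (0.8 mm; the pore is the face-diagonal opening
$l - 2t$). For cell edges in the working range 1.2-1.5 mm this leaves an
admissible density interval inside the optimization bounds $[0.2, 0.7]$:

```{r}
win <- design_window()
admissible_window(win, 1.35)
```

## Homogenization

`voxelize()` discretizes one cell into an $n^3$ periodic voxel grid.
Two fields are produced: a binary indicator (voxel centre within one strut
radius of a strut axis) and a composite-voxel fraction field in which
voxels cut by the strut surface carry their sub-sampled solid fraction
(3×3×3 sub-points by default). The composite field is the default for
analysis because the binary rule's staircase error is visible at working
resolutions — strut radii span only 2-5 voxels at $n = 48$ — and it is what
lets the surrogate fits reach the quality reported below. Setting
`subsamples = 1` recovers the pure binary discretization.

`effective_tensor()` solves six periodic cell problems, one per unit
macroscopic strain (the remaining five components zero), on a uniform
8-node hexahedral grid with 2×2×2 Gauss quadrature. Element stiffness
scales with the voxel solid fraction; zero-fraction voxels are removed from
the system entirely, after an explicit check that the solid phase is one
periodically connected component (the error message names the axis on which
continuity fails). Removing the void phase keeps the system well
conditioned — a contrast-1e9 ersatz material would make the conjugate
gradient solver crawl and a direct factorization of the full 48³ grid is
out of reach of desk-scale memory. Rigid translations are removed by
pinning one node; the six right-hand sides share one Jacobi-preconditioned
conjugate-gradient solve advanced in lockstep to a relative residual of
1e-8. The effective tensor is the energy average

$$C^H_{pq} = \frac{1}{|Y|}\sum_e f_e\,
  (\mathbf{u}^0_p - \boldsymbol\chi_p)^{\mathsf T} \mathbf{k}_e
  (\mathbf{u}^0_q - \boldsymbol\chi_q),$$

which is symmetric and positive semi-definite by construction, and the
engineering constants are read off the inverse (orthotropic compliance
layout). Voigt order is (11, 22, 33, 12, 13, 23) with engineering shears.

Two numerical properties deserve mention:

* the octet cell's cubic symmetry is reproduced to well under 2% at
  $n = 16$ already, and the fully solid limit recovers the isotropic solid
  matrix to 1e-6;
* the **modulus converges slowly from above** (roughly first order in the
  voxel size): fully integrated trilinear hexes overstiffen stair-cased
  slender struts, so refining 24³ → 48³ still lowers $E$ by ~12% at
  $\rho = 0.4$ while the Poisson ratio moves by only ~2%. Comparisons
  between resolutions should therefore be made at fixed $n$; the default
  working resolution is $n = 48$.

## The density-property surrogate

`density_sweep()` homogenizes the cell at $\rho = 0.1, \dots, 0.8$ and
`fit_surrogate()` fits

$$\bar E/E_s = a_2\rho^2 + a_1\rho + a_0, \qquad
  \bar\nu/\nu_s = b_3\rho^3 + b_2\rho^2 + b_1\rho + b_0$$

by least squares, reporting $R^2 = 1 - SS_\mathrm{res}/SS_\mathrm{tot}$ for
each fit. On the package's own sweep at 48³ both fits achieve
$R^2 > 0.999$. Exact coefficient values depend on the discretization (a
voxel RVE is not a body-fitted mesh), so published coefficient sets are
treated as an alternative surrogate — `surrogate_from_coefs()` — rather
than as values to reproduce; fitting noiseless samples of any quadratic /
cubic recovers its coefficients to machine precision.

The surrogate is trusted on the fitted interval $[0.1, 0.8]$ only: the
quadratic exceeds $E_s$ just above $\rho = 1$ and has no physical meaning
outside the data. Evaluation clamps to the domain with a warning (or raises
with `clamp = FALSE`); the optimizer queries only $[0.2, 0.7]$, so
extrapolation never occurs in the pipeline. The macro model uses the
$(\bar E(\rho), \bar\nu(\rho))$ pair as an isotropic law — a simplification,
since the octet cell is cubic rather than isotropic, but it is the law the
two scalar surrogates support.

## Bone material from CT values

Tissue density is linear in the Hounsfield value, anchored at
2.0 g/cm³ for HU = 1500, and Young's modulus follows the three-branch law
17000 MPa (cortical, HU ≥ 1500), $2713\,\rho_0^{2.36}$ MPa (cancellous),
20 MPa (marrow, HU ≤ 100), with Poisson ratio 0.3 everywhere. The outer
branches win at the shared breakpoints; the law is discontinuous at
HU = 1500 ($2713 \cdot 2^{2.36} \approx 13926 \ne 17000$) and is
implemented exactly as stated. `map_volume()` assigns each macro element
the mean HU of the voxels inside its bounding box (nearest voxel as a
fallback), so tissue fractions are conserved exactly only at matched
mesh/voxel resolution; coarser meshes smear boundary elements toward the
middle branch.

## The genetic optimizer

The optimization problem is compliance minimization under a volume
constraint,

$$\min_{\boldsymbol\rho}\; c(\boldsymbol\rho) = \mathbf{U}^{\mathsf T}
\mathbf{K}\mathbf{U}, \qquad \mathbf{K}\mathbf{U} = \mathbf{F}, \quad
\mathrm{mean}(\rho_e) \le V_0 = 0.4, \quad 0.2 \le \rho_e \le 0.7,$$

with every element an individual of the population: its density is a
binary gene (8 bits, linear quantization of $[0.2, 0.7]$, all-zero =
lower bound) and its fitness is its strain energy
$\Delta c_e = \mathbf{u}_e^{\mathsf T}\bar{\mathbf{k}}_e\mathbf{u}_e$,
which sums to the compliance. Each generation:

1. solve the macro FE problem and take element energies as fitness;
2. for every element draw a *mother* gene by fitness-proportional roulette;
   the element's own gene is the *father*; each child bit comes from the
   mother with probability 0.3 (uniform crossover);
3. mutate each bit with probability 0.2, setting mutated bits to 1 for
   elements above the median fitness rank and to 0 below (directional
   mutation — high-energy elements densify, unloaded ones empty out);
4. rescale multiplicatively toward the lower bound and re-encode with
   floor-quantization whenever the mean density exceeds $V_0$, so the
   volume constraint holds at every accepted iterate;
5. stop when $|c_k - c_{k-1}|/c_1 < 10^{-3}$ (relative normalization by the
   first compliance; the raw threshold is stated without units) or at the
   generation cap.

Two design choices matter here. First, keeping the element's own gene as
the father is what preserves spatial identity: if both parents are drawn by
roulette, every element's gene is resampled from the global pool each
generation and the scheme stops being an optimizer. The exported
`select_parents()` still implements the two-roulette draw for callers who
want the fully mixing variant. Second, the mutation rate is read per bit —
the classic binary-GA convention — because a single-bit nudge per element
is too weak to differentiate the field within realistic generation counts.

The best feasible design seen is tracked and returned (elitism), so the
result is never worse than the uniform $\rho = V_0$ initialization, and
runs are bit-reproducible for a fixed seed (one seeded generator, the seed
recorded in the result). Only a subset of elements need be designable:
`design_elements` plus a `base_material` let an implant be optimized inside
an assembly whose bone elements keep their CT-mapped material.

**Known limitation.** The rank-split dynamics drive densities toward the
two bounds. On bending-dominated benchmarks an optimality-criteria method
with the same stiffness law, bounds and volume (implemented as an
independent reference in the test suite) reaches compliances the GA does
not: on a 24×8×2 extruded beam the GA settles at roughly 1.6× the OC
optimum — between the optimum and the uniform baseline, but not close to
OC. Relatedly, a compliance-optimal cage in a cage+bone assembly attracts
a larger share of the joint load, so its *peak* interface stress can
exceed the uniform design's; on the synthetic hemispherical-cage fixture
this ordering varies with the random seed. Both behaviours are inherent to
the specified operators, not to their implementation.

## From density field to printable geometry

`build_lattice()` instantiates one unit cell per macro element (cell nodes
carried into the element by its trilinear map — elements are assumed close
to cubic; strongly curved elements distort the cell), sizes strut radii
from the element densities, merges coincident boundary nodes at 1e-6 of the
cell edge, and keeps shared struts once with the larger neighbour's radius.
Struts lying in a planar exterior face of the mesh are geometrically half
struts (the absent neighbour owns the other half); `export_stl()` writes
them as half cylinders, so the enclosed volume of the STL matches the
$\sum_e \rho_e V_e$ bookkeeping exactly for uniform fields and within a few
percent for graded ones (shared-strut radius promotion adds a little). Each
strut is emitted as a closed, consistently oriented cylinder with flat caps
— watertight per connected component — with the signed-volume and
Euler-characteristic checks in the test suite. Faceting with $m$ segments
underestimates the cross-section by $1 - \frac{m}{2\pi}\sin\frac{2\pi}{m}$
(about 1.1% at the default $m = 24$); use more segments where the volume
matters.

## Synthetic fixtures and what passing them shows

No real CT series or implant geometry ships with the package; every stage
is exercised on generated fixtures:

* `make_phantom()` — concentric spherical marrow/cancellous/cortical
  regions (50 / 600 / 1800 HU, Gaussian noise sd 30 HU) in a box,
  deterministic per seed, with ground-truth labels attached. It emulates
  the HU contrast of the three tissue classes, not anatomy: no cortical
  thinning, no gradients within a tissue, no beam-hardening artefacts.
* `make_cantilever()` — a regular grid with one face fixed and an edge
  load; the standard optimization benchmark (20×10×4 for the headline GA
  runs; its tip deflection at 40×4×4 matches Euler-Bernoulli beam theory
  within 10%).
* `make_cage_benchmark()` — a hemispherical shell with two flange strips
  (their end rings fixed, standing in for the ischial slot and iliac
  screws), loaded over the inner socket nodes, proportionally to tributary
  area, with the hip-joint resultant (−408, 1919, 0) N — 250% of the 80 kg
  subject's body weight, magnitude 1962 N. With `bone_layer = TRUE` a
  cancellous-bone element layer (modulus from the CT mapping at 600 HU) is
  bonded to the cage back so implant and bone share load in parallel —
  the minimal configuration in which stress shielding is observable.

Passing on these fixtures demonstrates the numerical machinery —
homogenization identities, constraint handling, determinism, geometry
bookkeeping — under controlled conditions. It does not validate clinical
stress magnitudes: real pelvic geometry, heterogeneous bone, cement and
liner layers, screw fixation and contact mechanics are all absent.

## Problem sizes and defaults

The working configuration homogenizes at 48³ (about 40 s per density on
one core; the eight-density sweep takes a few minutes), optimizes 800-2000
element macro models (sub-second FE solves, converged GA runs within a
couple of minutes), and builds lattices of a few thousand struts. The
defaults — titanium solid ($E_s$ = 110000 MPa, $\nu_s$ = 0.3), cell edge
1.35 mm, sweep $\rho$ = 0.1-0.8, GA crossover 0.3 / mutation 0.2 /
$V_0$ = 0.4 / bounds $[0.2, 0.7]$ / tolerance 1e-3 — are the study
conditions of the design problem the package implements.

## A compact example

```{r, eval = FALSE}
# 1. homogenize + fit (use resolution = 48 for production quality)
sweep <- density_sweep("octet", seq(0.1, 0.8, 0.1), n = 48)
surr <- fit_surrogate(sweep)

# 2. optimize a cantilever benchmark
mesh <- make_cantilever(20, 10, 4, total_load = c(0, -100, 0))
design <- optimize_lattice_density(mesh, surr, ga_config(seed = 1))
print(design)
plot(design)

# 3. export the graded lattice
lat <- build_lattice(mesh, design$rho)
export_stl(lat, "lattice.stl")
```
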