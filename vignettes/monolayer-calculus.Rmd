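---
title: "Discrete calculus and ablation mechanics on cell monolayers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discrete calculus and ablation mechanics on cell monolayers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(monodec)
```

## The model

An epithelial monolayer is represented as a set of confluent polygons: the
*primal network* of cell vertices, edges and faces, and the *dual network*
joining adjacent cell centres by links, triangulating the tissue around each
vertex. Two signed incidence matrices carry the whole topology: `A` (one row
per edge, `-1`/`+1` at its endpoints) and `B` (one row per cell, `+-1` on its
edges according to traversal direction), with the chain-complex identity
`B %*% A == 0`. For a monolayer with `n_h` internal holes the counts obey
`n_vertices - n_edges + n_cells = 1 - n_h`.

The geometric layer attaches to this: cell centres are vertex centroids, edge
vectors `t_j` and link vectors `T_j` follow from the incidence matrices, and
three families of areas tile the tissue --- cell areas `A_i`, triangle areas
`E_k` around vertices, and the parallelogram areas `F_j = T_j . eps t_j`
spanned by each edge and its link. Crucially, **edges and links are not
assumed orthogonal**: disordered epithelia generically violate the
Voronoi/Delaunay symmetry, and all operators here are built to be correct
without it. Orthogonality is a measurable special case (`Te * Tl = 1` on the
regular hexagonal fixture) with its own degeneracies, which the test-suite
checks both ways.

### Orientation conventions

Cells are wound clockwise; the quarter-turn `eps_i` attached to cells is the
clockwise rotation and triangles carry the opposite one. With these two
choices made once, every cell area, triangle area and interior parallelogram
area is strictly positive on any valid mesh, and the link direction
`T_j = sum_i B_ij R_i` never needs a per-edge sign fix. We considered the
alternative (anticlockwise `eps_i` plus a stored per-link sign flipped
wherever `F_j < 0`) and rejected it: a link sign detached from `B` breaks the
consistency between link vectors and the dual coboundary. A non-positive
`F_j` on an interior edge is therefore treated as an orientation *error*, not
a repairable state. The area identity `wedge_tilde(T_y, T_x) == 6 * E_k` at
every interior vertex pins all of these signs at once and is asserted on
both regular and grown meshes.

### Boundary handling

An isolated monolayer needs boundary conditions. These are implemented
combinatorially by *reduced* incidence matrices: peripheral edge rows and
peripheral vertex columns of `A` are zeroed and peripheral edge columns of
`B` are zeroed, which still satisfies `B_hat %*% A_hat == 0` exactly. Hole
boundaries created by ablation bound a single cell, and are treated exactly
like the outer periphery; the check that the edge-Laplacian kernel dimension
equals the number of holes validates this choice on every fixture.
Peripheral links terminate at edge centroids rather than at a missing
neighbour centre.

## Operators

Covector-valued fields carry two components per element, the projections on
edge-aligned (parallel) and rotated (perpendicular) bases. The calculus is
assembled from five primitives: the exterior derivative (the reduced
coboundary, applied componentwise), sharp/flat (exchange between component
pairs and genuine 2D vectors through the contravariant/covariant bases),
diagonal Hodge stars weighted by `E_k`, `A_i`, `F_j/t_j^2` or `F_j/T_j^2`
(with a quarter-turn in component space for covector-valued arguments), a
value-leg wedge product, and the interior product against a uniform
amplitude pair.

Composing them gives sixteen first-order operators in four families --
gradients `(d phi)^sharp`, curls `(star d v^flat)^sharp`, divergences
`star d star v^flat` and rotated gradients `(star d u^flat)^sharp` -- on the
primal and dual networks, and six Laplacians:

* `L_V`, `L_C`: scalar potentials on interior vertices / cells,
* `L_T`, `L_F`: the curl-rot companions (kernel = constants for the cell
  ones),
* `L_E`, `L_L`: edge and link Laplace-de Rham operators.

`L_E` is non-symmetric but similar to a symmetric positive-semidefinite
matrix via the diagonal weight `Te`; solvers and eigensolvers work on the
symmetrized form and map back. The compositions are verified *entrywise*
against the assembled matrices, the four adjointness identities hold to
`1e-10` on random fields, and on the regular hexagonal lattice the
orthogonality degeneracies (`L_V == L_T`, `L_C == L_F`, gradient/corot
coincidences) hold to machine precision and are broken by an affine shear.

On affine vector fields the operators are exact, not merely convergent: a
rigid rotation sampled at the edge-link intersections returns exactly twice
its rate from the cell-wise circulation (with the clockwise sign), and a
pure expansion returns exactly its divergence at interior vertices.

## Helmholtz--Hodge decomposition and harmonic fields

A field on interior edges splits as `v = grad(phi) + rot(u) + x`. The
potentials solve two Poisson problems: the vertex problem (`L_V`) is
nonsingular because the reduction imposes effective Dirichlet data at the
suppressed periphery, so `phi` takes *no* gauge fixing; the cell problem
(`L_F`) has the constants as kernel, so its forcing is first projected onto
the operator's range by removing the area-weighted mean (the discrete
solvability condition) and `u` is reported with zero area-weighted mean. The
applied projection is returned in the diagnostics so the correction is
auditable. The linear solves use a sparse Cholesky factorization (vertex
problem) and a pinned sparse solve on the range (cell problem).

On a monolayer with holes, the kernel of the scalar edge Laplacian has one
mode per hole. Eigenvalues below `1e-10` of the largest count as zero, and a
kernel dimension different from the hole count is raised as an error rather
than a warning, since it signals a reduction or topology bug, not a
numerical accident. Modes are orthonormalized under the field inner product
(weights `F_j / t_j^2`) and sign-fixed by their largest-magnitude entry.
Contracting a mode with a uniform amplitude pair and sharping gives the
harmonic vector field, divergence- and curl-free by construction, radial or
azimuthal around its hole depending on the amplitude pair.

## The vertex model

Dynamics are gradient flow of
`E = 1/2 sum_i ((A_i - 1)^2 + Gamma (L_i - L0)^2)` in units of the preferred
cell area. Defaults are `Gamma = 0.2` and `L0 = 0.75`, which keep the tissue
jammed (rigid). Growth starts from a single unit-area hexagon and repeats:
pick a cell uniformly at random, divide it along a uniformly oriented axis
through its centroid (daughters must keep at least three vertices, else the
axis is resampled, at most ten times), then relax. During growth an
isotropic boundary stress of `-0.1` (compressive, about a tenth of the bulk
modulus scale) is applied through an energy term proportional to the total
covered area; growing under load locks heterogeneous prestress into the
tissue, which is what makes the later stress analysis non-trivial. After the
target count is reached the boundary is unloaded and the monolayer relaxed
to the analysis tolerance (largest vertex force at most `1e-8`).

Topological moves during relaxation keep every vertex 3-valent:

* **T1 exchange**: an interior edge between two interior vertices shorter
  than `0.05` collapses and re-expands perpendicular at `0.075`
  (1.5 x threshold); the rewiring is purely combinatorial, derived from
  which cell traverses the edge forwards.
* **Boundary T1**: a vanishing peripheral edge whose endpoints are 3-valent
  detaches its cell from the boundary and makes the two side cells
  adjacent.
* **Boundary reach**: a vanishing interior edge whose boundary endpoint has
  only the two edge cells brings the third cell to the boundary.
* **Boundary merge**: a vanishing peripheral edge with a 2-valent endpoint
  fuses the endpoints.

The first is the classic neighbour exchange; the other three are its
boundary companions, without which gradient descent provably stalls at
non-smooth configurations under compression. Because the dynamics are a
gradient flow, every move is *energy-gated*: a rewiring is kept only if it
dissipates energy. A sub-threshold edge whose exchange would raise the
energy is a legitimate stable feature of the equilibrium and is left in
place; only near-degenerate edges (below 30% of the threshold) force the
move. Without the gate, exchanges on stable short edges rattle (move,
revert, move again) and the flow cannot reach tight force tolerances.

The integrator is explicit adaptive-step descent (step halved when the
energy would rise, grown on success) so exchanges occur at well-defined
states between steps. Near the minimum the energy decrement falls below
double-precision resolution (`E ~ 1e2`, so increments below `~3e-14` are
invisible) while forces are still `~1e-7`; the final polish therefore
switches to an L-BFGS stage followed by force-monitored fixed-step descent,
which converges to the `1e-8` force tolerance. Growth-phase relaxations use
a loose tolerance (`2e-3`) and a step budget per division; only equilibria
entering the analysis are tightened.

## Stress from the rotated force potential

At equilibrium the corner forces close around every vertex; rotated by a
quarter turn they assemble into a closed network whose nodes define one
vector `h_j` per edge. `h` is integrated by breadth-first traversal from a
peripheral edge (where it is pinned to zero), path-independence is verified
against all unused constraints, and the integrated values on the remaining
peripheral edges --- which vanish with the equilibrium residual under zero
external load --- are snapped to zero. The cell stress is then
`sigma_i = A_i^-1 sum_j B_ij (t_j x h_j) eps_i`, from which the shear stress
`zeta_i = sqrt(-det(sym deviatoric))` (the square root's argument is clipped
at zero against rounding) and the effective pressure `P_eff = tr(sigma)/2`
follow. Two independent routes to the pressure (trace versus the cell-wise
rotated derivative of `h`) agree to `1e-10`, and the whole construction is
anchored against a second, independent derivation of cell stress: the
derivative of each cell's energy under an affine strain of its own vertices.
At zero external load the area-weighted total stress and the area integrals
of both cell-wise derivatives of `h` vanish to the equilibration residual.

## Radial scaling fits

The mechanical response to ablating one interior cell is quantified by
log-log slopes of radial *upper bounds*: values are binned in log-spaced
radial bins, per-bin maxima are taken, and a least-squares line is fitted.
Two windowing choices matter and are fixed as follows:

* The fit starts at the **apex** of the per-bin maxima. Inside the apex the
  bound is set by saturation at the hole scale; anchoring the window below
  it contaminates the decay estimate with the rising part of the envelope
  and makes it realization-unstable, which we observed directly across
  growth seeds.
* Every fit excludes the outer 20% of the radius range (boundary
  effects). The stress differences `|d zeta|`, `|d P_eff|` additionally
  exclude peripheral cells (which are elongated and behave differently),
  and the Helmholtz residual is fitted on the inner half of the radius
  range, where the excited harmonic component stands above the background
  reconstruction error. Edge-level quantities (~1400 samples) use 12 log
  bins; cell-level quantities (~400 interior cells) use 8, keeping the
  per-bin envelope estimates populated.

With 8, 12 or 16 bins and across growth seeds these fits give slopes near
`-1` for `chi`, near `-2` for both stress-difference magnitudes, and near
`-1` for the near-hole residual, the discrete analogues of the `1/r`
harmonic decay and `1/r^2` stress perturbation of a punctured elastic sheet.

## What the generator does and does not emulate

The growth algorithm produces disordered, prestressed, jammed monolayers
with realistic topology (cell neighbour numbers centred on six, a mix of
cell sizes, elongated boundary cells). Study conditions are those stated
throughout: `Gamma = 0.2`, `L0 = 0.75`, growth under `-0.1` peripheral
compression, analysis at zero load, about 500 cells for the scaling runs
(about 100 and 200 for the topological and equilibrium identities), one
central ablation. It does **not** emulate biological wound healing ---
purse-string contraction, fluidization, migration, signalling --- nor cell
divisions or extrusions during the analysis itself, curved substrates, or
multiple simultaneous wound types. Passing tests therefore demonstrate the
mechanics of the jammed, passive response, not the active biology layered
on top of it in real epithelia.

## Numerical choices, in one place

* Null-space tolerance `1e-10` (relative) for harmonic modes; mismatch with
  the hole count is an error.
* Solvability corrections by area-weighted mean removal, logged in the
  decomposition diagnostics.
* Force tolerance `1e-8` for analysis equilibria; `2e-3` during growth.
* T1 threshold `0.05`, post-exchange length `0.075`, in units of the
  preferred cell diameter (~1).
* `zeta`'s square-root argument clipped at zero.
* Edge-link intersection points falling outside an edge segment (possible
  in strongly irregular meshes) are used as-is with a warning; only the
  local tangent bases attach to them.
* All randomness flows through R's RNG, seeded once per experiment; growth
  is bitwise reproducible given the seed.

## A worked example

```{r example, eval = FALSE}
## a small ablation study (a few seconds; the full-scale study uses
## n_cells = 500)
ex <- run_ablation_experiment(n_cells = 120, seed = 1)
ex$slopes$chi$slope        # ~ -1: harmonic field decay
ex$slopes$d_zeta$slope     # ~ -2: shear-stress perturbation decay
ex$basis$n_modes           # 1 mode: one hole
plot_monolayer(ex$post, fill = ex$stress_post$p_eff, fill_name = "P_eff")
```

## Known limitations

* The kernel eigensolve is dense; fine for the few-thousand-edge meshes
  targeted here, not for much larger tissues.
* Cells are polygons in a flat plane; no curvature, no periodic boundaries,
  no 3D.
* The two-species osmotic coupling that can make the perimeter stiffness
  dynamic is not implemented; `Gamma` is a plain (optionally
  time-programmable) scalar.
* Slope fits assume a single ablation site; multiple simultaneous wounds
  would superpose fields and need a different estimator.
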