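---
title: "A 3D hybrid cell-center/vertex model of epithelial wound healing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`epiwound3d` simulates a flat epithelial monolayer as a two-layer assembly of
prism-like cells. The primary kinematic unknowns are the apical and basal
*cell centers* (nodes) $x_A^i, x_B^i$; the cell boundary corners (*vertices*)
are not independent unknowns but are interpolated from the nodes: after a 2D
Delaunay triangulation of each layer's centers, one vertex sits at the
barycenter of each triangle,

$$ y^I = \tfrac{1}{3}\,(x^{I_1} + x^{I_2} + x^{I_3}), $$

which makes the model a hybrid between a cell-centered and a vertex model:
vertex mechanics acts on the cell cortex, but the system size is that of the
cell centers. Three families of vertices do carry their own degrees of
freedom: vertices on the wound edge (released from the constraint to avoid
zig-zag artifacts under the purse string), and *intermediate vertices* that
stitch cells whose apical and basal polygons disagree after the two layers
have remeshed independently.

Two bar networks connect the structure: the **nodal network** (in-layer
triangulation edges, one vertical bar per cell, and one apical-to-basal
diagonal per triangulation edge) and the **vertex network** (the polygonal
cell boundaries in each layer, vertical tricellular bars, and one diagonal
per lateral face). The total energy is

$$ W = \frac{k_N}{2}\sum_{ij}(l^{ij}-L^{ij})^2
     + \frac{k_V}{2}\sum_{IJ}(l^{IJ}-L^{IJ})^2
     + \frac{\lambda_{Vol}}{2}\sum_i \Big(\frac{V_i - V_i^0}{V_i^0}\Big)^2 , $$

plus, on each vertex segment, an elastic branch of stiffness $k_{V0}$ whose
tension is $\sigma_V = k_{V0}(\varepsilon_e + \hat{\Upsilon}^c)$ with elastic
strain $\varepsilon_e = (l-L_0)/L_0$ measured from the segment's birth length
and $\hat{\Upsilon}^c$ the scheduled wound-edge contractility. Cell volumes
are evaluated by a signed-tetrahedron decomposition: each cell's surface
(apical cap fanned from the apical node, basal cap from the basal node,
lateral faces fanned from a canonical anchor along their stored diagonals) is
coned to the cell midpoint $(x_A + x_B)/2$. On convex prisms this matches
convex-hull volumes to $10^{-9}$ relative (tested), and it handles non-planar
lateral faces deterministically.

Viscoelasticity enters through the rest lengths, which are internal variables
evolving by

$$ \frac{1}{L}\frac{dL}{dt} = \gamma\Big(\frac{l-L}{L} - \varepsilon^c\Big), $$

so each bar remodels toward the strain set point $\varepsilon^c$; for
$\varepsilon^c = 0$ the branch behaves like a Maxwell element. Nodal bars
have $\gamma = 0$ (purely elastic).

### Where the contractile set point acts

The printed evolution law carries one $\varepsilon^c$ for every vertex
segment. Applied literally to the lateral (apico-basal) bars, a contractile
set point produces a sustained tension proportional to bar *length*; on bars
as long as the monolayer is tall this tension is an order of magnitude larger
than any junctional force, and in our experiments it invariably extrudes the
softened wound column out of the monolayer and collapses the wound edge —
while every reported phenomenon of the model (recoil driven by junctional
tension, the height drop that mirrors the area gain through the volume
penalty, the failures at extreme volume-penalty weights, thinning under
lateral wound contractility) follows from junctional contractility alone.
The package therefore applies $\varepsilon^c$ to the in-plane (apical and
basal junctional) vertex segments; lateral vertex segments remodel as plain
Maxwell elements and carry only the scheduled wound-edge contractility
$\hat{\Upsilon}_L^c$. This is the package's reading of the rheology, stated
here rather than hidden in code.

### Units and patch geometry

The calibrated parameter set ($k_N = 0.3$, $k_V = 1$, $k_{V0} = 0.05$,
$\lambda_{Vol} = 20$, $\varepsilon^c = 1.3$, $\gamma = 0.2\,\mathrm{min}^{-1}$)
is dimensionless and only mutually consistent when lengths are of order the
monolayer height: the volume penalty must balance junctional tensions
($\lambda_{Vol}\,\delta / h \sim k_V \varepsilon^c l / (1+\varepsilon^c)$ with
volume deviations $\delta$ of a few percent), and the purse-string threshold
amplitude must be commensurate with the junctional line tension
($k_{V0}\Upsilon \sim k_V\, l_{junction}\, \varepsilon^c/(1+\varepsilon^c)$).
Both require junction lengths a modest fraction of the height. The mechanics
therefore runs in height-normalized coordinates (`run_simulation()` passes
`length_scale = height`), and the synthetic patch generator defaults to a
lattice spacing of 12 um at a height of 35 um — columnar cells roughly three
times taller than wide, the proportions of the model's own simulated tissue
rather than of segmented microscopy. Geometric observables are reported back
in micrometers.

### What the generator emulates — and what it does not

`generate_hex_patch()` produces jittered hexagonal lattices clipped to a
square (80-205 cells; uniform-disc jitter of 0.15 lattice spacings; fixed
seed; fixed rim cells plus a mirrored ring of non-cell boundary nodes). It
reproduces the statistical structure the model needs: roughly uniform
centers, hexagonal-dominated topology, a fixed frame. It does not reproduce
the cell-area dispersion, spatial correlations or curvature of real imaginal
disc tissue, so passing tests demonstrate correct mechanics on
representative geometry, not agreement with any particular specimen — the
in vivo area and height curves are not part of the test surface.

## Initialization

Rest lengths are born equal to current lengths (stress-free) when the mesh is
built; `run_simulation()` then applies the homeostatic prestrain
$L = l/(1+\varepsilon^c)$ to the junctional segments, which is the fixed point
of the remodeling law, and settles to equilibrium before ablation. The
tissue therefore carries the pre-existing junctional tension that recoil
measures; without it, ablation would open the wound only as fast as
remodeling can build tension.

## Wounding, purse string, removal

Ablation (t = 0) scales the stiffness of every segment *all of whose owner
cells are ablated* by 0.01 and removes those cells' volume penalty; segments
shared with a live cell keep full stiffness (degrading them as well leaves
the wound region floppy and unsolvable). Wound-edge vertices in both layers
become free unknowns. From $t_w = 6$ min the wound-edge apical junctions
carry $\hat{\Upsilon}_A^c = \Upsilon_A^c (1 - (t-t_w)/400)$ (clamped at zero)
and the wound-edge lateral bars the constant $\hat{\Upsilon}_L^c$.

A degraded cell is *removed* (extruded) once the purse string has compressed
its apical polygon below `removal_area_fraction` (default 0.8) of the cell's
own pre-ablation area — i.e. once the cable has both reversed the recoil
expansion and imposed a substantial (20%) constriction, the signature of
purse-driven extrusion rather than noise-level squeezing. Removal deletes the node from both triangulations (the star-shaped
holes are re-triangulated, identically in both layers whenever the neighbour
rings agree) and releases the dead cell's nodal tethers, which is what lets
the surviving cells advance; the closure of the wound proceeds as a ratchet
of squeeze-remove-intercalate events. The wound is declared closed (a
latching flag) when the apical wound area falls below 2% of its post-recoil
maximum or no degraded cell remains.

## Numerics

* **Time stepping.** $\Delta t = 0.6$ min during recoil ($t \le 6$ min) and
  1.0 min afterwards. The rest-length law is discretized with the
  $\theta$-weighted scheme ($\theta = 0.5$; second order, tested against a
  fine-step integration) and *substituted implicitly*: within a step
  $L_{n+1} = A + B\,l_{n+1}$ is a linear function of the trial length, so the
  Newton iteration sees rest lengths consistent with its trial geometry and
  the factor $dL_{n+1}/dl_{n+1} = \Delta t\gamma\theta / (1 +
  \Delta t\gamma\theta(1+\varepsilon^c))$ enters the tangent.
* **Solve.** Each step minimizes $W$ by Newton-Raphson with an analytic
  sparse tangent (assembled from cached index patterns and reduced by the
  interpolation map; Dirichlet rows/columns eliminated). The energy is
  nonconvex (compressed struts carry negative geometric stiffness), so when
  the tangent is not positive definite a tau-shifted Cholesky provides the
  descent direction, and a backtracking Armijo search on $W$ (constant
  $10^{-4}$, step-norm cap 0.5, floor $2^{-16}$, with an absolute slack of
  $10^{-12}(|W|+10^{-12})$ so the test stays meaningful at roundoff level)
  guarantees monotone energy decrease. Convergence requires both
  $\lVert\delta x\rVert$ and $\lVert g\rVert$ (2-norms) below $10^{-10}$.
* **Failure handling.** A non-converged step usually means the minimum
  requires a topological move (a junction crushed to zero length awaiting a
  neighbour exchange, or a cell awaiting extrusion). The driver then
  continues from the partially descended state — energy descent is monotone,
  so progress is never lost — remeshing first, then force-removing the most
  crushed degraded cell, and only then halving the time step (up to
  `max_halvings`); the schedule step is restored afterwards.
* **Remeshing.** After each converged step both layers re-triangulate
  independently by Lawson flipping of non-locally-Delaunay edges, gated by
  the aspect-ratio rule $r_{new} < (1+tol_r)\, r_{old}$ with $r$ the
  longest/shortest-edge ratio of the worse triangle and `tol_r = 0.1` by
  default. At `tol_r = 0` the gate is bypassed and plain Lawson flipping
  reaches the exact Delaunay triangulation (this limit is definitional for
  the method and pinned by a test against an independent implementation); at
  `tol_r > 0` stretched, suboptimal triangles may both form and persist near
  the wound. In addition, an in-layer junction compressed below `t1_frac`
  (default 0.1) of the mean initial junction length forces the neighbour
  exchange of its dual edge: crushed wound-edge junctions connect *relaxed*
  vertices that the node-based Delaunay criterion cannot see, and without
  this rule intercalation at the purse string never fires.
* **Intermediate vertices.** When one layer flips and the other does not,
  the mismatched quad acquires one intermediate vertex placed at the mean of
  the four bridged vertices and carrying its own degrees of freedom; lateral
  faces become pentagons (or triangles) stitched through it. A flip that
  would leave the layers unstitchable (stacked mismatches on overlapping
  quads) triggers the matching flip in the opposite layer — a synchronised
  T1 — and is reverted if that is impossible. When a later change restores
  matching loops the intermediate vertex disappears and its two half-bars
  merge (rest lengths add). All other remesh-created segments are born
  stress-free, so remeshing is energy-continuous apart from the active
  purse-string term.
* **Degenerate inputs.** Collinear center sets and duplicate points are
  rejected at triangulation; zero-height (collapsed) cells evaluate to zero
  volume and are flagged; ties in the in-circumcircle predicate (perfect
  lattices) resolve to an arbitrary but valid diagonal via a relative
  tolerance.

## Observables

Per step the driver records the projected apical wound area (shoelace formula
on the ordered purse-string polygon), the relative height
$1 - \mathrm{depth}/35\,\mu m$ (depth = 95th-percentile apical height in an
annulus 2-4 cell diameters outside the perimeter, minus the mean perimeter
height — a deterministic surrogate for the manual orthogonal-view procedure
used on images; it tracks trends, not absolute imaging values), the number of
wound-edge cells and perimeter junctions, and the mean/max per-cell relative
volume deviation over alive cells.

## Study sizes and what the battery shows

The validation battery runs on scaled-down patches chosen as the package's
own study sizes: 20-cell patches for derivative-level checks, the 65-cell
calibration patch for recoil sensitivity (ablating 5 cells), the 80-cell /
5-ablated patch for the volume-control and closure-threshold studies, and a
single 205-cell / 8-ablated reference run. Trends (monotone orderings,
bounds) are asserted rather than absolute in vivo values, which are not
reproducible from published material.

## Known limitations

* The closure threshold depends on the synthetic wound's perimeter
  discretization (the number and length of purse-string junctions); on
  jittered lattices it sits above the value reported for the original
  experimental geometries, though with the same finite-threshold behavior
  and monotone dependence on the amplitudes.
* One intermediate plane only: cells are stitched by at most one
  intermediate vertex per mismatched quad; deeper apico-basal discretization
  is out of scope.
* No contact mechanics: apposing wound edges interpenetrate rather than
  touch; the removal rule usually extrudes crushed cells first.
* No cell proliferation, no curved reference surfaces, no fitting to in
  vivo curves.
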