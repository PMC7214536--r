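# epiwound3d

A three-dimensional hybrid cell-center/vertex simulator of epithelial
monolayer mechanics, built to study laser-ablation wound healing: recoil,
apical purse-string contraction, lateral contractility, and closure by
progressive extrusion and intercalation.

## Who this is for

Researchers in computational tissue mechanics / morphogenesis who want a
tested, scriptable implementation of a 3D vertex-type model in which the
apical and basal surfaces of a flat monolayer can change their neighbour
topology *independently* (spatial T1 transitions, stitched by intermediate
vertices), with viscoelastic junctional rheology and near-incompressible
cells.

## The model in brief

Cells are prism-like polyhedra between an apical and a basal plane. The
degrees of freedom are the cell centers $x_A^i, x_B^i$ of both layers; the
boundary vertices sit at the barycenters of the Delaunay triangles of the
centers, $y^I = \frac13\sum_{i\in I} x^i$ (wound-edge and intermediate
vertices are released as independent unknowns). Mechanics is a total energy

$$ W \;=\; \frac{k_N}{2}\sum_{ij}\big(l^{ij}-L^{ij}\big)^2
      \;+\; \frac{k_V}{2}\sum_{IJ}\big(l^{IJ}-L^{IJ}\big)^2
      \;+\; \frac{\lambda_{Vol}}{2}\sum_i\Big(\frac{V_i-V_i^0}{V_i^0}\Big)^2 $$

over the nodal and vertex bar networks plus a volume penalty, with an
elastic branch of stiffness $k_{V0}$ on each vertex bar whose tension is
$\sigma_V = k_{V0}(\varepsilon_e + \hat\Upsilon^c)$. Rest lengths are
internal variables, $\dot L = \gamma\,(l - L(1+\varepsilon^c))$, giving
Maxwell-like viscoelasticity with a contractile set point $\varepsilon^c$ on
the junctional cortex. Equilibrium is solved every time step by
Newton-Raphson with an analytic sparse tangent, energy line search, and the
rest-length update substituted implicitly ($\theta = 0.5$ scheme). After
each step both layers re-triangulate independently under an aspect-ratio
acceptance rule; wounding degrades ablated cells, activates the scheduled
purse-string contractilities at the wound edge, and progressively extrudes
crushed cells. Calibrated defaults: $k_N = 0.3$, $k_V = 1$, $k_{V0} = 0.05$,
$\lambda_{Vol} = 20$, $\varepsilon^c = 1.3$, $\gamma = 0.2\,/\mathrm{min}$.

See `vignettes/model-and-methods.Rmd` for the full account, including the
package's documented readings of the under-specified parts (units and patch
proportions, the scope of $\varepsilon^c$, the removal rule).

## Worked example

```r
library(epiwound3d)

centers <- generate_hex_patch(patch_spec(n_cells = 80, seed = 1))
wound   <- wound_protocol(select_ablation_region(centers, 5), Y_Ac = 3.0)
sim     <- run_simulation(centers, material_params(), wound,
                          solver_settings(), t_end = 150)
sim
#> <epi_sim> 21 steps
#> closed: TRUE at t = 17 min
#> recoil area: 713.42 um^2; final area: 0 um^2
#> final relative height: 1

glance(sim)      # one-row summary (closure time, recoil area, volume stats)
tidy(sim)        # per-step observables: t_min, wound_area_um2, rel_height,
                 # n_edge_cells, mean_vol_dev, max_vol_dev, newton_iters, dt_min
autoplot(sim)    # wound area and relative height vs time
```

The run above ablates 5 central cells of a seeded 80-cell patch at t = 0;
the wound recoils from ~632 to ~713 um^2 while the tissue's pre-existing
junctional tension pulls it open, the apical purse string activates at
t = 6 min, and the cable progressively squeezes and extrudes the dead cells
until the wound closes (here at t = 17 min; at the just-critical amplitude,
closure takes much longer, and below ~2.8 on this patch it never completes).
Mean per-cell volume deviations stay within the band enforced by the volume
penalty.

A thin command-line interface wraps the same functions:

```sh
inst/cli/epiwound generate-patch --n-cells 205 --seed 1 --out centers.csv
inst/cli/epiwound simulate --out-dir runs/demo --frames
inst/cli/epiwound sweep --param Y_Ac --values 1.5:3.0:0.5 --out sweep.csv
inst/cli/epiwound metrics --run-dir runs/demo
```

`simulate` writes a self-describing run directory: resolved `config.yaml`,
`centers.csv`, per-step `timeseries.csv`, `summary.json`, and legacy-VTK
frames (`frames/frame_%04d.vtk`) with per-cell relative volume change for
rendering.

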