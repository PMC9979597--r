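# cogito

A coarse-grained (CG) force-field toolkit for triacylglycerides (TAGs),
for molecular modellers who simulate pure (non-aqueous) fat systems —
crystalline polymorphs and melts — and need CG topologies, parameter
files and analysis tooling without hand-editing every new molecule.

TAGs are glycerol esterified with three fatty-acid chains. The model
represents them with nine interchangeable bead types: three
glycerol-ester beads (`1CH2OCO`, `2CHOCO`, `3CH2OCO`, one per
sn-position, each absorbing a glycerol carbon plus the ester group),
an alkene bead (`CHCH`), glycerol-adjacent and interior two-/three-carbon
aliphatic beads (`C2H4E`, `C3H6E`, `C2H4`, `C3H6`) and a terminal bead
(`C3H7T`). Because two- and three-carbon beads coexist, chains that
differ by fewer than three carbons (e.g. palmitic vs stearic) get
distinct topologies, and any saturated or monounsaturated-per-chain TAG
is assembled by interchanging beads — no re-parameterization.

The potential is

```
U = Σ ½ k_b (r − r_eq)²                       (harmonic bonds)
  + Σ ½ k_θ (cos θ − cos θ_eq)²               (GROMOS-96 cosine angles)
  + Σ 4ε[(σ/r)¹² − (σ/r)⁶]  (shifted to 0 at the 1.1 nm cutoff)
  + Σ f q_i q_j / r                           (Coulomb, q = ±0.05 e)
```

with Lorentz–Berthelot mixing (σ arithmetic, ε geometric), one-bond
nonbonded exclusions and no torsion term. The package provides:

* the canonical bead/bond/angle/LJ parameter tables and their
  invariant checks (`cogito_ff()`, `validate_ff()`, `mix_lj()`);
* automatic topology construction for arbitrary chains
  (`fatty_acid()`, `map_chain()`, `build_tag()`) and
  centre-of-geometry mapping of atomistic coordinates (`cog_map()`);
* potential energy and analytic forces on periodic configurations,
  plus steepest-descent relaxation (`total_energy()`, `forces()`,
  `minimize()`);
* GROMACS-dialect file I/O: `.gro` frames and trajectories, molecule
  `.itp`, force-field sections and system `.top`
  (`read_gro()`, `write_itp()`, `write_top()`, ...);
* trajectory/series observables: density, unit-cell lattice
  parameters, RDFs, bonded distributions, bootstrap enthalpy
  estimators (`density_g_cm3()`, `lattice_params()`, `rdf()`,
  `bootstrap_mean()`, `delta_h_fus()`, `delta_h_vap()`);
* the top-down LJ parameterization workflow: weighted
  relative-deviation cost, random training, Gaussian-process-guided
  optimization with crash penalties, filter-and-average extraction
  (`cost_function()`, `optimize_lj()`, `extract_parameters()`);
* idealized lamellar and melt configuration generators for testing
  (`build_lamellar()`, `build_melt()`), and a CLI wrapper
  (`cogito_cli()`, `inst/cli/cogito.R`).

Production MD itself (thermostats, barostats, PME) is delegated to an
external engine consuming the exported files.

## Worked example

```r
library(cogito)
ff <- cogito_ff()

oleic <- fatty_acid(18, list(list(position = 9, geometry = "cis")))
posts <- build_tag("POSt", fatty_acid(16), oleic, fatty_acid(18))
posts
#> TAG topology "POSt": 21 beads, 20 bonds, 20 angles, net charge 0
#>   sn-1: C3H6E-C3H6-C3H6-C3H6-C3H7T
#>   sn-2: C2H4E-C2H4-C3H6-CHCH-C3H6-C2H4-C3H7T
#>   sn-3: C2H4E-C3H6-C3H6-C3H6-C3H6-C3H7T
```

1-palmitoyl-2-oleoyl-3-stearoyl-*sn*-glycerol collapses from 168
all-atom (or 64 united-atom) particles to 21 beads; the bead masses sum
to 861.413 g/mol, matching the C55H104O6 formula weight to 0.01.
Cross-interactions come from the mixing rules:

```r
mix_lj(ff, "C3H6", "C3H7T")
#>    sigma  epsilon
#> 0.445500 2.927889
```

An idealized four-molecule lamellar stack, its energy and density:

```r
stack <- build_lamellar(posts, ff, lattice = c(2, 1, 2), spacing = 0.5)
total_energy(stack, ff)
#> Potential energy (kJ/mol)
#>   bond           0.000000
#>   angle          0.000000
#>   lj          -102.962081
#>   coulomb       -4.427937
#>   total       -107.390018
density_g_cm3(stack)
#> [1] 0.05059274
```

Bonds and angles are exactly at equilibrium by construction (zero
bonded energy); the LJ cohesion is negative as the aligned chains
attract. The low density reflects the minimum-image padding of this
small test stack — production densities come from NPT runs on the
exported files. Writing those files:

```r
write_gro(as_gro_frame(stack), "posts.gro")
write_itp(posts, ff, "posts.itp")
write_top(list(list(topology = posts, count = 4)), ff, file = "posts.top")
```

Recovering parameters with the optimization workflow (here against a
deterministic mock backend whose optimum is the canonical LJ table):

```r
specs  <- metric_specs(c("d1", "d2", "d3"), c(0.92, 1.05, 0.98))
bounds <- lj_bounds(ff)
backend <- quadratic_backend(specs,
  setNames(c(ff$lj$sigma, ff$lj$epsilon),
           c(paste0(ff$lj$bead, ".sigma"), paste0(ff$lj$bead, ".epsilon"))),
  bounds)
opt <- optimize_lj(backend, specs, bounds, n_train = 30, n_iter = 40, seed = 3)
opt
#> LJ parameter optimization: 70 evaluations (30 train + 40 guided), 70 completed
#>   best completed cost: 1.17862e-05
```

`extract_parameters(opt, cost_threshold)` averages the completed
low-cost records into the production parameter vector.

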