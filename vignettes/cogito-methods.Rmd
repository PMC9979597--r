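---
title: "Methods: the CG TAG force-field toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CG TAG force-field toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogito)
```

## The model

`cogito` implements a coarse-grained (CG) force field for
triacylglycerides (TAGs) built from nine interchangeable bead types:
three glycerol-ester beads (`1CH2OCO`, `2CHOCO`, `3CH2OCO`, one per
stereospecific glycerol position, each absorbing a glycerol carbon plus
the ester group including the chain's carbonyl carbon), an alkene bead
(`CHCH`), two- and three-carbon aliphatic beads in glycerol-adjacent
(`C2H4E`, `C3H6E`) and interior (`C2H4`, `C3H6`) variants, and a
terminal bead (`C3H7T`). Distinguishing two- from three-carbon beads
lets chains differing by fewer than three carbons (palmitic vs stearic)
map to distinct topologies, and an explicit two-carbon alkene bead keeps
*cis*/*trans* geometry resolvable in starting structures.

The potential energy of a configuration is

$$
U = \sum_{\mathrm{bonds}} \tfrac12 k^b_{ij}\,(r_{ij} - r^{eq}_{ij})^2
  + \sum_{\mathrm{angles}} \tfrac12 k^\theta_{ijk}\,
      (\cos\theta_{ijk} - \cos\theta^{eq}_{ijk})^2
  + \sum_{i<j} 4\varepsilon_{ij}\!\left[
      \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12} -
      \left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]
  + \sum_{i<j} \frac{f\,q_i q_j}{r_{ij}},
$$

with harmonic bonds, the GROMOS-96 cosine angle form (regular at
180 degrees, which is why no torsion term exists in this force field:
the near-linear three-body angles that would anchor dihedrals make torsion
potentials numerically unstable, and the chains are flexible enough that
they add nothing), a 12-6 Lennard-Jones term shifted to zero at the
cutoff, and a Coulomb term over the small partial charges
(\(-0.05\,e\) on the glycerol-ester beads, \(+0.05\,e\) on the adjacent
`E` beads, zero elsewhere; every molecule is net neutral). Cross
LJ parameters follow the Lorentz-Berthelot rules (arithmetic mean of
\(\sigma\), geometric mean of \(\varepsilon\)). Nonbonded interactions
exclude only first bonded neighbours (`nrexcl = 1` in exported
topologies); second neighbours (angle partners) interact.

Units are GROMACS conventions throughout: nm, kJ/mol, degrees in
parameter tables (radians internally), elementary charges, g/mol.
Fixed constants: the Coulomb factor \(f = 138.935458\)
kJ mol\(^{-1}\) nm e\(^{-2}\), the molar gas constant
\(R = 8.314462618\) J mol\(^{-1}\) K\(^{-1}\), and IUPAC atomic
weights C = 12.0107, H = 1.00794, O = 15.9994, which reproduce every
tabulated bead mass digit-for-digit at three decimals. The canonical
parameter tables ship as plain TSV files under `inst/extdata/` and are
loaded by `cogito_ff()`; `validate_ff()` checks the structural
invariants (nine beads, 18 LJ scalars, mass/composition consistency,
positivity, no dangling bead references).

## Chain decomposition

`map_chain()` turns a fatty-acid spec (carbon count, double-bond
positions in acid numbering with C1 the carbonyl) into a bead sequence.
The carbonyl carbon is absorbed by the glycerol-ester bead; the terminal
three carbons are always `C3H7T`; each double bond becomes a `CHCH`
bead covering its two carbons, flanked on both sides by `C3H6` (the
only bead `CHCH` bonds to). The remaining saturated stretches are tiled
with two- and three-carbon beads by solving \(2a + 3b = n\) per stretch
while minimizing the number of two-carbon beads; required two-carbon
beads are placed nearest the glycerol end, never adjacent to each other
(no `C2H4`-`C2H4` bond is parameterized), and the attachment bead
prefers `C2H4E` over `C3H6E` when a two-carbon bead is needed anyway.
These rules reproduce the published arachidic mapping
(`C2H4E-C2H4-C3H6-C3H6-C3H6-C3H6-C3H7T`) and the unique oleic
decomposition, and the result is always verified against the bond
table, so chemistries the force field cannot express fail fast with a
message naming the violated constraint. Two double bonds exactly five
positions apart share a single `C3H6` flank; closer spacings are
unrepresentable. `build_tag()` then assembles the three-bead glycerol
backbone, attaches the chains, enumerates **all** angles from the bond
graph (an angle without a table row is an error, deliberately surfacing
unsupported chemistries at build time rather than silently skipping
terms), assigns charges and masses, and checks net neutrality.

*cis*/*trans* geometry is recorded as metadata only: the parameter
tables carry no geometric distinction, so geometry matters only to
starting-structure generators.

The bead name `CHOCO`, occasionally used as shorthand for the sn-2
glycerol-ester bead, is accepted everywhere as an alias for `2CHOCO`.

## Energy evaluation

`total_energy()` and `forces()` operate on periodic configurations with
a GROMACS lower-triangular triclinic box under the minimum-image
convention; the box must exceed twice the 1.1 nm cutoff in every
diagonal extent, which is enforced. The LJ term uses potential-shift
(zero exactly at the cutoff). The Coulomb term is plain truncation at
the same cutoff - **not** the particle-mesh Ewald a production engine
would use. This is a deliberate simplification: the charges are tiny
(\(\pm 0.05\,e\)) and locally neutral, and the evaluator's role is
fixture energetics, testing and file validation, not production
dynamics. An optional shift-to-zero of the Coulomb term at the cutoff
is available (`coulomb_shift = TRUE`, default off). Forces are analytic
(the angle term differentiated through its cosine) and are verified
against central finite differences of the energy; coincident beads
raise an error rather than being clamped.

`minimize()` is a steepest-descent relaxer with an adaptive step
(grow 1.2x on accepted steps, halve on rejected ones, maximum
displacement capped at 0.2 nm), intended to relax generated starting
structures, not to replace an engine's minimizer.

## Parameter optimization

The 18 LJ scalars (one \(\sigma\), \(\varepsilon\) pair per bead) are
fitted top-down against empirical observables. The cost of a candidate
parameter set is

$$ C = \sum_i w_i \left( 10\,\frac{r_i - r_{\mathrm{ref},i}}
   {r_{\mathrm{ref},i}} \right)^{\!2}, $$

zero exactly at the references, quadratic in the relative deviation,
and invariant to a joint rescaling of a metric and its reference. The
factor of 10 multiplies the relative deviation (so a 5% deviation on a
unit-weight metric costs \((10 \times 0.05)^2 = 0.25\)); the alternative
reading - 10 multiplying the normalized ratio itself - does not vanish
at the reference and was rejected. This implementation *minimizes*
cost; workflows that maximize a negated objective are equivalent, and
crashed evaluations enter the history with a large positive crash
penalty (default \(10^6\)) instead of a "highly negative" score.

`optimize_lj()` runs a uniform random training phase inside per-scalar
bounds, then surrogate-guided proposals: a Gaussian-process surrogate
(RBF kernel, lengthscale chosen by marginal likelihood from a small
grid, fitted to \(\log(\mathrm{cost} + 10^{-12})\) so the flat basin
floor stays resolvable) proposes points by maximizing expected
improvement on exploration steps and minimizing a lower confidence
bound on exploitation steps, each polished by bounded L-BFGS-B;
exploitation uses a local surrogate fitted to the points nearest the
incumbent once enough history exists, and proposal clouds shrink with
the spread of the current best points. Every evaluation - including
crashes - is recorded with full parameter provenance, and the whole run
is reproducible from one seed. The production parameter set is obtained
by `extract_parameters()`: filter to completed runs below a cost
threshold and average the surviving parameter vectors componentwise.

Metric weights and per-scalar bounds are configuration inputs, not
constants; the shipped defaults (\(\sigma \in [0.35, 0.50]\) nm,
\(\varepsilon \in [2.0, 5.0]\) kJ/mol) bracket the canonical values
with realistic bead-size margins. The backend is a pure callable
`params -> list(completed, metrics)`; the tests and the acceptance
script use a deterministic quadratic mock whose planted optimum is the
canonical LJ table, which the default 30 + 40 evaluation budget
recovers to within a few percent per coordinate. Workflows driving an
external MD engine implement the same contract.

## Observables

* **Density**: total molar mass over box volume; the windowed variant
  averages frames with \(t \ge t_{\mathrm{end}} - X\) (inclusive), the
  convention meant by "the last X ns".
* **Lattice parameters**: box vectors divided componentwise by the
  stacking counts (default `c(5, 1, 5)`, a crystal built by stacking
  five unit cells along a and c); lengths plus inter-vector angles.
  Angles are stacking-invariant, so the box angles and unit-cell angles
  coincide - reporting either answers both readings of a "box vs cell"
  beta angle. `box_from_lattice()` inverts the extraction exactly.
* **RDF**: minimum-image pair histogram with shell-volume and
  ideal-density normalization, frames averaged, self-pairs excluded for
  overlapping groups, `r_max` capped at half the smallest box extent.
  Groups are index vectors, so UA atoms pre-grouped to bead centroids
  via `cog_map()` are analysed identically to CG beads.
* **Bonded distributions**: pooled over all matching bond/angle
  instances and frames, reporting the histogram plus mean and standard
  deviation - the two statistics the bottom-up fitting procedure
  matches against atomistic reference data.
* **Enthalpies**: `bootstrap_mean()` uses the percentile bootstrap (no
  specific CI construction is mandated by the procedure it implements;
  the percentile method is the simplest honest choice and its
  coverage is verified empirically at roughly 95%). `delta_h_fus()` is
  the difference of melt and crystal bootstrap means with the CI
  propagated through the difference of the two independent bootstrap
  distributions; `average_runs()` aggregates repeated runs.
  `delta_h_vap()` is \(U_{gas} - U_{liq} + RT\).

## Synthetic configurations

`build_extended_molecule()` places a TAG with every bond and angle at
equilibrium: backbone in a plane, sn-1/sn-3 chains as planar zig-zags
on opposite sides, and the sn-2 attachment direction solved exactly
from the three angle equilibria meeting at the `2CHOCO` vertex (which
are mutually consistent but leave one out-of-plane degree of freedom,
resolved upward). Its bonded energy is numerically zero by
construction. `build_lamellar()` replicates it on a rectangular lattice
with aligned chains; `build_melt()` inserts rigid copies at random
seeded positions/orientations, rejecting any insertion that brings two
molecules' beads within a clearance (default 0.35 nm, about the
smallest \(\sigma\)).

These fixtures emulate the *topological* situation of crystalline and
molten TAG systems - dense aligned stacks vs disordered placements -
well enough to exercise every evaluator and observable. They are
**not** crystallographically faithful: real \(\beta\)/\(\beta'\)
polymorph cells come from X-ray structures that are intentionally out
of scope, the lamellar box is padded to satisfy the minimum-image
requirement rather than packed to experimental density, and the melts
are dilute compared to a real liquid. Consequently, passing tests
demonstrate correctness of the mechanics (energies, forces, file
round-trips, estimator calibration), not reproduction of experimental
densities or lattice constants, which require full MD runs with the
exported files.

## Problem sizes and numerical choices

The test-suite and acceptance-script workloads are sized for fast,
stable statistics: periodic stacks up to 252 beads for oracle
comparisons (a scalar double-loop reference agrees with the vectorized
evaluator to better than \(10^{-10}\) relative), 50 jittered
single-molecule configurations for force/finite-difference checks at
\(10^{-4}\) relative, ideal-gas RDFs over four 500-bead frames
(keeping bin noise near 1%), 500-replicate coverage experiments with
200-sample series and 1000 bootstrap resamples, and 70-evaluation
optimization runs. Degenerate inputs error loudly: zero bond distances,
empty mapping groups, boxes smaller than twice the cutoff, empty
bootstrap windows, optimization filters with no survivors.

## Limitations

No MD integrator, thermostat, barostat or Ewald summation: production
dynamics belong to an external engine consuming the exported
`.gro`/`.itp`/`.top` files. No torsion parameters, by design. No
mono-/di-acylglycerides or chemistries outside the parameterized bond
and angle tables. Enthalpy estimators consume time series produced
elsewhere; the package computes the statistics, not the trajectories.
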