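Package: cogito
Title: Coarse-Grained Force Field Toolkit for Triacylglycerides
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and working with a coarse-grained (CG)
    force field for triacylglycerides (TAGs) assembled from nine
    interchangeable bead types. Provides the canonical bead, bond,
    angle and Lennard-Jones parameter tables with Lorentz-Berthelot
    mixing; automatic CG topology construction for arbitrary saturated
    and unsaturated TAGs from fatty-acid chain specifications;
    centre-of-geometry mapping of atomistic coordinates onto beads;
    evaluation of the CG potential energy and analytic forces on
    periodic configurations; readers and writers for GROMACS-style
    .gro, .itp and .top files; trajectory observables (density,
    lattice parameters, radial distribution functions, bonded
    distributions, bootstrap enthalpy estimators); a surrogate-guided
    (Bayesian) optimization workflow for the nonbonded parameters with
    a weighted relative-deviation cost function; and generators for
    idealized lamellar and melt test configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
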