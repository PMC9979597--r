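# Force-field data model: the nine bead types, bonded parameter tables,
# Lennard-Jones parameters and mixing rules, in GROMACS units
# (nm, kJ/mol, degrees in tables, elementary charges, g/mol).

# IUPAC standard atomic weights; these reproduce every canonical bead mass
# digit-for-digit at 3 decimals.
ATOMIC_WEIGHTS <- c(C = 12.0107, H = 1.00794, O = 15.9994)

# Coulomb constant f = 1/(4 pi eps0) in kJ mol^-1 nm e^-2 (GROMACS value).
COULOMB_CONSTANT <- 138.935458

#' Molecular mass of a bead from its atomic composition
#'
#' Sums standard atomic weights over the composition and rounds to three
#' decimals, the convention used by the canonical bead table.
#'
#' @param composition Named integer vector or list of element counts,
#'   e.g. `c(C = 2, H = 4)`. Elements must be among C, H, O.
#' @return Mass in g/mol, rounded to 3 decimals.
#' @examples
#' bead_mass(c(C = 2, H = 2, O = 2)) # 58.036, the sn-1 glycerol-ester bead
#' @export
bead_mass <- function(composition) {
  composition <- unlist(composition)
  if (length(composition) == 0) return(0)
  counts <- as.numeric(composition)
  elems <- names(composition)
  if (is.null(elems) || any(!nzchar(elems)))
    stop("composition must be a named vector of element counts")
  unknown <- setdiff(elems, names(ATOMIC_WEIGHTS))
  if (length(unknown) > 0)
    stop("unknown element(s) in composition: ", paste(unknown, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    stop("composition counts must be non-negative integers")
  round(sum(counts * ATOMIC_WEIGHTS[elems]), 3)
}

# Parse a formula string like "C2H1O2" into a named count vector.
parse_composition <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(parts) == 0 || paste(parts, collapse = "") != formula)
    stop("cannot parse composition string: ", formula)
  elems <- sub("[0-9]*$", "", parts)
  counts <- as.integer(ifelse(grepl("[0-9]+$", parts),
                              sub("^[A-Za-z]+", "", parts), "1"))
  stats::setNames(counts, elems)
}

# Canonical unordered key for a bead pair; vertex-fixed key for a triple.
pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
triple_key <- function(a, b, c) {
  ends <- sort(c(a, c))
  paste(ends[1], b, ends[2], sep = "|")
}

#' Construct a CG force-field model for triacylglycerides
#'
#' Builds the force-field object holding the bead definitions, bond and
#' angle parameter tables, per-bead Lennard-Jones parameters, the nonbonded
#' cutoff and the Coulomb constant. By default the canonical parameter
#' tables shipped with the package are loaded; any component can be
#' overridden (e.g. the LJ table during parameter optimization).
#'
#' @param beads,bonds,angles,lj Data frames overriding the canonical
#'   tables. Column layout must match the shipped tables: beads
#'   (name, description, composition, mass, charge), bonds
#'   (bead_i, bead_j, r_eq nm, k_b kJ/mol/nm^2), angles
#'   (bead_i, bead_j, bead_k, theta_eq degrees, k_theta kJ/mol),
#'   lj (bead, sigma nm, epsilon kJ/mol).
#' @param cutoff Nonbonded cutoff in nm (default 1.1).
#' @return An object of class `cogito_ff`.
#' @examples
#' ff <- cogito_ff()
#' mix_lj(ff, "C3H6", "C3H7T")
#' @export
cogito_ff <- function(beads = NULL, bonds = NULL, angles = NULL, lj = NULL,
                      cutoff = 1.1) {
  read_tab <- function(file) {
    path <- system.file("extdata", file, package = "cogito", mustWork = TRUE)
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = NA, comment.char = "")
  }
  if (is.null(beads))  beads  <- read_tab("cogito_beads.tsv")
  if (is.null(bonds))  bonds  <- read_tab("cogito_bonds.tsv")
  if (is.null(angles)) angles <- read_tab("cogito_angles.tsv")
  if (is.null(lj))     lj     <- read_tab("cogito_lj.tsv")

  ff <- structure(list(
    beads = beads,
    bonds = bonds,
    angles = angles,
    lj = lj,
    cutoff = cutoff,
    coulomb_constant = COULOMB_CONSTANT,
    # lookup indices with orientation-insensitive canonical keys
    bond_index = stats::setNames(seq_len(nrow(bonds)),
                                 mapply(pair_key, bonds$bead_i, bonds$bead_j)),
    angle_index = stats::setNames(seq_len(nrow(angles)),
                                  mapply(triple_key, angles$bead_i,
                                         angles$bead_j, angles$bead_k)),
    lj_index = stats::setNames(seq_len(nrow(lj)), lj$bead),
    bead_index = stats::setNames(seq_len(nrow(beads)), beads$name)
  ), class = "cogito_ff")
  ff
}

# Resolve the "CHOCO" prose alias for the sn-2 glycerol-ester bead.
resolve_bead <- function(name) ifelse(name == "CHOCO", "2CHOCO", name)

#' Look up bond-stretch parameters for a bead pair
#'
#' Orientation-insensitive: `(a, b)` and `(b, a)` return the same row.
#' An absent pair is an error; the topology builder relies on this to
#' reject invalid bead adjacencies.
#'
#' @param ff A `cogito_ff` object.
#' @param a,b Bead type names.
#' @return List with `bead_i`, `bead_j`, `r_eq` (nm), `k_b` (kJ/mol/nm^2).
#' @export
lookup_bond <- function(ff, a, b) {
  a <- resolve_bead(a); b <- resolve_bead(b)
  i <- ff$bond_index[pair_key(a, b)]
  if (is.na(i))
    stop("unparameterized interaction: no bond parameters for (",
         a, ", ", b, ")")
  as.list(ff$bonds[i, ])
}

#' Look up angle-vibration parameters for a bonded bead triple
#'
#' The middle bead `b` is the vertex; the lookup is symmetric under
#' swapping the two end beads.
#'
#' @param ff A `cogito_ff` object.
#' @param a,b,c Bead type names (`b` is the vertex).
#' @return List with bead names, `theta_eq` (degrees), `k_theta` (kJ/mol).
#' @export
lookup_angle <- function(ff, a, b, c) {
  a <- resolve_bead(a); b <- resolve_bead(b); c <- resolve_bead(c)
  i <- ff$angle_index[triple_key(a, b, c)]
  if (is.na(i))
    stop("unparameterized interaction: no angle parameters for (",
         a, ", ", b, ", ", c, ")")
  as.list(ff$angles[i, ])
}

#' Lorentz-Berthelot mixing of Lennard-Jones parameters
#'
#' Cross-interaction parameters for two bead types: arithmetic mean of the
#' sigmas, geometric mean of the epsilons.
#'
#' @param ff A `cogito_ff` object.
#' @param a,b Bead type names.
#' @return Named numeric vector `c(sigma = , epsilon = )` in nm and kJ/mol.
#' @export
mix_lj <- function(ff, a, b) {
  a <- resolve_bead(a); b <- resolve_bead(b)
  ia <- ff$lj_index[a]; ib <- ff$lj_index[b]
  if (is.na(ia)) stop("no LJ parameters for bead: ", a)
  if (is.na(ib)) stop("no LJ parameters for bead: ", b)
  c(sigma = (ff$lj$sigma[ia] + ff$lj$sigma[ib]) / 2,
    epsilon = sqrt(ff$lj$epsilon[ia] * ff$lj$epsilon[ib]))
}

#' Validate a force-field model against its structural invariants
#'
#' Checks that the canonical invariants hold: nine bead types with 18 LJ
#' scalars in the canonical model, masses consistent with compositions,
#' positive force constants and equilibrium values, every bead referenced
#' by a bond/angle/LJ row defined, and charges drawn from the allowed set.
#'
#' @param ff A `cogito_ff` object.
#' @param canonical If `TRUE` (default), also require exactly 9 beads and
#'   9 LJ rows as in the shipped model.
#' @return Character vector of violation messages; empty when valid.
#' @export
validate_ff <- function(ff, canonical = TRUE) {
  v <- character()
  bn <- ff$beads$name
  if (canonical && length(bn) != 9)
    v <- c(v, sprintf("expected 9 bead types, found %d", length(bn)))
  if (canonical && nrow(ff$lj) != 9)
    v <- c(v, sprintf("expected 9 LJ entries (18 parameters), found %d",
                      nrow(ff$lj)))
  if (anyDuplicated(bn))
    v <- c(v, "duplicate bead names")
  for (i in seq_len(nrow(ff$beads))) {
    m <- bead_mass(parse_composition(ff$beads$composition[i]))
    if (abs(m - ff$beads$mass[i]) > 5e-4)
      v <- c(v, sprintf("bead %s: mass %.3f inconsistent with composition %s (%.3f)",
                        bn[i], ff$beads$mass[i], ff$beads$composition[i], m))
  }
  if (!all(ff$beads$charge %in% c(-0.05, 0, 0.05)))
    v <- c(v, "bead charges outside {-0.05, 0, +0.05}")
  dangle <- function(ref, what) {
    bad <- setdiff(unique(ref), bn)
    if (length(bad) > 0)
      sprintf("%s reference undefined bead(s): %s", what,
              paste(bad, collapse = ", "))
    else character()
  }
  v <- c(v, dangle(c(ff$bonds$bead_i, ff$bonds$bead_j), "bond rows"))
  v <- c(v, dangle(c(ff$angles$bead_i, ff$angles$bead_j, ff$angles$bead_k),
                   "angle rows"))
  v <- c(v, dangle(ff$lj$bead, "LJ rows"))
  if (any(ff$bonds$r_eq <= 0) || any(ff$bonds$k_b <= 0))
    v <- c(v, "non-positive bond parameters")
  if (any(ff$angles$theta_eq <= 0) || any(ff$angles$theta_eq >= 180) ||
      any(ff$angles$k_theta <= 0))
    v <- c(v, "angle parameters outside valid ranges")
  if (any(ff$lj$sigma <= 0) || any(ff$lj$epsilon <= 0))
    v <- c(v, "non-positive LJ parameters")
  if (ff$cutoff <= 0)
    v <- c(v, "non-positive cutoff")
  v
}

#' @export
print.cogito_ff <- function(x, ...) {
  cat("CG force field for triacylglycerides\n")
  cat(sprintf("  beads: %d   bonds: %d   angles: %d   LJ entries: %d\n",
              nrow(x$beads), nrow(x$bonds), nrow(x$angles), nrow(x$lj)))
  cat(sprintf("  cutoff: %.2f nm   Coulomb constant: %.6f kJ mol^-1 nm e^-2\n",
              x$cutoff, x$coulomb_constant))
  invisible(x)
}
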