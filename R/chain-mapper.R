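# Topology construction: decompose fatty-acid chains into the nine CG
# beads, assemble whole-TAG topologies, and map atomistic coordinates
# onto beads by centre of geometry.

#' Specify a fatty-acid chain
#'
#' Chains are described by their carbon count and the positions of any
#' double bonds, in acid (delta) numbering with the carbonyl carbon as C1.
#' A double bond at position p sits between carbons p and p+1. *cis* /
#' *trans* geometry is recorded as metadata: the parameter tables do not
#' distinguish the two, but starting-structure generators may.
#'
#' @param n_carbons Total carbons including the carbonyl carbon (>= 7).
#' @param double_bonds List of `list(position =, geometry =)` entries,
#'   or a bare integer vector of positions (geometry defaults to "cis").
#' @return Object of class `fatty_acid`.
#' @examples
#' fatty_acid(18, list(list(position = 9, geometry = "cis"))) # oleic
#' fatty_acid(16)                                             # palmitic
#' @export
fatty_acid <- function(n_carbons, double_bonds = list()) {
  if (length(n_carbons) != 1 || n_carbons != round(n_carbons) || n_carbons < 7)
    stop("n_carbons must be a single integer >= 7")
  if (is.numeric(double_bonds))
    double_bonds <- lapply(double_bonds, function(p) list(position = p,
                                                         geometry = "cis"))
  pos <- vapply(double_bonds, function(d) as.numeric(d$position), 0)
  geom <- vapply(double_bonds, function(d) {
    g <- if (is.null(d$geometry)) "cis" else d$geometry
    if (!g %in% c("cis", "trans"))
      stop("double-bond geometry must be \"cis\" or \"trans\", got: ", g)
    g
  }, "")
  if (length(pos) > 0) {
    o <- order(pos); pos <- pos[o]; geom <- geom[o]
    if (any(pos != round(pos) | pos < 2 | pos > n_carbons - 2))
      stop("double-bond positions must be integers in [2, n_carbons - 2]")
    if (any(pos < 5) || any(pos > n_carbons - 4))
      stop("double bonds must be separated from the chain ends by at least 3 carbons")
    if (length(pos) > 1 && any(diff(pos) < 5))
      stop("double bonds must be non-adjacent and separated by at least 3 carbons")
  }
  structure(list(n_carbons = as.integer(n_carbons),
                 double_bonds = Map(function(p, g) list(position = as.integer(p),
                                                        geometry = g),
                                    pos, geom)),
            class = "fatty_acid")
}

#' @export
print.fatty_acid <- function(x, ...) {
  db <- if (length(x$double_bonds) == 0) "saturated" else
    paste(vapply(x$double_bonds,
                 function(d) sprintf("%s-%d", d$geometry, d$position), ""),
          collapse = ", ")
  cat(sprintf("fatty acid %d:%d (%s)\n", x$n_carbons,
              length(x$double_bonds), db))
  invisible(x)
}

# Carbon count absorbed by each chain bead type.
BEAD_CARBONS <- c(C2H4E = 2, C2H4 = 2, C3H6E = 3, C3H6 = 3, C3H7T = 3,
                  CHCH = 2)

# Decompose `len` saturated carbons into two- and three-carbon beads,
# minimizing the number of two-carbon beads. For the attachment segment
# the first bead is the glycerol-adjacent E variant (C2H4E preferred over
# C3H6E when a two-carbon bead is required anyway); elsewhere required
# C2H4 beads are placed nearest the glycerol end, never adjacent to each
# other (no C2H4-C2H4 bond exists).
solve_segment <- function(len, attachment = FALSE) {
  if (len == 0) return(if (attachment) NULL else character(0))
  if (len == 1) return(NULL)
  n2 <- switch(as.character(len %% 3), "0" = 0, "2" = 1, "1" = 2)
  n3 <- (len - 2 * n2) / 3
  if (attachment) {
    if (n2 >= 1) c("C2H4E", rep("C2H4", n2 - 1), rep("C3H6", n3))
    else c("C3H6E", rep("C3H6", n3 - 1))
  } else {
    if (n2 == 2 && n3 == 0) return(NULL)       # C2H4-C2H4 is not bonded
    if (n2 == 2) c("C2H4", "C3H6", "C2H4", rep("C3H6", n3 - 1))
    else c(rep("C2H4", n2), rep("C3H6", n3))
  }
}

#' Decompose a fatty-acid chain into CG bead types
#'
#' The carbonyl carbon (C1) is absorbed into the glycerol-ester bead and
#' is not part of the returned chain. The decomposition anchors each
#' double bond as a CHCH bead flanked by C3H6 beads, assigns the terminal
#' three carbons to C3H7T, and fills the remaining saturated stretches
#' with two-/three-carbon beads, minimizing the number of two-carbon
#' beads. Every adjacent pair in the result is checked against the bond
#' parameter table, so chemistries the force field cannot express are
#' rejected here.
#'
#' @param spec A [fatty_acid()] object.
#' @param ff Force field used for the adjacency check (default canonical).
#' @return Character vector of bead type names, attachment end first.
#' @examples
#' map_chain(fatty_acid(20)) # arachidic: C2H4E C2H4 C3H6 x4 C3H7T
#' @export
map_chain <- function(spec, ff = cogito_ff()) {
  stopifnot(inherits(spec, "fatty_acid"))
  n <- spec$n_carbons
  pos <- vapply(spec$double_bonds, `[[`, 0L, "position")
  # chain carbons 2..n; terminal bead takes the last three
  term_start <- n - 2
  if (length(pos) > 0 && max(pos) + 4 >= term_start)
    stop("no valid decomposition: double bond at position ", max(pos),
         " too close to the methyl end (CHCH needs a C3H6 flank before the ",
         "terminal bead)")

  beads <- character(0)
  cursor <- 2                 # next unassigned carbon
  first <- TRUE
  for (p in pos) {
    if (!first && cursor == p) {
      # double bond exactly 5 positions after the previous one: the
      # previous right C3H6 flank doubles as this bond's left flank
      beads <- c(beads, "CHCH", "C3H6")
      cursor <- p + 5
      next
    }
    if (cursor > p - 3)
      stop("no valid decomposition: double bond at position ", p,
           " leaves no room for its C3H6 flank (flanks of neighbouring ",
           "double bonds overlap)")
    seg_len <- (p - 3) - cursor   # saturated carbons before the left flank
    seg <- solve_segment(seg_len, attachment = first)
    if (is.null(seg)) {
      if (first)
        stop("no valid decomposition: double bond at position ", p,
             " too close to the glycerol end (attachment bead plus C3H6 ",
             "flank does not fit)")
      stop("no valid decomposition: a saturated stretch of ", seg_len,
           " carbons before the double bond at position ", p,
           " cannot be tiled with two-/three-carbon beads")
    }
    beads <- c(beads, seg, "C3H6", "CHCH", "C3H6")
    cursor <- p + 5
    first <- FALSE
  }
  seg_len <- term_start - cursor
  if (first) {
    seg <- solve_segment(seg_len, attachment = TRUE)
    if (is.null(seg))
      stop("no valid decomposition: chain of ", n, " carbons leaves ",
           seg_len, " carbons before the terminal bead, which cannot start ",
           "a glycerol-attached segment")
    beads <- c(beads, seg)
  } else if (seg_len > 0) {
    seg <- solve_segment(seg_len, attachment = FALSE)
    if (is.null(seg))
      stop("no valid decomposition: a saturated stretch of ", seg_len,
           " carbons after the last double bond cannot be tiled with ",
           "two-/three-carbon beads")
    beads <- c(beads, seg)
  }
  beads <- c(beads, "C3H7T")

  # carbon conservation (internal consistency)
  stopifnot(1 + sum(BEAD_CARBONS[beads]) == n)
  # adjacency legality against the bond table
  for (i in seq_len(length(beads) - 1)) {
    tryCatch(lookup_bond(ff, beads[i], beads[i + 1]),
             error = function(e)
               stop("no valid decomposition: adjacent beads ", beads[i],
                    "-", beads[i + 1], " have no bond parameters",
                    call. = FALSE))
  }
  beads
}

#' Build the CG topology of a whole triacylglyceride
#'
#' Assembles the three-bead glycerol backbone (1CH2OCO-2CHOCO-3CH2OCO),
#' attaches the three mapped fatty-acid chains at the sn-1/sn-2/sn-3
#' positions, enumerates all bonded angles from the bond graph, assigns
#' charges (-0.05 on the glycerol-ester beads, +0.05 on the adjacent E
#' beads) and masses, and validates every bond and angle against the
#' force-field tables. Nonbonded exclusions are exactly the first
#' bonded neighbours.
#'
#' @param name Molecule name (used as residue name, truncated to 5 chars).
#' @param sn1,sn2,sn3 [fatty_acid()] specs for the three chains.
#' @param ff A `cogito_ff` force field.
#' @return Object of class `tag_topology`.
#' @examples
#' oleic <- fatty_acid(18, list(list(position = 9, geometry = "cis")))
#' posts <- build_tag("POSt", fatty_acid(16), oleic, fatty_acid(18))
#' @export
build_tag <- function(name, sn1, sn2, sn3, ff = cogito_ff()) {
  chains <- list(map_chain(sn1, ff), map_chain(sn2, ff), map_chain(sn3, ff))
  glycerol <- c("1CH2OCO", "2CHOCO", "3CH2OCO")
  bead_types <- glycerol
  bonds <- rbind(c(1L, 2L), c(2L, 3L))
  sn_positions <- integer(3)
  for (ch in 1:3) {
    start <- length(bead_types) + 1L
    bead_types <- c(bead_types, chains[[ch]])
    idx <- seq(start, length.out = length(chains[[ch]]))
    bonds <- rbind(bonds, cbind(ch, idx[1]),
                   if (length(idx) > 1) cbind(idx[-length(idx)], idx[-1]))
    sn_positions[ch] <- ch
  }
  bonds <- matrix(as.integer(bonds), ncol = 2)
  n <- length(bead_types)

  # adjacency list and exhaustive angle enumeration
  nbr <- vector("list", n)
  for (r in seq_len(nrow(bonds))) {
    i <- bonds[r, 1]; j <- bonds[r, 2]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  angles <- matrix(integer(0), ncol = 3)
  for (j in seq_len(n)) {
    nb <- sort(nbr[[j]])
    if (length(nb) >= 2) {
      pr <- utils::combn(nb, 2)
      angles <- rbind(angles, cbind(pr[1, ], j, pr[2, ]))
    }
  }
  angles <- matrix(as.integer(angles), ncol = 3)

  # parameter validation: every bond and angle must have a table row
  for (r in seq_len(nrow(bonds)))
    lookup_bond(ff, bead_types[bonds[r, 1]], bead_types[bonds[r, 2]])
  for (r in seq_len(nrow(angles)))
    lookup_angle(ff, bead_types[angles[r, 1]], bead_types[angles[r, 2]],
                 bead_types[angles[r, 3]])

  bi <- ff$bead_index[bead_types]
  topo <- structure(list(
    molecule_name = name,
    bead_types = bead_types,
    charges = ff$beads$charge[bi],
    masses = ff$beads$mass[bi],
    bonds = bonds,
    angles = angles,
    exclusions = bonds,
    sn_positions = stats::setNames(sn_positions, c("sn1", "sn2", "sn3")),
    chains = chains
  ), class = "tag_topology")
  stopifnot(abs(sum(topo$charges)) < 1e-12)
  topo
}

#' @export
print.tag_topology <- function(x, ...) {
  cat(sprintf("TAG topology \"%s\": %d beads, %d bonds, %d angles, net charge %g\n",
              x$molecule_name, length(x$bead_types), nrow(x$bonds),
              nrow(x$angles), sum(x$charges)))
  for (ch in 1:3)
    cat(sprintf("  sn-%d: %s\n", ch, paste(x$chains[[ch]], collapse = "-")))
  invisible(x)
}

#' Number of beads in a topology
#' @param topology A `tag_topology`.
#' @return Integer bead count.
#' @export
n_beads <- function(topology) length(topology$bead_types)

#' Map atomistic coordinates onto CG beads by centre of geometry
#'
#' Each bead position is the unweighted mean of the positions of the
#' atoms it absorbs (centre of geometry, not centre of mass).
#'
#' @param atom_positions N x 3 numeric matrix of atom coordinates.
#' @param mapping List with one integer vector of atom indices per bead.
#' @return length(mapping) x 3 matrix of bead coordinates.
#' @export
cog_map <- function(atom_positions, mapping) {
  atom_positions <- as.matrix(atom_positions)
  if (!all(is.finite(atom_positions)))
    stop("atom positions must be finite")
  out <- matrix(NA_real_, nrow = length(mapping), ncol = 3)
  for (b in seq_along(mapping)) {
    idx <- mapping[[b]]
    if (length(idx) == 0)
      stop("empty atom group for bead ", b)
    if (any(idx < 1 | idx > nrow(atom_positions)))
      stop("atom index out of range in group ", b)
    out[b, ] <- colMeans(atom_positions[idx, , drop = FALSE])
  }
  out
}
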