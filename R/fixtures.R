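# Synthetic configuration generators: a single TAG with every bond and
# angle at equilibrium, idealized lamellar stacks of such molecules, and
# random melts with clearance-based rejection sampling. These are
# idealized test structures, not crystallographically faithful polymorphs.

normalize3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# Next bead position: bond length r from parent, equilibrium angle theta
# (degrees) at the parent between grandparent and the new bead, placed in
# the plane with the given normal; `side` flips the zig-zag.
place_next <- function(pos_g, pos_p, r, theta_deg, normal, side) {
  u <- normalize3(pos_g - pos_p)
  w <- cross3(normal, u)
  nw <- sqrt(sum(w^2))
  if (nw < 1e-10) {  # chain direction parallel to the plane normal
    w <- cross3(c(0, 1, 0), u)
    nw <- sqrt(sum(w^2))
  }
  w <- side * w / nw
  th <- theta_deg * pi / 180
  pos_p + r * (cos(th) * u + sin(th) * w)
}

#' Build a single TAG with all bonded terms at equilibrium
#'
#' Places the glycerol backbone in the xy-plane, attaches the three
#' chains as planar zig-zags (sn-1 and sn-3 in the backbone plane on
#' opposite sides, sn-2 rising out of plane) with every bond at its
#' equilibrium length and every angle at its equilibrium value, so the
#' bonded energy of the result is numerically zero. The sn-2 attachment
#' direction is solved exactly from the three angle equilibria that meet
#' at the 2CHOCO vertex.
#'
#' @param topology A `tag_topology`.
#' @param ff A `cogito_ff`.
#' @return N x 3 matrix of bead coordinates in nm.
#' @export
build_extended_molecule <- function(topology, ff = cogito_ff()) {
  bt <- topology$bead_types
  n <- length(bt)
  pos <- matrix(NA_real_, n, 3)
  b12 <- lookup_bond(ff, bt[1], bt[2])$r_eq
  b23 <- lookup_bond(ff, bt[2], bt[3])$r_eq
  t123 <- lookup_angle(ff, bt[1], bt[2], bt[3])$theta_eq * pi / 180
  pos[2, ] <- c(0, 0, 0)
  pos[1, ] <- c(b12, 0, 0)
  pos[3, ] <- b23 * c(cos(t123), sin(t123), 0)

  # chain bead index ranges, in storage order sn1, sn2, sn3
  lens <- vapply(topology$chains, length, 0L)
  starts <- 3L + cumsum(c(0L, lens[-3])) + 1L

  place_chain <- function(pos, chain_idx, glycerol, first_pos, normal) {
    side <- 1
    g <- glycerol; p <- chain_idx[1]
    pos[p, ] <- first_pos
    for (k in chain_idx[-1]) {
      r <- lookup_bond(ff, bt[p], bt[k])$r_eq
      th <- lookup_angle(ff, bt[g], bt[p], bt[k])$theta_eq
      pos[k, ] <- place_next(pos[g, ], pos[p, ], r, th, normal, side)
      side <- -side
      g <- p; p <- k
    }
    pos
  }

  # sn-1: in-plane, on the -y side of the backbone
  e1 <- starts[1]
  r1 <- lookup_bond(ff, bt[1], bt[e1])$r_eq
  th1 <- lookup_angle(ff, bt[2], bt[1], bt[e1])$theta_eq
  p1 <- place_next(pos[2, ], pos[1, ], r1, th1, c(0, 0, 1), 1)
  pos <- place_chain(pos, seq(e1, length.out = lens[1]), 1L, p1, c(0, 0, 1))

  # sn-3: in-plane, on the +y side
  e3 <- starts[3]
  r3 <- lookup_bond(ff, bt[3], bt[e3])$r_eq
  th3 <- lookup_angle(ff, bt[2], bt[3], bt[e3])$theta_eq
  p3 <- place_next(pos[2, ], pos[3, ], r3, th3, c(0, 0, 1), -1)
  pos <- place_chain(pos, seq(e3, length.out = lens[3]), 3L, p3, c(0, 0, 1))

  # sn-2: direction solved from the three angle equilibria at the vertex
  e2 <- starts[2]
  r2 <- lookup_bond(ff, bt[2], bt[e2])$r_eq
  c1 <- cos(lookup_angle(ff, bt[1], bt[2], bt[e2])$theta_eq * pi / 180)
  c3 <- cos(lookup_angle(ff, bt[3], bt[2], bt[e2])$theta_eq * pi / 180)
  u1 <- normalize3(pos[1, ] - pos[2, ])
  u3 <- normalize3(pos[3, ] - pos[2, ])
  cg <- sum(u1 * u3)
  ab <- solve(rbind(c(1, cg), c(cg, 1)), c(c1, c3))
  inplane <- ab[1] * u1 + ab[2] * u3
  z2 <- 1 - sum(inplane^2)
  if (z2 < 0) stop("inconsistent angle equilibria at the sn-2 vertex")
  ue <- inplane + sqrt(z2) * normalize3(cross3(u1, u3))
  pos[e2, ] <- pos[2, ] + r2 * ue
  n2 <- cross3(ue, u1)
  if (sqrt(sum(n2^2)) < 1e-10) n2 <- cross3(ue, c(0, 1, 0))
  pos <- place_chain(pos, seq(e2, length.out = lens[2]), 2L, pos[e2, ],
                     normalize3(n2))
  pos
}

#' Idealized lamellar stack of extended TAG molecules
#'
#' Replicates the equilibrium-geometry molecule on a rectangular lattice
#' with all chains aligned, in a periodic box enclosing the lattice with
#' the configured spacing. A crude stand-in for a chain-stacked TAG
#' crystal; deterministic for a given topology and lattice.
#'
#' @param topology A `tag_topology`.
#' @param ff A `cogito_ff`.
#' @param lattice Integer triple: molecule copies along x, y, z.
#' @param spacing Gap between molecule bounding boxes in nm; must be at
#'   least `clearance`.
#' @param clearance Minimum allowed interbead distance in nm
#'   (default 0.35, about the smallest LJ sigma).
#' @param min_box Lower bound on each box edge in nm, so small stacks
#'   still satisfy the minimum-image requirement of the energy
#'   evaluator.
#' @return A `cg_configuration` with `prod(lattice)` molecules.
#' @export
build_lamellar <- function(topology, ff = cogito_ff(), lattice = c(2, 1, 2),
                           spacing = 0.5, clearance = 0.35, min_box = 2.4) {
  if (spacing < clearance)
    stop(sprintf("spacing %.3f nm is below the %.3f nm bead clearance; increase the spacing",
                 spacing, clearance))
  mol <- build_extended_molecule(topology, ff)
  mol <- sweep(mol, 2, apply(mol, 2, min))     # shift to positive octant
  extent <- apply(mol, 2, max)
  cell <- extent + spacing
  offs <- as.matrix(expand.grid(x = seq_len(lattice[1]) - 1,
                                y = seq_len(lattice[2]) - 1,
                                z = seq_len(lattice[3]) - 1))
  pos <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    sweep(mol, 2, offs[i, ] * cell, "+")))
  box <- pmax(cell * lattice, min_box)
  configuration(pos, box, topology, n_molecules = nrow(offs))
}

# Uniform random rotation matrix from a normalized quaternion.
random_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

#' Random melt configuration by rejection sampling
#'
#' Inserts rigid copies of the equilibrium-geometry molecule at random
#' positions and orientations, rejecting insertions that bring any bead
#' of the new molecule within `clearance` of an already placed bead
#' (minimum image). Deterministic under the seed.
#'
#' @param topology A `tag_topology`.
#' @param ff A `cogito_ff`.
#' @param n_molecules Number of molecules to place (>= 1).
#' @param box Box edge lengths in nm (3-vector) or 3x3 matrix.
#' @param clearance Minimum interbead distance between molecules in nm.
#' @param seed Integer seed.
#' @param max_attempts Insertion attempts per molecule before giving up.
#' @return A `cg_configuration`.
#' @export
build_melt <- function(topology, ff = cogito_ff(), n_molecules, box,
                       clearance = 0.35, seed = 1, max_attempts = 500) {
  if (n_molecules < 1) stop("n_molecules must be >= 1")
  box <- as_box(box)
  mol <- build_extended_molecule(topology, ff)
  mol <- sweep(mol, 2, colMeans(mol))           # centre at origin
  placed <- NULL
  with_seed(seed, {
    for (m in seq_len(n_molecules)) {
      ok <- FALSE
      for (att in seq_len(max_attempts)) {
        R <- random_rotation()
        shift <- stats::runif(3) * diag(box)
        cand <- sweep(mol %*% t(R), 2, shift, "+")
        if (is.null(placed)) { ok <- TRUE; break }
        dmin <- Inf
        for (i in seq_len(nrow(cand))) {
          D <- min_image(placed - matrix(cand[i, ], nrow(placed), 3,
                                         byrow = TRUE), box)
          dmin <- min(dmin, sqrt(min(rowSums(D^2))))
          if (dmin < clearance) break
        }
        if (dmin >= clearance) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf(
          "melt insertion failed after %d attempts: placed %d of %d molecules; use a larger box or smaller clearance",
          max_attempts, m - 1, n_molecules))
      placed <- rbind(placed, cand)
    }
  })
  configuration(placed, box, topology, n_molecules = n_molecules)
}
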