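# Potential-energy and analytic-force evaluation for periodic CG
# configurations: harmonic bonds, GROMOS-96 cosine angles, potential-shifted
# Lennard-Jones and plain truncated Coulomb, under the minimum-image
# convention for a GROMACS lower-triangular triclinic box.

as_box <- function(box) {
  if (is.numeric(box) && length(box) == 3) box <- diag(box)
  box <- as.matrix(box)
  if (!all(dim(box) == c(3, 3))) stop("box must be a 3-vector or 3x3 matrix")
  if (any(abs(box[upper.tri(box)]) > 1e-12))
    stop("box must be lower-triangular (GROMACS convention)")
  if (any(diag(box) <= 0)) stop("box diagonal must be positive")
  box
}

#' Build a periodic CG configuration
#'
#' @param positions N x 3 matrix of bead coordinates in nm.
#' @param box Box edge lengths (length-3 vector, orthorhombic) or a 3x3
#'   lower-triangular matrix whose rows are the box vectors, in nm.
#' @param topology A `tag_topology`; replicated `n_molecules` times.
#' @param n_molecules Number of copies of `topology` in the system.
#' @return Object of class `cg_configuration` with system-level bead
#'   types, charges, bonds, angles and exclusions expanded per molecule.
#' @export
configuration <- function(positions, box, topology, n_molecules = 1) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  if (!all(is.finite(positions))) stop("positions must be finite")
  box <- as_box(box)
  nb <- n_beads(topology)
  if (nrow(positions) != nb * n_molecules)
    stop(sprintf("expected %d beads (%d molecules x %d), got %d",
                 nb * n_molecules, n_molecules, nb, nrow(positions)))
  offsets <- (seq_len(n_molecules) - 1L) * nb
  rep_idx <- function(m) do.call(rbind, lapply(offsets, function(o) m + o))
  structure(list(
    positions = positions,
    box = box,
    topology = topology,
    n_molecules = n_molecules,
    bead_types = rep(topology$bead_types, n_molecules),
    charges = rep(topology$charges, n_molecules),
    masses = rep(topology$masses, n_molecules),
    bonds = rep_idx(topology$bonds),
    angles = rep_idx(topology$angles),
    exclusions = rep_idx(topology$exclusions)
  ), class = "cg_configuration")
}

#' @export
print.cg_configuration <- function(x, ...) {
  cat(sprintf("CG configuration: %d beads (%d x %s), box %.3f x %.3f x %.3f nm\n",
              nrow(x$positions), x$n_molecules, x$topology$molecule_name,
              x$box[1, 1], x$box[2, 2], x$box[3, 3]))
  invisible(x)
}

# Minimum-image displacement for a lower-triangular triclinic box.
# D is an M x 3 matrix of raw displacement vectors.
min_image <- function(D, box) {
  D <- D - outer(round(D[, 3] / box[3, 3]), box[3, ])
  D <- D - outer(round(D[, 2] / box[2, 2]), box[2, ])
  D <- D - outer(round(D[, 1] / box[1, 1]), box[1, ])
  D
}

check_box_cutoff <- function(box, cutoff) {
  if (2 * cutoff >= min(diag(box)))
    stop(sprintf(
      "box too small for minimum image: smallest extent %.3f nm must exceed twice the cutoff (%.3f nm)",
      min(diag(box)), 2 * cutoff))
}

#' Harmonic bond-stretch energy
#'
#' @param r Bond length in nm (vectorized).
#' @param param Bond parameter row (list with `r_eq`, `k_b`).
#' @return Energy in kJ/mol: `0.5 * k_b * (r - r_eq)^2`.
#' @export
bond_energy <- function(r, param) 0.5 * param$k_b * (r - param$r_eq)^2

#' GROMOS-96 cosine angle-bending energy
#'
#' @param theta Angle in radians (vectorized).
#' @param param Angle parameter row (list with `theta_eq` in degrees,
#'   `k_theta`).
#' @return Energy in kJ/mol: `0.5 * k_theta * (cos(theta) - cos(theta_eq))^2`.
#' @export
angle_energy <- function(theta, param)
  0.5 * param$k_theta * (cos(theta) - cos(param$theta_eq * pi / 180))^2

#' Potential-shifted Lennard-Jones energy
#'
#' The LJ potential shifted so it is exactly zero at the cutoff
#' (GROMACS `vdw-modifier = potential-shift`), and zero beyond it.
#'
#' @param r Distance in nm (vectorized).
#' @param sigma,epsilon LJ parameters (nm, kJ/mol).
#' @param cutoff Cutoff distance in nm.
#' @return Energy in kJ/mol.
#' @export
lj_shifted <- function(r, sigma, epsilon, cutoff) {
  lj <- function(x) { sr6 <- (sigma / x)^6; 4 * epsilon * (sr6^2 - sr6) }
  ifelse(r < cutoff, lj(r) - lj(cutoff), 0)
}

# Per-row bonded parameter vectors for a configuration (internal).
bonded_params <- function(config, ff) {
  bt <- config$bead_types
  nb <- nrow(config$bonds)
  r_eq <- k_b <- numeric(nb)
  for (r in seq_len(nb)) {
    p <- lookup_bond(ff, bt[config$bonds[r, 1]], bt[config$bonds[r, 2]])
    r_eq[r] <- p$r_eq; k_b[r] <- p$k_b
  }
  na <- nrow(config$angles)
  cos_eq <- k_th <- numeric(na)
  for (r in seq_len(na)) {
    p <- lookup_angle(ff, bt[config$angles[r, 1]], bt[config$angles[r, 2]],
                      bt[config$angles[r, 3]])
    cos_eq[r] <- cos(p$theta_eq * pi / 180); k_th[r] <- p$k_theta
  }
  list(r_eq = r_eq, k_b = k_b, cos_eq = cos_eq, k_theta = k_th)
}

# Geometry of all bonds/angles under minimum image (internal).
bond_vectors <- function(config) {
  b <- config$bonds
  min_image(config$positions[b[, 2], , drop = FALSE] -
            config$positions[b[, 1], , drop = FALSE], config$box)
}
angle_vectors <- function(config) {
  a <- config$angles
  list(va = min_image(config$positions[a[, 1], , drop = FALSE] -
                      config$positions[a[, 2], , drop = FALSE], config$box),
       vc = min_image(config$positions[a[, 3], , drop = FALSE] -
                      config$positions[a[, 2], , drop = FALSE], config$box))
}

# Exclusion adjacency: list of excluded partner indices per bead (internal).
exclusion_list <- function(config) {
  n <- nrow(config$positions)
  ex <- vector("list", n)
  e <- config$exclusions
  for (r in seq_len(nrow(e))) {
    i <- e[r, 1]; j <- e[r, 2]
    ex[[i]] <- c(ex[[i]], j); ex[[j]] <- c(ex[[j]], i)
  }
  ex
}

#' Total CG potential energy of a configuration
#'
#' Sums harmonic bond, GROMOS-96 cosine angle, potential-shifted LJ
#' (Lorentz-Berthelot mixed) and truncated Coulomb terms using
#' minimum-image distances. Nonbonded interactions exclude only first
#' bonded neighbours; intermolecular pairs are never excluded. The
#' Coulomb term is plain `f q_i q_j / r` truncated at the cutoff
#' (optionally shifted to zero there); long-range electrostatics are the
#' job of the simulation engine, not this evaluator.
#'
#' @param config A `cg_configuration`.
#' @param ff A `cogito_ff`.
#' @param coulomb_shift If `TRUE`, shift the Coulomb term to zero at the
#'   cutoff (default `FALSE`).
#' @return Object of class `energy_breakdown`: list with `bond`, `angle`,
#'   `lj`, `coulomb` and `total` in kJ/mol.
#' @export
total_energy <- function(config, ff, coulomb_shift = FALSE) {
  check_box_cutoff(config$box, ff$cutoff)
  pars <- bonded_params(config, ff)

  bv <- bond_vectors(config)
  rb <- sqrt(rowSums(bv^2))
  if (any(rb < 1e-9)) stop("degenerate geometry: zero distance between bonded beads")
  e_bond <- sum(0.5 * pars$k_b * (rb - pars$r_eq)^2)

  av <- angle_vectors(config)
  na_ <- sqrt(rowSums(av$va^2)); nc_ <- sqrt(rowSums(av$vc^2))
  cth <- rowSums(av$va * av$vc) / (na_ * nc_)
  e_angle <- sum(0.5 * pars$k_theta * (cth - pars$cos_eq)^2)

  nb <- nonbonded_sum(config, ff, coulomb_shift)

  structure(list(bond = e_bond, angle = e_angle, lj = nb$lj,
                 coulomb = nb$coulomb,
                 total = e_bond + e_angle + nb$lj + nb$coulomb),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("Potential energy (kJ/mol)\n")
  for (k in c("bond", "angle", "lj", "coulomb", "total"))
    cat(sprintf("  %-8s %14.6f\n", k, x[[k]]))
  invisible(x)
}

# Nonbonded LJ + Coulomb over all pairs within the cutoff (internal).
# Vectorized half-loop over beads; exclusions are first bonded neighbours.
nonbonded_sum <- function(config, ff, coulomb_shift = FALSE) {
  pos <- config$positions
  n <- nrow(pos)
  sig <- ff$lj$sigma[ff$lj_index[config$bead_types]]
  eps <- ff$lj$epsilon[ff$lj_index[config$bead_types]]
  if (anyNA(sig)) stop("bead without LJ parameters in configuration")
  q <- config$charges
  ex <- exclusion_list(config)
  cut <- ff$cutoff
  fconst <- ff$coulomb_constant
  e_lj <- 0; e_coul <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    D <- min_image(pos[j, , drop = FALSE] -
                   matrix(pos[i, ], length(j), 3, byrow = TRUE), config$box)
    r2 <- rowSums(D^2)
    keep <- r2 < cut^2
    if (length(ex[[i]]) > 0) keep[j %in% ex[[i]]] <- FALSE
    if (!any(keep)) next
    r <- sqrt(r2[keep])
    if (any(r < 1e-9)) stop("degenerate geometry: coincident nonbonded beads")
    jj <- j[keep]
    s <- (sig[i] + sig[jj]) / 2
    e <- sqrt(eps[i] * eps[jj])
    sr6 <- (s / r)^6; sc6 <- (s / cut)^6
    e_lj <- e_lj + sum(4 * e * ((sr6^2 - sr6) - (sc6^2 - sc6)))
    qq <- q[i] * q[jj]
    ec <- fconst * qq / r
    if (coulomb_shift) ec <- ec - fconst * qq / cut
    e_coul <- e_coul + sum(ec)
  }
  list(lj = e_lj, coulomb = e_coul)
}

#' Analytic forces on every bead
#'
#' Negative gradient of [total_energy()] with respect to bead positions.
#' The angle term is differentiated through its cosine, which is regular
#' at 180 degrees.
#'
#' @inheritParams total_energy
#' @return N x 3 matrix of forces in kJ mol^-1 nm^-1.
#' @export
forces <- function(config, ff, coulomb_shift = FALSE) {
  check_box_cutoff(config$box, ff$cutoff)
  pos <- config$positions
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  pars <- bonded_params(config, ff)

  bv <- bond_vectors(config)            # d = r_j - r_i (min image)
  rb <- sqrt(rowSums(bv^2))
  if (any(rb < 1e-9)) stop("degenerate geometry: zero distance between bonded beads")
  coef <- pars$k_b * (rb - pars$r_eq) / rb
  for (r in seq_len(nrow(config$bonds))) {
    i <- config$bonds[r, 1]; j <- config$bonds[r, 2]
    f <- coef[r] * bv[r, ]
    F[i, ] <- F[i, ] + f
    F[j, ] <- F[j, ] - f
  }

  av <- angle_vectors(config)
  na_ <- sqrt(rowSums(av$va^2)); nc_ <- sqrt(rowSums(av$vc^2))
  cth <- rowSums(av$va * av$vc) / (na_ * nc_)
  dU <- pars$k_theta * (cth - pars$cos_eq)   # dU/dcos(theta)
  for (r in seq_len(nrow(config$angles))) {
    i <- config$angles[r, 1]; j <- config$angles[r, 2]; k <- config$angles[r, 3]
    a <- av$va[r, ]; b <- av$vc[r, ]
    ga <- b / (na_[r] * nc_[r]) - cth[r] * a / na_[r]^2
    gb <- a / (na_[r] * nc_[r]) - cth[r] * b / nc_[r]^2
    fi <- -dU[r] * ga
    fk <- -dU[r] * gb
    F[i, ] <- F[i, ] + fi
    F[k, ] <- F[k, ] + fk
    F[j, ] <- F[j, ] - fi - fk
  }

  sig <- ff$lj$sigma[ff$lj_index[config$bead_types]]
  eps <- ff$lj$epsilon[ff$lj_index[config$bead_types]]
  q <- config$charges
  ex <- exclusion_list(config)
  cut <- ff$cutoff
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    D <- min_image(pos[j, , drop = FALSE] -
                   matrix(pos[i, ], length(j), 3, byrow = TRUE), config$box)
    r2 <- rowSums(D^2)
    keep <- r2 < cut^2
    if (length(ex[[i]]) > 0) keep[j %in% ex[[i]]] <- FALSE
    if (!any(keep)) next
    r <- sqrt(r2[keep])
    if (any(r < 1e-9)) stop("degenerate geometry: coincident nonbonded beads")
    jj <- j[keep]
    Dk <- D[keep, , drop = FALSE]
    s <- (sig[i] + sig[jj]) / 2
    e <- sqrt(eps[i] * eps[jj])
    sr6 <- (s / r)^6
    dUdr <- -24 * e * (2 * sr6^2 - sr6) / r +          # LJ
            -ff$coulomb_constant * q[i] * q[jj] / r^2   # Coulomb
    # F_i = dU/dr * d/r with d = r_j - r_i
    Fi <- Dk * (dUdr / r)
    F[i, ] <- F[i, ] + colSums(Fi)
    F[jj, ] <- F[jj, ] - Fi
  }
  F
}

#' Steepest-descent energy minimization
#'
#' Relaxes a configuration by steepest descent with an adaptive step:
#' accepted steps (energy decreases) grow the step size, rejected ones
#' shrink it. Intended for relaxing generated starting structures, not
#' for production minimization.
#'
#' @param config A `cg_configuration`.
#' @param ff A `cogito_ff`.
#' @param max_steps Maximum iterations (default 500).
#' @param tol Convergence threshold on the largest force component,
#'   kJ mol^-1 nm^-1 (default 1).
#' @param step0 Initial maximum displacement in nm (default 0.01).
#' @return The relaxed `cg_configuration` with attributes `energy`
#'   (final breakdown) and `converged`.
#' @export
minimize <- function(config, ff, max_steps = 500, tol = 1, step0 = 0.01) {
  e <- total_energy(config, ff)$total
  if (!is.finite(e)) stop("divergence: initial energy is not finite")
  step <- step0
  converged <- FALSE
  for (it in seq_len(max_steps)) {
    F <- forces(config, ff)
    fmax <- max(abs(F))
    if (fmax < tol) { converged <- TRUE; break }
    trial <- config
    trial$positions <- config$positions + step * F / fmax
    et <- total_energy(trial, ff)$total
    if (is.nan(et)) stop("divergence: energy became NaN during minimization")
    if (et < e) {
      config <- trial; e <- et; step <- min(step * 1.2, 0.2)
    } else {
      step <- step / 2
      if (step < 1e-10) { converged <- TRUE; break }
    }
  }
  attr(config, "energy") <- total_energy(config, ff)
  attr(config, "converged") <- converged
  config
}
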