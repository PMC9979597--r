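# Shared fixtures and independent oracles for the test suite.

oleic_spec <- function() fatty_acid(18, list(list(position = 9, geometry = "cis")))

make_posts <- function(ff = cogito_ff())
  build_tag("POSt", fatty_acid(16), oleic_spec(), fatty_acid(18), ff)

make_ooo <- function(ff = cogito_ff())
  build_tag("OOO", oleic_spec(), oleic_spec(), oleic_spec(), ff)

# Minimal two-bead topology for isolated bond tests.
dimer_topology <- function(type_a = "C3H6", type_b = "C3H6",
                           ff = cogito_ff()) {
  bi <- ff$bead_index[c(type_a, type_b)]
  structure(list(
    molecule_name = "DIMER",
    bead_types = c(type_a, type_b),
    charges = ff$beads$charge[bi],
    masses = ff$beads$mass[bi],
    bonds = matrix(c(1L, 2L), ncol = 2),
    angles = matrix(integer(0), ncol = 3),
    exclusions = matrix(c(1L, 2L), ncol = 2),
    sn_positions = NULL, chains = NULL
  ), class = "tag_topology")
}

# A bare configuration of free beads (no bonded terms), for RDF and
# ideal-gas tests: rdf() and density only touch positions/box/bead fields.
free_bead_config <- function(positions, box, bead_type = "C3H6",
                             ff = cogito_ff()) {
  n <- nrow(positions)
  structure(list(
    positions = positions, box = as_box_oracle(box),
    topology = NULL, n_molecules = n,
    bead_types = rep(bead_type, n),
    charges = rep(0, n),
    masses = rep(ff$beads$mass[ff$bead_index[bead_type]], n),
    bonds = matrix(integer(0), ncol = 2),
    angles = matrix(integer(0), ncol = 3),
    exclusions = matrix(integer(0), ncol = 2)
  ), class = "cg_configuration")
}

as_box_oracle <- function(box) if (is.matrix(box)) box else diag(box)

# Scalar minimum-image displacement (independent of the package's
# vectorized implementation path, same lower-triangular convention).
mi_oracle <- function(d, box) {
  d <- d - box[3, ] * round(d[3] / box[3, 3])
  d <- d - box[2, ] * round(d[2] / box[2, 2])
  d <- d - box[1, ] * round(d[1] / box[1, 1])
  d
}

# Brute-force O(N^2) scalar double-loop energy oracle: explicit loops,
# scalar arithmetic, no shared code with the production evaluator beyond
# the parameter tables.
brute_force_energy <- function(config, ff) {
  pos <- config$positions
  n <- nrow(pos)
  bt <- config$bead_types
  box <- config$box
  cut <- ff$cutoff
  e_bond <- 0
  for (r in seq_len(nrow(config$bonds))) {
    i <- config$bonds[r, 1]; j <- config$bonds[r, 2]
    p <- lookup_bond(ff, bt[i], bt[j])
    d <- mi_oracle(pos[j, ] - pos[i, ], box)
    rij <- sqrt(sum(d^2))
    e_bond <- e_bond + 0.5 * p$k_b * (rij - p$r_eq)^2
  }
  e_angle <- 0
  for (r in seq_len(nrow(config$angles))) {
    i <- config$angles[r, 1]; j <- config$angles[r, 2]; k <- config$angles[r, 3]
    p <- lookup_angle(ff, bt[i], bt[j], bt[k])
    a <- mi_oracle(pos[i, ] - pos[j, ], box)
    b <- mi_oracle(pos[k, ] - pos[j, ], box)
    cth <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    e_angle <- e_angle + 0.5 * p$k_theta * (cth - cos(p$theta_eq * pi / 180))^2
  }
  excl <- new.env()
  for (r in seq_len(nrow(config$exclusions))) {
    i <- config$exclusions[r, 1]; j <- config$exclusions[r, 2]
    assign(paste(min(i, j), max(i, j)), TRUE, envir = excl)
  }
  e_lj <- 0; e_coul <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.null(excl[[paste(i, j)]])) next
    d <- mi_oracle(pos[j, ] - pos[i, ], box)
    rij <- sqrt(sum(d^2))
    if (rij >= cut) next
    m <- mix_lj(ff, bt[i], bt[j])
    sr6 <- (m[["sigma"]] / rij)^6
    sc6 <- (m[["sigma"]] / cut)^6
    e_lj <- e_lj + 4 * m[["epsilon"]] * ((sr6^2 - sr6) - (sc6^2 - sc6))
    e_coul <- e_coul + ff$coulomb_constant * config$charges[i] *
      config$charges[j] / rij
  }
  list(bond = e_bond, angle = e_angle, lj = e_lj, coulomb = e_coul,
       total = e_bond + e_angle + e_lj + e_coul)
}

# Central finite-difference forces from total_energy.
fd_forces <- function(config, ff, h = 1e-6) {
  n <- nrow(config$positions)
  F <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    cp <- config; cp$positions[i, k] <- cp$positions[i, k] + h
    cm <- config; cm$positions[i, k] <- cm$positions[i, k] - h
    F[i, k] <- -(total_energy(cp, ff)$total - total_energy(cm, ff)$total) /
      (2 * h)
  }
  F
}

# A single-TAG configuration with thermally jittered coordinates.
jittered_config <- function(topology, ff, seed, box = c(12, 12, 12),
                            sd = 0.02) {
  mol <- build_extended_molecule(topology, ff)
  mol <- sweep(mol, 2, apply(mol, 2, min)) + 3
  set.seed(seed)
  mol <- mol + matrix(rnorm(length(mol), 0, sd), ncol = 3)
  configuration(mol, box, topology, 1)
}

canonical_lj_optimum <- function(ff = cogito_ff())
  stats::setNames(c(ff$lj$sigma, ff$lj$epsilon),
                  c(paste0(ff$lj$bead, ".sigma"),
                    paste0(ff$lj$bead, ".epsilon")))

# Random valid fatty-acid specs for property tests: lengths 10-24,
# 0-3 double bonds at legal spacings.
random_chain_spec <- function() {
  n <- sample(10:24, 1)
  k <- sample(0:3, 1)
  pos <- integer(0)
  lo <- 5
  while (k > 0 && lo <= n - 7) {
    cand <- lo:(n - 7)
    p <- cand[sample.int(length(cand), 1)]
    pos <- c(pos, p)
    lo <- p + 5
    k <- k - 1
  }
  fatty_acid(n, lapply(pos, function(p)
    list(position = p, geometry = sample(c("cis", "trans"), 1))))
}
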