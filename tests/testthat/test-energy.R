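test_that("bonded term formulas match hand arithmetic", {
  ff <- cogito_ff()
  b <- lookup_bond(ff, "1CH2OCO", "2CHOCO")
  expect_equal(bond_energy(b$r_eq, b), 0)
  expect_equal(bond_energy(0.480, b), 0.5 * 4000 * 0.010^2)
  expect_equal(bond_energy(5, list(r_eq = 0.3, k_b = 0)), 0)
  a <- lookup_angle(ff, "1CH2OCO", "2CHOCO", "3CH2OCO")
  expect_equal(angle_energy(a$theta_eq * pi / 180, a), 0)
  expect_equal(angle_energy(pi / 2, a), 0.5 * 120 * cos(65 * pi / 180)^2)
  expect_equal(angle_energy(pi / 2, a), 10.72, tolerance = 1e-3)
  # cosine symmetry: theta and 180 - theta agree when theta_eq = 90
  p90 <- list(theta_eq = 90, k_theta = 35)
  expect_equal(angle_energy(1.1, p90), angle_energy(pi - 1.1, p90))
})

test_that("shifted LJ vanishes at and beyond the cutoff and loses the shift at sigma", {
  expect_equal(lj_shifted(1.1, 0.4, 3, 1.1), 0)
  expect_equal(lj_shifted(2.5, 0.4, 3, 1.1), 0)
  sr6 <- (0.4 / 1.1)^6
  shift <- 4 * 3 * (sr6^2 - sr6)
  expect_equal(lj_shifted(0.4, 0.4, 3, 1.1), -shift)
})

test_that("total energy matches the brute-force double-loop oracle", {
  ff <- cogito_ff()
  topo <- make_posts(ff)
  # single jittered molecule
  cfg <- jittered_config(topo, ff, seed = 11)
  e <- total_energy(cfg, ff)
  o <- brute_force_energy(cfg, ff)
  for (k in c("bond", "angle", "lj", "coulomb", "total"))
    expect_equal(e[[k]], o[[k]], tolerance = 1e-10, info = k)
  expect_equal(e$total, e$bond + e$angle + e$lj + e$coulomb)
  # a periodic lamellar stack (interacting images)
  stack <- build_lamellar(topo, ff, lattice = c(2, 1, 2), spacing = 0.5)
  e2 <- total_energy(stack, ff)
  o2 <- brute_force_energy(stack, ff)
  expect_equal(e2$total, o2$total, tolerance = 1e-10)
})

test_that("energy is invariant under periodic translation and rigid rotation", {
  ff <- cogito_ff()
  topo <- make_posts(ff)
  cfg <- jittered_config(topo, ff, seed = 3)
  e0 <- total_energy(cfg, ff)$total
  # translate by a full box vector
  tr <- cfg
  tr$positions <- sweep(tr$positions, 2, tr$box[1, ], "+")
  expect_equal(total_energy(tr, ff)$total, e0, tolerance = 1e-10)
  # rigid 90-degree rotation about z in a cubic box
  rot <- cfg
  R <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  rot$positions <- cfg$positions %*% t(R) + 12
  expect_equal(total_energy(rot, ff)$total, e0, tolerance = 1e-9)
})

test_that("energy is extensive and vanishes for isolated neutral beads", {
  ff <- cogito_ff()
  topo <- make_posts(ff)
  cfg <- jittered_config(topo, ff, seed = 5, box = c(30, 12, 12))
  e1 <- total_energy(cfg, ff)$total
  two <- configuration(rbind(cfg$positions, sweep(cfg$positions, 2,
                                                  c(15, 0, 0), "+")),
                       c(30, 12, 12), topo, n_molecules = 2)
  expect_equal(total_energy(two, ff)$total, 2 * e1, tolerance = 1e-10)
  # two neutral beads far beyond the cutoff
  d <- dimer_topology("C3H6", "C3H7T", ff)
  iso <- configuration(rbind(c(1, 1, 1), c(1, 1, 1.4)), c(10, 10, 10), d, 1)
  e <- total_energy(iso, ff)
  expect_equal(e$lj + e$coulomb, 0)   # bonded pair is excluded
  expect_error(
    total_energy(configuration(rbind(c(1, 1, 1), c(1, 1, 1.4)),
                               c(2, 2, 2), d, 1), ff),
    "box too small")
})

test_that("analytic forces match central finite differences and sum to zero", {
  ff <- cogito_ff()
  topo <- make_posts(ff)
  for (seed in c(1, 2, 3)) {
    cfg <- jittered_config(topo, ff, seed = seed)
    F <- forces(cfg, ff)
    expect_lt(max(abs(colSums(F))), 1e-8)
    Ffd <- fd_forces(cfg, ff)
    rel <- abs(F - Ffd) / pmax(abs(Ffd), 1)
    expect_lt(max(rel), 1e-4)
  }
})

test_that("a stretched bond gives equal and opposite forces of magnitude k(r - r_eq)", {
  ff <- cogito_ff()
  d <- dimer_topology("C3H6", "C3H6", ff)
  p <- lookup_bond(ff, "C3H6", "C3H6")
  r <- p$r_eq + 0.05
  cfg <- configuration(rbind(c(2, 2, 2), c(2 + r, 2, 2)), c(10, 10, 10), d, 1)
  F <- forces(cfg, ff)
  expect_equal(F[1, ], -F[2, ])
  expect_equal(F[1, 1], p$k_b * 0.05, tolerance = 1e-10)
  expect_equal(F[1, 2:3], c(0, 0))
  # coincident bonded beads are an error, not a silent clamp
  bad <- configuration(rbind(c(2, 2, 2), c(2, 2, 2 + 1e-12)),
                       c(10, 10, 10), d, 1)
  expect_error(total_energy(bad, ff), "degenerate")
})

test_that("steepest descent relaxes a perturbed bond back to equilibrium", {
  ff <- cogito_ff()
  d <- dimer_topology("C3H6", "C3H6", ff)
  p <- lookup_bond(ff, "C3H6", "C3H6")
  at_eq <- configuration(rbind(c(2, 2, 2), c(2 + p$r_eq, 2, 2)),
                         c(10, 10, 10), d, 1)
  res <- minimize(at_eq, ff, tol = 1e-6)
  expect_equal(res$positions, at_eq$positions)
  pert <- configuration(rbind(c(2, 2, 2), c(2 + p$r_eq + 0.08, 2, 2)),
                        c(10, 10, 10), d, 1)
  rel <- minimize(pert, ff, max_steps = 2000, tol = 1e-4)
  r_final <- sqrt(sum((rel$positions[2, ] - rel$positions[1, ])^2))
  expect_lt(abs(r_final - p$r_eq), 1e-4)
  # energy never increases on a fixture stack
  topo <- make_posts(ff)
  stack <- build_lamellar(topo, ff, lattice = c(2, 1, 1), spacing = 0.5)
  e0 <- total_energy(stack, ff)$total
  relaxed <- minimize(stack, ff, max_steps = 50)
  expect_lte(attr(relaxed, "energy")$total, e0)
})
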