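test_that("density follows the closed-form mass/volume arithmetic", {
  cfg <- free_bead_config(matrix(5, 1, 3), c(10, 10, 10))
  m_total <- 100 * 861.413
  expected <- (m_total / 6.02214076e23) / 1e-18   # 1000 nm^3 in cm^3
  expect_equal(density_g_cm3(cfg, molar_mass = m_total), expected)
  expect_equal(density_g_cm3(cfg, molar_mass = m_total), 0.14304,
               tolerance = 1e-4)
  big <- free_bead_config(matrix(5, 1, 3), c(20, 20, 20))
  expect_equal(density_g_cm3(big, molar_mass = m_total),
               density_g_cm3(cfg, molar_mass = m_total) / 8)
  expect_error(density_g_cm3(cfg, molar_mass = 0), "empty")
  # translation invariance: density only sees the box
  shifted <- cfg; shifted$positions <- cfg$positions + 3
  expect_equal(density_g_cm3(shifted), density_g_cm3(cfg))
})

test_that("density over a window averages the selected frames", {
  cfgs <- lapply(c(10, 10, 20), function(L)
    free_bead_config(matrix(1, 4, 3) + runif(12), c(L, L, L)))
  fs <- frame_series(c(0, 1000, 2000), cfgs)
  d10 <- density_g_cm3(cfgs[[1]])
  d20 <- density_g_cm3(cfgs[[3]])
  expect_equal(density_window(fs), (2 * d10 + d20) / 3)
  expect_equal(density_window(fs, window_start = 2000), d20)
  expect_error(density_window(fs, window_start = 1e6), "no frames")
})

test_that("lattice parameters divide out the stacking and invert exactly", {
  lp <- lattice_params(c(25, 5, 40), stacking = c(5, 1, 5))
  expect_equal(c(lp$a, lp$b, lp$c), c(5, 5, 8))
  expect_equal(c(lp$alpha, lp$beta, lp$gamma), c(90, 90, 90))
  lp1 <- lattice_params(diag(3), stacking = c(1, 1, 1))
  expect_equal(c(lp1$a, lp1$b, lp1$c), c(1, 1, 1))
  # monoclinic: c-vector tilted in the xz-plane, beta from the dot product
  box <- rbind(c(5, 0, 0), c(0, 4, 0), c(-1.5, 0, 6))
  lp2 <- lattice_params(box, stacking = c(1, 1, 1))
  expect_equal(lp2$beta, acos(-1.5 / sqrt(1.5^2 + 6^2)) * 180 / pi)
  expect_equal(lp2$alpha, 90)
  # round trip through box construction is exact to 1e-10
  rebuilt <- box_from_lattice(lp2)
  expect_equal(rebuilt, box, tolerance = 1e-10)
  lp3 <- lattice_params(rebuilt, stacking = c(1, 1, 1))
  for (k in c("a", "b", "c", "alpha", "beta", "gamma"))
    expect_equal(lp3[[k]], lp2[[k]], tolerance = 1e-10)
  expect_error(lattice_params(rbind(c(-1, 0, 0), c(0, 1, 0), c(0, 0, 1))),
               "diagonal")
})

test_that("the RDF of a seeded ideal gas is flat at unity with the right coordination", {
  set.seed(99)
  L <- 5; n <- 500; bw <- 0.1
  cfgs <- lapply(1:4, function(i)
    free_bead_config(matrix(runif(3 * n, 0, L), ncol = 3), c(L, L, L)))
  fs <- frame_series(seq_along(cfgs), cfgs)
  tab <- rdf(fs, seq_len(n), seq_len(n), bin_width = bw)
  upper <- tab$g[tab$r > max(tab$r) / 2]
  expect_true(all(abs(upper - 1) < 0.05))
  # integral of g rho 4 pi r^2 dr gives the ideal coordination within 2%
  r_lim <- 1.5
  sel <- tab$r <= r_lim
  rho <- (n - 1) / L^3
  shell <- 4 / 3 * pi * diff(c(0, tab$r[sel] + bw / 2)^3)
  coord <- sum(tab$g[sel] * rho * shell)
  expect_equal(coord, (n - 1) * 4 / 3 * pi * r_lim^3 / L^3, tolerance = 0.02)
})

test_that("the RDF resolves a fixed pair distance into a single bin", {
  cfg <- free_bead_config(rbind(c(1, 1, 1), c(2, 1, 1)), c(6, 6, 6))
  tab <- rdf(cfg, 1, 2, bin_width = 0.1, r_max = 2.5)
  nz <- which(tab$g > 0)
  expect_length(nz, 1)
  expect_lt(abs(tab$r[nz] - 1), 0.05 + 1e-12)
  expect_error(rdf(cfg, integer(0), 2), "empty")
  expect_error(rdf(cfg, 1, 2, r_max = 4), "half")
})

test_that("bonded distributions recover means and spreads of bond and angle samples", {
  ff <- cogito_ff()
  topo <- make_posts(ff)
  mol <- build_extended_molecule(topo, ff)
  cfg <- configuration(sweep(mol, 2, apply(mol, 2, min)) + 3,
                       c(12, 12, 12), topo, 1)
  # at equilibrium geometry every matching bond sits exactly at r_eq
  d <- bonded_distributions(cfg, c("C3H6", "C3H6"))
  expect_equal(d$mean, lookup_bond(ff, "C3H6", "C3H6")$r_eq, tolerance = 1e-9)
  expect_equal(d$sd, 0, tolerance = 1e-9)
  # ... and the glycerol backbone angle at its 65-degree equilibrium
  a <- bonded_distributions(cfg, c("1CH2OCO", "2CHOCO", "3CH2OCO"))
  expect_equal(a$mean, 65, tolerance = 1e-6)
  expect_error(bonded_distributions(cfg, c("CHCH", "CHCH")), "no bond")

  # Gaussian-perturbed bond lengths: pooled mean within 3 standard errors
  dt <- dimer_topology("C3H6", "C3H6", ff)
  r_eq <- lookup_bond(ff, "C3H6", "C3H6")$r_eq
  set.seed(7)
  n <- 200
  lens <- rnorm(n, r_eq, 0.01)
  cfgs <- lapply(lens, function(r)
    configuration(rbind(c(2, 2, 2), c(2 + r, 2, 2)), c(10, 10, 10), dt, 1))
  fs <- frame_series(seq_len(n), cfgs)
  db <- bonded_distributions(fs, c("C3H6", "C3H6"))
  expect_length(db$values, n)
  expect_lt(abs(db$mean - r_eq), 3 * 0.01 / sqrt(n))
})

test_that("bootstrap means are deterministic, honest on constants and well calibrated", {
  const <- energy_series(1:50, rep(42, 50))
  b <- bootstrap_mean(const, n_boot = 500, seed = 1)
  expect_equal(b$mean, 42)
  expect_equal(diff(b$ci), 0)
  noisy <- energy_series(1:100, rnorm(100, 10, 2))
  expect_identical(bootstrap_mean(noisy, n_boot = 300, seed = 9)$ci,
                   bootstrap_mean(noisy, n_boot = 300, seed = 9)$ci)
  # law of large numbers: bootstrap mean-of-means approaches the sample mean
  big <- bootstrap_mean(noisy, n_boot = 1e5, seed = 2)
  expect_lt(abs(mean(big$boot) - big$mean), 0.02)
  expect_error(bootstrap_mean(const, window_start = 1e9), "fewer than 2")

  # percentile CI coverage on i.i.d. normal data is close to 95%
  set.seed(31)
  n_rep <- 500
  covered <- 0
  for (i in seq_len(n_rep)) {
    s <- energy_series(1:100, rnorm(100, 5, 1))
    ci <- bootstrap_mean(s, n_boot = 200, seed = i)$ci
    if (ci[1] <= 5 && 5 <= ci[2]) covered <- covered + 1
  }
  expect_gt(covered / n_rep, 0.90)
  expect_lt(covered / n_rep, 0.99)
})

test_that("enthalpy-of-fusion differences recover planted offsets", {
  t <- 1:80
  base <- sin(t / 9)
  melt <- energy_series(t, base + 50)
  crystal <- energy_series(t, base)
  expect_equal(delta_h_fus(melt, melt, n_boot = 200, seed = 1)$estimate, 0)
  d <- delta_h_fus(melt, crystal, n_boot = 200, seed = 1)
  expect_equal(d$estimate, 50)
  # noisy recovery: planted offset falls inside the propagated CI
  set.seed(12)
  m2 <- energy_series(t, rnorm(80, 130, 4))
  c2 <- energy_series(t, rnorm(80, 100, 4))
  d2 <- delta_h_fus(m2, c2, n_boot = 500, seed = 3)
  expect_gt(30, d2$ci[1]); expect_lt(30, d2$ci[2])
  agg <- average_runs(c(29, 31, 30.5))
  expect_equal(agg$mean, mean(c(29, 31, 30.5)))
})

test_that("the vaporization enthalpy formula reproduces RT arithmetic", {
  expect_equal(delta_h_vap(0, 0, 300), 8.314462618e-3 * 300)
  expect_equal(delta_h_vap(0, 0, 300), 2.4943, tolerance = 1e-4)
  expect_equal(delta_h_vap(150, 50, 0), 100)
  expect_equal(delta_h_vap(150, 50, 298.15), 102.479, tolerance = 1e-4)
  expect_error(delta_h_vap(1, 1, -5), "non-negative")
  expect_equal(pct_diff(0.94, 1.0), -6)
})

test_that("series containers enforce ordering and parse tabular text", {
  expect_error(energy_series(c(1, 1, 2), c(0, 0, 0)), "increasing")
  expect_error(frame_series(c(2, 1), list(
    free_bead_config(matrix(1, 1, 3), c(5, 5, 5)),
    free_bead_config(matrix(1, 1, 3), c(5, 5, 5)))), "increasing")
  tf <- tempfile()
  writeLines(c("# comment", "@ legend", "0 10.5", "1 11.5", "2 12.5"), tf)
  s <- read_energy_series(tf)
  expect_equal(s$times, c(0, 1, 2))
  expect_equal(s$values, c(10.5, 11.5, 12.5))
})
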