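# Trajectory and energy-series observables: mass density, unit-cell
# lattice parameters, radial distribution functions with
# centre-of-geometry bead grouping, bonded-distribution extraction for
# bottom-up fitting, and bootstrap enthalpy estimators.

AVOGADRO <- 6.02214076e23
GAS_CONSTANT <- 8.314462618e-3   # kJ mol^-1 K^-1

#' Ordered series of configuration frames
#'
#' @param times Frame times in ps, strictly increasing.
#' @param configs List of `cg_configuration` objects with a constant
#'   bead count.
#' @return Object of class `frame_series`.
#' @export
frame_series <- function(times, configs) {
  if (length(times) != length(configs))
    stop("times and configs must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  nb <- vapply(configs, function(c) nrow(c$positions), 0L)
  if (length(unique(nb)) > 1)
    stop("all frames must have the same bead count")
  structure(list(times = as.numeric(times), configs = configs),
            class = "frame_series")
}

#' Ordered time series of enthalpy or energy samples
#'
#' @param times Sample times in ps, strictly increasing.
#' @param values Samples in kJ/mol.
#' @param label Which quantity the series holds (free text, e.g.
#'   "enthalpy" or "total energy").
#' @return Object of class `energy_series`.
#' @export
energy_series <- function(times, values, label = "enthalpy") {
  if (length(times) != length(values))
    stop("times and values must have equal length")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("sample times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "energy_series")
}

#' Read an energy series from two-column plain text
#'
#' Accepts the (time, value) tabular text exported by standard energy
#' extraction tools; lines starting with `#`, `@` or `;` are skipped.
#'
#' @param path File path.
#' @param label Series label.
#' @return An `energy_series`.
#' @export
read_energy_series <- function(path, label = "enthalpy") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*[#@;]", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"),
                             function(f) as.numeric(f[1:2])))
  energy_series(m[, 1], m[, 2], label)
}

#' Mass density of a configuration
#'
#' @param config A `cg_configuration`.
#' @param molar_mass Total molar mass of the box contents in g/mol;
#'   defaults to the sum of the bead masses in `config`.
#' @return Density in g/cm^3.
#' @examples
#' # 100 molecules of molar mass 861.413 g/mol in a 1000 nm^3 box:
#' # 100 * 861.413 / N_A / 1e-18 cm^3 = 0.14304 g/cm^3
#' @export
density_g_cm3 <- function(config, molar_mass = sum(config$masses)) {
  if (nrow(config$positions) == 0 || molar_mass <= 0)
    stop("empty configuration: no mass to compute a density from")
  vol_nm3 <- det(config$box)
  if (vol_nm3 <= 0) stop("box volume must be positive")
  (molar_mass / AVOGADRO) / (vol_nm3 * 1e-21)
}

#' Mean density over a time window of a frame series
#'
#' Frames with `t >= window_start` (inclusive) contribute; the
#' convention "last X ns" is `window_start = t_end - X`.
#'
#' @param frames A `frame_series`.
#' @param window_start Window start in ps (default: whole series).
#' @return Mean density in g/cm^3.
#' @export
density_window <- function(frames, window_start = -Inf) {
  sel <- which(frames$times >= window_start)
  if (length(sel) == 0) stop("no frames in the requested window")
  mean(vapply(frames$configs[sel], density_g_cm3, 0))
}

#' Unit-cell lattice parameters from a simulation box
#'
#' Divides each box vector by its stacking count (how many unit cells
#' the box stacks along that crystallographic direction) and returns the
#' cell edge lengths and inter-vector angles. The default stacking
#' (5, 1, 5) matches a crystal built by stacking five unit cells along
#' a and c. Angles are stacking-invariant, so box and unit-cell angles
#' coincide.
#'
#' @param box 3-vector or 3x3 lower-triangular box matrix (nm).
#' @param stacking Integer triple (n_a, n_b, n_c).
#' @return Object of class `lattice_params`: a, b, c in nm and alpha,
#'   beta, gamma in degrees (alpha between b and c, beta between a and
#'   c, gamma between a and b).
#' @export
lattice_params <- function(box, stacking = c(5, 1, 5)) {
  box <- as_box(box)
  v <- sweep(box, 1, stacking, "/")
  len <- sqrt(rowSums(v^2))
  ang <- function(i, j)
    acos(sum(v[i, ] * v[j, ]) / (len[i] * len[j])) * 180 / pi
  structure(list(a = len[1], b = len[2], c = len[3],
                 alpha = ang(2, 3), beta = ang(1, 3), gamma = ang(1, 2)),
            class = "lattice_params")
}

#' @export
print.lattice_params <- function(x, ...) {
  cat(sprintf("a = %.4f  b = %.4f  c = %.4f nm\n", x$a, x$b, x$c))
  cat(sprintf("alpha = %.3f  beta = %.3f  gamma = %.3f deg\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Lower-triangular box from lattice parameters
#'
#' Inverse of [lattice_params()] (up to the GROMACS lower-triangular
#' orientation convention).
#'
#' @param lp A `lattice_params` object (or list with the same fields).
#' @param stacking Integer triple multiplying the cell along each
#'   direction.
#' @return 3x3 lower-triangular box matrix in nm.
#' @export
box_from_lattice <- function(lp, stacking = c(1, 1, 1)) {
  d2r <- pi / 180
  ca <- cos(lp$alpha * d2r); cb <- cos(lp$beta * d2r); cg <- cos(lp$gamma * d2r)
  sg <- sin(lp$gamma * d2r)
  v1 <- c(lp$a, 0, 0)
  v2 <- c(lp$b * cg, lp$b * sg, 0)
  cz2 <- 1 - cb^2 - ((ca - cb * cg) / sg)^2
  if (cz2 <= 0) stop("inconsistent lattice angles")
  v3 <- c(lp$c * cb, lp$c * (ca - cb * cg) / sg, lp$c * sqrt(cz2))
  rbind(v1 * stacking[1], v2 * stacking[2], v3 * stacking[3])
}

#' Radial distribution function between two bead groups
#'
#' Standard pair RDF with minimum-image distances, shell-volume and
#' ideal-gas-density normalization, averaged over frames. Self pairs are
#' excluded when the groups overlap. Groups are index vectors, so UA
#' atoms already grouped to CG beads by centre of geometry (see
#' [cog_map()]) can be analysed identically to CG beads.
#'
#' @param frames A `frame_series` or a single `cg_configuration`.
#' @param group_a,group_b Integer bead indices.
#' @param bin_width Histogram bin width in nm.
#' @param r_max Maximum distance in nm; must not exceed half the
#'   smallest box extent.
#' @return Data frame with bin centres `r` and `g`.
#' @export
rdf <- function(frames, group_a, group_b, bin_width = 0.01, r_max = NULL) {
  if (inherits(frames, "cg_configuration"))
    frames <- frame_series(0, list(frames))
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("empty bead group")
  boxes <- lapply(frames$configs, `[[`, "box")
  half_min <- min(vapply(boxes, function(b) min(diag(b)), 0)) / 2
  if (is.null(r_max)) r_max <- half_min
  if (r_max > half_min + 1e-9)
    stop(sprintf("r_max (%.3f nm) exceeds half the smallest box extent (%.3f nm)",
                 r_max, half_min))
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, r_max)
  counts <- numeric(length(edges) - 1)
  norm <- 0
  n_common <- length(intersect(group_a, group_b))
  n_pairs <- length(group_a) * length(group_b) - n_common
  if (n_pairs == 0) stop("no distinct pairs between the groups")
  for (cfg in frames$configs) {
    pos <- cfg$positions
    d <- numeric(0)
    for (i in group_a) {
      j <- setdiff(group_b, i)
      if (length(j) == 0) next
      D <- min_image(pos[j, , drop = FALSE] -
                     matrix(pos[i, ], length(j), 3, byrow = TRUE), cfg$box)
      d <- c(d, sqrt(rowSums(D^2)))
    }
    counts <- counts + graphics::hist(d[d < r_max], breaks = edges,
                                      plot = FALSE)$counts
    norm <- norm + n_pairs / det(cfg$box)
  }
  shell <- 4 / 3 * pi * diff(edges^3)
  data.frame(r = (edges[-1] + edges[-length(edges)]) / 2,
             g = counts / (shell * norm))
}

#' Pooled bond or angle distributions across a trajectory
#'
#' Collects every instance of a bonded term whose bead types match the
#' selector, over all molecules and frames, and reports the pooled
#' histogram together with its mean and standard deviation - the two
#' statistics the bottom-up fitting workflow matches against UA data.
#'
#' @param frames A `frame_series` or single `cg_configuration`.
#' @param selector Character vector of 2 (bond) or 3 (angle, vertex in
#'   the middle) bead type names.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @return List with `kind`, `values` (nm or degrees), `mean`, `sd` and
#'   `histogram`.
#' @export
bonded_distributions <- function(frames, selector, breaks = 50) {
  if (inherits(frames, "cg_configuration"))
    frames <- frame_series(0, list(frames))
  cfg1 <- frames$configs[[1]]
  bt <- cfg1$bead_types
  if (length(selector) == 2) {
    kind <- "bond"
    key <- pair_key(selector[1], selector[2])
    rows <- which(vapply(seq_len(nrow(cfg1$bonds)), function(r)
      pair_key(bt[cfg1$bonds[r, 1]], bt[cfg1$bonds[r, 2]]) == key, TRUE))
  } else if (length(selector) == 3) {
    kind <- "angle"
    key <- triple_key(selector[1], selector[2], selector[3])
    rows <- which(vapply(seq_len(nrow(cfg1$angles)), function(r)
      triple_key(bt[cfg1$angles[r, 1]], bt[cfg1$angles[r, 2]],
                 bt[cfg1$angles[r, 3]]) == key, TRUE))
  } else stop("selector must name 2 (bond) or 3 (angle) bead types")
  if (length(rows) == 0)
    stop("no ", kind, " instances match selector: ",
         paste(selector, collapse = "-"))
  values <- numeric(0)
  for (cfg in frames$configs) {
    if (kind == "bond") {
      b <- cfg$bonds[rows, , drop = FALSE]
      D <- min_image(cfg$positions[b[, 2], , drop = FALSE] -
                     cfg$positions[b[, 1], , drop = FALSE], cfg$box)
      values <- c(values, sqrt(rowSums(D^2)))
    } else {
      a <- cfg$angles[rows, , drop = FALSE]
      va <- min_image(cfg$positions[a[, 1], , drop = FALSE] -
                      cfg$positions[a[, 2], , drop = FALSE], cfg$box)
      vc <- min_image(cfg$positions[a[, 3], , drop = FALSE] -
                      cfg$positions[a[, 2], , drop = FALSE], cfg$box)
      cth <- rowSums(va * vc) /
        (sqrt(rowSums(va^2)) * sqrt(rowSums(vc^2)))
      values <- c(values, acos(pmin(1, pmax(-1, cth))) * 180 / pi)
    }
  }
  list(kind = kind, selector = selector, values = values,
       mean = mean(values), sd = stats::sd(values),
       histogram = graphics::hist(values, breaks = breaks, plot = FALSE))
}

#' Bootstrap mean of an energy series over a time window
#'
#' Resamples the windowed samples with replacement `n_boot` times and
#' returns the window mean with a percentile 95% confidence interval.
#' Deterministic under a fixed seed.
#'
#' @param series An `energy_series`.
#' @param window_start Window start in ps, inclusive ("last X ns" is
#'   `t_end - X`).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return List with `mean`, `ci` (2.5% and 97.5% percentiles), `n` and
#'   the bootstrap means in `boot`.
#' @export
bootstrap_mean <- function(series, window_start = -Inf, n_boot = 1000,
                           seed = 1) {
  sel <- series$values[series$times >= window_start]
  if (length(sel) < 2)
    stop("bootstrap window holds fewer than 2 samples")
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(sel, replace = TRUE)), 0)
  })
  list(mean = mean(sel),
       ci = stats::quantile(boot, c(0.025, 0.975), names = FALSE),
       n = length(sel), boot = boot)
}

#' Enthalpy of fusion from melt and crystal enthalpy series
#'
#' Bootstrap mean of the melt series minus bootstrap mean of the
#' crystal series over the same window, with the confidence interval
#' propagated through the difference of the two (independent) bootstrap
#' distributions. Repeated runs can be averaged with [average_runs()].
#'
#' @param melt,crystal `energy_series` for the melted and crystalline
#'   system at the same temperature.
#' @param window_start Window start in ps.
#' @param n_boot Bootstrap resamples per series.
#' @param seed Integer seed (melt and crystal use derived sub-seeds).
#' @return List with `estimate` (kJ/mol), `ci`, and the per-phase
#'   bootstrap summaries.
#' @export
delta_h_fus <- function(melt, crystal, window_start = -Inf, n_boot = 1000,
                        seed = 1) {
  bm <- bootstrap_mean(melt, window_start, n_boot, derive_seed(seed, "melt"))
  bc <- bootstrap_mean(crystal, window_start, n_boot,
                       derive_seed(seed, "crystal"))
  diffs <- bm$boot - bc$boot
  list(estimate = bm$mean - bc$mean,
       ci = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
       melt = bm, crystal = bc)
}

#' Average an estimator over repeated runs
#'
#' @param estimates Numeric vector of per-run estimates.
#' @return List with `mean`, `sd` and `n`.
#' @export
average_runs <- function(estimates) {
  list(mean = mean(estimates), sd = stats::sd(estimates),
       n = length(estimates))
}

#' Enthalpy of vaporization from gas and liquid total energies
#'
#' `delta_H_vap ~ U_gas - U_liq + R T`, with U per mole and R the molar
#' gas constant (8.314462618 J/mol/K).
#'
#' @param u_gas,u_liq Total energies per mole (kJ/mol) of the gas-phase
#'   single molecule (NVT) and the liquid (NPT).
#' @param temperature Temperature in K (>= 0).
#' @return Enthalpy of vaporization in kJ/mol.
#' @examples
#' delta_h_vap(0, 0, 300)  # RT at 300 K = 2.4943 kJ/mol
#' @export
delta_h_vap <- function(u_gas, u_liq, temperature) {
  if (temperature < 0) stop("temperature must be non-negative")
  u_gas - u_liq + GAS_CONSTANT * temperature
}

#' Relative percentage difference from a reference value
#'
#' `100 * (simulated - reference) / reference`, the convention used when
#' reporting validation metrics against empirical values.
#'
#' @param simulated,reference Numeric values.
#' @return Percentage difference.
#' @export
pct_diff <- function(simulated, reference) {
  if (any(reference == 0)) stop("reference value must be nonzero")
  100 * (simulated - reference) / reference
}
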