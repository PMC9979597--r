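# Readers and writers for the simulation file formats the force field
# touches: .gro coordinate frames, .itp molecule/parameter files and
# system-level .top files (GROMACS dialects).

# ---- .gro frames -----------------------------------------------------------

#' Read a .gro coordinate frame
#'
#' Parses the fixed-width .gro format: title line, atom count, one record
#' per atom (residue number/name, atom name, atom number, x/y/z in nm,
#' optional velocities) and a final box line with 3 or 9 floats.
#'
#' @param x Path to a .gro file, or a character vector of lines.
#' @return Object of class `gro_frame`: list with `title`, `atoms`
#'   (data frame) and `box` (3x3 matrix, rows are box vectors).
#' @export
read_gro <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  parse_gro_lines(lines, offset = 0)$frame
}

parse_gro_lines <- function(lines, offset = 0) {
  if (length(lines) < 3)
    stop("malformed .gro: fewer than 3 lines at line ", offset + 1)
  title <- lines[1]
  natoms <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(natoms) || natoms < 0)
    stop("malformed .gro: bad atom count at line ", offset + 2)
  if (length(lines) < natoms + 3)
    stop("malformed .gro: header declares ", natoms, " atoms but only ",
         length(lines) - 3, " records follow (line ", offset + 2, ")")
  rec <- lines[3:(2 + natoms)]
  num <- function(s) {
    v <- suppressWarnings(as.numeric(s))
    bad <- which(is.na(v) | !nzchar(trimws(s)))
    if (length(bad) > 0)
      stop("malformed .gro record at line ", offset + 2 + bad[1])
    v
  }
  atoms <- data.frame(
    resnum = as.integer(num(substr(rec, 1, 5))),
    resname = trimws(substr(rec, 6, 10)),
    atomname = trimws(substr(rec, 11, 15)),
    atomnum = as.integer(num(substr(rec, 16, 20))),
    x = num(substr(rec, 21, 28)),
    y = num(substr(rec, 29, 36)),
    z = num(substr(rec, 37, 44)),
    stringsAsFactors = FALSE
  )
  if (all(nchar(rec) >= 68)) {
    atoms$vx <- num(substr(rec, 45, 52))
    atoms$vy <- num(substr(rec, 53, 60))
    atoms$vz <- num(substr(rec, 61, 68))
  }
  bl <- as.numeric(strsplit(trimws(lines[natoms + 3]), "\\s+")[[1]])
  if (anyNA(bl) || !length(bl) %in% c(3, 9))
    stop("malformed .gro box line at line ", offset + natoms + 3)
  box <- if (length(bl) == 3) diag(bl) else
    rbind(c(bl[1], bl[4], bl[5]),
          c(bl[6], bl[2], bl[7]),
          c(bl[8], bl[9], bl[3]))
  list(frame = structure(list(title = title, atoms = atoms, box = box),
                         class = "gro_frame"),
       consumed = natoms + 3)
}

#' Write a .gro coordinate frame
#'
#' Serializes a `gro_frame` in fixed-width .gro format; positions are
#' written to 3 decimals (the format's grid), velocities to 4. Atom and
#' residue names are truncated to the format's 5-character fields.
#'
#' @param frame A `gro_frame`.
#' @param file Optional path; if given the text is also written there.
#' @return Character vector of lines, invisibly when `file` is given.
#' @export
write_gro <- function(frame, file = NULL) {
  a <- frame$atoms
  has_vel <- all(c("vx", "vy", "vz") %in% names(a))
  fmt <- if (has_vel) "%5d%-5.5s%5.5s%5d%8.3f%8.3f%8.3f%8.4f%8.4f%8.4f"
         else "%5d%-5.5s%5.5s%5d%8.3f%8.3f%8.3f"
  rec <- if (has_vel)
    sprintf(fmt, a$resnum %% 100000, a$resname, a$atomname,
            a$atomnum %% 100000, a$x, a$y, a$z, a$vx, a$vy, a$vz)
  else
    sprintf(fmt, a$resnum %% 100000, a$resname, a$atomname,
            a$atomnum %% 100000, a$x, a$y, a$z)
  b <- frame$box
  off_diag <- c(b[1, 2], b[1, 3], b[2, 1], b[2, 3], b[3, 1], b[3, 2])
  boxline <- if (all(abs(off_diag) < 1e-12))
    sprintf("%10.5f%10.5f%10.5f", b[1, 1], b[2, 2], b[3, 3])
  else
    paste(sprintf("%10.5f", c(b[1, 1], b[2, 2], b[3, 3], b[1, 2], b[1, 3],
                              b[2, 1], b[2, 3], b[3, 1], b[3, 2])),
          collapse = "")
  out <- c(frame$title, sprintf("%5d", nrow(a)), rec, boxline)
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Read all frames of a multi-frame .gro trajectory
#'
#' @param x Path or character vector of lines holding concatenated
#'   .gro frames.
#' @return List of `gro_frame` objects.
#' @export
read_gro_traj <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  frames <- list()
  pos <- 0
  while (pos < length(lines)) {
    res <- parse_gro_lines(lines[(pos + 1):length(lines)], offset = pos)
    frames[[length(frames) + 1]] <- res$frame
    pos <- pos + res$consumed
  }
  frames
}

#' Build a `gro_frame` from a configuration
#'
#' Bead atom names are the bead type names (truncated to the format's
#' 5-character field on writing); one residue per molecule, residue name
#' the molecule name truncated to 5 characters.
#'
#' @param config A `cg_configuration`.
#' @param title Title line text.
#' @return A `gro_frame`.
#' @export
as_gro_frame <- function(config, title = config$topology$molecule_name) {
  nb <- n_beads(config$topology)
  n <- nrow(config$positions)
  structure(list(
    title = title,
    atoms = data.frame(
      resnum = rep(seq_len(config$n_molecules), each = nb),
      resname = substr(config$topology$molecule_name, 1, 5),
      atomname = config$bead_types,
      atomnum = seq_len(n),
      x = config$positions[, 1],
      y = config$positions[, 2],
      z = config$positions[, 3],
      stringsAsFactors = FALSE
    ),
    box = config$box
  ), class = "gro_frame")
}

#' Configuration from a `gro_frame` plus its topology
#'
#' @param frame A `gro_frame`.
#' @param topology The `tag_topology` the frame's beads instantiate.
#' @param n_molecules Number of molecule copies in the frame.
#' @return A `cg_configuration`.
#' @export
as_configuration <- function(frame, topology,
                             n_molecules = nrow(frame$atoms) / n_beads(topology)) {
  configuration(as.matrix(frame$atoms[, c("x", "y", "z")]), frame$box,
                topology, n_molecules)
}

# ---- .itp / .top topology files -------------------------------------------

fmt_num <- function(x) sub("\\.?0+$", "", sprintf("%.6f", x))

#' Emit GROMACS-dialect force-field parameter sections
#'
#' Writes `[atomtypes]` (name, mass, charge, ptype, sigma, epsilon),
#' `[bondtypes]` (function type 1, harmonic) and `[angletypes]`
#' (function type 2, GROMOS-96 cosine) for every row of the parameter
#' tables. Angle equilibria are written in degrees.
#'
#' @param ff A `cogito_ff`.
#' @param file Optional output path.
#' @return Character vector of lines.
#' @export
write_ff_itp <- function(ff, file = NULL) {
  out <- c(
    "[ atomtypes ]",
    "; name      mass   charge  ptype   sigma  epsilon",
    sprintf("%-9s %8.3f %8.2f  A  %s  %s",
            ff$beads$name, ff$beads$mass, ff$beads$charge,
            fmt_num(ff$lj$sigma[ff$lj_index[ff$beads$name]]),
            fmt_num(ff$lj$epsilon[ff$lj_index[ff$beads$name]])),
    "",
    "[ bondtypes ]",
    "; i         j        funct   r_eq    k_b",
    sprintf("%-9s %-9s 1  %s  %s", ff$bonds$bead_i, ff$bonds$bead_j,
            fmt_num(ff$bonds$r_eq), fmt_num(ff$bonds$k_b)),
    "",
    "[ angletypes ]",
    "; i         j         k        funct  theta_eq  k_theta",
    sprintf("%-9s %-9s %-9s 2  %s  %s", ff$angles$bead_i, ff$angles$bead_j,
            ff$angles$bead_k, fmt_num(ff$angles$theta_eq),
            fmt_num(ff$angles$k_theta))
  )
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

# Split .itp text into named sections of whitespace-tokenized rows.
parse_itp_sections <- function(lines) {
  lines <- sub(";.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      current <- trimws(gsub("\\[|\\]", "", ln))
      if (is.null(sections[[current]])) sections[[current]] <- list()
    } else {
      if (is.null(current)) stop("content before first [ section ] header")
      sections[[current]] <- c(sections[[current]],
                               list(strsplit(ln, "\\s+")[[1]]))
    }
  }
  sections
}

#' Read force-field parameter sections back into a model
#'
#' Inverse of [write_ff_itp()]: reconstructs the bead, bond, angle and LJ
#' tables from `[atomtypes]`, `[bondtypes]` and `[angletypes]` sections.
#' Bead compositions/descriptions are restored from the canonical bead
#' table by name.
#'
#' @param x Path or character vector of lines.
#' @param cutoff Nonbonded cutoff for the reconstructed model (nm).
#' @return A `cogito_ff`.
#' @export
read_ff_itp <- function(x, cutoff = 1.1) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  s <- parse_itp_sections(lines)
  for (need in c("atomtypes", "bondtypes", "angletypes"))
    if (is.null(s[[need]])) stop("missing [ ", need, " ] section")
  at <- do.call(rbind, lapply(s$atomtypes, function(f)
    data.frame(name = f[1], mass = as.numeric(f[2]),
               charge = as.numeric(f[3]), sigma = as.numeric(f[5]),
               epsilon = as.numeric(f[6]), stringsAsFactors = FALSE)))
  canon <- cogito_ff()$beads
  beads <- data.frame(
    name = at$name,
    description = canon$description[match(at$name, canon$name)],
    composition = canon$composition[match(at$name, canon$name)],
    mass = at$mass, charge = at$charge, stringsAsFactors = FALSE)
  bonds <- do.call(rbind, lapply(s$bondtypes, function(f)
    data.frame(bead_i = f[1], bead_j = f[2], r_eq = as.numeric(f[4]),
               k_b = as.numeric(f[5]), stringsAsFactors = FALSE)))
  angles <- do.call(rbind, lapply(s$angletypes, function(f)
    data.frame(bead_i = f[1], bead_j = f[2], bead_k = f[3],
               theta_eq = as.numeric(f[5]), k_theta = as.numeric(f[6]),
               stringsAsFactors = FALSE)))
  lj <- data.frame(bead = at$name, sigma = at$sigma, epsilon = at$epsilon,
                   stringsAsFactors = FALSE)
  cogito_ff(beads = beads, bonds = bonds, angles = angles, lj = lj,
            cutoff = cutoff)
}

#' Emit a molecule .itp for a TAG topology
#'
#' Writes `[moleculetype]` with `nrexcl = 1` (the one-bond nonbonded
#' exclusion rule), `[atoms]`, `[bonds]` (function type 1, harmonic) and
#' `[angles]` (function type 2, GROMOS-96 cosine), with the equilibrium
#' values and force constants taken from the parameter tables.
#'
#' @param topology A `tag_topology`.
#' @param ff A `cogito_ff`.
#' @param file Optional output path.
#' @return Character vector of lines.
#' @export
write_itp <- function(topology, ff, file = NULL) {
  bt <- topology$bead_types
  res <- substr(topology$molecule_name, 1, 5)
  bl <- lapply(seq_len(nrow(topology$bonds)), function(r) {
    p <- lookup_bond(ff, bt[topology$bonds[r, 1]], bt[topology$bonds[r, 2]])
    sprintf("%4d %4d  1  %s  %s", topology$bonds[r, 1],
            topology$bonds[r, 2], fmt_num(p$r_eq), fmt_num(p$k_b))
  })
  al <- lapply(seq_len(nrow(topology$angles)), function(r) {
    p <- lookup_angle(ff, bt[topology$angles[r, 1]], bt[topology$angles[r, 2]],
                      bt[topology$angles[r, 3]])
    sprintf("%4d %4d %4d  2  %s  %s", topology$angles[r, 1],
            topology$angles[r, 2], topology$angles[r, 3],
            fmt_num(p$theta_eq), fmt_num(p$k_theta))
  })
  out <- c(
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%-8s 1", topology$molecule_name),
    "",
    "[ atoms ]",
    ";  nr  type      resnr residue atom      cgnr  charge    mass",
    sprintf("%5d  %-9s %4d  %-6s %-9s %4d  %6.2f  %8.3f",
            seq_along(bt), bt, 1L, res, bt, seq_along(bt),
            topology$charges, topology$masses),
    "",
    "[ bonds ]",
    ";   i    j  funct  r_eq  k_b",
    unlist(bl),
    "",
    "[ angles ]",
    ";   i    j    k  funct  theta_eq  k_theta",
    unlist(al)
  )
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Parse a molecule .itp back into a topology
#'
#' Reconstructs bead types, charges, masses, bonds and angles from the
#' sections emitted by [write_itp()]. Exclusions are the bonded pairs
#' (`nrexcl = 1`).
#'
#' @param x Path or character vector of lines.
#' @return A `tag_topology` (without chain provenance fields).
#' @export
read_itp <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  s <- parse_itp_sections(lines)
  if (is.null(s$moleculetype) || is.null(s$atoms))
    stop("missing [ moleculetype ] or [ atoms ] section")
  name <- s$moleculetype[[1]][1]
  nrexcl <- as.integer(s$moleculetype[[1]][2])
  bead_types <- vapply(s$atoms, `[`, "", 2)
  charges <- vapply(s$atoms, function(f) as.numeric(f[7]), 0)
  masses <- vapply(s$atoms, function(f) as.numeric(f[8]), 0)
  bonds <- if (is.null(s$bonds)) matrix(integer(0), ncol = 2) else
    do.call(rbind, lapply(s$bonds, function(f) as.integer(f[1:2])))
  angles <- if (is.null(s$angles)) matrix(integer(0), ncol = 3) else
    do.call(rbind, lapply(s$angles, function(f) as.integer(f[1:3])))
  structure(list(
    molecule_name = name,
    bead_types = bead_types,
    charges = charges,
    masses = masses,
    bonds = bonds,
    angles = angles,
    exclusions = bonds,
    sn_positions = NULL,
    chains = NULL,
    nrexcl = nrexcl
  ), class = "tag_topology")
}

#' Emit a system-level .top file
#'
#' Includes `[defaults]` (LJ with Lorentz-Berthelot combination rule 2),
#' the force-field parameter sections, one molecule block per species and
#' the `[system]`/`[molecules]` sections with counts in insertion order.
#'
#' @param molecules List of `list(topology =, count =)` entries.
#' @param ff A `cogito_ff`.
#' @param system_name Name for the `[system]` section.
#' @param file Optional output path.
#' @return Character vector of lines.
#' @export
write_top <- function(molecules, ff, system_name = "CG TAG system",
                      file = NULL) {
  if (length(molecules) == 0)
    stop("empty system: at least one molecule species is required")
  out <- c("[ defaults ]",
           "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
           "1  2  yes  1.0  1.0",
           "",
           write_ff_itp(ff))
  for (m in molecules)
    out <- c(out, "", write_itp(m$topology, ff))
  out <- c(out, "",
           "[ system ]", system_name, "",
           "[ molecules ]",
           "; name  count",
           vapply(molecules, function(m)
             sprintf("%-8s %d", m$topology$molecule_name, m$count), ""))
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}
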