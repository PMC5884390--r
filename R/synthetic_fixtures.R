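# Generation of small, fully valid synthetic crystal structures with known
# geometry and controlled B-factor structure, plus the brute-force contact
# oracle that supplies their ground truth. The generator writes standard PDB
# records (CRYST1 + ATOM/HETATM) so that every pipeline stage can be tested
# without any download; it makes no attempt to mimic realistic protein
# geometry -- only the coordinate, occupancy, altloc, element and B-factor
# structure that the method actually consumes.

fmt_atom_name <- function(name) {
  # names of up to 3 characters start in column 14 (column 13 blank)
  ifelse(nchar(name) <= 3, sprintf(" %-3s", name), sprintf("%-4s", name))
}

pdb_atom_line <- function(record, serial, name, alt, resn, chain, resno,
                          x, y, z, occ, b, element) {
  sprintf("%-6s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, fmt_atom_name(name), alt, resn, chain, resno,
          x, y, z, occ, b, element)
}

pdb_cryst1 <- function(cell_par, space_group) {
  sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
          cell_par[1], cell_par[2], cell_par[3],
          cell_par[4], cell_par[5], cell_par[6], space_group, 1L)
}

#' Brute-force neighbour enumeration (validation oracle)
#'
#' Enumerates every symmetry image of every atom over an explicit lattice
#' block (by default shifts of -2..2 in each dimension, a 5x5x5 block) with
#' no wrapping and no spatial indexing, and keeps the images within
#' `radius` of any input atom. This is deliberately independent of the
#' production geometry path ([expand_to_unit_cell()] + [build_assembly()] +
#' [trim_to_radius()]), which it is used to validate.
#'
#' @param atoms Data frame with `x`, `y`, `z`, `file_order`.
#' @param cell A [unit_cell()].
#' @param operators List of symmetry operators; default resolved from the
#'   cell's space group.
#' @param radius Contact radius in Angstrom.
#' @param shift_range Integer lattice shifts to enumerate per dimension.
#' @return Data frame with `source`, `x`, `y`, `z` for every retained image
#'   (duplicate images of one source atom within 1e-3 Angstrom removed).
#' @export
brute_force_neighbor_set <- function(atoms, cell, operators = NULL,
                                     radius = 7.0, shift_range = -2:2) {
  if (is.null(operators)) operators <- resolve_operators(cell)
  au <- as.matrix(atoms[, c("x", "y", "z")])
  frac <- t(cell$frac %*% t(au))
  shifts <- as.matrix(expand.grid(shift_range, shift_range, shift_range))
  keep <- list()
  for (k in seq_along(operators)) {
    op <- operators[[k]]
    f0 <- t(op$rot %*% t(frac) + op$trans)
    for (s in seq_len(nrow(shifts))) {
      f <- sweep(f0, 2, shifts[s, ], "+")
      xyz <- t(cell$orth %*% t(f))
      d <- min_dist_to_set(xyz, au)
      sel <- d <= radius
      if (any(sel))
        keep[[length(keep) + 1L]] <- data.frame(
          source = atoms$file_order[sel],
          x = xyz[sel, 1], y = xyz[sel, 2], z = xyz[sel, 3])
    }
  }
  out <- do.call(rbind, keep)
  if (is.null(out)) return(data.frame(source = integer(0), x = numeric(0),
                                      y = numeric(0), z = numeric(0)))
  key <- paste(out$source, round(out$x, 3), round(out$y, 3), round(out$z, 3))
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Brute-force packing densities (validation oracle)
#'
#' Counts, for each query atom, the brute-force neighbour images within
#' `radius`, excluding the atom's own zero-distance image.
#'
#' @param atoms Query atoms (data frame with `x`, `y`, `z`, `file_order`).
#' @param neighbor_atoms Atoms seeding the enumeration (non-hydrogen set).
#' @inheritParams brute_force_neighbor_set
#' @return Integer vector of contact counts.
#' @export
brute_force_packing_density <- function(atoms, neighbor_atoms, cell,
                                        operators = NULL, radius = 7.0,
                                        shift_range = -2:2) {
  ns <- brute_force_neighbor_set(neighbor_atoms, cell, operators, radius,
                                 shift_range)
  np <- as.matrix(ns[, c("x", "y", "z")])
  vapply(seq_len(nrow(atoms)), function(i) {
    p <- as.numeric(atoms[i, c("x", "y", "z")])
    d2 <- (np[, 1] - p[1])^2 + (np[, 2] - p[2])^2 + (np[, 3] - p[3])^2
    within <- d2 <= radius^2 + 1e-9
    self <- ns$source == atoms$file_order[i] & d2 < 1e-6
    as.integer(sum(within & !self))
  }, integer(1))
}

#' Generate a synthetic crystal-structure fixture
#'
#' Writes a conformant PDB file (CRYST1 + ATOM/HETATM records) with
#' controlled coordinates, occupancies, alternate conformers, hydrogens,
#' waters and B factors, together with a ground-truth table. The same
#' specification and seed always produce byte-identical output.
#'
#' Protein atoms are laid down as alanine residues (atom names cycling
#' N/CA/C/O/CB, five per residue, chain A) at the requested coordinates;
#' chemically sensible geometry is deliberately not attempted. B factors
#' follow `b_rule`:
#' \describe{
#'   \item{`constant`}{every atom gets `b_base`.}
#'   \item{`lognormal`}{log-normal around `b_base` with `sdlog = 0.3`.}
#'   \item{`pd_correlated`}{`b_base + slope * (max(pd) - pd) + noise`,
#'     emulating the positive mobility--packing relationship: buried
#'     (high-contact) atoms get low B. The true packing densities come
#'     from the brute-force oracle and are recorded in the ground truth.}
#' }
#' Atoms listed in `spike_atoms` then have their B multiplied by
#' `spike_multiplier`, emulating site-specific damage.
#'
#' @param n_atoms Number of protein heavy atoms.
#' @param cell Cell parameters `c(a, b, c, alpha, beta, gamma)`.
#' @param space_group Hermann--Mauguin symbol (must be resolvable by
#'   [resolve_operators()]).
#' @param coords `"random"` (uniform in the cell interior), `"cluster"`
#'   (Gaussian blob at the cell centre, giving a packing-density gradient),
#'   or an explicit `n_atoms` x 3 matrix of orthogonal coordinates.
#' @param b_rule B-factor rule (see Details).
#' @param b_base,slope,noise_sd Parameters of the B-factor rules.
#' @param spike_atoms Indices (into the protein heavy atoms) whose B is
#'   multiplied by `spike_multiplier`.
#' @param spike_multiplier Damage multiplier (> 1 for damage emulation).
#' @param glu_fraction Fraction of residues written as glutamate (atom
#'   names N/CA/C/OE1/OE2), providing side-chain carboxyl oxygens for the
#'   B_net subset; default 0 (all alanine).
#' @param altloc_residues Number of residues to duplicate as A/B alternate
#'   conformers of their CB atom (occupancies 0.6/0.4).
#' @param n_hydrogens Number of hydrogen atoms to attach.
#' @param n_waters Number of HOH water oxygens (HETATM).
#' @param seed Integer seed; fully determines the output.
#' @param path Output PDB path.
#' @return List with `path`, `lines` (the PDB text) and `truth`: one row
#'   per coordinate record with the generating values, flags
#'   (`is_hydrogen`, `is_water`, `alt_loc`, `spiked`, `expected_analysed`,
#'   `expected_neighbor`) and, for the expected analysed atoms, the
#'   oracle packing density `true_pd`.
#' @export
generate_fixture <- function(n_atoms = 50,
                             cell = c(40, 40, 40, 90, 90, 90),
                             space_group = "P 1",
                             coords = "random",
                             b_rule = c("constant", "lognormal", "pd_correlated"),
                             b_base = 20, slope = 0.15, noise_sd = 0.4,
                             spike_atoms = integer(0), spike_multiplier = 2.0,
                             glu_fraction = 0, altloc_residues = 0L,
                             n_hydrogens = 0L,
                             n_waters = 0L, seed = 1L,
                             path = tempfile(fileext = ".pdb")) {
  b_rule <- match.arg(b_rule)
  if (length(spike_atoms) && (any(spike_atoms < 1) || any(spike_atoms > n_atoms)))
    stop("spike_atoms indices out of range 1..", n_atoms)
  set.seed(seed)
  ucell <- unit_cell(cell[1], cell[2], cell[3], cell[4], cell[5], cell[6],
                     space_group)
  ops <- resolve_operators(ucell)

  if (is.matrix(coords)) {
    stopifnot(nrow(coords) == n_atoms, ncol(coords) == 3)
    xyz <- coords
  } else if (coords == "random") {
    f <- matrix(stats::runif(3 * n_atoms, 0.08, 0.92), ncol = 3)
    xyz <- t(ucell$orth %*% t(f))
  } else if (coords == "cluster") {
    f <- matrix(stats::rnorm(3 * n_atoms, 0.5, 0.12), ncol = 3)
    f <- pmin(pmax(f, 0.08), 0.92)
    xyz <- t(ucell$orth %*% t(f))
  } else stop("unknown coordinate rule: ", coords)

  resno <- (seq_len(n_atoms) - 1L) %/% 5L + 1L
  n_res <- max(resno)
  res_names <- rep("ALA", n_res)
  if (glu_fraction > 0 && n_res >= 1) {
    n_glu <- max(1L, floor(glu_fraction * n_res))
    res_names[round(seq(1, n_res, length.out = n_glu))] <- "GLU"
  }
  # per-position name within the residue's 5-atom cycle
  pos <- ((seq_len(n_atoms) - 1L) %% 5L) + 1L
  ala_cycle <- c("N", "CA", "C", "O", "CB")
  glu_cycle <- c("N", "CA", "C", "OE1", "OE2")
  atom_names <- ifelse(res_names[resno] == "GLU", glu_cycle[pos], ala_cycle[pos])
  elements <- substr(atom_names, 1, 1)

  # water oxygens participate in the neighbour set but not the analysis set
  if (n_waters > 0) {
    fw <- matrix(stats::runif(3 * n_waters, 0.08, 0.92), ncol = 3)
    wxyz <- t(ucell$orth %*% t(fw))
  } else wxyz <- matrix(numeric(0), ncol = 3)

  # ground-truth packing densities over the full heavy-atom neighbour set
  heavy <- data.frame(x = c(xyz[, 1], wxyz[, 1]),
                      y = c(xyz[, 2], wxyz[, 2]),
                      z = c(xyz[, 3], wxyz[, 3]),
                      file_order = seq_len(n_atoms + n_waters) - 1L)
  true_pd_all <- brute_force_packing_density(heavy, heavy, ucell, ops)
  true_pd <- true_pd_all[seq_len(n_atoms)]

  b <- switch(b_rule,
    constant = rep(b_base, n_atoms),
    lognormal = stats::rlnorm(n_atoms, log(b_base), 0.3),
    pd_correlated = b_base + slope * (max(true_pd) - true_pd) +
      stats::rnorm(n_atoms, 0, noise_sd))
  b <- pmax(b, 1)
  spiked <- seq_len(n_atoms) %in% spike_atoms
  b[spiked] <- b[spiked] * spike_multiplier

  rec <- data.frame(record = "ATOM", name = atom_names, alt = "",
                    resn = res_names[resno], chain = "A", resno = resno,
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    occ = 1.0, b = b, element = elements,
                    is_hydrogen = FALSE, is_water = FALSE,
                    spiked = spiked, expected_analysed = TRUE,
                    expected_neighbor = TRUE,
                    true_pd = true_pd, stringsAsFactors = FALSE)

  # alternate conformers: duplicate the CB of the first altloc_residues
  # residues as A (occ 0.60, kept) and B (occ 0.40, discarded by selection)
  if (altloc_residues > 0) {
    cb_rows <- which(rec$name == "CB")
    cb_rows <- utils::head(cb_rows, altloc_residues)
    for (r in cb_rows) {
      rec$alt[r] <- "A"; rec$occ[r] <- 0.60
      dup <- rec[r, ]
      dup$alt <- "B"; dup$occ <- 0.40
      dup$x <- dup$x + 0.8   # offset conformer
      dup$expected_analysed <- FALSE
      dup$expected_neighbor <- FALSE
      dup$true_pd <- NA_integer_
      rec <- rbind(rec, dup)
    }
  }

  if (n_hydrogens > 0) {
    parents <- sample.int(n_atoms, n_hydrogens, replace = TRUE)
    hrec <- rec[parents, ]
    hrec$name <- paste0("H", seq_len(n_hydrogens) %% 10)
    hrec$alt <- ""; hrec$occ <- 1.0
    hrec$element <- "H"
    hrec$x <- hrec$x + 0.5
    hrec$is_hydrogen <- TRUE
    hrec$spiked <- FALSE
    hrec$expected_analysed <- FALSE
    hrec$expected_neighbor <- FALSE
    hrec$true_pd <- NA_integer_
    rec <- rbind(rec, hrec)
  }

  if (n_waters > 0) {
    wrec <- data.frame(record = "HETATM", name = "O", alt = "",
                       resn = "HOH", chain = "W",
                       resno = seq_len(n_waters),
                       x = wxyz[, 1], y = wxyz[, 2], z = wxyz[, 3],
                       occ = 1.0, b = b_base, element = "O",
                       is_hydrogen = FALSE, is_water = TRUE,
                       spiked = FALSE, expected_analysed = FALSE,
                       expected_neighbor = TRUE,
                       true_pd = NA_integer_, stringsAsFactors = FALSE)
    rec <- rbind(rec, wrec)
  }

  rec$serial <- seq_len(nrow(rec))
  lines <- c(pdb_cryst1(cell, space_group),
             pdb_atom_line(rec$record, rec$serial, rec$name, rec$alt,
                           rec$resn, rec$chain, rec$resno,
                           rec$x, rec$y, rec$z, rec$occ, rec$b, rec$element),
             "END")
  writeLines(lines, path)
  list(path = path, lines = lines, truth = rec)
}

#' Generate a damage-detection benchmark fixture
#'
#' A P 1 structure with a packing-density gradient (clustered coordinates)
#' and B factors positively coupled to mobility (low packing density ->
#' high B), in which `k_damaged` randomly chosen atoms have their B factor
#' inflated by `multiplier` relative to peers at matched packing density --
#' the signature the B_Damage metric is designed to recover.
#'
#' @param n Number of protein heavy atoms.
#' @param k_damaged Number of damage-spiked atoms (`k_damaged < n`).
#' @param multiplier B-factor inflation factor (> 1).
#' @param seed Integer seed.
#' @param cell_edge Cubic cell edge in Angstrom.
#' @param path Output PDB path.
#' @return As [generate_fixture()], plus `spiked_file_order`: the
#'   `file_order` values (0-based) of the damaged atoms, i.e. the expected
#'   top-`k_damaged` B_Damage set.
#' @export
generate_damage_benchmark <- function(n = 500, k_damaged = 10,
                                      multiplier = 2.0, seed = 1L,
                                      cell_edge = 60,
                                      path = tempfile(fileext = ".pdb")) {
  stopifnot(k_damaged < n, multiplier >= 1)
  set.seed(seed)
  spike <- if (k_damaged > 0) sort(sample.int(n, k_damaged)) else integer(0)
  fx <- generate_fixture(
    n_atoms = n, cell = c(cell_edge, cell_edge, cell_edge, 90, 90, 90),
    space_group = "P 1", coords = "cluster", b_rule = "pd_correlated",
    b_base = 8, slope = 0.15, noise_sd = 0.4,
    spike_atoms = spike, spike_multiplier = multiplier,
    glu_fraction = 0.2, seed = seed + 1L, path = path)
  fx$spiked_file_order <- fx$truth$serial[fx$truth$spiked] - 1L
  fx
}
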