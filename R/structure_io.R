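# Reading and writing coordinate files, and the atom-selection rules that
# define the analysed and neighbour-eligible atom sets.

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")
# modified residues deposited as HETATM but treated as protein
.modified_aa <- c("MSE")

#' Read a protein crystal structure from a PDB or mmCIF file
#'
#' Parses the coordinate records (via \pkg{bio3d}) together with the
#' crystallographic cell and symmetry information (CRYST1 and REMARK 290
#' SMTRY records for PDB; `_cell`, `_symmetry`/`_space_group` and
#' symmetry-equivalence items for mmCIF). Only the first model of a
#' multi-model file is read, with a warning. Blank element fields are
#' inferred from the atom-name columns.
#'
#' @param file Path to a PDB or mmCIF file.
#' @param format `"auto"` (by file extension), `"pdb"` or `"cif"`.
#' @return An object of class `"bdam_structure"`: a list with
#'   \describe{
#'     \item{atoms}{data frame of coordinate records: `record` (ATOM/HETATM),
#'       `serial`, `atom_name`, `alt_loc`, `residue_name`, `chain`,
#'       `residue_number`, `insert`, `x`, `y`, `z`, `occupancy`, `b_factor`,
#'       `element`, `file_order` (0-based file position).}
#'     \item{cell}{a [unit_cell()] object, or `NULL` when the file carries
#'       no crystal description (an error for the damage pipeline).}
#'     \item{symmetry_ops}{explicit symmetry operators from the file, if any.}
#'     \item{source_id}{the input path (or accession).}
#'     \item{format}{`"pdb"` or `"cif"`.}
#'   }
#' @export
read_structure <- function(file, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(file)) stop("file not found: ", file)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  lines <- readLines(file, warn = FALSE)
  if (format == "pdb") parse_pdb(lines, file) else parse_cif(lines, file)
}

#' @export
print.bdam_structure <- function(x, ...) {
  cat(sprintf("Crystal structure '%s' (%s): %d coordinate records\n",
              x$source_id, x$format, nrow(x$atoms)))
  if (!is.null(x$cell)) print(x$cell) else cat("No crystal symmetry\n")
  invisible(x)
}

parse_pdb <- function(lines, file) {
  # honour MODEL/ENDMDL: keep the first model only
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) > 1) {
    warning("multi-model file: only the first model is read")
    endm <- grep("^ENDMDL", lines)
    first_end <- endm[endm > model_starts[1]][1]
    keep <- !(seq_along(lines) > first_end & grepl("^(ATOM  |HETATM)", lines))
    lines <- lines[keep]
  }

  coord_idx <- grep("^(ATOM  |HETATM)", lines)
  if (length(coord_idx) == 0) stop("no ATOM/HETATM records in ", file)

  # validate numeric fields before handing to bio3d, so failures name lines
  for (i in coord_idx) {
    ln <- lines[i]
    nums <- suppressWarnings(as.numeric(c(
      substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54),
      substr(ln, 55, 60), substr(ln, 61, 66))))
    if (anyNA(nums))
      stop("cannot parse coordinate record at line ", i, " of ", file)
  }

  cryst <- grep("^CRYST1", lines, value = TRUE)
  if (length(cryst) == 0)
    stop("no crystal symmetry: missing CRYST1 record in ", file)
  cp <- suppressWarnings(as.numeric(c(
    substr(cryst[1], 7, 15), substr(cryst[1], 16, 24), substr(cryst[1], 25, 33),
    substr(cryst[1], 34, 40), substr(cryst[1], 41, 47), substr(cryst[1], 48, 54))))
  if (anyNA(cp))
    stop("no crystal symmetry: garbled CRYST1 record in ", file)
  sg <- trimws(substr(cryst[1], 56, 66))

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, rm.insert = FALSE, verbose = FALSE)

  atoms <- atoms_from_bio3d(pdb$atom)
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6], space_group = sg)
  ops <- parse_remark290(lines, cell)
  new_structure(atoms, cell, ops, file, "pdb")
}

# REMARK 290 SMTRY operators act on orthogonal coordinates (translations in
# Angstrom); convert to the fractional convention used throughout:
#   R_frac = F R_orth M,  t_frac = F t_orth.
parse_remark290 <- function(lines, cell) {
  sm <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(sm) == 0) return(NULL)
  rows <- lapply(sm, function(ln) {
    f <- strsplit(trimws(substr(ln, 12, nchar(ln))), "[[:space:]]+")[[1]]
    # SMTRYn  opnum  r1 r2 r3 t
    list(axis = as.integer(substr(f[1], 6, 6)), n = as.integer(f[2]),
         r = as.numeric(f[3:5]), t = as.numeric(f[6]))
  })
  nops <- max(vapply(rows, function(r) r$n, integer(1)))
  ops <- vector("list", nops)
  for (k in seq_len(nops)) {
    rot <- matrix(0, 3, 3); trans <- numeric(3)
    for (r in rows) if (r$n == k) { rot[r$axis, ] <- r$r; trans[r$axis] <- r$t }
    rf <- cell$frac %*% rot %*% cell$orth
    tf <- as.vector(cell$frac %*% trans)
    ops[[k]] <- symop_from_matrix(snap_rational(rf), snap_rational(tf))
  }
  ops
}

# snap near-rational matrix entries (multiples of 1/12) produced by the
# orthogonal->fractional conversion back to exact values
snap_rational <- function(x, tol = 1e-4) {
  snapped <- round(x * 12) / 12
  x[abs(x - snapped) < tol] <- snapped[abs(x - snapped) < tol]
  x
}

cif_unquote <- function(x) gsub("^['\"]|['\"]$", "", x)

parse_cif <- function(lines, file) {
  tmp <- tempfile(fileext = ".cif")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.cif(tmp, rm.alt = FALSE, rm.insert = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("cannot parse mmCIF coordinate records in ",
                             file, ": ", conditionMessage(e)))
  atoms <- atoms_from_bio3d(pdb$atom)
  if (any(pdb$atom$type == "ATOM" | pdb$atom$type == "HETATM") &&
      nrow(atoms) == 0) stop("no ATOM/HETATM records in ", file)

  kv <- function(tag) {
    hit <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (length(hit) == 0) return(NA_character_)
    cif_unquote(trimws(sub(paste0("^", tag, "[[:space:]]+"), "", hit[1])))
  }
  cp <- suppressWarnings(as.numeric(c(
    kv("_cell\\.length_a"), kv("_cell\\.length_b"), kv("_cell\\.length_c"),
    kv("_cell\\.angle_alpha"), kv("_cell\\.angle_beta"), kv("_cell\\.angle_gamma"))))
  sg <- kv("_symmetry\\.space_group_name_H-M")
  if (is.na(sg)) sg <- kv("_space_group\\.name_H-M_alt")
  if (is.na(sg)) sg <- kv("_space_group\\.name_H-M")
  if (anyNA(cp))
    stop("no crystal symmetry: missing or garbled _cell items in ", file)
  if (is.na(sg)) sg <- "P 1"

  ops <- parse_cif_symops(lines)
  cell <- unit_cell(cp[1], cp[2], cp[3], cp[4], cp[5], cp[6], space_group = sg)
  new_structure(atoms, cell, ops, file, "cif")
}

# symmetry-equivalence xyz loop (either legacy or current tag family)
parse_cif_symops <- function(lines) {
  tag <- grep("^_(symmetry_equiv\\.pos_as_xyz|symmetry_equiv_pos_as_xyz|space_group_symop\\.operation_xyz)",
              lines)
  if (length(tag) == 0) return(NULL)
  # values may be inline or follow in the loop body
  vals <- character(0)
  i <- tag[1]
  inline <- trimws(sub("^_[^[:space:]]+", "", lines[i]))
  if (nzchar(inline)) vals <- inline
  j <- i + 1
  while (j <= length(lines)) {
    ln <- trimws(lines[j])
    if (!nzchar(ln) || startsWith(ln, "_") || startsWith(ln, "loop_") ||
        startsWith(ln, "#") || startsWith(ln, "data_")) break
    # take the last whitespace-separated field that looks like a triplet
    m <- regmatches(ln, regexpr("['\"]?[-0-9xyzXYZ/+, ]*[xyzXYZ][-0-9xyzXYZ/+, ]*['\"]?$", ln))
    if (length(m) == 1 && grepl(",", m)) vals <- c(vals, m)
    j <- j + 1
  }
  vals <- cif_unquote(vals)
  vals <- vals[nzchar(vals)]
  if (length(vals) == 0) return(NULL)
  lapply(vals, parse_symop)
}

atoms_from_bio3d <- function(at) {
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  if (any(blank))
    element[blank] <- infer_element(at$elety[blank])
  data.frame(
    record = at$type,
    serial = as.integer(at$eleno),
    atom_name = trimws(at$elety),
    alt_loc = ifelse(is.na(at$alt), "", at$alt),
    residue_name = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    residue_number = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occupancy = at$o, b_factor = at$b,
    element = toupper(trimws(element)),
    file_order = seq_len(nrow(at)) - 1L,
    stringsAsFactors = FALSE)
}

# Element from the atom-name columns per PDB v3.3: two-character elements
# occupy column 13; names starting in column 14 are one-character elements.
# Digits and primes are stripped; a leading digit (e.g. "1HB2") means H.
infer_element <- function(atom_name) {
  vapply(atom_name, function(nm) {
    nm0 <- gsub("['\"]", "", nm)
    if (grepl("^[0-9]", trimws(nm0))) return("H")
    nm1 <- gsub("[0-9]", "", trimws(nm0))
    if (!nzchar(nm1)) return("X")
    two <- toupper(substr(nm1, 1, 2))
    if (two %in% c("FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE",
                   "CA", "NI", "CO", "CD", "HG")
        && nchar(trimws(nm)) >= 4) return(two)  # 4-char names start col 13
    toupper(substr(nm1, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

new_structure <- function(atoms, cell, ops, source_id, format) {
  stopifnot(nrow(atoms) >= 1)
  structure(list(atoms = atoms, cell = cell, symmetry_ops = ops,
                 source_id = source_id, format = format),
            class = "bdam_structure")
}

# For each residue carrying alternate conformers, keep the conformer label
# with the highest occupancy (ties: the label appearing earliest in the
# file); atoms without an altloc label are always kept.
collapse_altloc <- function(atoms) {
  has_alt <- nzchar(atoms$alt_loc)
  if (!any(has_alt)) return(atoms)
  res_key <- paste(atoms$chain, atoms$residue_number, atoms$insert,
                   atoms$residue_name)
  keep <- rep(TRUE, nrow(atoms))
  for (rk in unique(res_key[has_alt])) {
    rows <- which(res_key == rk & has_alt)
    labs <- atoms$alt_loc[rows]
    occ_by_lab <- tapply(atoms$occupancy[rows], labs, max)
    first_by_lab <- tapply(atoms$file_order[rows], labs, min)
    best <- max(occ_by_lab)
    cand <- names(occ_by_lab)[occ_by_lab == best]
    winner <- cand[which.min(first_by_lab[cand])]
    keep[rows[labs != winner]] <- FALSE
  }
  atoms[keep, , drop = FALSE]
}

#' Select the atoms analysed for damage
#'
#' Applies the analysis-selection rules: hydrogens are removed; for each
#' residue with alternate conformers only the highest-occupancy conformer is
#' retained (ties broken by file order); by default only protein atoms are
#' analysed (`ATOM` records of the 20 standard amino acids, plus
#' selenomethionine `MSE`). The configuration can widen the selection to
#' HETATM records or additional residue names, or narrow it by residue name,
#' chain, or atom serial number. Because B_Damage compares B factors between
#' atoms, widening beyond protein atoms is rarely appropriate.
#'
#' @param model A `bdam_structure`.
#' @param config A [bdam_config()]; its `selection` entry controls
#'   widening/narrowing.
#' @return Data frame of analysed atoms, in original file order.
#' @export
select_analysis_atoms <- function(model, config = bdam_config()) {
  at <- model$atoms
  # occupancy-refinement guidance: non-altloc atoms should have occupancy 1
  odd <- !nzchar(at$alt_loc) & is.finite(at$occupancy) & at$occupancy < 1
  if (any(odd))
    warning(sum(odd), " non-alternate-conformer atom(s) have occupancy < 1; ",
            "B factors of occupancy-refined atoms are not comparable")
  at <- at[at$element != "H" & at$element != "D", , drop = FALSE]
  at <- collapse_altloc(at)

  sel <- config$selection
  protein <- .standard_aa
  if (length(sel$add_residues)) protein <- c(protein, toupper(sel$add_residues))
  keep <- (at$record == "ATOM" & at$residue_name %in% protein) |
          (at$residue_name %in% c(.modified_aa, toupper(sel$add_residues)))
  if (isTRUE(sel$include_hetatm)) keep <- keep | at$record == "HETATM"
  if (length(sel$exclude_residues))
    keep <- keep & !(at$residue_name %in% toupper(sel$exclude_residues))
  if (length(sel$exclude_chains))
    keep <- keep & !(at$chain %in% sel$exclude_chains)
  if (length(sel$exclude_serials))
    keep <- keep & !(at$serial %in% sel$exclude_serials)
  out <- at[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("no atoms of interest after selection filtering")
  rownames(out) <- NULL
  out
}

#' Select the neighbour-eligible atoms
#'
#' Returns all non-hydrogen atoms (protein, nucleic acid, heteroatoms and
#' waters alike) with the same single-conformer collapse as
#' [select_analysis_atoms()]. This set seeds the symmetry expansion: packing
#' density counts contacts to every non-hydrogen atom, whether or not it is
#' itself analysed.
#'
#' @param model A `bdam_structure`.
#' @return Data frame of neighbour-eligible atoms, in original file order.
#' @export
select_neighbor_atoms <- function(model) {
  at <- model$atoms[model$atoms$element != "H" & model$atoms$element != "D", ,
                    drop = FALSE]
  at <- collapse_altloc(at)
  rownames(at) <- NULL
  at
}

#' Write coordinate files coloured by B_Damage
#'
#' Writes (1) a PDB file containing only the analysed atoms, with the
#' B-factor column (columns 61--66, `%6.2f`) replaced by `ln(B_Damage)` --
#' suitable for uniform colouring in molecular-graphics software -- and
#' (2) an mmCIF file reproducing the analysed `atom_site` rows with a
#' `B_Damage` column appended.
#'
#' @param model A `bdam_structure`.
#' @param table Damage table from [compute_bdamage()], one row per analysed
#'   atom.
#' @param out_dir Output directory (created if needed).
#' @param prefix File-name prefix; defaults to the structure id.
#' @return Character vector of the two paths written (`pdb`, `cif`).
#' @export
write_bdam_files <- function(model, table, out_dir, prefix = NULL) {
  if (any(!is.finite(table$b_damage) | table$b_damage <= 0))
    stop("non-positive B_Damage value: cannot take logarithm")
  if (is.null(prefix)) prefix <- structure_label(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  at <- model$atoms[match(table$file_order, model$atoms$file_order), ,
                    drop = FALSE]
  pdb_path <- file.path(out_dir, paste0(prefix, "_bdamage.pdb"))
  bio3d::write.pdb(file = pdb_path, type = at$record, eleno = at$serial,
                   elety = at$atom_name, resid = at$residue_name,
                   chain = at$chain, resno = at$residue_number,
                   insert = ifelse(nzchar(at$insert), at$insert, NA),
                   alt = ifelse(nzchar(at$alt_loc), at$alt_loc, NA),
                   xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   o = at$occupancy, b = log(table$b_damage),
                   elesy = at$element)
  # prepend the crystal description so the output stands alone
  if (!is.null(model$cell)) {
    body <- readLines(pdb_path, warn = FALSE)
    writeLines(c(pdb_cryst1(c(model$cell$a, model$cell$b, model$cell$c,
                              model$cell$alpha, model$cell$beta,
                              model$cell$gamma),
                            model$cell$space_group),
                 body), pdb_path)
  }
  cif_path <- file.path(out_dir, paste0(prefix, "_bdamage.cif"))
  write_bdam_cif(model, at, table, cif_path)
  c(pdb = pdb_path, cif = cif_path)
}

write_bdam_cif <- function(model, at, table, path) {
  hdr <- c(sprintf("data_%s", gsub("[^A-Za-z0-9]", "_", structure_label(model))),
           "#",
           sprintf("_cell.length_a    %.3f", model$cell$a),
           sprintf("_cell.length_b    %.3f", model$cell$b),
           sprintf("_cell.length_c    %.3f", model$cell$c),
           sprintf("_cell.angle_alpha %.2f", model$cell$alpha),
           sprintf("_cell.angle_beta  %.2f", model$cell$beta),
           sprintf("_cell.angle_gamma %.2f", model$cell$gamma),
           sprintf("_symmetry.space_group_name_H-M '%s'", model$cell$space_group),
           "#", "loop_",
           paste0("_atom_site.",
                  c("group_PDB", "id", "type_symbol", "label_atom_id",
                    "label_alt_id", "label_comp_id", "label_asym_id",
                    "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
                    "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
                    "B_iso_or_equiv", "auth_seq_id", "auth_comp_id",
                    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num",
                    "B_Damage")))
  alt <- ifelse(nzchar(at$alt_loc), at$alt_loc, ".")
  chn <- ifelse(nzchar(at$chain), at$chain, ".")
  ins <- ifelse(nzchar(at$insert), at$insert, "?")
  rows <- sprintf(
    "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f %d %s %s %s 1 %.6f",
    at$record, at$serial, at$element, at$atom_name, alt, at$residue_name,
    chn, at$residue_number, ins, at$x, at$y, at$z, at$occupancy,
    at$b_factor, at$residue_number, at$residue_name, chn, at$atom_name,
    table$b_damage)
  writeLines(c(hdr, rows, "#"), path)
  path
}

#' Write the per-atom results table as CSV
#'
#' One row per analysed atom: the input record properties plus the computed
#' packing density and B_Damage (and rank, when present).
#'
#' @inheritParams write_bdam_files
#' @return Path of the CSV written.
#' @export
write_atom_csv <- function(model, table, out_dir, prefix = NULL) {
  if (is.null(prefix)) prefix <- structure_label(model)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  at <- model$atoms[match(table$file_order, model$atoms$file_order), ,
                    drop = FALSE]
  df <- data.frame(serial = at$serial, record = at$record,
                   atom_name = at$atom_name, alt_loc = at$alt_loc,
                   residue_name = at$residue_name, chain = at$chain,
                   residue_number = at$residue_number,
                   x = at$x, y = at$y, z = at$z,
                   occupancy = at$occupancy, b_factor = at$b_factor,
                   packing_density = table$packing_density,
                   b_damage = table$b_damage)
  if (!is.null(table$rank)) df$rank <- table$rank
  path <- file.path(out_dir, paste0(prefix, "_bdamage.csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

structure_label <- function(model) {
  id <- model$source_id
  base <- tools::file_path_sans_ext(basename(id))
  if (!nzchar(base)) base <- "structure"
  base
}

#' Check an accession against a full-isotropic-B accession list
#'
#' Structures refined with TLS groups often deposit residual rather than
#' full isotropic B factors, which invalidates B-factor comparison between
#' atoms. Given a user-supplied list of accession codes known to carry full
#' isotropic B factors (one per line), this flags accessions absent from the
#' list. With no list configured the check is skipped.
#'
#' @param accession 4-character PDB accession code.
#' @param list_path Optional path to a plain-text accession list.
#' @return `TRUE` if the accession is on the list (or no list is configured);
#'   `FALSE`, with a warning, otherwise.
#' @export
check_full_b_factor_list <- function(accession, list_path = NULL) {
  if (is.null(list_path)) {
    message("full-isotropic-B accession check skipped: no list configured")
    return(TRUE)
  }
  codes <- tryCatch(toupper(trimws(readLines(list_path, warn = FALSE))),
                    error = function(e) NULL)
  if (is.null(codes)) {
    warning("cannot read accession list '", list_path, "'; check skipped")
    return(TRUE)
  }
  ok <- toupper(accession) %in% codes
  if (!ok)
    warning("accession ", accession, " is not on the full-isotropic-B list; ",
            "its B-factor field may hold residual B factors")
  ok
}
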