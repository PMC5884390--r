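# Shared fixture builders and comparison utilities. All fixtures are built
# in code at test time; nothing is read from disk besides what the tests
# themselves write to tempdir().

# a syntactically minimal PDB: cubic P 1 cell + supplied coordinate lines
minimal_pdb <- function(atom_lines,
                        cryst = "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1") {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(cryst, atom_lines, "END"), path)
  path
}

pdb_line <- function(record = "ATOM", serial = 1, name = "CA", alt = "",
                     resn = "ALA", chain = "A", resno = 1,
                     x = 1, y = 2, z = 3, occ = 1, b = 20, element = "C") {
  nm <- if (nchar(name) <= 3) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("%-6s%5d %s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, resn, chain, resno, x, y, z, occ, b, element)
}

# the same single-atom structure as mmCIF text
minimal_cif <- function(x = 1, y = 2, z = 3, occ = 1, b = 20) {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a 10.000", "_cell.length_b 10.000", "_cell.length_c 10.000",
    "_cell.angle_alpha 90.00", "_cell.angle_beta 90.00", "_cell.angle_gamma 90.00",
    "_symmetry.space_group_name_H-M 'P 1'",
    "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
             "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
             "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
             "auth_atom_id", "pdbx_PDB_model_num")),
    sprintf("ATOM 1 C CA . ALA A 1 1 ? %.3f %.3f %.3f %.2f %.2f 1 ALA A CA 1",
            x, y, z, occ, b)), path)
  path
}

# canonical multiset key of a neighbour set: one sorted string per image
neighbor_key <- function(ns) {
  sort(paste(ns$source, sprintf("%.3f %.3f %.3f", ns$x, ns$y, ns$z)))
}

# run geometry + contact counting for a structure file, returning both the
# production result and the brute-force oracle result
pd_both_routes <- function(path, radius = 7.0) {
  s <- read_structure(path)
  analysed <- suppressWarnings(select_analysis_atoms(s))
  neigh <- select_neighbor_atoms(s)
  ops <- resolve_operators(s)
  prod_ns <- build_neighbor_set(s, radius = radius)
  prod_pd <- packing_density(analysed, prod_ns, radius = radius)
  oracle_ns <- brute_force_neighbor_set(neigh, s$cell, ops, radius = radius)
  oracle_pd <- brute_force_packing_density(analysed, neigh, s$cell, ops,
                                           radius = radius)
  list(structure = s, analysed = analysed,
       prod_ns = prod_ns, prod_pd = prod_pd,
       oracle_ns = oracle_ns, oracle_pd = oracle_pd)
}
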