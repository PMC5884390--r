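test_that("a minimal PDB and its mmCIF equivalent parse to identical fields", {
  p <- minimal_pdb(pdb_line(x = 1, y = 2, z = 3, occ = 1, b = 20))
  s <- read_structure(p)
  expect_s3_class(s, "bdam_structure")
  expect_equal(nrow(s$atoms), 1)
  a <- s$atoms[1, ]
  expect_equal(a$record, "ATOM")
  expect_equal(a$atom_name, "CA")
  expect_equal(a$residue_name, "ALA")
  expect_equal(c(a$x, a$y, a$z), c(1, 2, 3))
  expect_equal(a$b_factor, 20)
  expect_equal(a$occupancy, 1)
  expect_equal(a$element, "C")
  expect_equal(a$file_order, 0L)
  expect_equal(c(s$cell$a, s$cell$b, s$cell$c), c(10, 10, 10))
  expect_equal(s$cell$space_group, "P 1")

  s2 <- read_structure(minimal_cif(x = 1, y = 2, z = 3, occ = 1, b = 20))
  for (f in c("record", "atom_name", "residue_name", "x", "y", "z",
              "occupancy", "b_factor", "element", "file_order"))
    expect_equal(s2$atoms[[f]], s$atoms[[f]], info = f)
  expect_equal(c(s2$cell$a, s2$cell$alpha), c(10, 90))
})

test_that("fixture round trip preserves count, order and coordinates at PDB precision", {
  fx <- generate_fixture(n_atoms = 50, b_rule = "lognormal", seed = 11)
  s <- read_structure(fx$path)
  expect_equal(nrow(s$atoms), 50)
  expect_equal(s$atoms$serial, fx$truth$serial)
  expect_equal(s$atoms$x, round(fx$truth$x, 3), tolerance = 1e-9)
  expect_equal(s$atoms$y, round(fx$truth$y, 3), tolerance = 1e-9)
  expect_equal(s$atoms$z, round(fx$truth$z, 3), tolerance = 1e-9)
  expect_equal(s$atoms$b_factor, round(fx$truth$b, 2), tolerance = 1e-9)
  expect_true(all(diff(s$atoms$file_order) == 1))
})

test_that("parse errors are informative", {
  # no CRYST1
  p1 <- tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(), "END"), p1)
  expect_error(read_structure(p1), "no crystal symmetry")
  # garbled coordinate line: error names the line number
  bad <- pdb_line()
  substr(bad, 33, 38) <- "xxxxxx"
  p2 <- minimal_pdb(c(pdb_line(), bad))
  expect_error(read_structure(p2), "line 3")
  # no atoms
  p3 <- tempfile(fileext = ".pdb")
  writeLines(c("CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1",
               "END"), p3)
  expect_error(read_structure(p3), "no ATOM/HETATM")
})

test_that("analysis selection removes hydrogens, waters and lower-occupancy conformers", {
  # residue with A/B conformers on OG: highest occupancy wins
  p <- minimal_pdb(c(
    pdb_line(serial = 1, name = "CA", resn = "SER", resno = 10),
    pdb_line(serial = 2, name = "OG", alt = "A", resn = "SER", resno = 10,
             x = 2, occ = 0.60, element = "O"),
    pdb_line(serial = 3, name = "OG", alt = "B", resn = "SER", resno = 10,
             x = 2.5, occ = 0.40, element = "O")))
  sel <- suppressWarnings(select_analysis_atoms(read_structure(p)))
  expect_equal(sel$serial, c(1, 2))
  expect_equal(sel$alt_loc[2], "A")

  # 3 protein + 2 H + 1 water -> 3 analysed, 4 neighbour-eligible
  p2 <- minimal_pdb(c(
    pdb_line(serial = 1, name = "N", element = "N"),
    pdb_line(serial = 2, name = "CA", x = 2),
    pdb_line(serial = 3, name = "C", x = 3),
    pdb_line(serial = 4, name = "H", x = 4, element = "H"),
    pdb_line(serial = 5, name = "HA", x = 5, element = "H"),
    pdb_line(record = "HETATM", serial = 6, name = "O", resn = "HOH",
             resno = 2, x = 6, element = "O")))
  s2 <- read_structure(p2)
  expect_equal(nrow(select_analysis_atoms(s2)), 3)
  expect_equal(nrow(select_neighbor_atoms(s2)), 4)

  # analysed set is a subset of the neighbour set under defaults
  fx <- generate_fixture(n_atoms = 60, seed = 5, n_hydrogens = 10,
                         n_waters = 6, altloc_residues = 3)
  s3 <- read_structure(fx$path)
  an <- suppressWarnings(select_analysis_atoms(s3))
  ne <- select_neighbor_atoms(s3)
  expect_true(all(an$file_order %in% ne$file_order))
  expect_equal(nrow(an), sum(fx$truth$expected_analysed))
  expect_equal(nrow(ne), sum(fx$truth$expected_neighbor))
  # analysed + excluded = total coordinate records
  expect_equal(nrow(an) + (nrow(s3$atoms) - nrow(an)), nrow(s3$atoms))
})

test_that("selection honours widening and narrowing rules", {
  p <- minimal_pdb(c(
    pdb_line(serial = 1, name = "CA"),
    pdb_line(record = "HETATM", serial = 2, name = "SE", resn = "MSE",
             resno = 2, x = 4, element = "SE"),
    pdb_line(record = "HETATM", serial = 3, name = "O", resn = "HOH",
             resno = 3, x = 6, element = "O")))
  s <- read_structure(p)
  # MSE treated as protein by default; waters excluded
  expect_equal(select_analysis_atoms(s)$serial, c(1, 2))
  # widen to HETATM
  cfg <- bdam_config(selection = list(include_hetatm = TRUE))
  expect_equal(select_analysis_atoms(s, cfg)$serial, c(1, 2, 3))
  # narrow by serial
  cfg2 <- bdam_config(selection = list(exclude_serials = 1))
  expect_equal(select_analysis_atoms(s, cfg2)$serial, 2)
  # empty selection is an error
  cfg3 <- bdam_config(selection = list(exclude_residues = c("ALA", "MSE")))
  expect_error(select_analysis_atoms(s, cfg3), "no atoms of interest")
})

test_that("damage-coloured PDB output has exact ln(B_Damage) columns and 80-char records", {
  fx <- generate_fixture(n_atoms = 10, b_rule = "lognormal", seed = 2)
  s <- read_structure(fx$path)
  an <- select_analysis_atoms(s)
  tbl <- compute_bdamage(an, rep(1L, 10), window = 5L)
  # force known values: B_Damage 1 -> "  0.00", e -> "  1.00"
  tbl$b_damage <- c(1, exp(1), tbl$b_damage[3:10])
  out <- write_bdam_files(s, tbl, tempfile())
  lines <- readLines(out[["pdb"]])
  rec <- grep("^(ATOM  |HETATM)", lines, value = TRUE)
  expect_length(rec, 10)
  expect_true(all(nchar(rec) == 80))
  expect_equal(substr(rec[1], 61, 66), "  0.00")
  expect_equal(substr(rec[2], 61, 66), "  1.00")
  # round trip: B column equals ln(B_Damage) to 2 decimals
  reread <- read_structure(out[["pdb"]])
  expect_equal(reread$atoms$b_factor, round(log(tbl$b_damage), 2),
               tolerance = 1e-9)
  # mmCIF twin re-parses with a B_Damage column appended
  cif_lines <- readLines(out[["cif"]])
  expect_true(any(grepl("_atom_site.B_Damage", cif_lines, fixed = TRUE)))
  s_cif <- read_structure(out[["cif"]])
  expect_equal(nrow(s_cif$atoms), 10)
  # non-positive B_Damage refuses to write
  tbl$b_damage[1] <- 0
  expect_error(write_bdam_files(s, tbl, tempfile()), "non-positive")
})

test_that("atom CSV lists one row per analysed atom and round-trips values", {
  fx <- generate_fixture(n_atoms = 40, b_rule = "lognormal", seed = 3,
                         n_hydrogens = 5)
  res <- run_bdamage(fx$path, bdam_config(outputs = "csv"),
                     out_dir = tempfile())
  csv <- res$files[["csv"]]
  lines <- readLines(csv)
  expect_length(lines, nrow(res$table) + 1)   # header + one row per atom
  df <- read.csv(csv)
  expect_true(all(df$packing_density == as.integer(df$packing_density)))
  expect_equal(df$b_damage, res$table$b_damage, tolerance = 1e-6)
  expect_equal(df$packing_density, res$table$packing_density)
})

test_that("full-isotropic-B accession list check warns only for absent codes", {
  lst <- tempfile()
  writeLines(c("2BLP", "2BLZ"), lst)
  expect_true(check_full_b_factor_list("2blp", lst))
  expect_warning(ok <- check_full_b_factor_list("9XYZ", lst),
                 "not on the full-isotropic-B list")
  expect_false(ok)
  expect_message(expect_true(check_full_b_factor_list("2BLP", NULL)),
                 "skipped")
})

test_that("multi-model files are truncated to the first model with a warning", {
  p <- tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   10.000   10.000   10.000  90.00  90.00  90.00 P 1           1",
    "MODEL        1",
    pdb_line(serial = 1, x = 1),
    "ENDMDL",
    "MODEL        2",
    pdb_line(serial = 1, x = 5),
    "ENDMDL", "END"), p)
  expect_warning(s <- read_structure(p), "first model")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$x, 1)
})
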