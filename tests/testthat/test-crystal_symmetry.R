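test_that("cell transforms follow the PDB orthogonalization convention", {
  tf <- build_cell_transforms(10, 10, 10, 90, 90, 90)
  expect_equal(tf$orth, diag(c(10, 10, 10)), tolerance = 1e-12)
  expect_equal(as.vector(tf$orth %*% c(0.5, 0.5, 0.5)), c(5, 5, 5))

  # cross-checked against an independent crystallographic reference
  # implementation (gemmi 0.7.4) for a monoclinic and a triclinic cell
  mono <- build_cell_transforms(10, 12, 15, 90, 110, 90)
  expect_equal(mono$orth,
               matrix(c(10, 0, -5.130302149885,
                        0, 12, 0,
                        0, 0, 14.095389311789), 3, 3, byrow = TRUE),
               tolerance = 1e-8)
  tri <- build_cell_transforms(11.5, 13.2, 17.8, 72.3, 81.6, 95.4)
  expect_equal(tri$orth,
               matrix(c(11.5, -1.242229735804, 2.600277908411,
                        0, 13.141417932761, 5.681711891081,
                        0, 0, 16.667234467235), 3, 3, byrow = TRUE),
               tolerance = 1e-8)

  # matrices are mutual inverses
  for (tfx in list(tf, mono, tri))
    expect_equal(tfx$orth %*% tfx$frac, diag(3), tolerance = 1e-10)

  expect_error(build_cell_transforms(-1, 10, 10, 90, 90, 90), "positive")
  expect_error(build_cell_transforms(10, 10, 10, 20, 20, 170), "degenerate")
})

test_that("symmetry operators resolve with the correct group order", {
  expect_length(resolve_operators("P 1"), 1)
  expect_length(resolve_operators("P 21"), 2)
  expect_length(resolve_operators("P 1 21 1"), 2)
  expect_length(resolve_operators("C 2"), 4)
  expect_length(resolve_operators("P 21 21 21"), 4)
  expect_length(resolve_operators("P 43 21 2"), 8)
  expect_error(resolve_operators("X 99"), "supported")

  # the 2_1 screw along b: (x,y,z) -> (-x, y+1/2, -z)
  op <- resolve_operators("P 21")[[2]]
  expect_equal(as.vector(op$rot %*% c(0.1, 0.2, 0.3) + op$trans),
               c(-0.1, 0.7, -0.3))
  # every operator is a proper/improper rotation with rational translation
  for (ops in lapply(c("P 21 21 21", "P 43 21 2", "C 2"), resolve_operators))
    for (o in ops) {
      expect_true(abs(det(o$rot)) == 1)
      expect_true(all(abs(o$trans * 12 - round(o$trans * 12)) < 1e-9))
    }
})

test_that("unit-cell expansion wraps images into [0,1) and has |atoms| x |ops| size", {
  cell <- unit_cell(20, 20, 20, 90, 90, 90, "P 21")
  at <- data.frame(x = 2, y = 4, z = 6, file_order = 0L)  # frac (0.1,0.2,0.3)
  img <- expand_to_unit_cell(at, cell)
  expect_equal(nrow(img), 2)
  expect_equal(unlist(img[1, c("fx", "fy", "fz")], use.names = FALSE),
               c(0.1, 0.2, 0.3))
  expect_equal(unlist(img[2, c("fx", "fy", "fz")], use.names = FALSE),
               c(0.9, 0.7, 0.7))   # wrap of (-0.1, 0.7, -0.3)

  fx <- generate_fixture(n_atoms = 10, cell = c(25, 30, 35, 90, 90, 90),
                         space_group = "P 21 21 21", seed = 4)
  s <- read_structure(fx$path)
  img2 <- expand_to_unit_cell(s$atoms, s$cell, resolve_operators(s))
  expect_equal(nrow(img2), 40)
  expect_true(all(img2$fx >= 0 & img2$fx < 1))
})

test_that("the 3x3x3 assembly enumerates all 27 lattice translations", {
  cell <- unit_cell(10, 10, 10, 90, 90, 90, "P 1")
  at <- data.frame(x = 0, y = 0, z = 0, file_order = 0L)
  img <- expand_to_unit_cell(at, cell)
  asm <- build_assembly(img, cell)
  expect_equal(nrow(asm), 27)
  # single atom at the origin of a cubic cell: the 3x3x3 integer grid x 10
  got <- round(unname(as.matrix(asm[, c("x", "y", "z")])), 9)
  got <- got[order(got[, 1], got[, 2], got[, 3]), ]
  grid <- expand.grid(x = c(-10, 0, 10), y = c(-10, 0, 10), z = c(-10, 0, 10))
  grid <- unname(as.matrix(grid[order(grid$x, grid$y, grid$z), ]))
  expect_equal(got, grid)
  # the zero-shift copy coincides with the input image
  zero <- asm[asm$sx == 0 & asm$sy == 0 & asm$sz == 0, ]
  expect_equal(c(zero$x, zero$y, zero$z), c(0, 0, 0))

  # |assembly| = 27 x |operators| x |atoms|
  fx <- generate_fixture(n_atoms = 15, cell = c(30, 30, 30, 90, 90, 90),
                         space_group = "P 21 21 21", seed = 9)
  s <- read_structure(fx$path)
  img2 <- expand_to_unit_cell(s$atoms, s$cell, resolve_operators(s))
  expect_equal(nrow(build_assembly(img2, s$cell)), 27 * 4 * 15)
})

test_that("radius trimming keeps exactly the within-radius images", {
  # lone atom, huge P 1 cell: only its own image survives
  cell <- unit_cell(100, 100, 100, 90, 90, 90, "P 1")
  at <- data.frame(x = 50, y = 50, z = 50, file_order = 0L)
  ns <- trim_to_radius(build_assembly(expand_to_unit_cell(at, cell), cell),
                       as.matrix(at[, c("x", "y", "z")]))
  expect_equal(nrow(ns), 1)
  expect_true(ns$identity_image)

  # 10 A cell: face neighbours sit at exactly 10 A > 7, excluded
  cell2 <- unit_cell(10, 10, 10, 90, 90, 90, "P 1")
  at2 <- data.frame(x = 5, y = 5, z = 5, file_order = 0L)
  ns2 <- trim_to_radius(build_assembly(expand_to_unit_cell(at2, cell2), cell2),
                        as.matrix(at2[, c("x", "y", "z")]))
  expect_equal(nrow(ns2), 1)

  # the boundary is inclusive: an image at exactly the radius is retained
  cell3 <- unit_cell(30, 30, 30, 90, 90, 90, "P 1")
  at3 <- data.frame(x = c(5, 12), y = c(5, 5), z = c(5, 5), file_order = 0:1)
  asm3 <- build_assembly(expand_to_unit_cell(at3, cell3), cell3)
  ns3 <- trim_to_radius(asm3, as.matrix(at3[1, c("x", "y", "z")]), radius = 7)
  expect_true(any(ns3$source == 1))

  # 20-atom fixture: exact set equality with the brute-force enumeration
  fx <- generate_fixture(n_atoms = 20, cell = c(22, 26, 30, 90, 100, 90),
                         space_group = "P 21", seed = 12)
  r <- pd_both_routes(fx$path)
  expect_equal(neighbor_key(r$prod_ns), neighbor_key(r$oracle_ns))
})

test_that("packing densities are invariant to lattice shifts and rigid motions", {
  fx <- generate_fixture(n_atoms = 30, cell = c(24, 24, 24, 90, 90, 90),
                         space_group = "P 1", seed = 21)
  s <- read_structure(fx$path)
  an <- select_analysis_atoms(s)
  pd0 <- packing_density(an, build_neighbor_set(s))

  # shift every atom by an integer lattice vector
  s_shift <- s
  shift <- as.vector(s$cell$orth %*% c(1, -2, 1))
  s_shift$atoms$x <- s$atoms$x + shift[1]
  s_shift$atoms$y <- s$atoms$y + shift[2]
  s_shift$atoms$z <- s$atoms$z + shift[3]
  pd1 <- packing_density(select_analysis_atoms(s_shift),
                         build_neighbor_set(s_shift))
  expect_identical(pd0, pd1)

  # rigid motion in a large P 1 cell leaves contact counts unchanged
  fx2 <- generate_fixture(n_atoms = 30, cell = c(200, 200, 200, 90, 90, 90),
                          space_group = "P 1", coords = "cluster", seed = 22)
  s2 <- read_structure(fx2$path)
  pd2 <- packing_density(select_analysis_atoms(s2), build_neighbor_set(s2))
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(s2$atoms[, c("x", "y", "z")])
  centre <- colMeans(xyz)
  moved <- sweep(sweep(xyz, 2, centre) %*% t(rot), 2, centre + c(3, -2, 5), "+")
  s3 <- s2
  s3$atoms$x <- moved[, 1]; s3$atoms$y <- moved[, 2]; s3$atoms$z <- moved[, 3]
  pd3 <- packing_density(select_analysis_atoms(s3), build_neighbor_set(s3))
  expect_identical(pd2, pd3)
})

test_that("explicit REMARK 290 operator records take priority and match the table", {
  fx <- generate_fixture(n_atoms = 8, cell = c(20, 24, 28, 90, 90, 90),
                         space_group = "P 21 21 21", seed = 33)
  lines <- readLines(fx$path)
  smtry <- c(
    "REMARK 290   SMTRY1   1  1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   1  0.000000  1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   1  0.000000  0.000000  1.000000        0.00000",
    "REMARK 290   SMTRY1   2 -1.000000  0.000000  0.000000       10.00000",
    "REMARK 290   SMTRY2   2  0.000000 -1.000000  0.000000        0.00000",
    "REMARK 290   SMTRY3   2  0.000000  0.000000  1.000000       14.00000",
    "REMARK 290   SMTRY1   3  1.000000  0.000000  0.000000       10.00000",
    "REMARK 290   SMTRY2   3  0.000000 -1.000000  0.000000       12.00000",
    "REMARK 290   SMTRY3   3  0.000000  0.000000 -1.000000        0.00000",
    "REMARK 290   SMTRY1   4 -1.000000  0.000000  0.000000        0.00000",
    "REMARK 290   SMTRY2   4  0.000000  1.000000  0.000000       12.00000",
    "REMARK 290   SMTRY3   4  0.000000  0.000000 -1.000000       14.00000")
  p <- tempfile(fileext = ".pdb")
  writeLines(c(lines[1], smtry, lines[-1]), p)
  s <- read_structure(p)
  ops_file <- resolve_operators(s)
  ops_table <- resolve_operators("P 21 21 21")
  expect_length(ops_file, 4)
  key <- function(ops) sort(vapply(ops, function(o)
    paste(round(c(o$rot, o$trans %% 1), 6), collapse = ","), character(1)))
  expect_equal(key(ops_file), key(ops_table))
})
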