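# Crystallographic symmetry: unit-cell generation from the asymmetric unit,
# the 3x3x3 lattice assembly and trimming to the contact radius.

#' Unit-cell geometry and fractional/orthogonal transforms
#'
#' Builds the fractional-to-orthogonal ("orthogonalization") and
#' orthogonal-to-fractional ("fractionalization") matrices for a crystal
#' unit cell, following the standard PDB convention: the a axis lies along
#' Cartesian x and the b axis in the x--y plane.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; each in (0, 180).
#' @param space_group Hermann--Mauguin space-group symbol (e.g. `"P 21 21 21"`).
#' @param operators Optional list of symmetry operators (as returned by
#'   [parse_symop()]); when `NULL` they are resolved lazily from
#'   `space_group` by [resolve_operators()].
#'
#' @return An object of class `"bdam_cell"`: a list with elements `a`, `b`,
#'   `c`, `alpha`, `beta`, `gamma`, `space_group`, `operators`, `orth`
#'   (3x3 fractional-to-orthogonal matrix, Angstrom) and `frac`
#'   (its inverse).
#'
#' @examples
#' cell <- unit_cell(10, 10, 10, 90, 90, 90, "P 1")
#' cell$orth %*% c(0.5, 0.5, 0.5)   # fractional centre -> (5, 5, 5) Angstrom
#' @export
unit_cell <- function(a, b, c, alpha, beta, gamma, space_group = "P 1",
                      operators = NULL) {
  tf <- build_cell_transforms(a, b, c, alpha, beta, gamma)
  structure(list(a = a, b = b, c = c,
                 alpha = alpha, beta = beta, gamma = gamma,
                 space_group = space_group,
                 operators = operators,
                 orth = tf$orth, frac = tf$frac),
            class = "bdam_cell")
}

#' @export
print.bdam_cell <- function(x, ...) {
  cat(sprintf("Unit cell  a=%.3f b=%.3f c=%.3f  alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  cat(sprintf("Space group: %s", x$space_group))
  if (!is.null(x$operators)) cat(sprintf("  (%d operators)", length(x$operators)))
  cat("\n")
  invisible(x)
}

#' Fractional/orthogonal transformation matrices for a unit cell
#'
#' @inheritParams unit_cell
#' @return List with `orth` (fractional -> orthogonal, Angstrom) and `frac`
#'   (orthogonal -> fractional) 3x3 matrices, mutual inverses.
#' @export
build_cell_transforms <- function(a, b, c, alpha, beta, gamma) {
  if (!all(is.finite(c(a, b, c, alpha, beta, gamma))))
    stop("cell parameters must be finite numbers")
  if (any(c(a, b, c) <= 0))
    stop("cell lengths must be positive")
  if (any(c(alpha, beta, gamma) <= 0) || any(c(alpha, beta, gamma) >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  # squared reduced volume; <= 0 means the angles cannot close a cell
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 1e-12)
    stop("degenerate cell: angle combination gives non-positive volume")
  v <- sqrt(v2)
  orth <- matrix(c(a, b * cg, c * cb,
                   0, b * sg, c * (ca - cb * cg) / sg,
                   0, 0,      c * v / sg),
                 nrow = 3, byrow = TRUE)
  frac <- solve(orth)
  list(orth = orth, frac = frac)
}

#' Parse a symmetry operator given as an xyz triplet
#'
#' Converts strings such as `"-x,y+1/2,-z"` (the notation used in
#' International Tables, mmCIF `_symmetry_equiv` loops and space-group
#' references) into a rotation matrix and translation vector acting on
#' fractional coordinates.
#'
#' @param triplet Character scalar, three comma-separated coordinate
#'   expressions in x, y, z with optional rational translations.
#' @return List with `rot` (3x3 numeric) and `trans` (length-3 numeric),
#'   class `"bdam_symop"`.
#' @examples
#' op <- parse_symop("-x,y+1/2,-z")
#' op$rot %*% c(0.1, 0.2, 0.3) + op$trans   # (-0.1, 0.7, -0.3)
#' @export
parse_symop <- function(triplet) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3L)
    stop("symmetry operator must have three comma-separated components: ", triplet)
  rot <- matrix(0, 3, 3)
  trans <- numeric(3)
  for (i in seq_len(3)) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (term in terms) {
      sign <- if (startsWith(term, "-")) -1 else 1
      body <- sub("^[+-]", "", term)
      if (body %in% c("x", "y", "z")) {
        rot[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nd <- as.numeric(strsplit(body, "/")[[1]])
        trans[i] <- trans[i] + sign * nd[1] / nd[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trans[i] <- trans[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry operator term '", term, "' in: ", triplet)
      }
    }
  }
  structure(list(rot = rot, trans = trans), class = "bdam_symop")
}

symop_from_matrix <- function(rot, trans) {
  structure(list(rot = rot, trans = trans), class = "bdam_symop")
}

is_identity_op <- function(op) {
  all(abs(op$rot - diag(3)) < 1e-9) && all(abs(op$trans) < 1e-9)
}

# Embedded Hermann-Mauguin -> operator-triplet table, standard settings.
# Covers the space groups exercised by the test fixtures; deposited
# REMARK 290 / mmCIF operator records take priority over this table.
.space_group_table <- list(
  "P 1"        = c("x,y,z"),
  "P 1 2 1"    = c("x,y,z", "-x,y,-z"),
  "P 1 21 1"   = c("x,y,z", "-x,y+1/2,-z"),
  "C 1 2 1"    = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 21 21 2"  = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
  "P 43 21 2"  = c("x,y,z", "-y+1/2,x+1/2,z+3/4", "-x,-y,z+1/2",
                   "y+1/2,-x+1/2,z+1/4", "x+1/2,-y+1/2,-z+1/4", "-y,-x,-z+1/2",
                   "-x+1/2,y+1/2,-z+3/4", "y,x,-z")
)

# short monoclinic aliases used on CRYST1 records
.space_group_aliases <- c("P 2"  = "P 1 2 1",
                          "P 21" = "P 1 21 1",
                          "C 2"  = "C 1 2 1")

normalize_space_group <- function(symbol) {
  s <- toupper(trimws(gsub("[[:space:]]+", " ", symbol)))
  if (s %in% names(.space_group_aliases)) s <- .space_group_aliases[[s]]
  s
}

#' Resolve the symmetry operators of a structure
#'
#' Operators are taken, in priority order, from (1) explicit operator
#' records carried by the coordinate file (PDB `REMARK 290 SMTRY` rows or an
#' mmCIF symmetry-equivalence loop), else (2) an embedded Hermann--Mauguin
#' table of standard settings. The identity operator is always first.
#'
#' @param x A `bdam_structure`, a `bdam_cell`, or a space-group symbol.
#' @return List of `bdam_symop` operators.
#' @export
resolve_operators <- function(x) {
  if (inherits(x, "bdam_structure")) {
    if (!is.null(x$symmetry_ops) && length(x$symmetry_ops) > 0)
      return(order_identity_first(x$symmetry_ops))
    if (is.null(x$cell)) stop("no crystal symmetry available for this structure")
    x <- x$cell
  }
  if (inherits(x, "bdam_cell")) {
    if (!is.null(x$operators) && length(x$operators) > 0)
      return(order_identity_first(x$operators))
    x <- x$space_group
  }
  key <- normalize_space_group(x)
  if (!key %in% names(.space_group_table))
    stop("unknown space group '", x, "' and no explicit operator records; ",
         "supported symbols: ",
         paste(c(names(.space_group_table), names(.space_group_aliases)),
               collapse = ", "))
  lapply(.space_group_table[[key]], parse_symop)
}

order_identity_first <- function(ops) {
  idx <- which(vapply(ops, is_identity_op, logical(1)))
  if (length(idx) == 0)
    stop("operator list lacks the identity operator")
  c(ops[idx[1]], ops[-idx[1]])
}

#' Expand asymmetric-unit atoms to one unit cell
#'
#' Applies every symmetry operator to every atom and wraps the resulting
#' fractional coordinates into `[0, 1)` component-wise. Wrapping may split
#' molecules across cell boundaries; this is harmless for contact counting
#' because the subsequent +-1 lattice translations restore all images.
#'
#' @param atoms Data frame of atoms with columns `x`, `y`, `z` (orthogonal,
#'   Angstrom) and `file_order`.
#' @param cell A `bdam_cell`.
#' @param operators List of `bdam_symop`; defaults to `resolve_operators(cell)`.
#' @return Data frame with one row per (atom, operator) image: `source`
#'   (the atom's `file_order`), `op` (operator index, 1 = identity),
#'   `fx`, `fy`, `fz` (wrapped fractional coordinates).
#' @export
expand_to_unit_cell <- function(atoms, cell, operators = NULL) {
  if (is.null(operators)) operators <- resolve_operators(cell)
  frac <- t(cell$frac %*% t(as.matrix(atoms[, c("x", "y", "z")])))
  out <- vector("list", length(operators))
  for (k in seq_along(operators)) {
    op <- operators[[k]]
    f <- t(op$rot %*% t(frac) + op$trans)
    f <- f - floor(f)
    out[[k]] <- data.frame(source = atoms$file_order, op = k,
                           fx = f[, 1], fy = f[, 2], fz = f[, 3])
  }
  do.call(rbind, out)
}

#' Build the 3x3x3 lattice assembly of unit cells
#'
#' Translates the unit-cell images by every lattice shift in `{-1, 0, 1}^3`
#' (fractional space) and orthogonalises the result.
#'
#' @param images Data frame from [expand_to_unit_cell()].
#' @param cell A `bdam_cell`.
#' @return Data frame with columns `source`, `op`, `sx`, `sy`, `sz`
#'   (lattice shift) and `x`, `y`, `z` (orthogonal, Angstrom);
#'   `27 * nrow(images)` rows.
#' @export
build_assembly <- function(images, cell) {
  shifts <- unname(as.matrix(expand.grid(-1:1, -1:1, -1:1)))
  n <- nrow(images)
  fr <- as.matrix(images[, c("fx", "fy", "fz")])
  out <- vector("list", nrow(shifts))
  for (s in seq_len(nrow(shifts))) {
    f <- sweep(fr, 2, shifts[s, ], "+")
    xyz <- t(cell$orth %*% t(f))
    out[[s]] <- data.frame(source = images$source, op = images$op,
                           sx = shifts[s, 1], sy = shifts[s, 2], sz = shifts[s, 3],
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  }
  do.call(rbind, out)
}

# Minimum distance from each row of p (m x 3) to the point set q (n x 3),
# computed in chunks to bound memory.
min_dist_to_set <- function(p, q, chunk = 2000L) {
  m <- nrow(p)
  qq <- rowSums(q^2)
  res <- numeric(m)
  i <- 1L
  while (i <= m) {
    j <- min(i + chunk - 1L, m)
    pc <- p[i:j, , drop = FALSE]
    d2 <- outer(rowSums(pc^2), qq, "+") - 2 * tcrossprod(pc, q)
    res[i:j] <- sqrt(pmax(apply(d2, 1, min), 0))
    i <- j + 1L
  }
  res
}

#' Trim the lattice assembly to the contact radius of the asymmetric unit
#'
#' Retains exactly the assembly positions whose minimum distance to any
#' asymmetric-unit atom is less than or equal to `radius` (inclusive
#' boundary: a position at exactly `radius` is kept). Images of the same
#' source atom that coincide within 1e-3 Angstrom (atoms on special
#' positions) are de-duplicated to avoid double counting.
#'
#' @param assembly Data frame from [build_assembly()].
#' @param au_xyz Numeric matrix (n x 3) of asymmetric-unit atom positions
#'   (orthogonal, Angstrom).
#' @param radius Contact radius in Angstrom (default 7).
#' @return The retained subset of `assembly` rows (the neighbour set), with
#'   a logical column `identity_image` marking each source atom's own
#'   untransformed image (identity operator, zero shift).
#' @export
trim_to_radius <- function(assembly, au_xyz, radius = 7.0) {
  stopifnot(radius > 0)
  au_xyz <- as.matrix(au_xyz)
  # cheap bounding-box prefilter before exact distances
  lo <- apply(au_xyz, 2, min) - radius
  hi <- apply(au_xyz, 2, max) + radius
  inbox <- assembly$x >= lo[1] & assembly$x <= hi[1] &
           assembly$y >= lo[2] & assembly$y <= hi[2] &
           assembly$z >= lo[3] & assembly$z <= hi[3]
  cand <- assembly[inbox, , drop = FALSE]
  if (nrow(cand) > 0) {
    d <- min_dist_to_set(as.matrix(cand[, c("x", "y", "z")]), au_xyz)
    cand <- cand[d <= radius, , drop = FALSE]
  }
  if (nrow(cand) > 1) {
    key <- paste(cand$source,
                 round(cand$x, 3), round(cand$y, 3), round(cand$z, 3))
    cand <- cand[!duplicated(key), , drop = FALSE]
  }
  cand$identity_image <- cand$op == 1L &
    cand$sx == 0L & cand$sy == 0L & cand$sz == 0L
  rownames(cand) <- NULL
  cand
}

#' Build the trimmed neighbour set of a structure
#'
#' Convenience wrapper running the full geometry stage: symmetry expansion
#' of the non-hydrogen neighbour atoms to the unit cell, the 3x3x3 lattice
#' assembly, and trimming to the contact radius.
#'
#' @param model A `bdam_structure`.
#' @param radius Contact radius in Angstrom (default 7).
#' @return As [trim_to_radius()].
#' @export
build_neighbor_set <- function(model, radius = 7.0) {
  if (is.null(model$cell))
    stop("no crystal symmetry: structure lacks cell parameters")
  neigh <- select_neighbor_atoms(model)
  ops <- resolve_operators(model)
  cell <- model$cell
  # Deposited asymmetric units need not sit inside the home unit cell, but
  # the 3x3x3 assembly is built around it. Canonicalise by the integer
  # lattice translation that brings the AU centroid into [0,1)^3 -- a rigid
  # motion of the whole crystal -- and shift the result back afterwards.
  fr <- t(cell$frac %*% t(as.matrix(neigh[, c("x", "y", "z")])))
  lat <- floor(colMeans(fr))
  shift_orth <- as.vector(cell$orth %*% lat)
  work <- neigh
  work$x <- work$x - shift_orth[1]
  work$y <- work$y - shift_orth[2]
  work$z <- work$z - shift_orth[3]
  images <- expand_to_unit_cell(work, cell, ops)
  assembly <- build_assembly(images, cell)
  ns <- trim_to_radius(assembly, as.matrix(work[, c("x", "y", "z")]), radius)
  ns$x <- ns$x + shift_orth[1]
  ns$y <- ns$y + shift_orth[2]
  ns$z <- ns$z + shift_orth[3]
  ns
}
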