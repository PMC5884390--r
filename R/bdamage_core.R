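# Per-atom packing densities and the B_Damage metric.
#
# B_Damage of atom j is B_j divided by the mean B factor of the atoms that
# occupy a similar packing-density environment, where packing density is the
# atomic contact number: non-hydrogen atoms (own crystallographic images
# included, self excluded) within a fixed radius, by default 7 Angstrom.

#' Packing density (atomic contact number) of the analysed atoms
#'
#' Counts, for each analysed atom, the neighbour-set positions within the
#' contact radius. The atom's own untransformed image is excluded;
#' symmetry- and lattice-related images of the same atom do count, so an
#' atom near a crystal contact sees its own symmetry mates.
#'
#' @param atoms Data frame of analysed atoms (needs `x`, `y`, `z`,
#'   `file_order`).
#' @param neighbors Trimmed neighbour set from [build_neighbor_set()] /
#'   [trim_to_radius()].
#' @param radius Contact radius in Angstrom; must equal the radius used to
#'   trim the neighbour set.
#' @return Integer vector of contact counts, one per analysed atom.
#' @export
packing_density <- function(atoms, neighbors, radius = 7.0) {
  n <- nrow(atoms)
  counts <- integer(n)
  if (nrow(neighbors) == 0) return(counts)
  np <- as.matrix(neighbors[, c("x", "y", "z")])
  nsrc <- neighbors$source
  chunk <- max(1L, floor(2e6 / max(1, nrow(neighbors))))
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    p <- as.matrix(atoms[i:j, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(p^2), rowSums(np^2), "+") - 2 * tcrossprod(p, np)
    within <- d2 <= radius^2 + 1e-9
    # exclude each atom's own zero-distance image (same source atom)
    self <- outer(atoms$file_order[i:j], nsrc, "==") & d2 < 1e-6
    counts[i:j] <- as.integer(rowSums(within & !self))
    i <- j + 1L
  }
  counts
}

#' Resolve the sliding-window size
#'
#' The window defaults to 2% of the number of analysed atoms, rounded to
#' the nearest integer, made odd (incremented when even), raised to the
#' minimum size, and finally clamped to the largest odd value not exceeding
#' the atom count.
#'
#' @param n_atoms Number of analysed atoms (>= 1).
#' @param fraction Window fraction of the atom count, in (0, 1]; default 0.02.
#' @param minimum Minimum window size (odd); default 11.
#' @return Odd integer window size.
#' @examples
#' resolve_window(1000)        # 21
#' resolve_window(100)         # 11 (minimum)
#' resolve_window(7)           # 7  (clamped to the structure size)
#' @export
resolve_window <- function(n_atoms, fraction = 0.02, minimum = 11L) {
  stopifnot(n_atoms >= 1, fraction > 0, fraction <= 1, minimum >= 1)
  w <- floor(fraction * n_atoms + 0.5)   # round half up, platform-stable
  if (w %% 2 == 0) w <- w + 1
  w <- max(w, minimum)
  if (w > n_atoms) w <- if (n_atoms %% 2 == 1) n_atoms else n_atoms - 1L
  as.integer(max(w, 1L))
}

#' Compute B_Damage for the analysed atoms
#'
#' Atoms are ordered by ascending packing density (stable tie-break on file
#' order). Each atom is normalised by the mean B factor of a contiguous
#' window of `window` atoms centred on it in this ordering; at the two ends
#' of the ordering the window is shifted inward (clamped) so that every atom
#' is normalised by exactly `window` peers.
#'
#' @param atoms Data frame of analysed atoms with columns `file_order` and
#'   `b_factor`.
#' @param pd Integer vector of packing densities, parallel to `atoms`.
#' @param window Odd window size from [resolve_window()].
#' @return The damage table: a data frame in the original atom order with
#'   columns `file_order`, `packing_density`, `b_factor`, `window_mean_b`,
#'   `b_damage` and `rank` (1 = highest B_Damage; ties get the average of
#'   the ranks they span).
#' @export
compute_bdamage <- function(atoms, pd, window = resolve_window(nrow(atoms))) {
  n <- nrow(atoms)
  stopifnot(length(pd) == n, window >= 1, window <= n, window %% 2 == 1)
  ord <- order(pd, atoms$file_order)
  b <- atoms$b_factor[ord]
  half <- (window - 1L) %/% 2L
  centre <- seq_len(n)
  start <- pmin(pmax(centre - half, 1L), n - window + 1L)
  # windowed means via a cumulative sum over the sorted B factors
  cs <- c(0, cumsum(b))
  wmean <- (cs[start + window] - cs[start]) / window
  if (any(wmean == 0))
    stop("degenerate B factors: a packing-density window has mean B of zero")
  bdam_sorted <- b / wmean
  out <- data.frame(file_order = atoms$file_order,
                    packing_density = as.integer(pd),
                    b_factor = atoms$b_factor,
                    window_mean_b = NA_real_,
                    b_damage = NA_real_)
  out$window_mean_b[ord] <- wmean
  out$b_damage[ord] <- bdam_sorted
  rank_bdamage(out)
}

#' Rank atoms by B_Damage
#'
#' Rank 1 is the largest B_Damage value; tied values receive the average of
#' the ranks they span, so ranks always sum to `N(N+1)/2`.
#'
#' @param table Damage table from [compute_bdamage()].
#' @return The table with its `rank` column (re)filled.
#' @export
rank_bdamage <- function(table) {
  table$rank <- rank(-table$b_damage, ties.method = "average")
  table
}
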