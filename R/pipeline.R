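# End-to-end damage analysis for one structure.

#' Analyse one crystal structure for specific radiation damage
#'
#' Runs the full pipeline on a single structure: parse the coordinate file,
#' select the analysed and neighbour-eligible atoms, expand the asymmetric
#' unit through the crystal symmetry to the trimmed 3x3x3 assembly, count
#' packing densities, compute B_Damage and ranks, and (optionally) write
#' the selected output files.
#'
#' @param input A `bdam_structure`, or a path to a PDB/mmCIF file.
#' @param config A [bdam_config()] controlling radius, window, atom
#'   selection and output classes.
#' @param out_dir Output directory for written files; `NULL` computes the
#'   results without writing anything.
#' @param prompt Consent hook for `overwrite = "ask"`: a function
#'   `(path) -> logical`. `NULL` consents silently in non-interactive use.
#' @return Object of class `"bdam_result"`: list with `structure`, `table`
#'   (the damage table: `file_order`, `packing_density`, `b_factor`,
#'   `window_mean_b`, `b_damage`, `rank`), `window`, `kde`, `bnet`,
#'   `parameters`, `out_dir` and `files` (paths written).
#' @examples
#' fx <- generate_fixture(n_atoms = 60, seed = 7)
#' res <- run_bdamage(fx$path)
#' head(res$table)
#' @export
run_bdamage <- function(input, config = bdam_config(), out_dir = NULL,
                        prompt = NULL) {
  model <- if (inherits(input, "bdam_structure")) input
           else read_structure(input)
  if (is.null(model$cell))
    stop("no crystal symmetry: structure lacks cell parameters")

  analysed <- select_analysis_atoms(model, config)
  neighbors <- build_neighbor_set(model, radius = config$pd_radius)
  pd <- packing_density(analysed, neighbors, radius = config$pd_radius)
  window <- resolve_window(nrow(analysed), config$window_fraction,
                           config$window_minimum)
  table <- compute_bdamage(analysed, pd, window)

  parameters <- list(source = model$source_id,
                     n_analysed = nrow(analysed),
                     pd_radius = config$pd_radius,
                     window_fraction = config$window_fraction,
                     window = window,
                     outputs = config$outputs)

  result <- structure(list(structure = model, table = table, window = window,
                           kde = NULL, bnet = NULL, parameters = parameters,
                           out_dir = out_dir, files = character(0)),
                      class = "bdam_result")

  writing <- !is.null(out_dir)
  if (writing) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    guard <- overwrite_guard(config, prompt)
    label <- structure_label(model)
  }

  if ("kde" %in% config$outputs || "summary" %in% config$outputs) {
    hl <- NULL
    if (length(config$highlight_atoms)) {
      at <- model$atoms[match(table$file_order, model$atoms$file_order), ]
      idx <- match(config$highlight_atoms, at$serial)
      ok <- !is.na(idx)
      if (any(ok)) hl <- stats::setNames(table$b_damage[idx[ok]],
                                         config$highlight_atoms[ok])
    }
    kde_png <- if (writing && "kde" %in% config$outputs)
      guard(file.path(out_dir, paste0(structure_label(model), "_kde.png")))
    else NULL
    result$kde <- kde_bdamage(table$b_damage, highlight = hl,
                              plot_file = kde_png)
    if (!is.null(kde_png)) result$files <- c(result$files, kde = kde_png)
  }

  if ("bnet" %in% config$outputs || "summary" %in% config$outputs) {
    bnet_png <- if (writing && "bnet" %in% config$outputs)
      guard(file.path(out_dir, paste0(structure_label(model), "_bnet_kde.png")))
    else NULL
    result$bnet <- withCallingHandlers(
      compute_bnet(table, model, plot_file = bnet_png),
      warning = function(w) {
        message("note: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    if (writing && "bnet" %in% config$outputs && !is.na(result$bnet$value)) {
      bnet_txt <- guard(file.path(out_dir,
                                  paste0(structure_label(model), "_bnet.csv")))
      utils::write.csv(data.frame(metric = "B_net",
                                  value = result$bnet$value,
                                  subset_size = result$bnet$subset_size,
                                  subset_rule = result$bnet$subset_rule),
                       bnet_txt, row.names = FALSE)
      result$files <- c(result$files, bnet = bnet_txt)
      if (!is.null(bnet_png)) result$files <- c(result$files, bnet_kde = bnet_png)
    }
  }

  if (writing && "bdam" %in% config$outputs) {
    guard(file.path(out_dir, paste0(label, "_bdamage.pdb")))
    guard(file.path(out_dir, paste0(label, "_bdamage.cif")))
    paths <- write_bdam_files(model, table, out_dir)
    result$files <- c(result$files, paths)
  }
  if (writing && "csv" %in% config$outputs) {
    guard(file.path(out_dir, paste0(label, "_bdamage.csv")))
    csv <- write_atom_csv(model, table, out_dir)
    result$files <- c(result$files, csv = csv)
  }
  if (writing && "summary" %in% config$outputs) {
    guard(file.path(out_dir, paste0(label, "_summary.html")))
    html <- write_summary(result, out_dir)
    result$files <- c(result$files, summary = html)
  }
  result
}

# honour the overwrite policy: returns the path, erroring when an existing
# file may not be replaced
overwrite_guard <- function(config, prompt) {
  function(path) {
    if (file.exists(path) && config$overwrite == "ask") {
      consent <- if (is.null(prompt)) !interactive() else isTRUE(prompt(path))
      if (!consent)
        stop("refusing to overwrite existing file: ", path)
    }
    path
  }
}

#' @export
print.bdam_result <- function(x, ...) {
  cat(sprintf("B_Damage analysis of '%s'\n", structure_label(x$structure)))
  cat(sprintf("  %d atoms analysed; window %d; packing density %d-%d contacts\n",
              nrow(x$table), x$window,
              min(x$table$packing_density), max(x$table$packing_density)))
  cat(sprintf("  B_Damage: mean %.4f, max %.4f\n",
              mean(x$table$b_damage), max(x$table$b_damage)))
  if (!is.null(x$bnet) && !is.na(x$bnet$value))
    cat(sprintf("  B_net = %.4f (n = %d %s)\n", x$bnet$value,
                x$bnet$subset_size, x$bnet$subset_rule))
  top <- x$table[order(x$table$rank), ]
  at <- x$structure$atoms[match(utils::head(top$file_order, 5),
                                x$structure$atoms$file_order), ]
  cat("  top atoms: ",
      paste(sprintf("%s%d:%s (%.3f)", at$residue_name, at$residue_number,
                    at$atom_name, utils::head(top$b_damage, 5)),
            collapse = ", "), "\n")
  invisible(x)
}
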