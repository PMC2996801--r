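#' Coarse-grained structure objects
#'
#' A `cg_structure` holds one node per residue (its C-alpha position) plus, at
#' the end of the node list, one node per included metal ion. It is the common
#' input to [build_topology()], [gnm()], [anm()] and [unfold()].
#'
#' @param labels data frame with columns `chain`, `resno`, `resname` (one row
#'   per node). An optional `insert` column carries PDB insertion codes.
#' @param xyz numeric matrix, one row per node, columns x/y/z in Angstrom.
#' @param is_metal logical, one entry per node. Metal nodes must all come
#'   after all protein nodes.
#' @param model integer; index of the coordinate model the positions came
#'   from (1 for single-model sources and generated structures).
#'
#' @return An object of class `cg_structure`.
#' @seealso [read_structure()], [make_chain()]
#' @export
cg_structure <- function(labels, xyz, is_metal, model = 1L) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  n <- nrow(xyz)
  if (n < 2L) {
    stop("a coarse-grained structure needs at least 2 nodes, got ", n)
  }
  if (ncol(xyz) != 3L) stop("'xyz' must have 3 columns")
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  if (nrow(labels) != n || length(is_metal) != n) {
    stop("'labels', 'xyz' and 'is_metal' must describe the same number of nodes")
  }
  is_metal <- as.logical(is_metal)
  if (any(is_metal) && !all(diff(is_metal) >= 0L)) {
    stop("metal nodes must be appended after all protein nodes")
  }
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(labels = labels, xyz = xyz, is_metal = is_metal,
         model = as.integer(model)),
    class = "cg_structure"
  )
}

#' @export
print.cg_structure <- function(x, ...) {
  n <- nrow(x$xyz)
  nm <- sum(x$is_metal)
  cat(sprintf("Coarse-grained structure: %d nodes (%d residues + %d metal), model %d\n",
              n, n - nm, nm, x$model))
  if (nm > 0L) {
    m <- which(x$is_metal)
    cat("  metal nodes:",
        paste(sprintf("%s%d (%s)", x$labels$chain[m], x$labels$resno[m],
                      x$labels$resname[m]), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.cg_structure <- function(x, ...) {
  data.frame(
    index = seq_len(nrow(x$xyz)),
    x$labels,
    x = x$xyz[, 1], y = x$xyz[, 2], z = x$xyz[, 3],
    is_metal = x$is_metal,
    stringsAsFactors = FALSE
  )
}

#' Number of nodes in a coarse-grained structure
#' @param x a `cg_structure`.
#' @return Integer node count (residues plus metals).
#' @export
n_nodes <- function(x) {
  stopifnot(inherits(x, "cg_structure"))
  nrow(x$xyz)
}

#' Write a structure summary as TSV
#'
#' One row per node: index, chain, residue number, residue name, coordinates
#' and the metal flag. Floats are written with 6 significant digits.
#'
#' @param x a `cg_structure`.
#' @param file output path.
#' @return The path, invisibly.
#' @export
write_structure_tsv <- function(x, file) {
  df <- as.data.frame(x)
  for (col in c("x", "y", "z")) df[[col]] <- fmt_num(df[[col]])
  write_tsv_raw(df, file)
  invisible(file)
}

#' Write a coarse-grained structure as PDB text
#'
#' Protein nodes are written as ATOM records holding a single CA atom per
#' residue; metal nodes as HETATM records. The output is a valid single-model
#' PDB file that round-trips through [read_structure()].
#'
#' @param x a `cg_structure`, or a list of `cg_structure` objects sharing
#'   node labels, written as consecutive MODEL blocks (an NMR-style ensemble).
#' @param file output path.
#' @param bfactors optional numeric vector of per-protein-node B-factors to
#'   place in the B column (default 0).
#' @return The path, invisibly.
#' @export
write_pdb <- function(x, file, bfactors = NULL) {
  models <- if (inherits(x, "cg_structure")) list(x) else x
  stopifnot(all(vapply(models, inherits, logical(1), "cg_structure")))
  multi <- length(models) > 1L
  con <- file(file, open = "wt")
  on.exit(close(con))
  for (m in seq_along(models)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    writeLines(pdb_record_lines(models[[m]], bfactors), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

pdb_record_lines <- function(x, bfactors = NULL) {
  n <- nrow(x$xyz)
  b <- rep(0, n)
  if (!is.null(bfactors)) {
    bp <- unclass_bfactors(bfactors)
    np <- sum(!x$is_metal)
    if (length(bp) != np) {
      stop("'bfactors' must have one value per protein node (", np, ")")
    }
    b[!x$is_metal] <- bp
  }
  lines <- character(n)
  for (i in seq_len(n)) {
    metal <- x$is_metal[i]
    record <- if (metal) "HETATM" else "ATOM  "
    name <- if (metal) sprintf("%-4s", toupper(x$labels$resname[i])) else " CA "
    elem <- if (metal) toupper(x$labels$resname[i]) else "C"
    lines[i] <- sprintf(
      "%s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      record, i, name, substr(x$labels$resname[i], 1, 3), x$labels$chain[i],
      x$labels$resno[i], x$xyz[i, 1], x$xyz[i, 2], x$xyz[i, 3], 1.00, b[i],
      substr(elem, 1, 2))
  }
  lines
}

unclass_bfactors <- function(b) {
  if (inherits(b, "experimental_bfactors")) b$values else as.numeric(b)
}
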