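#' Read a PDB file or PDB text into a coarse-grained structure
#'
#' One node is created per residue that has a C-alpha atom, in chain/sequence
#' order, followed by one node per HETATM whose element symbol is in
#' `metals` (in file order). Waters are never included. Alternate locations
#' are resolved to the blank or 'A' conformer (first occurrence); residues
#' with insertion codes are kept as distinct nodes.
#'
#' @param pdb path to a PDB file, or PDB-format text (a single string with
#'   newlines, or a character vector of lines).
#' @param model 1-based index of the coordinate model to use (NMR ensembles
#'   have several). An out-of-range request is an error naming the available
#'   models.
#' @param metals character vector of element symbols whose HETATMs become
#'   metal nodes (default `"ZN"`).
#' @return A [cg_structure()].
#' @details A residue that has ATOM records but no C-alpha is an error (no
#'   silent skipping). Parsing is delegated to \pkg{bio3d}'s PDB reader; the
#'   node selection and ordering rules above are applied on top.
#' @examples
#' s <- toy_zinc_finger()
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(s, f)
#' read_structure(f)
#' @export
read_structure <- function(pdb, model = 1L, metals = "ZN") {
  parsed <- parse_pdb_input(pdb)
  model <- as.integer(model)
  nm <- nrow(parsed$xyz_models)
  if (model < 1L || model > nm) {
    stop("model ", model, " not present; available models: 1..", nm)
  }
  atom <- parsed$atom

  # blank/'A' altloc only, first occurrence of any remaining duplicates
  alt <- atom$alt
  keep_alt <- is.na(alt) | alt == "" | alt == "A"
  atom <- atom[keep_alt, , drop = FALSE]

  ins <- atom$insert
  ins[is.na(ins)] <- ""
  res_id <- paste(atom$chain, atom$resno, ins, sep = "|")

  is_atom_rec <- atom$type == "ATOM"
  is_water <- toupper(atom$resid) %in% c("HOH", "WAT", "DOD")

  # protein nodes: residues among ATOM records, each must have a CA
  prot_rows <- which(is_atom_rec & !is_water)
  ca_rows <- prot_rows[atom$elety[prot_rows] == "CA"]
  if (length(prot_rows)) {
    res_all <- unique(res_id[prot_rows])
    res_ca <- unique(res_id[ca_rows])
    missing_ca <- setdiff(res_all, res_ca)
    if (length(missing_ca)) {
      stop("residue(s) without a C-alpha atom: ",
           paste(gsub("\\|", " ", missing_ca), collapse = ", "))
    }
  }
  ca_rows <- ca_rows[!duplicated(res_id[ca_rows])]
  ord <- order(atom$chain[ca_rows], atom$resno[ca_rows], ins[ca_rows])
  ca_rows <- ca_rows[ord]

  # metal nodes: HETATMs whose element matches, in file order
  elem <- toupper(trimws(ifelse(is.na(atom$elesy) | atom$elesy == "",
                                atom$resid, atom$elesy)))
  met_rows <- which(!is_atom_rec & !is_water & elem %in% toupper(metals))
  met_rows <- met_rows[!duplicated(res_id[met_rows])]

  rows <- c(ca_rows, met_rows)
  if (length(rows) < 2L) {
    stop("fewer than 2 nodes found (", length(rows), "); not a usable structure")
  }
  xyz_row <- parsed$xyz_models[model, ]
  idx <- parsed$atom_index[rows]          # index into xyz triplets
  coords <- cbind(xyz_row[3 * idx - 2], xyz_row[3 * idx - 1], xyz_row[3 * idx])

  labels <- data.frame(
    chain = atom$chain[rows],
    resno = atom$resno[rows],
    resname = trimws(atom$resid[rows]),
    insert = ins[rows],
    stringsAsFactors = FALSE
  )
  cg_structure(labels, coords,
               is_metal = rep(c(FALSE, TRUE), c(length(ca_rows), length(met_rows))),
               model = model)
}

#' Extract experimental B-factors from a PDB file
#'
#' Returns one B-factor per protein node (C-alpha), in the node order of
#' [read_structure()]. If the deposited B-factor column carries real
#' information (it is not constant across C-alphas) it is used directly
#' (`source = "pdb_column"`). NMR depositions typically have a constant
#' column; in that case the fluctuation surrogate is the ensemble spread:
#' every model is least-squares superposed onto model 1 over all C-alphas,
#' and `B_i = (8*pi^2/3) * var_i`, where `var_i` is the positional variance
#' of node i across models (sum of the three coordinate variances,
#' denominator `n_models - 1`); `source = "nmr_ensemble_rmsf"`.
#'
#' @inheritParams read_structure
#' @return An object of class `experimental_bfactors`: list with `values`
#'   (Angstrom^2, one per protein node) and `source`.
#' @details A single-model file with a constant B column carries no
#'   fluctuation information and is an error. An ensemble of identical models
#'   yields all-zero values with a warning (not an error), so pipelines can
#'   proceed and fail later, explicitly, at the fit stage.
#' @export
read_experimental_bfactors <- function(pdb, metals = "ZN") {
  parsed <- parse_pdb_input(pdb)
  s1 <- read_structure(pdb, model = 1L, metals = metals)
  prot <- !s1$is_metal
  np <- sum(prot)

  # recover the atom-table rows of the protein nodes to read the B column
  b <- node_bfactor_column(parsed, s1)
  if (length(unique(b)) > 1L) {
    return(new_experimental_bfactors(b, "pdb_column"))
  }

  nm <- nrow(parsed$xyz_models)
  if (nm < 2L) {
    stop("no fluctuation information: single-model file with a constant ",
         "B-factor column")
  }
  # ensemble surrogate: superpose models onto model 1 over all C-alphas
  ca_xyz <- matrix(NA_real_, nm, 3 * np)
  for (m in seq_len(nm)) {
    sm <- read_structure(pdb, model = m, metals = metals)
    ca_xyz[m, ] <- as.vector(t(sm$xyz[prot, , drop = FALSE]))
  }
  ref <- matrix(ca_xyz[1, ], ncol = 3, byrow = TRUE)
  fitted <- lapply(seq_len(nm), function(m) {
    kabsch_superpose(matrix(ca_xyz[m, ], ncol = 3, byrow = TRUE), ref)
  })
  msf <- vapply(seq_len(np), function(i) {
    P <- do.call(rbind, lapply(fitted, function(m) m[i, ]))
    sum(apply(P, 2, stats::var))
  }, numeric(1))
  values <- (8 * pi^2 / 3) * msf
  if (all(values == 0)) {
    warning("all models are identical after superposition; ",
            "ensemble B-factor surrogate is zero everywhere")
  }
  new_experimental_bfactors(values, "nmr_ensemble_rmsf")
}

new_experimental_bfactors <- function(values, source) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("B-factors must be nonnegative")
  structure(list(values = values, source = source),
            class = "experimental_bfactors")
}

#' @export
print.experimental_bfactors <- function(x, ...) {
  cat(sprintf("Experimental B-factors: %d residues, source = %s\n",
              length(x$values), x$source))
  cat(sprintf("  range %.3g .. %.3g Angstrom^2\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.experimental_bfactors <- function(x) length(x$values)

# ---- internals -------------------------------------------------------------

# least-squares rigid superposition of 'mobile' onto 'ref' (Kabsch). Handles
# rank-deficient (e.g. collinear) coordinate sets, where the rotation is only
# partially determined, by picking any optimal orthogonal completion.
kabsch_superpose <- function(mobile, ref) {
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  A <- t(sweep(mobile, 2, cm)) %*% sweep(ref, 2, cr)
  s <- svd(A)
  d <- if (det(s$v %*% t(s$u)) < 0) -1 else 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(sweep(mobile, 2, cm) %*% t(R), 2, cr, "+")
}

# Accept a path / text / vector of lines; parse once with bio3d::read.pdb.
# Returns list(atom = data.frame, xyz_models = models x 3N matrix,
#              atom_index = position of each atom row in the xyz triplets).
parse_pdb_input <- function(pdb) {
  path <- pdb_as_path(pdb)
  p <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                        verbose = FALSE))
  xyz <- p$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  list(atom = p$atom, xyz_models = xyz, atom_index = seq_len(nrow(p$atom)))
}

pdb_as_path <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    return(pdb)
  }
  lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  tf <- tempfile(fileext = ".pdb")
  writeLines(lines, tf)
  tf
}

node_bfactor_column <- function(parsed, s1) {
  atom <- parsed$atom
  alt <- atom$alt
  keep_alt <- is.na(alt) | alt == "" | alt == "A"
  ins <- atom$insert
  ins[is.na(ins)] <- ""
  prot <- !s1$is_metal
  key_nodes <- paste(s1$labels$chain[prot], s1$labels$resno[prot],
                     s1$labels$insert[prot], sep = "|")
  is_ca <- keep_alt & atom$type == "ATOM" & atom$elety == "CA"
  key_atoms <- paste(atom$chain, atom$resno, ins, sep = "|")
  ca_rows <- which(is_ca)
  ca_rows <- ca_rows[!duplicated(key_atoms[ca_rows])]
  b <- atom$b[ca_rows][match(key_nodes, key_atoms[ca_rows])]
  b[is.na(b)] <- 0
  as.numeric(b)
}
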