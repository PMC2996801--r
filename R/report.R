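#' TSV writers and readers for profiles and matrices
#'
#' All tabular output is tab-separated with '.' decimal separator, LF line
#' endings, and floats at 6 significant digits. Dense matrices are written
#' row-major with a header row of node labels.
#'
#' @param values numeric per-node values.
#' @param labels character node labels (same length).
#' @param file output path.
#' @return The path, invisibly.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
write_profile_tsv <- function(values, labels, file) {
  stopifnot(length(values) == length(labels))
  write_tsv_raw(data.frame(index = seq_along(values), label = labels,
                           value = fmt_num(values)), file)
  invisible(file)
}

#' @rdname tsv_io
#' @param mat numeric matrix (columns labelled by `labels`).
#' @export
write_matrix_tsv <- function(mat, labels, file) {
  stopifnot(ncol(mat) == length(labels))
  df <- as.data.frame(apply(mat, 2, fmt_num, simplify = TRUE))
  names(df) <- labels
  write_tsv_raw(df, file)
  invisible(file)
}

#' @rdname tsv_io
#' @export
read_profile_tsv <- function(file) {
  df <- read.delim(file, sep = "\t", stringsAsFactors = FALSE)
  df$value <- as.numeric(df$value)
  df
}

#' @rdname tsv_io
#' @export
read_matrix_tsv <- function(file) {
  df <- read.delim(file, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  as.matrix(sapply(df, as.numeric))
}

node_label_strings <- function(structure) {
  sprintf("%s%d.%s", structure$labels$chain, structure$labels$resno,
          structure$labels$resname)
}

#' Run the full coarse-grained analysis workflow
#'
#' Executes the whole pipeline on one structure: parse (if given a PDB path),
#' build the GNM, fit the fluctuation scale against experimental B-factors
#' when available, write mode-shape profiles and the cross-correlation map,
#' run the iterative unfolding with contact-map and cross-correlation
#' snapshots, and compute the slowest ANM mode. All results are written as
#' TSV files under `out_prefix` together with a key=value summary and a log
#' of the configuration.
#'
#' @param input a PDB file path, PDB text, or a [cg_structure()].
#' @param out_prefix path prefix for output files (directories are created).
#' @param model model index used when parsing a PDB input.
#' @param metals metal element symbols included as nodes.
#' @param gnm_cutoff GNM contact cutoff (Angstrom).
#' @param anm_cutoff ANM contact cutoff (Angstrom).
#' @param snapshots LNNC values at which contact maps and cross-correlation
#'   maps are written (values exceeding the trajectory length are dropped
#'   with a warning). Must be nonnegative and strictly increasing.
#' @param bfactors optional experimental B-factors (used when `input` is a
#'   `cg_structure`); for PDB inputs they are read from the file when the
#'   file carries fluctuation information.
#' @param flag_pairs optional 2-column matrix of node pairs whose break steps
#'   are reported in the summary (e.g. metal-ligand bonds).
#' @param n_fast,n_slow number of modes in the fast/slow profiles.
#' @param seed recorded in the log; the pipeline itself is deterministic.
#' @return Invisibly, a list with the fitted `gnm`, `anm`, `unfolding`, the
#'   `summary` (named list) and the vector of written `files`.
#' @export
run_full_analysis <- function(input, out_prefix, model = 1L, metals = "ZN",
                              gnm_cutoff = 7.3, anm_cutoff = 13,
                              snapshots = c(0, 20, 30, 48, 60, 72),
                              bfactors = NULL, flag_pairs = NULL,
                              n_fast = 5L, n_slow = 1L, seed = 1L) {
  stopifnot(gnm_cutoff > 0, anm_cutoff > 0)
  snapshots <- as.integer(snapshots)
  if (any(snapshots < 0L) || is.unsorted(snapshots, strictly = TRUE)) {
    stop("'snapshots' must be nonnegative and strictly increasing")
  }
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)

  if (inherits(input, "cg_structure")) {
    structure <- input
  } else {
    structure <- read_structure(input, model = model, metals = metals)
    if (is.null(bfactors)) {
      bfactors <- tryCatch(read_experimental_bfactors(input, metals = metals),
                           error = function(e) {
                             warning("no usable experimental B-factors: ",
                                     conditionMessage(e))
                             NULL
                           })
    }
  }
  labels <- node_label_strings(structure)
  prot <- !structure$is_metal

  files <- character(0)
  add <- function(path) { files <<- c(files, path); path }

  add(write_structure_tsv(structure, paste0(out_prefix, "structure.tsv")))

  g <- gnm(structure, cutoff = gnm_cutoff, bfactors = bfactors)
  bpred <- if (is.null(g$fit)) {
    predicted_bfactors(mean_square_fluctuations(g, 1))[prot]
  } else {
    fitted(g)
  }
  bdf <- data.frame(index = which(prot), label = labels[prot],
                    predicted = fmt_num(bpred))
  if (!is.null(g$fit)) bdf$experimental <- fmt_num(g$fit$experimental)
  write_tsv_raw(bdf, add(paste0(out_prefix, "bfactors.tsv")))

  write_profile_tsv(mode_shape_profile(g, "slowest", n_slow), labels,
                    add(paste0(out_prefix, "modes_slow.tsv")))
  write_profile_tsv(mode_shape_profile(g, "fastest", n_fast), labels,
                    add(paste0(out_prefix, "modes_fast.tsv")))
  write_matrix_tsv(cross_correlation_map(g), labels,
                   add(paste0(out_prefix, "crosscorr.tsv")))

  tr <- unfold(structure, cutoff = gnm_cutoff)
  ev <- tr$events
  ev_out <- data.frame(step = ev$step, i = ev$i, j = ev$j,
                       label_i = labels[ev$i], label_j = labels[ev$j],
                       fluctuation = fmt_num(ev$fluctuation), lnnc = ev$lnnc)
  write_tsv_raw(ev_out, add(paste0(out_prefix, "events.tsv")))

  usable <- snapshots[snapshots <= nrow(ev)]
  if (length(usable) < length(snapshots)) {
    warning("snapshot LNNC values beyond the trajectory length dropped: ",
            paste(setdiff(snapshots, usable), collapse = ", "))
  }
  for (k in usable) {
    topo_k <- snapshot_topology(tr, k)
    write_tsv_raw(contact_edges(topo_k),
                  add(paste0(out_prefix, sprintf("contactmap_%d.tsv", k))))
    write_matrix_tsv(snapshot_cross_correlation(tr, k), labels,
                     add(paste0(out_prefix, sprintf("crosscorr_%d.tsv", k))))
  }

  a <- anm(structure, cutoff = anm_cutoff)
  f1 <- mode_field(a, 1)
  anm_df <- data.frame(index = seq_along(labels), label = labels,
                       vx = fmt_num(f1$vectors[, 1]),
                       vy = fmt_num(f1$vectors[, 2]),
                       vz = fmt_num(f1$vectors[, 3]),
                       magnitude = fmt_num(f1$magnitudes))
  write_tsv_raw(anm_df, add(paste0(out_prefix, "anm_mode1.tsv")))

  summary <- list(
    n_nodes = n_nodes(structure),
    n_metal = sum(structure$is_metal),
    n_covalent = nrow(tr$initial$covalent),
    n_noncovalent = nrow(tr$initial$noncovalent),
    kt_over_gamma = if (is.null(g$fit)) NA_real_ else g$fit$kt_over_gamma,
    bfactor_correlation = if (is.null(g$fit)) NA_real_ else g$fit$correlation,
    total_unfolding_events = nrow(ev),
    anm_zero_modes = a$spectrum$n_zero
  )
  if (!is.null(flag_pairs)) {
    bo <- bond_break_order(tr, flag_pairs)
    summary$flagged_break_order <- bo
    flag_df <- data.frame(i = bo$i, j = bo$j, label_i = labels[bo$i],
                          label_j = labels[bo$j], step = bo$step)
    write_tsv_raw(flag_df, add(paste0(out_prefix, "flagged_breaks.tsv")))
  }
  scal <- summary[!vapply(summary, is.data.frame, logical(1))]
  write_tsv_raw(data.frame(key = names(scal),
                           value = vapply(scal, function(v)
                             if (is.numeric(v)) fmt_num(v) else
                               as.character(v), character(1))),
                add(paste0(out_prefix, "summary.tsv")))

  cfg <- c(package = "enmfold",
           version = as.character(utils::packageVersion("enmfold")),
           input = if (inherits(input, "cg_structure")) "<cg_structure>"
                   else as.character(input)[1],
           model = model, metals = paste(metals, collapse = ","),
           gnm_cutoff = gnm_cutoff, anm_cutoff = anm_cutoff,
           snapshots = paste(snapshots, collapse = ","), seed = seed)
  write_tsv_raw(data.frame(key = names(cfg), value = unname(cfg)),
                add(paste0(out_prefix, "run.log")))

  invisible(list(gnm = g, anm = a, unfolding = tr, summary = summary,
                 files = files))
}
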