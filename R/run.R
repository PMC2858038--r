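#' Decompose and label a structure file into a substructure table
#'
#' End-to-end wrapper: reads structures and their annotation, runs
#' [decompose_structure()] and [label_substructures()], and writes a
#' TSV of labeled substructures plus a JSON manifest into `out_dir`.
#'
#' @param structure_file dot-bracket (or CT/bpseq) file path.
#' @param annotation_file tab-separated annotation
#'   (`molecule_id start end label`, 1-based).
#' @param scheme a [homology_scheme()] or a path to a scheme TSV.
#' @param out_dir output directory (created if needed).
#' @param format structure file format.
#' @return invisibly, the labeled substructure tibble.
#' @export
run_decompose <- function(structure_file, annotation_file, scheme, out_dir,
                          format = "dotbracket") {
  if (!file.exists(annotation_file)) {
    abort(sprintf("annotation file not found: %s", annotation_file))
  }
  if (is.character(scheme)) scheme <- read_scheme(scheme)
  structures <- read_structures(structure_file, format)
  ann <- read_annotation(annotation_file)
  subs <- dplyr::bind_rows(lapply(structures, decompose_structure))
  labeled <- label_substructures(subs, scheme, ann)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- dplyr::select(labeled, "molecule_id", "label", "kind",
                       "length", "gu_count")
  utils::write.table(out, file.path(out_dir, "substructures.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    tool = "rnaclad", step = "decompose",
    version = as.character(utils::packageVersion("rnaclad")),
    structure_file = structure_file, annotation_file = annotation_file,
    n_molecules = length(structures), n_substructures = nrow(labeled)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("decomposed %d molecule(s) into %d labeled row(s)",
                  length(structures), nrow(labeled)))
  invisible(labeled)
}

#' Run the full cladistic analysis of a character matrix
#'
#' Polarizes the matrix (if not already), searches for minimal trees,
#' writes the trees, the strict consensus, tree statistics (length,
#' number of trees, CI with and without uninformative characters, RI,
#' RC, optionally g1 and bootstrap supports), nd ancestry values of the
#' consensus, and a manifest that records every seed and setting needed
#' to reproduce the run byte for byte.
#'
#' @param M a [char_matrix()], or a path to a matrix TSV
#'   ([read_matrix_tsv()]) or NEXUS file ([read_nexus()]).
#' @param out_dir output directory.
#' @param strategy,reps,seed,max_trees passed to [mp_search()].
#' @param partition optional partition name applied first
#'   (see [partition_matrix()]).
#' @param transpose transpose the (partitioned) matrix before analysis
#'   to build a tree of substructures.
#' @param g1_reps random trees for [g1_statistic()] (0 skips it).
#' @param bootstrap_reps replicates for [mp_bootstrap()] (0 skips it).
#' @param heatmap_layout optional layout table/TSV for
#'   [render_heatmap()].
#' @return invisibly, a list with the fit, consensus, stats and nd map.
#' @export
run_analysis <- function(M, out_dir, strategy = "heuristic", reps = 10,
                         seed = 1, max_trees = 10000, partition = NULL,
                         transpose = FALSE, g1_reps = 0, bootstrap_reps = 0,
                         heatmap_layout = NULL) {
  if (is.character(M)) {
    M <- if (grepl("\\.nex(us)?$", M, ignore.case = TRUE)) read_nexus(M)
         else read_matrix_tsv(M)
  }
  stopifnot(inherits(M, "char_matrix"))
  if (!is.null(partition)) M <- partition_matrix(M, partition)
  if (transpose) M <- transpose_matrix(M)
  if (is.null(M$ancestor)) M <- add_ancestor(M)

  fit <- mp_search(M, strategy = strategy, reps = reps, seed = seed,
                   max_trees = max_trees)
  cons <- strict_consensus(fit)
  stats <- consistency_stats(fit)
  if (g1_reps > 0) {
    stats$g1 <- as.numeric(g1_statistic(M, n_random = g1_reps, seed = seed))
  }
  amap <- node_distance(cons)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(fit$trees, file.path(out_dir, "trees.nwk"))
  ape::write.tree(cons, file.path(out_dir, "consensus.nwk"))
  write_nexus(M, file.path(out_dir, "matrix.nex"))
  utils::write.table(
    dplyr::select(as_tibble(amap), "label", "nd"),
    file.path(out_dir, "nd.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  boot <- NULL
  if (bootstrap_reps > 0) {
    boot <- mp_bootstrap(M, n_reps = bootstrap_reps, seed = seed)
    bt <- dplyr::mutate(boot,
                        tips = vapply(.data$tips, paste,
                                      character(1), collapse = "|"))
    utils::write.table(bt, file.path(out_dir, "bootstrap.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(heatmap_layout)) {
    render_heatmap(amap, heatmap_layout,
                   path = file.path(out_dir, "heatmap.svg"))
  }
  stats_out <- c(
    as.list(stats),
    list(saturated = fit$saturated, strategy = strategy)
  )
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest <- list(
    tool = "rnaclad", step = "analyze",
    version = as.character(utils::packageVersion("rnaclad")),
    strategy = strategy, reps = reps, seed = seed, max_trees = max_trees,
    partition = partition, transposed = transpose,
    g1_reps = g1_reps, bootstrap_reps = bootstrap_reps,
    n_taxa = nrow(M$states), n_characters = ncol(M$states)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (isTRUE(fit$saturated)) {
    warn("minimal-tree buffer saturated; tree count is a lower bound")
  }
  invisible(list(fit = fit, consensus = cons, stats = stats,
                 nd = amap, bootstrap = boot))
}
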