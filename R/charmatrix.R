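#' Construct a character matrix object
#'
#' A `char_matrix` holds taxa-by-character integer states (0-61, `NA`
#' for missing), per-character metadata (kind, folding domain, metric,
#' ordered flag), optional taxon metadata, an optional hypothetical
#' ancestor row, and an orientation flag saying whether rows are
#' molecules or substructures.
#'
#' @param states integer matrix, rows named by taxa.
#' @param chars tibble with columns `char_id`, `kind`
#'   (`stabilizing`/`destabilizing`/`sequence`), `domain`
#'   (`S`/`C`/`none`), `metric`, `ordered` (logical).
#' @param taxa optional tibble with `taxon_id`, `superkingdom`, `rpr_type`.
#' @param ancestor optional integer vector of ancestral states (NA = `?`).
#' @param orientation `"molecules_as_taxa"` or `"substructures_as_taxa"`.
#' @return an object of class `char_matrix`.
#' @export
char_matrix <- function(states, chars, taxa = NULL, ancestor = NULL,
                        orientation = c("molecules_as_taxa",
                                        "substructures_as_taxa")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(states)) abort("`states` must be a matrix")
  storage.mode(states) <- "integer"
  if (is.null(rownames(states))) abort("`states` must have row names (taxa)")
  if (anyDuplicated(rownames(states))) abort("duplicate taxon id")
  if (any(states < 0L | states > 61L, na.rm = TRUE)) {
    abort("states must lie in 0..61 (or NA for missing)")
  }
  chars <- as_tibble(chars)
  need <- c("char_id", "kind", "domain", "metric", "ordered")
  if (!all(need %in% names(chars))) {
    abort(sprintf("`chars` must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(chars) != ncol(states)) {
    abort("`chars` must describe every column of `states`")
  }
  colnames(states) <- chars$char_id
  if (is.null(taxa)) {
    taxa <- tibble(taxon_id = rownames(states),
                   superkingdom = NA_character_, rpr_type = NA_character_)
  }
  if (!is.null(ancestor)) {
    ancestor <- as.integer(ancestor)
    if (length(ancestor) != ncol(states)) {
      abort("ancestor length must equal the number of characters")
    }
    names(ancestor) <- chars$char_id
  }
  structure(
    list(states = states, chars = chars, taxa = as_tibble(taxa),
         ancestor = ancestor, orientation = orientation),
    class = "char_matrix"
  )
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf(
    "<char_matrix> %d taxa x %d characters (%s)%s\n",
    nrow(x$states), ncol(x$states), x$orientation,
    if (!is.null(x$ancestor)) ", polarized (ancestor present)" else ""
  ))
  kinds <- table(x$chars$kind)
  cat("  characters:", paste(sprintf("%s %d", names(kinds), kinds),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$states)

#' @export
as_tibble.char_matrix <- function(x, ...) {
  sym <- apply(x$states, 2, encode_state)
  out <- as_tibble(as.data.frame(sym, stringsAsFactors = FALSE))
  dplyr::bind_cols(tibble(taxon = rownames(x$states)), out)
}

#' Build the taxa-by-character matrix from labeled substructures
#'
#' One stabilizing stem-length character per stem label (optionally a
#' G:U-pair character per stem) and one de-stabilizing length character
#' per unpaired-kind label, in scheme order.  Missing substructures are
#' coded with the minimum state 0.  Lengths above 61 are clamped (see
#' [encode_state()]).
#'
#' @param labeled tibble from [label_substructures()] covering one or
#'   more molecules.
#' @param scheme the [homology_scheme()] the molecules were labeled with.
#' @param taxa optional taxon metadata tibble (`taxon_id`,
#'   `superkingdom`, `rpr_type`).
#' @param gu logical: also emit one `<label>.gu` stabilizing character
#'   per stem label, counting G:U/U:G pairs.
#' @return a [char_matrix()] with molecules as taxa.
#' @export
build_char_matrix <- function(labeled, scheme, taxa = NULL, gu = FALSE) {
  stopifnot(inherits(scheme, "homology_scheme"))
  mols <- unique(labeled$molecule_id)
  if (!length(mols)) abort("no molecules to code")
  if (anyDuplicated(mols)) abort("duplicate molecule id")  # defensive

  metric_of <- function(kind) {
    switch(kind,
      stem = "stem_bp", hairpin = "loop_nt", bulge = "loop_nt",
      internal_loop = "loop_nt", "unpaired_nt"
    )
  }
  chars <- tibble(
    char_id = paste0(scheme$label, ".len"),
    label = scheme$label,
    kind = ifelse(scheme$kind == "stem", "stabilizing", "destabilizing"),
    domain = scheme$domain,
    metric = vapply(scheme$kind, metric_of, character(1)),
    ordered = TRUE
  )
  if (gu) {
    stems <- scheme[scheme$kind == "stem", ]
    chars <- dplyr::bind_rows(chars, tibble(
      char_id = paste0(stems$label, ".gu"), label = stems$label,
      kind = "stabilizing", domain = stems$domain,
      metric = "gu_pairs", ordered = TRUE
    ))
  }

  states <- matrix(0L, length(mols), nrow(chars),
                   dimnames = list(mols, chars$char_id))
  lab_rows <- labeled[!is.na(labeled$label), ]
  for (k in seq_len(nrow(lab_rows))) {
    r <- lab_rows[k, ]
    states[r$molecule_id, paste0(r$label, ".len")] <- r$length
    if (gu && paste0(r$label, ".gu") %in% chars$char_id) {
      states[r$molecule_id, paste0(r$label, ".gu")] <- r$gu_count
    }
  }
  over <- states > 61L
  if (any(over)) {
    warn(sprintf("%d state value(s) exceed 61 and were clamped", sum(over)))
    states[over] <- 61L
  }
  char_matrix(states, dplyr::select(chars, -"label"), taxa = taxa)
}

#' Add the hypothetical ancestor used for intrinsic rooting
#'
#' Polarization fixes the direction of character change towards
#' molecular order: for stabilizing characters (stems, G:U pairs) the
#' ancestral state is the column maximum; for de-stabilizing characters
#' (hairpins, bulges and other unpaired regions) it is the minimum
#' state 0.  Sequence characters get `?` (missing).  The ancestor takes
#' part in tree searches only to root the tree and is pruned afterwards.
#'
#' @param M a [char_matrix()].
#' @return `M` with the `ancestor` slot populated.
#' @export
add_ancestor <- function(M) {
  stopifnot(inherits(M, "char_matrix"))
  if (nrow(M$states) < 1L) abort("matrix has no taxa")
  anc <- integer(ncol(M$states))
  for (c in seq_len(ncol(M$states))) {
    anc[c] <- switch(M$chars$kind[c],
      stabilizing = {
        mx <- suppressWarnings(max(M$states[, c], na.rm = TRUE))
        if (is.infinite(mx)) NA_integer_ else mx
      },
      destabilizing = 0L,
      NA_integer_
    )
  }
  M$ancestor <- setNames(as.integer(anc), M$chars$char_id)
  M
}

#' Transpose a character matrix
#'
#' Swaps the roles of taxa and characters so that cladistic analysis of
#' the result yields a tree of substructures instead of a tree of
#' molecules.  Only single-kind matrices can be transposed (trees of
#' stems are built separately from trees of hairpins, bulges or
#' unpaired segments, because the rows of the transposed matrix must
#' share one evolutionary model); partition first with
#' [partition_matrix()].  Any ancestor row is dropped — re-polarize the
#' transposed matrix with [add_ancestor()].
#'
#' @param M a [char_matrix()].
#' @return the transposed [char_matrix()].
#' @export
transpose_matrix <- function(M) {
  stopifnot(inherits(M, "char_matrix"))
  kinds <- unique(M$chars$kind)
  if (length(kinds) != 1L) {
    abort(paste0(
      "cannot transpose a mixed-kind matrix (found: ",
      paste(kinds, collapse = ", "),
      "); partition by kind first"
    ))
  }
  if (kinds == "sequence") abort("sequence blocks cannot be transposed")
  st <- t(M$states)
  chars <- tibble(
    char_id = rownames(M$states),
    kind = kinds, domain = "none",
    metric = M$chars$metric[1], ordered = TRUE
  )
  orientation <- if (M$orientation == "molecules_as_taxa")
    "substructures_as_taxa" else "molecules_as_taxa"
  char_matrix(st, chars, orientation = orientation)
}

core_sets <- list(
  core_A = c("P1", "P2", "P3", "P4", "P10", "P11"),
  core_B = c("P1", "P2", "P3", "P4", "P7", "P9", "P10", "P11")
)

#' Extract a partition of a character matrix
#'
#' Partitions follow the published analysis design: by folding domain
#' (`domain_S`, `domain_C`), by character type (`stabilizing`,
#' `destabilizing`), by taxon superkingdom (`"superkingdom:Archaea"`
#' etc.), or one of the conserved-core presets `core_A` (P1-P4, P10,
#' P11) and `core_B` (P1-P4, P7, P9-P11).
#'
#' @param M a [char_matrix()].
#' @param scheme partition name (see Details).
#' @return the filtered [char_matrix()] (ancestor, when present, is
#'   subset along with the characters).
#' @export
partition_matrix <- function(M, scheme) {
  stopifnot(inherits(M, "char_matrix"), is.character(scheme))
  label_of <- function(ids) sub("\\.(len|gu)$", "", ids)
  keep_chars <- NULL
  keep_taxa <- NULL
  if (scheme == "domain_S") {
    keep_chars <- M$chars$domain == "S"
  } else if (scheme == "domain_C") {
    keep_chars <- M$chars$domain == "C"
  } else if (scheme %in% c("stabilizing", "destabilizing")) {
    keep_chars <- M$chars$kind == scheme
  } else if (startsWith(scheme, "superkingdom:")) {
    sk <- sub("^superkingdom:", "", scheme)
    keep_taxa <- M$taxa$superkingdom %in% sk
  } else if (scheme %in% names(core_sets)) {
    wanted <- core_sets[[scheme]]
    have <- label_of(M$chars$char_id)
    missing <- setdiff(wanted, have)
    if (length(missing)) {
      abort(sprintf("%s preset needs label(s) absent from the matrix: %s",
                    scheme, paste(missing, collapse = ", ")))
    }
    keep_chars <- have %in% wanted
  } else {
    abort(sprintf("unknown partition scheme '%s'", scheme))
  }
  out <- M
  if (!is.null(keep_chars)) {
    if (!any(keep_chars)) abort(sprintf("partition '%s' is empty", scheme))
    out$states <- out$states[, keep_chars, drop = FALSE]
    out$chars <- out$chars[keep_chars, ]
    if (!is.null(out$ancestor)) out$ancestor <- out$ancestor[keep_chars]
  }
  if (!is.null(keep_taxa)) {
    if (!any(keep_taxa)) abort(sprintf("partition '%s' is empty", scheme))
    out$states <- out$states[keep_taxa, , drop = FALSE]
    out$taxa <- out$taxa[keep_taxa, ]
  }
  out
}

#' Combine structural characters with an aligned sequence block
#'
#' Total-evidence concatenation: aligned nucleotide columns are appended
#' as unordered characters; gaps and `?` are treated as missing, and the
#' hypothetical ancestor is missing (`?`) at every sequence column so
#' sequence data contribute signal but not polarity.
#'
#' @param M a [char_matrix()] (molecules as taxa).
#' @param seqs named character vector of aligned sequences
#'   (names = taxa, equal lengths, alphabet `A C G U - ?`; `T` read as
#'   `U`), or `NULL`/empty to return `M` unchanged.
#' @return the concatenated [char_matrix()].
#' @export
combine_total_evidence <- function(M, seqs) {
  stopifnot(inherits(M, "char_matrix"))
  if (is.null(seqs) || !length(seqs)) return(M)
  if (is.null(names(seqs))) abort("`seqs` must be named by taxon")
  if (!setequal(names(seqs), rownames(M$states))) {
    abort("sequence block and matrix must share the same taxon set")
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) abort("aligned sequences must have equal length")
  seqs <- toupper(gsub("T", "U", seqs))
  code <- setNames(decode_state(c("A", "C", "G", "U")), c("A", "C", "G", "U"))
  sm <- matrix(NA_integer_, nrow(M$states), L,
               dimnames = list(rownames(M$states),
                               paste0("seq", seq_len(L))))
  for (tx in rownames(M$states)) {
    ch <- strsplit(seqs[[tx]], "")[[1]]
    bad <- !ch %in% c(names(code), "-", "?", "N")
    if (any(bad)) {
      abort(sprintf("unexpected alignment symbol '%s' in %s",
                    ch[bad][1], tx))
    }
    sm[tx, ] <- unname(code[ch])
  }
  schars <- tibble(
    char_id = colnames(sm), kind = "sequence", domain = "none",
    metric = "aligned_site", ordered = FALSE
  )
  anc <- M$ancestor
  if (!is.null(anc)) anc <- c(anc, setNames(rep(NA_integer_, L), colnames(sm)))
  char_matrix(cbind(M$states, sm), dplyr::bind_rows(M$chars, schars),
              taxa = M$taxa, ancestor = anc, orientation = M$orientation)
}

#' Write / read a character matrix as annotated TSV
#'
#' The body has a `taxon` column plus one symbol column per character;
#' `#`-prefixed header lines carry the per-character kind, domain,
#' metric, ordered flag and the ancestor row, so the round trip is
#' lossless.  This is also the ingest path for externally prepared
#' matrices (e.g. transcribed from published data tables).
#'
#' @param M a [char_matrix()].
#' @param path file path.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` returns a [char_matrix()].
#' @export
write_matrix_tsv <- function(M, path) {
  stopifnot(inherits(M, "char_matrix"))
  hdr <- c(
    paste0("#kind\t", paste(M$chars$kind, collapse = "\t")),
    paste0("#domain\t", paste(M$chars$domain, collapse = "\t")),
    paste0("#metric\t", paste(M$chars$metric, collapse = "\t")),
    paste0("#ordered\t", paste(as.integer(M$chars$ordered), collapse = "\t")),
    paste0("#orientation\t", M$orientation)
  )
  if (!is.null(M$ancestor)) {
    hdr <- c(hdr, paste0("#ancestor\t",
                         paste(encode_state(M$ancestor), collapse = "\t")))
  }
  sym <- apply(M$states, 2, encode_state)
  if (nrow(M$states) == 1L) sym <- matrix(sym, nrow = 1L)
  body <- apply(cbind(rownames(M$states), sym), 1, paste, collapse = "\t")
  writeLines(c(hdr, paste(c("taxon", M$chars$char_id), collapse = "\t"), body),
             path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_meta <- function(key) {
    hit <- meta[startsWith(meta, paste0("#", key, "\t"))]
    if (!length(hit)) return(NULL)
    strsplit(hit[1], "\t", fixed = TRUE)[[1]][-1]
  }
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  char_ids <- header[-1]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  taxa <- vapply(rows, `[`, character(1), 1L)
  states <- t(vapply(rows, function(r) decode_state(r[-1]),
                     integer(length(char_ids))))
  dimnames(states) <- list(taxa, char_ids)
  kind <- get_meta("kind") %||% rep("stabilizing", length(char_ids))
  ordv <- get_meta("ordered")
  chars <- tibble(
    char_id = char_ids,
    kind = kind,
    domain = get_meta("domain") %||% rep("none", length(char_ids)),
    metric = get_meta("metric") %||% rep("stem_bp", length(char_ids)),
    ordered = if (is.null(ordv)) kind != "sequence"
              else as.logical(as.integer(ordv))
  )
  anc <- get_meta("ancestor")
  if (!is.null(anc)) anc <- decode_state(anc)
  orientation <- get_meta("orientation") %||% "molecules_as_taxa"
  char_matrix(states, chars, ancestor = anc, orientation = orientation[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
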