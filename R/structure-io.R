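#' Parse an RNA secondary structure
#'
#' Reads one molecule from dot-bracket, CT or bpseq text into a
#' `secondary_structure` object: the sequence plus a set of base pairs.
#' Dot-bracket input may use up to four bracket layers — `()`, `[]`,
#' `{}` and `<>` — so pseudoknotted structures can be represented; pairs
#' from different layers may cross, pairs within one layer must nest.
#' CT and bpseq coordinates are 1-based on disk and converted to the
#' 0-based internal convention at this boundary.
#'
#' @param text character scalar holding the record: for `dotbracket`
#'   either the bracket string alone (with `sequence` supplied) or a
#'   two/three-line record (optional `>id` header, sequence line,
#'   structure line); for `ct`/`bpseq` the full file body.
#' @param format one of `"dotbracket"`, `"ct"`, `"bpseq"`.
#' @param sequence optional nucleotide sequence (dot-bracket only).
#' @param molecule_id identifier for the molecule.
#' @param taxon_meta optional named list with `superkingdom`
#'   (`"Archaea"`, `"Bacteria"` or `"Eukarya"`) and `rpr_type`
#'   (`"A"`, `"B"`, `"C"`, `"M"` or `"E"`).
#' @return an object of class `secondary_structure`: a list with
#'   `molecule_id`, `sequence`, `pairs` (integer matrix, columns `i` and
#'   `j`, 0-based, `i < j`), `layer` (bracket layer of each pair) and
#'   `taxon_meta`.
#' @examples
#' ss <- parse_structure("((((....))))", "dotbracket",
#'                       sequence = "GGGGAAAACCCC")
#' ss$pairs
#' @export
parse_structure <- function(text, format = c("dotbracket", "ct", "bpseq"),
                            sequence = NULL, molecule_id = "molecule",
                            taxon_meta = NULL) {
  format <- match.arg(format)
  switch(format,
    dotbracket = parse_dotbracket(text, sequence, molecule_id, taxon_meta),
    ct = parse_ct(text, molecule_id, taxon_meta),
    bpseq = parse_bpseq(text, molecule_id, taxon_meta)
  )
}

bracket_open <- c("(", "[", "{", "<")
bracket_close <- c(")", "]", "}", ">")

parse_dotbracket <- function(text, sequence, molecule_id, taxon_meta) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) > 1L) {
    if (startsWith(lines[1], ">")) {
      molecule_id <- trimws(sub("^>", "", lines[1]))
      lines <- lines[-1]
    }
    if (length(lines) == 2L) {
      sequence <- trimws(lines[1])
      struct <- trimws(lines[2])
    } else if (length(lines) == 1L) {
      struct <- trimws(lines[1])
    } else {
      abort("dot-bracket record must have at most a header, a sequence line and a structure line")
    }
  } else {
    struct <- trimws(lines)
  }
  chars <- strsplit(struct, "")[[1]]
  n <- length(chars)
  if (n < 1L) abort("empty structure string")
  if (is.null(sequence)) sequence <- strrep("N", n)
  sequence <- toupper(gsub("T", "U", sequence))
  if (nchar(sequence) != n) {
    abort(sprintf(
      "sequence length (%d) does not match structure length (%d)",
      nchar(sequence), n
    ))
  }
  if (grepl("[^ACGUN-]", sequence)) {
    abort("sequence contains letters outside {A,C,G,U,N}")
  }
  bad <- which(!chars %in% c(".", "-", bracket_open, bracket_close))
  if (length(bad)) {
    abort(sprintf(
      "unexpected character '%s' at column %d of the structure string",
      chars[bad[1]], bad[1]
    ))
  }
  pairs <- matrix(integer(0), 0, 2)
  layer <- integer(0)
  for (l in seq_along(bracket_open)) {
    stack <- integer(0)
    for (k in seq_len(n)) {
      if (chars[k] == bracket_open[l]) {
        stack <- c(stack, k)
      } else if (chars[k] == bracket_close[l]) {
        if (!length(stack)) {
          abort(sprintf(
            "unmatched '%s' at column %d", bracket_close[l], k
          ))
        }
        i <- stack[length(stack)]
        stack <- stack[-length(stack)]
        pairs <- rbind(pairs, c(i - 1L, k - 1L))
        layer <- c(layer, l - 1L)
      }
    }
    if (length(stack)) {
      abort(sprintf(
        "unmatched '%s' at column %d", bracket_open[l], stack[1]
      ))
    }
  }
  new_secondary_structure(molecule_id, sequence, pairs, layer, taxon_meta)
}

parse_ct <- function(text, molecule_id, taxon_meta) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort("CT input needs a header line and residue lines")
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nres <- suppressWarnings(as.integer(hdr[1]))
  if (is.na(nres)) abort("CT header must start with the residue count")
  body <- lines[-1]
  if (length(body) != nres) {
    abort(sprintf(
      "CT header announces %d residues but %d lines follow", nres, length(body)
    ))
  }
  seq_chars <- character(nres)
  partner <- integer(nres)
  for (k in seq_len(nres)) {
    f <- strsplit(trimws(body[k]), "\\s+")[[1]]
    if (length(f) < 5L) {
      abort(sprintf("malformed CT line %d: fewer than 5 fields", k + 1L))
    }
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx) || idx != k) {
      abort(sprintf("CT line %d: residue index is not %d", k + 1L, k))
    }
    seq_chars[k] <- f[2]
    partner[k] <- suppressWarnings(as.integer(f[5]))
    if (is.na(partner[k])) abort(sprintf("CT line %d: bad pairing field", k + 1L))
  }
  pairs_from_partner(partner, paste(seq_chars, collapse = ""),
                     molecule_id, taxon_meta)
}

parse_bpseq <- function(text, molecule_id, taxon_meta) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  nres <- length(lines)
  if (!nres) abort("empty bpseq input")
  seq_chars <- character(nres)
  partner <- integer(nres)
  for (k in seq_len(nres)) {
    f <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(f) != 3L) {
      abort(sprintf("malformed bpseq line %d: expected 3 fields", k))
    }
    idx <- suppressWarnings(as.integer(f[1]))
    if (is.na(idx) || idx != k) {
      abort(sprintf("bpseq line %d: residue index is not %d", k, k))
    }
    seq_chars[k] <- f[2]
    partner[k] <- suppressWarnings(as.integer(f[3]))
    if (is.na(partner[k])) abort(sprintf("bpseq line %d: bad pairing field", k))
  }
  pairs_from_partner(partner, paste(seq_chars, collapse = ""),
                     molecule_id, taxon_meta)
}

pairs_from_partner <- function(partner, sequence, molecule_id, taxon_meta) {
  n <- length(partner)
  if (any(partner < 0 | partner > n)) {
    abort("pairing index outside the molecule")
  }
  for (k in seq_len(n)) {
    j <- partner[k]
    if (j > 0L && partner[j] != k) {
      abort(sprintf(
        "pair conflict: residue %d pairs with %d but %d pairs with %d",
        k, j, j, partner[j]
      ))
    }
  }
  keep <- which(partner > seq_len(n))
  pairs <- cbind(keep - 1L, partner[keep] - 1L)
  layer <- assign_layers(pairs)
  sequence <- toupper(gsub("T", "U", sequence))
  new_secondary_structure(molecule_id, sequence, pairs, layer, taxon_meta)
}

# greedy layering: a pair goes to the first layer where it crosses nothing
assign_layers <- function(pairs) {
  np <- nrow(pairs)
  layer <- integer(np)
  if (!np) return(layer)
  ord <- order(pairs[, 1])
  for (l in 0:7) {
    idx <- ord[layer[ord] == l]
    if (!length(idx)) break
    kept <- integer(0)
    for (k in idx) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      crosses <- any(
        (pairs[kept, 1] < i & i < pairs[kept, 2] & pairs[kept, 2] < j) |
        (i < pairs[kept, 1] & pairs[kept, 1] < j & j < pairs[kept, 2])
      )
      if (crosses) layer[k] <- l + 1L else kept <- c(kept, k)
    }
  }
  layer
}

new_secondary_structure <- function(molecule_id, sequence, pairs, layer,
                                    taxon_meta) {
  n <- nchar(sequence)
  colnames(pairs) <- c("i", "j")
  storage.mode(pairs) <- "integer"
  if (nrow(pairs)) {
    if (any(pairs < 0L | pairs >= n)) abort("pair index outside the sequence")
    if (any(pairs[, 1] >= pairs[, 2])) abort("pairs must satisfy i < j")
    all_idx <- c(pairs[, 1], pairs[, 2])
    if (anyDuplicated(all_idx)) {
      abort(sprintf(
        "residue %d participates in more than one pair",
        all_idx[duplicated(all_idx)][1] + 1L
      ))
    }
    ord <- order(pairs[, 1])
    pairs <- pairs[ord, , drop = FALSE]
    layer <- layer[ord]
  }
  if (!is.null(taxon_meta)) {
    sk <- taxon_meta$superkingdom
    if (!is.null(sk) && !sk %in% c("Archaea", "Bacteria", "Eukarya")) {
      abort("superkingdom must be Archaea, Bacteria or Eukarya")
    }
    ty <- taxon_meta$rpr_type
    if (!is.null(ty) && !ty %in% c("A", "B", "C", "M", "E")) {
      abort("rpr_type must be one of A, B, C, M, E")
    }
  }
  structure(
    list(
      molecule_id = molecule_id,
      sequence = sequence,
      pairs = pairs,
      layer = layer,
      taxon_meta = taxon_meta
    ),
    class = "secondary_structure"
  )
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf(
    "<secondary_structure> %s: %d nt, %d pairs%s\n",
    x$molecule_id, nchar(x$sequence), nrow(x$pairs),
    if (length(x$layer) && any(x$layer > 0)) " (pseudoknotted)" else ""
  ))
  invisible(x)
}

#' Read a multi-record structure file
#'
#' Dot-bracket files hold records of `>id`, sequence, structure lines;
#' CT and bpseq files hold a single molecule each.
#'
#' @param path file path.
#' @param format `"dotbracket"`, `"ct"` or `"bpseq"`.
#' @return a list of [secondary_structure][parse_structure] objects.
#' @export
read_structures <- function(path, format = c("dotbracket", "ct", "bpseq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format != "dotbracket") {
    return(list(parse_structure(txt, format,
                                molecule_id = sub("\\.[^.]*$", "", basename(path)))))
  }
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  starts <- which(startsWith(lines, ">"))
  if (!length(starts)) {
    return(list(parse_structure(paste(lines, collapse = "\n"), "dotbracket")))
  }
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(k) {
    rec <- lines[starts[k]:ends[k]]
    parse_structure(paste(rec, collapse = "\n"), "dotbracket")
  })
}

#' Write structures as dot-bracket
#'
#' Pairs are laid out on bracket layers `()`, `[]`, `{}`, `<>` so that
#' pairs within a layer nest; parsing the output reproduces the pair set
#' (layer assignment may differ from the original input).
#'
#' @param ss a `secondary_structure` or list of them.
#' @param path output file; if `NULL` the text is returned.
#' @return invisibly (or visibly when `path` is `NULL`) the dot-bracket text.
#' @export
write_dotbracket <- function(ss, path = NULL) {
  if (inherits(ss, "secondary_structure")) ss <- list(ss)
  recs <- vapply(ss, function(s) {
    n <- nchar(s$sequence)
    chars <- rep(".", n)
    layer <- assign_layers(s$pairs)
    if (any(layer > 3L)) {
      abort("more than four crossing layers cannot be written as dot-bracket")
    }
    for (k in seq_len(nrow(s$pairs))) {
      chars[s$pairs[k, 1] + 1L] <- bracket_open[layer[k] + 1L]
      chars[s$pairs[k, 2] + 1L] <- bracket_close[layer[k] + 1L]
    }
    paste0(">", s$molecule_id, "\n", s$sequence, "\n",
           paste(chars, collapse = ""))
  }, character(1))
  txt <- paste(recs, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a substructure annotation table
#'
#' Tab-separated columns `molecule_id`, `start`, `end`, `label` with
#' 1-based inclusive coordinates.
#'
#' @param path file path.
#' @return a tibble with the four columns (coordinates kept 1-based).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such annotation file: %s", path))
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("molecule_id", "start", "end", "label"),
                          stringsAsFactors = FALSE, comment.char = "#")
  if (any(df$start < 1 | df$end < df$start)) {
    abort("annotation intervals must satisfy 1 <= start <= end")
  }
  as_tibble(df)
}
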