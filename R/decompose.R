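#' Decompose a secondary structure into typed substructures
#'
#' Stems are maximal runs of stacked pairs (pairs `(i,j)` and
#' `(i+1,j-1)`); every unpaired run is classified from the loop of the
#' nested skeleton that contains it: `hairpin` (loop closed by one stem
#' with no stems inside), `bulge`/`internal_loop` (loop with exactly one
#' inner stem; the two sides are merged into a single substructure — a
#' bulge when one side is empty), `multiloop_segment` (loop with two or
#' more inner stems), `joint` (exterior run between top-level stems) and
#' `free_end` (5'/3' termini).  With pseudoknots, pairs beyond the first
#' (maximal non-crossing) bracket layer are ordinary stems, and unpaired
#' runs are classified against the non-crossing skeleton.  The spans of
#' the returned substructures partition the molecule.
#'
#' @param ss a [secondary_structure][parse_structure].
#' @return a tibble with one row per substructure: `molecule_id`, `kind`,
#'   `length` (base pairs for stems, nucleotides otherwise), `gu_count`
#'   (stems only), `span` (list column of 0-based inclusive
#'   `[start, end]` interval matrices) and `pos5` (first residue, for
#'   5'-to-3' ordering).
#' @examples
#' ss <- parse_structure("..((..((...))..))..", "dotbracket")
#' decompose_structure(ss)
#' @export
decompose_structure <- function(ss) {
  stopifnot(inherits(ss, "secondary_structure"))
  n <- nchar(ss$sequence)
  pairs <- ss$pairs
  seq_chars <- strsplit(ss$sequence, "")[[1]]

  rows <- list()
  add_row <- function(kind, length, gu, span) {
    first <- as.integer(min(span[, 1]))
    rows[[length(rows) + 1L]] <<- tibble(
      molecule_id = ss$molecule_id, kind = kind,
      length = as.integer(length), gu_count = as.integer(gu),
      span = list(span), pos5 = first
    )
  }

  # --- stems: maximal stacked runs over ALL pairs -------------------------
  if (nrow(pairs)) {
    ord <- order(pairs[, 1])
    p <- pairs[ord, , drop = FALSE]
    k <- 1L
    while (k <= nrow(p)) {
      run <- k
      while (run < nrow(p) &&
             p[run + 1L, 1] == p[run, 1] + 1L &&
             p[run + 1L, 2] == p[run, 2] - 1L) {
        run <- run + 1L
      }
      i1 <- p[k, 1]; i2 <- p[run, 1]
      j2 <- p[run, 2]; j1 <- p[k, 2]
      len <- run - k + 1L
      b1 <- seq_chars[(i1:i2) + 1L]
      b2 <- seq_chars[(j1:j2) + 1L]   # aligned: i1:j1, i2:j2
      gu <- sum((b1 == "G" & seq_chars[p[k:run, 2] + 1L] == "U") |
                (b1 == "U" & seq_chars[p[k:run, 2] + 1L] == "G"))
      span <- rbind(c(i1, i2), c(j2, j1))
      add_row("stem", len, gu, span)
      k <- run + 1L
    }
  }

  # --- nested skeleton for loop classification ----------------------------
  partner <- rep(NA_integer_, n)
  skeleton <- matrix(integer(0), 0, 2)
  if (nrow(pairs)) {
    keep <- ss$layer == min(ss$layer)
    skeleton <- pairs[keep, , drop = FALSE]
    partner[pairs[, 1] + 1L] <- pairs[, 2]
    partner[pairs[, 2] + 1L] <- pairs[, 1]
  }
  # enclosing skeleton pair of a position: smallest interval (i,j) with i<a<j
  enclosing <- function(a) {
    if (!nrow(skeleton)) return(NULL)
    hit <- skeleton[skeleton[, 1] < a & skeleton[, 2] > a, , drop = FALSE]
    if (!nrow(hit)) return(NULL)
    hit[which.min(hit[, 2] - hit[, 1]), ]
  }
  # direct child pairs of skeleton pair (i,j): outermost skeleton pairs inside
  children_of <- function(ij) {
    inner <- skeleton[skeleton[, 1] > ij[1] & skeleton[, 2] < ij[2], ,
                      drop = FALSE]
    if (!nrow(inner)) return(inner)
    keep <- vapply(seq_len(nrow(inner)), function(k) {
      !any(inner[, 1] < inner[k, 1] & inner[, 2] > inner[k, 2])
    }, logical(1))
    inner[keep, , drop = FALSE]
  }

  unpaired <- which(is.na(partner)) - 1L
  runs <- split_runs(unpaired)
  handled <- rep(FALSE, length(runs))

  for (ri in seq_along(runs)) {
    if (handled[ri]) next
    r <- runs[[ri]]
    a <- r[1]; b <- r[2]
    if (a == 0L || b == n - 1L) {
      add_row("free_end", b - a + 1L, 0L, rbind(c(a, b)))
      handled[ri] <- TRUE
      next
    }
    enc <- enclosing(a)
    if (is.null(enc)) {
      add_row("joint", b - a + 1L, 0L, rbind(c(a, b)))
      handled[ri] <- TRUE
      next
    }
    kids <- children_of(enc)
    if (nrow(kids) == 0L) {
      add_row("hairpin", b - a + 1L, 0L, rbind(c(a, b)))
      handled[ri] <- TRUE
    } else if (nrow(kids) == 1L) {
      # merge the runs on both sides of the single inner stem
      sides <- which(!handled & vapply(runs, function(q) {
        q[1] > enc[1] & q[2] < enc[2] &
          (q[2] < kids[1, 1] | q[1] > kids[1, 2])
      }, logical(1)))
      span <- do.call(rbind, lapply(runs[sides], function(q) c(q[1], q[2])))
      tot <- sum(span[, 2] - span[, 1] + 1L)
      left <- any(span[, 2] < kids[1, 1])
      right <- any(span[, 1] > kids[1, 2])
      add_row(if (left && right) "internal_loop" else "bulge", tot, 0L, span)
      handled[sides] <- TRUE
    } else {
      add_row("multiloop_segment", b - a + 1L, 0L, rbind(c(a, b)))
      handled[ri] <- TRUE
    }
  }

  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(molecule_id = character(), kind = character(),
           length = integer(), gu_count = integer(),
           span = list(), pos5 = integer())
  }
  dplyr::arrange(out, .data$pos5)
}

split_runs <- function(idx) {
  if (!length(idx)) return(list())
  breaks <- which(diff(idx) > 1L)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  lapply(seq_along(starts), function(k) c(idx[starts[k]], idx[ends[k]]))
}

#' Define a homology scheme
#'
#' The universe of canonical substructure labels shared by all molecules
#' under comparison, each with its structural kind and folding domain.
#' By convention the S (specificity) domain holds stem P7 and the stems
#' distal to it (including P12 and the coaxial P10-11 tract), while
#' P1-P6, P15 and the rest of the molecule form the C (catalytic)
#' domain.
#'
#' @param labels character vector of unique canonical labels (e.g.
#'   `"P1"`, `"P12"`, `"L15"`, `"U5end"`).
#' @param kinds substructure kind for each label: `stem`, `hairpin`,
#'   `bulge`, `internal_loop`, `multiloop_segment`, `joint`, `free_end`.
#' @param domains folding-domain tag for each label: `"S"`, `"C"` or
#'   `"none"`.
#' @return a tibble of class `homology_scheme`.
#' @export
homology_scheme <- function(labels, kinds,
                            domains = rep("none", length(labels))) {
  kinds_ok <- c("stem", "hairpin", "bulge", "internal_loop",
                "multiloop_segment", "joint", "free_end")
  if (anyDuplicated(labels)) abort("scheme labels must be unique")
  if (length(kinds) != length(labels) || length(domains) != length(labels)) {
    abort("labels, kinds and domains must have equal length")
  }
  if (!all(kinds %in% kinds_ok)) {
    abort(sprintf("unknown kind(s): %s",
                  paste(setdiff(kinds, kinds_ok), collapse = ", ")))
  }
  if (!all(domains %in% c("S", "C", "none"))) {
    abort("domains must be 'S', 'C' or 'none'")
  }
  structure(
    tibble(label = as.character(labels), kind = kinds, domain = domains),
    class = c("homology_scheme", "tbl_df", "tbl", "data.frame")
  )
}

#' Read a homology scheme from TSV
#'
#' Columns `label`, `kind` and optionally `domain`.
#'
#' @param path file path.
#' @return a [homology_scheme()].
#' @export
read_scheme <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  homology_scheme(df$label, df$kind,
                  if ("domain" %in% names(df)) df$domain
                  else rep("none", nrow(df)))
}

#' Attach canonical homology labels to decomposed substructures
#'
#' Each decomposed substructure is matched against annotation intervals;
#' substructures annotated with the same label are merged (this is how
#' coaxial stem tracts such as P10-11 become single characters: the
#' stems add their base pairs, enclosed unpaired residues are absorbed
#' into the span without contributing to the length).  Labels from the
#' scheme universe with no matching substructure are emitted with length
#' 0, so every molecule reports every character.  A label whose
#' scheme kind has no representative of that kind among its matched
#' substructures (e.g. a hairpin annotated with a stem label) is an
#' error.
#'
#' @param subs tibble from [decompose_structure()] (one or more molecules).
#' @param scheme a [homology_scheme()].
#' @param annotation tibble with `molecule_id`, `start`, `end`, `label`
#'   (1-based inclusive, as from [read_annotation()]).
#' @return a tibble like `subs` with a `label` column; unannotated
#'   substructures keep `label = NA` and are ignored by
#'   [build_char_matrix()].
#' @export
label_substructures <- function(subs, scheme, annotation) {
  stopifnot(inherits(scheme, "homology_scheme"))
  bad <- setdiff(annotation$label, scheme$label)
  if (length(bad)) {
    abort(sprintf("annotation label(s) outside the scheme universe: %s",
                  paste(unique(bad), collapse = ", ")))
  }
  ann <- dplyr::mutate(annotation, start0 = .data$start - 1L,
                       end0 = .data$end - 1L)
  out <- vector("list", length = 0L)
  for (mol in unique(subs$molecule_id)) {
    smol <- subs[subs$molecule_id == mol, ]
    amol <- ann[ann$molecule_id == mol, ]
    lab <- rep(NA_character_, nrow(smol))
    for (k in seq_len(nrow(smol))) {
      sp <- smol$span[[k]]
      hits <- unique(amol$label[vapply(seq_len(nrow(amol)), function(a) {
        any(sp[, 1] <= amol$end0[a] & sp[, 2] >= amol$start0[a])
      }, logical(1))])
      if (length(hits) > 1L) {
        abort(sprintf(
          "substructure at %d-%d of %s overlaps multiple labels: %s",
          sp[1, 1] + 1L, sp[1, 2] + 1L, mol, paste(hits, collapse = ", ")
        ))
      }
      if (length(hits) == 1L) lab[k] <- hits
    }
    smol$label <- lab
    merged <- list()
    for (L in scheme$label) {
      kind_l <- scheme$kind[scheme$label == L]
      grp <- smol[!is.na(smol$label) & smol$label == L, ]
      if (!nrow(grp)) {
        merged[[L]] <- tibble(
          molecule_id = mol, label = L, kind = kind_l,
          length = 0L, gu_count = 0L, span = list(matrix(integer(0), 0, 2)),
          pos5 = NA_integer_
        )
        next
      }
      match_kind <- if (kind_l == "stem") grp$kind == "stem"
                    else grp$kind == kind_l
      if (!any(match_kind)) {
        abort(sprintf(
          "label %s is annotated as kind '%s' but matched only %s in %s",
          L, kind_l, paste(unique(grp$kind), collapse = "/"), mol
        ))
      }
      core <- grp[match_kind, ]
      merged[[L]] <- tibble(
        molecule_id = mol, label = L, kind = kind_l,
        length = sum(core$length), gu_count = sum(core$gu_count),
        span = list(do.call(rbind, grp$span)),
        pos5 = min(grp$pos5)
      )
    }
    rest <- smol[is.na(smol$label), ]
    out[[mol]] <- dplyr::bind_rows(dplyr::bind_rows(merged), rest)
  }
  dplyr::bind_rows(out)
}
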