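#' Write a character matrix as a NEXUS file
#'
#' Emits a `DATA` block (dimensions, symbol list, matrix), an
#' `ASSUMPTIONS` block declaring every structural character as linearly
#' ordered (`ord`) and sequence columns as unordered (`unord`), and —
#' when the matrix is polarized — a `PAUP` block whose `ANCSTATES`
#' command carries the hypothetical-ancestor states that root the
#' trees.  Character kind/domain/metric metadata travel in bracketed
#' NEXUS comments (ignored by other programs) so that
#' [read_nexus()] recovers the matrix exactly.
#'
#' @param M a [char_matrix()].
#' @param path output file; `NULL` returns the text.
#' @return the NEXUS text, invisibly when written to `path`.
#' @export
write_nexus <- function(M, path = NULL) {
  stopifnot(inherits(M, "char_matrix"))
  taxa <- gsub("[^A-Za-z0-9_.]", "_", rownames(M$states))
  if (anyDuplicated(taxa)) abort("taxon names collide after NEXUS sanitizing")
  wide <- max(nchar(taxa)) + 2L
  sym <- apply(M$states, 2, encode_state)
  if (nrow(M$states) == 1L) sym <- matrix(sym, nrow = 1L)
  rows <- vapply(seq_len(nrow(sym)), function(i) {
    paste0(formatC(taxa[i], width = -wide), paste(sym[i, ], collapse = ""))
  }, character(1))

  ranges <- function(idx) {
    if (!length(idx)) return(NULL)
    br <- c(0L, which(diff(idx) > 1L), length(idx))
    paste(vapply(seq_len(length(br) - 1L), function(k) {
      a <- idx[br[k] + 1L]; b <- idx[br[k + 1L]]
      if (a == b) as.character(a) else paste0(a, "-", b)
    }, character(1)), collapse = " ")
  }
  ord_idx <- which(M$chars$ordered)
  unord_idx <- which(!M$chars$ordered)
  typeset <- paste0(
    "  TYPESET * polarity = ",
    paste(c(
      if (length(ord_idx)) paste0("ord: ", ranges(ord_idx)),
      if (length(unord_idx)) paste0("unord: ", ranges(unord_idx))
    ), collapse = ", "),
    ";"
  )

  out <- c(
    "#NEXUS",
    "[structural character matrix written by rnaclad]",
    sprintf("[CHARIDS %s]", paste(M$chars$char_id, collapse = " ")),
    sprintf("[KINDS %s]", paste(M$chars$kind, collapse = " ")),
    sprintf("[DOMAINS %s]", paste(M$chars$domain, collapse = " ")),
    sprintf("[METRICS %s]", paste(M$chars$metric, collapse = " ")),
    sprintf("[ORIENTATION %s]", M$orientation),
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(M$states), ncol(M$states)),
    paste0("  FORMAT SYMBOLS=\"", paste(state_alphabet, collapse = ""),
           "\" MISSING=?;"),
    "  MATRIX",
    rows,
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    typeset,
    "END;"
  )
  if (!is.null(M$ancestor)) {
    out <- c(out,
      "BEGIN PAUP;",
      paste0("  ANCSTATES polarized VECTOR = ",
             paste(encode_state(M$ancestor), collapse = ""), ";"),
      "END;"
    )
  }
  txt <- paste(out, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a NEXUS character matrix written by [write_nexus()]
#'
#' Parses the `DATA` block (dimensions, matrix), the `ASSUMPTIONS`
#' typeset (ordered/unordered columns) and any `PAUP` `ANCSTATES`
#' vector; the bracketed metadata comments are honoured when present
#' and sensible defaults are used otherwise.
#'
#' @param text NEXUS text, or a path to a file.
#' @return a [char_matrix()].
#' @export
read_nexus <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  if (!grepl("^\\s*#NEXUS", text, ignore.case = TRUE)) {
    abort("not a NEXUS file (missing #NEXUS header)")
  }
  grab_comment <- function(key) {
    m <- stringr::str_match(text, sprintf("\\[%s ([^\\]]*)\\]", key))[, 2]
    if (is.na(m)) NULL else strsplit(trimws(m), "\\s+")[[1]]
  }
  char_ids <- grab_comment("CHARIDS")
  kinds <- grab_comment("KINDS")
  domains <- grab_comment("DOMAINS")
  metrics <- grab_comment("METRICS")
  orientation <- grab_comment("ORIENTATION")

  dims <- stringr::str_match(
    text, stringr::regex("DIMENSIONS\\s+NTAX\\s*=\\s*(\\d+)\\s+NCHAR\\s*=\\s*(\\d+)\\s*;",
                         ignore_case = TRUE))
  if (is.na(dims[1, 1])) abort("malformed DATA block: DIMENSIONS not found")
  ntax <- as.integer(dims[1, 2]); nchar_ <- as.integer(dims[1, 3])

  mat <- stringr::str_match(
    text, stringr::regex("MATRIX\\s*\n(.*?)\n\\s*;", dotall = TRUE,
                         ignore_case = TRUE))[, 2]
  if (is.na(mat)) abort("malformed DATA block: MATRIX not found")
  mrows <- strsplit(mat, "\n")[[1]]
  mrows <- trimws(mrows)
  mrows <- mrows[nzchar(mrows)]
  if (length(mrows) != ntax) {
    abort(sprintf("MATRIX has %d rows but NTAX=%d", length(mrows), ntax))
  }
  taxa <- character(ntax)
  states <- matrix(NA_integer_, ntax, nchar_)
  for (i in seq_len(ntax)) {
    f <- strsplit(mrows[i], "\\s+")[[1]]
    taxa[i] <- f[1]
    symbols <- strsplit(paste(f[-1], collapse = ""), "")[[1]]
    if (length(symbols) != nchar_) {
      abort(sprintf("row %s has %d symbols, expected %d",
                    taxa[i], length(symbols), nchar_))
    }
    states[i, ] <- decode_state(symbols)
  }
  rownames(states) <- taxa

  ordered <- rep(TRUE, nchar_)
  ts <- stringr::str_match(
    text, stringr::regex("TYPESET[^=]*=\\s*([^;]*);", ignore_case = TRUE))[, 2]
  if (!is.na(ts)) {
    expand <- function(spec) {
      unlist(lapply(strsplit(trimws(spec), "\\s+")[[1]], function(tok) {
        ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
        if (length(ab) == 2L) seq(ab[1], ab[2]) else ab
      }))
    }
    for (part in strsplit(ts, ",")[[1]]) {
      kv <- strsplit(part, ":", fixed = TRUE)[[1]]
      if (length(kv) != 2L) next
      idx <- expand(kv[2])
      ordered[idx] <- trimws(tolower(kv[1])) == "ord"
    }
  }

  anc <- NULL
  am <- stringr::str_match(
    text, stringr::regex("ANCSTATES[^=]*=\\s*([^;]*);", ignore_case = TRUE))[, 2]
  if (!is.na(am)) {
    anc <- decode_state(strsplit(gsub("\\s", "", am), "")[[1]])
    if (length(anc) != nchar_) {
      abort("ANCSTATES vector length does not match NCHAR")
    }
  }

  if (is.null(kinds)) kinds <- ifelse(ordered, "stabilizing", "sequence")
  chars <- tibble(
    char_id = char_ids %||% paste0("char", seq_len(nchar_)),
    kind = kinds,
    domain = domains %||% rep("none", nchar_),
    metric = metrics %||% ifelse(ordered, "stem_bp", "aligned_site"),
    ordered = ordered
  )
  char_matrix(states, chars, ancestor = anc,
              orientation = (orientation %||% "molecules_as_taxa")[1])
}
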