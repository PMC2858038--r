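#' Alphanumeric character-state codec
#'
#' Character states are written in alphanumeric format: integer values
#' 0-9 map to digits `'0'`-`'9'`, 10-35 to `'A'`-`'Z'` and 36-61 to
#' `'a'`-`'z'`.  Values above 61 are clamped to `'z'` with a warning so
#' the symbol alphabet stays closed; `NA` (missing) encodes as `'?'`.
#'
#' @param value integer vector of non-negative state values (`NA` allowed).
#' @param symbol character vector of single state symbols.
#' @return `encode_state()` returns a character vector of single symbols;
#'   `decode_state()` returns an integer vector (`'?'` decodes to `NA`).
#' @examples
#' encode_state(c(0, 9, 10, 35, 36, 61))
#' decode_state(c("0", "A", "a", "z", "?"))
#' @export
encode_state <- function(value) {
  if (!is.numeric(value)) abort("`value` must be numeric")
  value <- as.integer(value)
  if (any(value < 0, na.rm = TRUE)) {
    abort("character states must be non-negative")
  }
  over <- !is.na(value) & value > 61L
  if (any(over)) {
    warn(sprintf(
      "%d state value(s) exceed 61 and were clamped to 'z'", sum(over)
    ))
    value[over] <- 61L
  }
  out <- rep("?", length(value))
  ok <- !is.na(value)
  out[ok] <- state_alphabet[value[ok] + 1L]
  out
}

#' @rdname encode_state
#' @export
decode_state <- function(symbol) {
  if (!is.character(symbol)) abort("`symbol` must be character")
  idx <- match(symbol, state_alphabet)
  bad <- is.na(idx) & !symbol %in% c("?", NA)
  if (any(bad)) {
    abort(sprintf(
      "unknown state symbol(s): %s",
      paste(unique(symbol[bad]), collapse = ", ")
    ))
  }
  as.integer(idx - 1L)
}

state_alphabet <- c(as.character(0:9), LETTERS, letters)
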