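#' Corpus text objects
#'
#' A `corpus_text` holds a decoded symbol sequence together with its
#' provenance. In code-point mode the symbols are Unicode scalar values; in
#' byte mode they are raw byte values 0-255. All search functions accept
#' either a plain character scalar or a `corpus_text`.
#'
#' @param x A character scalar, or an integer vector of symbols.
#' @param source_id Identifier of the text (file name, FASTA record id, ...).
#' @param encoding Label of the source encoding, e.g. `"UTF-8"`.
#' @param mode `"codepoint"` (default) or `"byte"`.
#' @return An object of class `corpus_text` with fields `symbols`,
#'   `source_id`, `encoding`, `mode` and length `n`.
#' @examples
#' txt <- corpus_text("HELOGEMLED", source_id = "demo")
#' txt$n
#' @export
corpus_text <- function(x, source_id = "text", encoding = "UTF-8",
                        mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    symbols <- string_to_symbols(x, mode)
  } else if (is.numeric(x)) {
    symbols <- as.integer(x)
    if (mode == "byte" && length(symbols) &&
        (min(symbols) < 0L || max(symbols) > 255L)) {
      stop("byte-mode symbols must lie in 0..255")
    }
  } else {
    stop("`x` must be a character scalar or an integer vector of symbols")
  }
  structure(
    list(symbols = symbols, source_id = source_id, encoding = encoding,
         mode = mode, n = length(symbols)),
    class = "corpus_text")
}

#' @export
print.corpus_text <- function(x, ...) {
  cat(sprintf("<corpus_text '%s': %d symbols, %s mode, %s>\n",
              x$source_id, x$n, x$mode, x$encoding))
  preview <- symbols_to_string(head(x$symbols, 60L), x$mode)
  cat(" ", preview, if (x$n > 60L) "...", "\n")
  invisible(x)
}

#' @export
length.corpus_text <- function(x) x$n

#' @export
as.character.corpus_text <- function(x, ...) symbols_to_string(x$symbols, x$mode)

# Decode a character scalar into integer symbols.
string_to_symbols <- function(x, mode = "codepoint") {
  if (mode == "byte") return(as.integer(charToRaw(x)))
  out <- utf8ToInt(enc2utf8(x))
  if (anyNA(out)) stop("input is not valid UTF-8")
  out
}

# Re-encode integer symbols as a character scalar.
symbols_to_string <- function(symbols, mode = "codepoint") {
  if (length(symbols) == 0L) return("")
  if (mode == "byte") return(rawToChar(as.raw(symbols)))
  intToUtf8(symbols)
}

# Normalise any supported text argument to an integer symbol vector, and
# keep track of the source id for occurrence reporting.
resolve_text <- function(text, mode = "codepoint") {
  if (inherits(text, "corpus_text")) {
    list(symbols = text$symbols, source_id = text$source_id, mode = text$mode)
  } else if (is.character(text)) {
    stopifnot(length(text) == 1L)
    list(symbols = string_to_symbols(text, mode), source_id = "text",
         mode = mode)
  } else if (is.numeric(text)) {
    list(symbols = as.integer(text), source_id = "text", mode = mode)
  } else {
    stop("`text` must be a character scalar, corpus_text, or integer vector")
  }
}

# Normalise a pattern to integer symbols in the same mode as the text.
resolve_pattern <- function(pattern, mode = "codepoint") {
  if (is.character(pattern)) {
    stopifnot(length(pattern) == 1L)
    out <- string_to_symbols(pattern, mode)
  } else if (is.numeric(pattern)) {
    out <- as.integer(pattern)
  } else if (inherits(pattern, "pattern_split")) {
    out <- string_to_symbols(pattern$pattern, mode)
  } else {
    stop("`pattern` must be a character scalar or integer symbol vector")
  }
  if (length(out) == 0L) stop("empty pattern has no defined split or match")
  out
}

# Render pattern symbols back to a string for report columns.
pattern_label <- function(pattern, mode = "codepoint") {
  if (is.character(pattern)) pattern
  else if (inherits(pattern, "pattern_split")) pattern$pattern
  else symbols_to_string(as.integer(pattern), mode)
}

# Case folding used by the ignore_case flags: simple lowercase mapping of
# the code points (byte mode folds only ASCII A-Z).
fold_symbols <- function(symbols, mode = "codepoint") {
  if (mode == "byte") {
    up <- symbols >= 65L & symbols <= 90L
    symbols[up] <- symbols[up] + 32L
    return(symbols)
  }
  string_to_symbols(tolower(symbols_to_string(symbols, mode)), mode)
}
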