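#' Read a plain-text corpus
#'
#' Reads the whole file as one searchable symbol sequence. In code-point
#' mode the bytes are decoded from `encoding` to Unicode code points; in
#' byte mode the raw bytes are the symbols. Windows line endings are
#' normalised to `"\n"`; newlines then remain ordinary searchable symbols.
#'
#' @param path File path.
#' @param encoding Source encoding (code-point mode only), default UTF-8.
#' @param mode `"codepoint"` (default) or `"byte"`.
#' @param nfc Apply Unicode NFC normalisation after decoding (code-point
#'   mode; requires the stringi package). Off by default: by default the
#'   symbols searched are exactly the decoded code points.
#' @return A [corpus_text()] whose `source_id` is the file's base name.
#' @export
read_text <- function(path, encoding = "UTF-8",
                      mode = c("codepoint", "byte"), nfc = FALSE) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, what = "raw", n = file.size(path))
  # universal newline translation
  raw <- raw[!(raw == as.raw(13L) & c(raw[-1L], as.raw(0L)) == as.raw(10L))]
  raw[raw == as.raw(13L)] <- as.raw(10L)
  if (mode == "byte") {
    return(corpus_text(as.integer(raw), source_id = basename(path),
                       encoding = encoding, mode = "byte"))
  }
  s <- rawToChar(raw)
  if (toupper(encoding) %in% c("UTF-8", "UTF8", "ASCII")) {
    Encoding(s) <- "UTF-8"
  } else {
    s <- iconv(s, from = encoding, to = "UTF-8")
    if (is.na(s)) stop("file ", path, " cannot be decoded from ", encoding)
  }
  if (!validUTF8(s)) {
    off <- utf8_error_offset(raw)
    stop("invalid ", encoding, " byte sequence in ", path,
         " at byte offset ", off)
  }
  if (nfc) {
    if (!requireNamespace("stringi", quietly = TRUE)) {
      stop("NFC normalisation requires the 'stringi' package")
    }
    s <- stringi::stri_trans_nfc(s)
  }
  corpus_text(s, source_id = basename(path), encoding = encoding,
              mode = "codepoint")
}

# 0-based byte offset of the first invalid UTF-8 byte.
utf8_error_offset <- function(raw) {
  for (i in seq_along(raw)) {
    s <- rawToChar(raw[seq_len(i)])
    Encoding(s) <- "UTF-8"
    # a prefix ending inside a multibyte char is invalid but may become
    # valid again; find the first position after which validity never
    # recovers
    if (!validUTF8(s) && (i == length(raw) ||
        !any(vapply(seq(i + 1L, min(i + 4L, length(raw))), function(j) {
          t <- rawToChar(raw[seq_len(j)]); Encoding(t) <- "UTF-8"; validUTF8(t)
        }, logical(1))))) {
      return(i - 1L)
    }
  }
  length(raw)
}

#' Read a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()]: one record per header, wrapped
#' sequence lines concatenated. The header is split into an `id` (first
#' whitespace-delimited token) and a `description` (the remainder).
#' Records with empty sequences are dropped with a warning.
#'
#' @param path FASTA file path.
#' @return A list of `fasta_record` objects, each with `id`, `description`
#'   and `sequence` fields, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    seq <- as.character(set[[i]])
    if (id == "") stop("FASTA record ", i, " has an empty id")
    structure(list(id = id, description = desc, sequence = seq),
              class = "fasta_record")
  })
  empty <- vapply(out, function(r) nchar(r$sequence) == 0L, logical(1))
  if (any(empty)) {
    warning("skipping ", sum(empty), " FASTA record(s) with empty sequence")
    out <- out[!empty]
  }
  out
}

#' Write FASTA records
#'
#' @param records List of `fasta_record` objects (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  seqs <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(seqs) <- vapply(records, function(r) {
    if (nzchar(r$description)) paste(r$id, r$description) else r$id
  }, "")
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' @export
print.fasta_record <- function(x, ...) {
  cat(sprintf("<fasta_record %s (%d nt/aa)%s>\n", x$id, nchar(x$sequence),
              if (nzchar(x$description)) paste0(" ", x$description) else ""))
  invisible(x)
}

#' Reverse complement of a DNA sequence
#'
#' Accepts A/C/G/T/N in either case; case is preserved and N maps to N.
#' Any other symbol is an error that names the offending character and its
#' 1-based position.
#'
#' @param sequence Character scalar over the DNA alphabet.
#' @return The reverse-complemented sequence.
#' @examples
#' reverse_complement("AAC")  # "GTT"
#' @export
reverse_complement <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N",
                             "a", "c", "g", "t", "n"))
  if (length(bad)) {
    stop("non-ACGTN symbol '", chars[bad[1L]], "' at position ", bad[1L])
  }
  comp <- chartr("ACGTacgt", "TGCAtgca", sequence)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Read a pattern list
#'
#' One pattern per line; the trailing newline is the only thing stripped,
#' so internal spaces (multi-word queries) survive verbatim. Blank lines
#' are skipped.
#'
#' @param path File path.
#' @param encoding Source encoding, default UTF-8.
#' @return Character vector of patterns in file order.
#' @export
read_patterns <- function(path, encoding = "UTF-8") {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, encoding = encoding)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  pats <- lines[nzchar(lines)]
  if (length(pats) == 0L) stop("no usable patterns in ", path)
  pats
}

#' Search FASTA records
#'
#' Runs an exact-search algorithm over each record independently (no
#' cross-record matches); optionally also scans the reverse complement of
#' the pattern, reporting those hits on the minus strand in plus-strand
#' coordinates.
#'
#' @param pattern Character scalar.
#' @param records List of `fasta_record`s, or a FASTA file path.
#' @param algorithm Registered algorithm name (default `"split"`).
#' @param both_strands Also search the pattern's reverse complement.
#' @param ignore_case Case-fold before matching.
#' @return Data frame with columns `source_id`, `pattern`, `start`, `end`
#'   (0-based half-open), `strand`, plus a `stats` attribute (summed
#'   comparison counts).
#' @export
search_fasta <- function(pattern, records, algorithm = "split",
                         both_strands = FALSE, ignore_case = FALSE) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_fasta(records)
  }
  fn <- algorithm_fn(algorithm)
  queries <- data.frame(pattern = pattern, strand = "+",
                        stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- reverse_complement(pattern)
    if (!identical(rc, pattern)) {
      queries <- rbind(queries, data.frame(pattern = rc, strand = "-"))
    } else {
      queries$strand <- "+/-"   # palindromic pattern: strands coincide
    }
  }
  total <- 0
  rows <- list()
  for (rec in records) {
    txt <- corpus_text(rec$sequence, source_id = rec$id)
    for (q in seq_len(nrow(queries))) {
      res <- fn(queries$pattern[q], txt, ignore_case = ignore_case)
      total <- total + res$stats$total_cmps
      if (nrow(res$occurrences)) {
        occ <- res$occurrences
        occ$pattern <- pattern        # report the query, not its complement
        occ$strand <- queries$strand[q]
        rows[[length(rows) + 1L]] <- occ
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(source_id = character(), pattern = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$source_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_cmps") <- total
  out
}

#' Write occurrences to TSV, JSON or BED
#'
#' TSV and JSON carry `source_id`, `pattern`, `start`, `end`, the algorithm
#' name and the comparison counts. Coordinates are 0-based half-open;
#' `one_based = TRUE` switches the TSV to 1-based inclusive. BED (0-based
#' half-open by definition) is only available for FASTA searches, i.e. when
#' a `strand` column is present.
#'
#' @param result A `match_result`, or a data frame as returned by
#'   [search_fasta()].
#' @param path Output path.
#' @param format `"tsv"`, `"json"` or `"bed"`.
#' @param one_based Render TSV coordinates 1-based inclusive.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(result, path, format = c("tsv", "json", "bed"),
                              one_based = FALSE) {
  format <- match.arg(format)
  if (inherits(result, "match_result")) {
    occ <- result$occurrences
    occ$algorithm <- rep(result$algorithm, nrow(occ))
    stats <- result$stats
  } else {
    occ <- as.data.frame(result)
    if (is.null(occ$algorithm)) occ$algorithm <- rep(NA_character_, nrow(occ))
    stats <- list(total_cmps = attr(result, "total_cmps"))
  }
  if (format == "bed") {
    if (is.null(occ$strand)) {
      stop("BED output requires a FASTA search result (strand column)")
    }
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     occ$source_id, occ$start, occ$end, occ$pattern,
                     occ$strand)
    writeLines(lines, path)
    return(invisible(path))
  }
  if (format == "json") {
    payload <- list(
      occurrences = occ,
      stats = lapply(
        stats[!vapply(stats, is.null, logical(1))], as.numeric))
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
    writeLines(json, path)
    return(invisible(path))
  }
  # tsv
  tsv <- occ
  if (one_based) {
    tsv$start <- tsv$start + 1L   # 1-based inclusive: end is unchanged
  }
  header <- sprintf("# total_cmps=%s",
                    format(if (is.null(stats$total_cmps)) NA else
                           stats$total_cmps, scientific = FALSE))
  con <- if (inherits(path, "connection")) path else {
    con <- file(path, "w")
    on.exit(close(con))
    con
  }
  writeLines(header, con)
  suppressWarnings(utils::write.table(
    tsv, con, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
  invisible(path)
}
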