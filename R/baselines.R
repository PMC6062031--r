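#' Brute-force exact search (ground-truth comparator)
#'
#' Classical window-by-window matcher: at each alignment the pattern is
#' verified left to right until a mismatch, and the window advances by one.
#' Its occurrence set is the ground truth against which all other
#' algorithms in the package are validated.
#'
#' @inheritParams split_find_all
#' @return A `match_result`; all comparisons are reported in
#'   `stats$p2_cmps`-free form: `total_cmps` carries the count, the
#'   split-specific phase fields are zero.
#' @examples
#' brute_force_find_all("OGEM", "HELOGEMLED")$occurrences$start  # 3
#' @export
brute_force_find_all <- function(pattern, text, ignore_case = FALSE,
                                 mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  a <- prepare_search(pattern, text, mode, ignore_case)
  res <- .cpp_brute_search(a$pat, a$txt)
  make_match_result(res, pattern, a$src, "brute", a$mode)
}

#' Bad-character shift tables
#'
#' `build_horspool_table()` returns the Horspool table: for every character
#' occurring in `pattern[1..m-1]` (all but the last position), the shift is
#' `m - 1 - r` where `r` is the character's rightmost 0-based index in that
#' prefix; every other character shifts by `m`. `build_quick_search_table()`
#' returns the Quick Search table keyed on the character just after the
#' window: shift `m - r` with `r` the rightmost index in the whole pattern,
#' default `m + 1`.
#'
#' @inheritParams split_pattern
#' @return An object of class `bad_char_table`: integer `shifts` named by
#'   character, a `default` shift, the `variant`, and the raw code-point
#'   `keys`.
#' @examples
#' build_horspool_table("OGEM")      # O:3 G:2 E:1, default 4
#' build_quick_search_table("OGEM")  # O:4 G:3 E:2 M:1, default 5
#' @export
build_horspool_table <- function(pattern, mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  sym <- resolve_pattern(pattern, mode)
  m <- length(sym)
  prefix <- sym[seq_len(m - 1L)]          # empty when m = 1
  keys <- unique(prefix)
  shifts <- vapply(keys, function(c) m - max(which(prefix == c)), integer(1))
  new_bad_char_table(keys, shifts, default = m, variant = "horspool",
                     mode = mode)
}

#' @rdname build_horspool_table
#' @export
build_quick_search_table <- function(pattern, mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  sym <- resolve_pattern(pattern, mode)
  m <- length(sym)
  keys <- unique(sym)
  shifts <- vapply(keys, function(c) m - (max(which(sym == c)) - 1L), integer(1))
  new_bad_char_table(keys, shifts, default = m + 1L, variant = "quick_search",
                     mode = mode)
}

new_bad_char_table <- function(keys, shifts, default, variant, mode) {
  keys <- as.integer(keys); shifts <- as.integer(shifts)
  names(shifts) <- vapply(keys, function(k) symbols_to_string(k, mode), "")
  structure(
    list(shifts = shifts, keys = keys, default = as.integer(default),
         variant = variant, mode = mode),
    class = "bad_char_table")
}

#' @export
print.bad_char_table <- function(x, ...) {
  cat(sprintf("<bad_char_table (%s): default %d>\n", x$variant, x$default))
  if (length(x$shifts)) print(x$shifts)
  invisible(x)
}

#' Good-suffix shift table
#'
#' Strong good-suffix shifts for Boyer-Moore, indexed by the 0-based
#' mismatch position `j` (after the suffix `pattern[(j+2)..m]` in 1-based
#' terms has matched). Every entry lies in `[1, m]`. Computed with the
#' classical linear-time suffixes-array construction.
#'
#' @inheritParams split_pattern
#' @return Integer vector of length `m`; element `j + 1` is the shift for a
#'   mismatch at 0-based position `j`.
#' @examples
#' build_good_suffix_table("ABCAB")
#' @export
build_good_suffix_table <- function(pattern, mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  .cpp_good_suffix_table(resolve_pattern(pattern, mode))
}

#' Horspool exact search
#'
#' Right-to-left window verification; on leaving a window (match or
#' mismatch) the shift is the Horspool bad-character entry of the text
#' character aligned with the window's last position. No good-suffix rule.
#'
#' @inheritParams split_find_all
#' @return A `match_result`.
#' @export
horspool_find_all <- function(pattern, text, ignore_case = FALSE,
                              mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  a <- prepare_search(pattern, text, mode, ignore_case)
  tab <- build_horspool_table(a$pat, mode = a$mode)
  res <- .cpp_horspool_search(a$pat, a$txt, tab$keys, unname(tab$shifts),
                              tab$default)
  make_match_result(res, pattern, a$src, "horspool", a$mode)
}

#' Boyer-Moore exact search
#'
#' Right-to-left window verification; the shift is the maximum of the strong
#' good-suffix shift and the bad-character shift (floored at 1). After a
#' full match the window advances by the pattern period, so overlapping
#' occurrences are reported.
#'
#' @inheritParams split_find_all
#' @return A `match_result`.
#' @export
boyer_moore_find_all <- function(pattern, text, ignore_case = FALSE,
                                 mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  a <- prepare_search(pattern, text, mode, ignore_case)
  keys <- unique(a$pat)
  last <- vapply(keys, function(c) max(which(a$pat == c)) - 1L, integer(1))
  res <- .cpp_bm_search(a$pat, a$txt, keys, last)
  make_match_result(res, pattern, a$src, "bm", a$mode)
}

#' Quick Search exact search
#'
#' Left-to-right window verification; after every window the shift is the
#' Quick-Search bad-character entry of the text character immediately
#' following the window (default `m + 1` when that character does not occur
#' in the pattern).
#'
#' @inheritParams split_find_all
#' @return A `match_result`.
#' @export
quick_search_find_all <- function(pattern, text, ignore_case = FALSE,
                                  mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  a <- prepare_search(pattern, text, mode, ignore_case)
  tab <- build_quick_search_table(a$pat, mode = a$mode)
  res <- .cpp_quick_search(a$pat, a$txt, tab$keys, unname(tab$shifts),
                           tab$default)
  make_match_result(res, pattern, a$src, "qs", a$mode)
}
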