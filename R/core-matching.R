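#' Split a pattern into its two halves
#'
#' The query pattern of length `m` is divided into a left half `p1` of length
#' `m1 = floor(m/2)` and a right half `p2` of length `m2 = ceiling(m/2)`:
#' when `m` is odd the right half receives the extra character. The right
#' half is the part searched first; the left half is only verified once the
#' right half has matched.
#'
#' @param pattern A nonempty character scalar (or integer symbol vector).
#' @param mode Symbol mode used when `pattern` is a string, see
#'   [corpus_text()].
#' @return An object of class `pattern_split` with fields `pattern`, `p1`,
#'   `p2`, `m`, `m1`, `m2`.
#' @examples
#' split_pattern("OGEM")   # p1 = "OG", p2 = "EM"
#' split_pattern("WORLD")  # p1 = "WO", p2 = "RLD"
#' @export
split_pattern <- function(pattern, mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  sym <- resolve_pattern(pattern, mode)
  m <- length(sym)
  m1 <- m %/% 2L
  m2 <- m - m1
  structure(
    list(pattern = pattern_label(pattern, mode),
         p1 = symbols_to_string(sym[seq_len(m1)], mode),
         p2 = symbols_to_string(sym[(m1 + 1L):m], mode),
         m = m, m1 = m1, m2 = m2),
    class = "pattern_split")
}

#' @export
print.pattern_split <- function(x, ...) {
  cat(sprintf("<pattern_split '%s' (m = %d): p1 = '%s' (m1 = %d), p2 = '%s' (m2 = %d)>\n",
              x$pattern, x$m, x$p1, x$m1, x$p2, x$m2))
  invisible(x)
}

#' Map an anchor position to the left-half window
#'
#' Given the 0-based text index `i0` at which the last character of the
#' right half `p2` matched, the last character of the left-half window sits
#' at `pmap = i0 - m2`, where `m2` is the right-half length. For a window
#' starting at `s` this equals `s + m1 - 1`.
#'
#' @param i0 0-based anchor index (vectorised).
#' @param m2 Right-half length (scalar or vectorised).
#' @return Integer vector of 0-based `pmap` indices.
#' @examples
#' map_left_window(6, 2)  # 4
#' @export
map_left_window <- function(i0, m2) {
  i0 <- as.integer(i0); m2 <- as.integer(m2)
  if (any(m2 < 1L)) stop("`m2` must be at least 1")
  if (any(i0 < m2)) stop("anchor index `i0` must be >= `m2`: the left-half window would extend past the text start")
  i0 - m2
}

# Build the user-facing result object from a C++ search result.
make_match_result <- function(res, pattern, src, algorithm, mode) {
  m <- length(resolve_pattern(pattern, mode))
  starts <- as.integer(res$starts)
  occ <- data.frame(
    source_id = rep(src$source_id, length(starts)),
    pattern = rep(pattern_label(pattern, mode), length(starts)),
    start = starts,
    end = starts + m,
    stringsAsFactors = FALSE)
  stats <- structure(
    list(alignments = res$alignments,
         anchor_cmps = res$anchor_cmps,
         p2_cmps = res$p2_cmps,
         p1_cmps = res$p1_cmps,
         total_cmps = res$total_cmps,
         matches = length(starts)),
    class = "search_stats")
  out <- structure(
    list(occurrences = occ, stats = stats, algorithm = algorithm,
         pattern = pattern_label(pattern, mode), m = m, n = length(src$symbols),
         mode = mode),
    class = "match_result")
  if (!is.null(res$trace)) {
    tr <- res$trace
    tr$char <- vapply(tr$symbol, function(s) symbols_to_string(s, mode), "")
    out$trace <- tr
  }
  out
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: '%s' (m = %d) vs %d symbols, algorithm = %s>\n",
              x$pattern, x$m, x$n, x$algorithm))
  cat(sprintf("  %d occurrence(s); %g alignment(s), %g comparison(s)\n",
              nrow(x$occurrences), x$stats$alignments, x$stats$total_cmps))
  if (nrow(x$occurrences)) print(head(x$occurrences, 10L))
  invisible(x)
}

#' @export
print.search_stats <- function(x, ...) {
  cat("<search_stats>\n")
  for (f in names(x)) cat(sprintf("  %-11s %g\n", f, if (is.null(x[[f]]) || is.na(x[[f]])) NA else x[[f]]))
  invisible(x)
}

# Shared argument handling for all find_all-style front ends.
prepare_search <- function(pattern, text, mode, ignore_case) {
  src <- resolve_text(text, mode)
  mode <- src$mode
  pat <- resolve_pattern(pattern, mode)
  txt <- src$symbols
  if (ignore_case) {
    pat <- fold_symbols(pat, mode)
    txt <- fold_symbols(txt, mode)
  }
  list(pat = pat, txt = txt, src = src, mode = mode)
}

#' Find all exact occurrences with the split algorithm
#'
#' Searches `text` for every (possibly overlapping) occurrence of `pattern`
#' using the split method: at each alignment the last character of the right
#' half is compared first (the anchor); on an anchor hit the remaining right
#' half is verified right to left, then the left half is verified inside the
#' window ending at `pmap = i0 - m2`. The window always advances by exactly
#' one position -- no shift table and no preprocessing.
#'
#' Two anchor-scan conventions are available. `anchor_scan = "window"`
#' (default) examines every full-pattern window `s = 0..n-m`, so the number
#' of alignments is `n - m + 1` and every alignment costs exactly one anchor
#' comparison. `anchor_scan = "p2"` slides the right half alone from the
#' text start (anchor index `i0 = m2-1 .. n-1`), discarding right-half
#' matches whose left half would fall off the text; this reproduces the
#' textbook worked trace of the method and performs `n - m2 + 1` anchor
#' comparisons. Both conventions return the identical occurrence set.
#'
#' @param pattern Nonempty character scalar or integer symbol vector.
#' @param text Character scalar, [corpus_text()] or integer symbol vector.
#' @param anchor_scan `"window"` or `"p2"`, see Details.
#' @param trace If `TRUE`, attach a data frame of every anchor comparison
#'   (`i0`, symbol, whether it hit).
#' @param ignore_case Case-fold pattern and text before matching.
#' @param mode Symbol mode when `pattern`/`text` are plain strings.
#' @return A `match_result`: occurrence table (`source_id`, `pattern`,
#'   0-based half-open `start`/`end`), a `search_stats` record
#'   (`alignments`, `anchor_cmps`, `p2_cmps`, `p1_cmps`, `total_cmps`,
#'   `matches`) and optionally the anchor trace.
#' @examples
#' res <- split_find_all("OGEM", "HELOGEMLED")
#' res$occurrences$start  # 3
#' @export
split_find_all <- function(pattern, text, anchor_scan = c("window", "p2"),
                           trace = FALSE, ignore_case = FALSE,
                           mode = c("codepoint", "byte")) {
  anchor_scan <- match.arg(anchor_scan)
  mode <- match.arg(mode)
  a <- prepare_search(pattern, text, mode, ignore_case)
  res <- .cpp_split_search(a$pat, a$txt, p2_scan = (anchor_scan == "p2"),
                           trace = trace)
  make_match_result(res, pattern, a$src, "split", a$mode)
}

#' Count exact occurrences
#'
#' @inheritParams split_find_all
#' @param algorithm Registered algorithm name (`"split"`, `"brute"`,
#'   `"horspool"`, `"bm"`, `"qs"`).
#' @return Number of occurrences (all algorithms agree; the split algorithm
#'   is the default).
#' @examples
#' count_occurrences("AA", "AAAA")  # 3
#' @export
count_occurrences <- function(pattern, text, algorithm = "split",
                              ignore_case = FALSE,
                              mode = c("codepoint", "byte")) {
  mode <- match.arg(mode)
  fn <- algorithm_fn(algorithm)
  nrow(fn(pattern, text, ignore_case = ignore_case, mode = mode)$occurrences)
}
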