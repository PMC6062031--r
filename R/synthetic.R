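#' Built-in alphabets for synthetic corpora
#'
#' Named alphabets covering the sizes exercised throughout the package's
#' randomized tests: binary (2), DNA (4), the 20 amino acids, and a
#' 64-symbol alphanumeric set approximating a large-script character
#' inventory.
#'
#' @param name `"binary"`, `"dna"`, `"protein"` or `"alnum64"`.
#' @return Character vector of single-character symbols.
#' @export
alphabet <- function(name = c("binary", "dna", "protein", "alnum64")) {
  name <- match.arg(name)
  switch(name,
    binary = c("A", "B"),
    dna = c("A", "C", "G", "T"),
    protein = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
    alnum64 = strsplit(paste0("ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                              "abcdefghijklmnopqrstuvwxyz",
                              "0123456789+/"), "")[[1L]])
}

#' Generate a uniform random text
#'
#' `n` symbols drawn independently and uniformly from `alphabet`,
#' deterministic under `seed` (the caller's RNG state is untouched).
#'
#' @param alphabet Character vector of single-character symbols, or a name
#'   accepted by [alphabet()].
#' @param n Number of symbols (>= 0).
#' @param seed Integer seed.
#' @param source_id Identifier for the generated text.
#' @return A [corpus_text()].
#' @examples
#' gen_uniform_text("dna", 20, seed = 1)
#' @export
gen_uniform_text <- function(alphabet, n, seed, source_id = "uniform") {
  if (is.character(alphabet) && length(alphabet) == 1L &&
      alphabet %in% c("binary", "dna", "protein", "alnum64")) {
    alphabet <- alphabet(alphabet)
  }
  if (length(alphabet) == 0L) stop("empty alphabet")
  stopifnot(n >= 0)
  syms <- string_to_symbols(paste(alphabet, collapse = ""))
  draw <- withr::with_seed(seed,
    sample.int(length(syms), size = n, replace = TRUE))
  corpus_text(syms[draw], source_id = source_id)
}

# Deterministic pseudo-word vocabulary: rank r maps to a lowercase word
# whose letters encode r in base 26, length grows logarithmically.
zipf_vocabulary <- function(vocab_size) {
  vapply(seq_len(vocab_size), function(r) {
    digits <- integer(0)
    x <- r - 1L
    repeat {
      digits <- c(x %% 26L, digits)
      x <- x %/% 26L
      if (x == 0L) break
    }
    paste(letters[digits + 1L], collapse = "")
  }, "")
}

#' Generate a Zipf-distributed word stream
#'
#' A space-separated stream of `n_words` pseudo-words whose rank-frequency
#' distribution follows a power law: word of rank `r` has probability
#' proportional to `r^-exponent`. This emulates natural-language corpora,
#' where a handful of function words dominate and the tail is long.
#'
#' @param vocab_size Vocabulary size (>= 1).
#' @param n_words Number of word tokens (>= 0).
#' @param exponent Zipf exponent (> 0), default 1.
#' @param seed Integer seed.
#' @param source_id Identifier for the generated text.
#' @return A [corpus_text()] of the space-joined stream.
#' @examples
#' gen_zipf_text(100, 50, seed = 1)
#' @export
gen_zipf_text <- function(vocab_size, n_words, exponent = 1, seed,
                          source_id = "zipf") {
  stopifnot(vocab_size >= 1, n_words >= 0, exponent > 0)
  prob <- seq_len(vocab_size)^(-exponent)
  ranks <- withr::with_seed(seed,
    sample.int(vocab_size, size = n_words, replace = TRUE, prob = prob))
  vocab <- zipf_vocabulary(vocab_size)
  corpus_text(paste(vocab[ranks], collapse = " "), source_id = source_id)
}

#' Plant a pattern at known positions
#'
#' Overwrites `k` seeded, non-overlapping windows of `text` with `pattern`.
#' The returned ground truth is NOT simply the `k` planted positions: it is
#' the brute-force oracle's occurrence set on the modified text, which also
#' captures accidental pre-existing occurrences and overlapping occurrences
#' created where planted windows touch.
#'
#' @param text A [corpus_text()] or character scalar.
#' @param pattern Character scalar, length `m <= n`.
#' @param k Number of copies to plant (>= 1).
#' @param seed Integer seed.
#' @return List with `text` (the modified [corpus_text()]) and `truth`
#'   (integer vector of 0-based occurrence starts).
#' @export
plant_pattern <- function(text, pattern, k, seed) {
  src <- resolve_text(text)
  pat <- resolve_pattern(pattern, src$mode)
  m <- length(pat); n <- length(src$symbols)
  stopifnot(k >= 1, m <= n)
  candidates <- withr::with_seed(seed, sample.int(n - m + 1L)) - 1L
  chosen <- integer(0)
  for (s in candidates) {
    if (length(chosen) == k) break
    if (!any(abs(chosen - s) < m)) chosen <- c(chosen, s)
  }
  if (length(chosen) < k) {
    stop("cannot place ", k, " non-overlapping windows of length ", m,
         " in a text of length ", n)
  }
  symbols <- src$symbols
  for (s in chosen) symbols[(s + 1L):(s + m)] <- pat
  out <- corpus_text(symbols, source_id = paste0(src$source_id, "+planted"))
  truth <- brute_force_find_all(pattern, out)$occurrences$start
  list(text = out, truth = truth, planted = sort(chosen))
}

#' Sample query patterns from a text
#'
#' Draws `count` substrings of `text` with lengths from the requested
#' category -- short (1-4), medium (5-8) or long (9-16) characters --
#' mirroring the pattern-length categories of the benchmark design. Every
#' sampled pattern occurs at least once in its source text by construction.
#'
#' @param text A [corpus_text()] or character scalar.
#' @param category `"short"`, `"medium"` or `"long"`.
#' @param count Number of patterns.
#' @param seed Integer seed.
#' @return Character vector of patterns.
#' @export
sample_patterns <- function(text, category = c("short", "medium", "long"),
                            count, seed) {
  category <- match.arg(category)
  src <- resolve_text(text)
  n <- length(src$symbols)
  range <- switch(category, short = 1:4, medium = 5:8, long = 9:16)
  if (n < min(range)) stop("text too short to sample '", category,
                           "' patterns")
  range <- range[range <= n]
  withr::with_seed(seed, {
    lens <- sample(range, size = count, replace = TRUE)
    vapply(lens, function(m) {
      s <- sample.int(n - m + 1L, 1L)
      symbols_to_string(src$symbols[s:(s + m - 1L)], src$mode)
    }, "")
  })
}
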