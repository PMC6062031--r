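# Independent ground-truth oracles, deliberately written in plain R with
# none of the package's search machinery.

# Every 0-based start position where `pattern` occurs in `text`
# (overlapping occurrences included). Pure substring enumeration.
oracle_find <- function(pattern, text) {
  m <- nchar(pattern); n <- nchar(text)
  if (m < 1 || m > n) return(integer(0))
  starts <- integer(0)
  for (s in 1:(n - m + 1)) {
    if (substr(text, s, s + m - 1) == pattern) starts <- c(starts, s - 1L)
  }
  starts
}

# Definitional strong good-suffix shift for a mismatch at 0-based position
# j: the smallest d >= 1 such that the matched suffix re-aligns consistently
# (P[k-d] == P[k] for all k > j with k-d >= 0) and the character that
# caused the mismatch is not re-aligned with itself (P[j-d] != P[j] when
# j-d >= 0). Tried exhaustively.
oracle_good_suffix <- function(pattern) {
  p <- strsplit(pattern, "")[[1]]
  m <- length(p)
  vapply(seq_len(m), function(j1) {     # j1 = j + 1 (1-based)
    for (d in 1:m) {
      suffix_ok <- TRUE
      if (j1 < m) {
        for (k in (j1 + 1):m) {
          if (k - d >= 1 && p[k - d] != p[k]) { suffix_ok <- FALSE; break }
        }
      }
      if (suffix_ok && (j1 - d < 1 || p[j1 - d] != p[j1])) return(d)
    }
    m
  }, integer(1))
}

# Random string over an alphabet (uses the current RNG stream).
rand_string <- function(len, alpha) {
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

# Seeded random (pattern, text) cases over a given alphabet; half the
# patterns are substrings of the text so that match-heavy paths are
# exercised even on large alphabets.
random_cases <- function(n_cases, alpha, seed, m_max = 12, n_max = 300) {
  withr::with_seed(seed, lapply(seq_len(n_cases), function(i) {
    n <- sample(1:n_max, 1)
    m <- sample(1:min(m_max, n), 1)
    text <- rand_string(n, alpha)
    pattern <- if (i %% 2 == 0) {
      s <- sample(1:(n - m + 1), 1)
      substr(text, s, s + m - 1)
    } else {
      rand_string(m, alpha)
    }
    list(pattern = pattern, text = text)
  }))
}

all_alphabets <- list(
  size2 = c("A", "B"),
  size4 = c("A", "C", "G", "T"),
  size20 = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
  size64 = strsplit(paste0("ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                           "abcdefghijklmnopqrstuvwxyz", "0123456789+/"),
                    "")[[1]])

# All strings of length 1..max_len over an alphabet.
enumerate_patterns <- function(alpha, max_len) {
  unlist(lapply(seq_len(max_len), function(m) {
    grid <- do.call(expand.grid, rep(list(alpha), m))
    apply(grid, 1, paste, collapse = "")
  }))
}
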