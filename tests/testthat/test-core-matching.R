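test_that("split_pattern halves the query with the larger right half", {
  ps <- split_pattern("OGEM")
  expect_equal(ps$p1, "OG")
  expect_equal(ps$p2, "EM")
  expect_equal(c(ps$m, ps$m1, ps$m2), c(4L, 2L, 2L))

  ps <- split_pattern("WORLD")
  expect_equal(ps$p1, "WO")
  expect_equal(ps$p2, "RLD")

  ps <- split_pattern("A")
  expect_equal(ps$p1, "")
  expect_equal(ps$p2, "A")

  for (m in 1:64) {
    p <- rand_string(m, letters)
    ps <- split_pattern(p)
    expect_equal(ps$m1, m %/% 2)
    expect_equal(ps$m2, ceiling(m / 2))
    expect_equal(paste0(ps$p1, ps$p2), p)
  }

  expect_error(split_pattern(""), "empty pattern")
})

test_that("map_left_window applies the anchor-to-left-half mapping", {
  expect_equal(map_left_window(6, 2), 4L)
  # occurrence at the text start: i0 = m - 1 maps to m1 - 1
  for (m in 2:10) {
    m1 <- m %/% 2; m2 <- m - m1
    expect_equal(map_left_window(m - 1, m2), m1 - 1L)
  }
  expect_error(map_left_window(1, 2), "past the text start")
})

test_that("split search reproduces the worked even-length example", {
  res <- split_find_all("OGEM", "HELOGEMLED", trace = TRUE)
  expect_equal(res$occurrences$start, 3L)
  expect_equal(res$occurrences$end, 7L)
  expect_equal(oracle_find("OGEM", "HELOGEMLED"), 3L)
  # window-scan trace: anchors at i0 = 3..9
  expect_equal(res$trace$i0, 3:9)
  expect_equal(res$trace$i0[res$trace$anchor_hit][1], 6L)
})

test_that("p2-scan trace follows the narrative anchor sequence", {
  res <- split_find_all("OGEM", "HELOGEMLED", anchor_scan = "p2",
                        trace = TRUE)
  expect_equal(res$occurrences$start, 3L)
  first_hit <- which(res$trace$anchor_hit)[1]
  expect_equal(res$trace$char[1:first_hit], c("E", "L", "O", "G", "E", "M"))
  expect_equal(res$trace$i0[first_hit], 6L)
  expect_equal(first_hit, 6L)  # six anchor windows examined up to the hit
})

test_that("overlapping occurrences and misses are handled", {
  expect_equal(split_find_all("AA", "AAAA")$occurrences$start, c(0L, 1L, 2L))
  expect_equal(nrow(split_find_all("ZZ", "HELLO")$occurrences), 0L)
  expect_equal(count_occurrences("OGEM", "HELOGEMLED"), 1L)
  expect_equal(count_occurrences("AA", "AAAA"), 3L)
  # self-match
  for (p in c("X", "AB", "HELLO")) expect_equal(count_occurrences(p, p), 1L)
})

test_that("comparison accounting matches the analytic fixtures", {
  # anchor-only work: 'B' never matches in an all-A text
  res <- split_find_all("AAB", strrep("A", 10))
  expect_equal(nrow(res$occurrences), 0L)
  expect_equal(res$stats$total_cmps, 8)
  expect_equal(res$stats$alignments, 8)
  brute <- brute_force_find_all("AAB", strrep("A", 10))
  expect_equal(brute$stats$total_cmps, 24)
})

test_that("degenerate inputs follow the documented contract", {
  expect_error(split_find_all("", "ABC"), "empty pattern")
  # pattern longer than text: empty result, zero alignments
  res <- split_find_all("ABCDE", "AB")
  expect_equal(nrow(res$occurrences), 0L)
  expect_equal(res$stats$alignments, 0)
  # empty text
  res <- split_find_all("A", "")
  expect_equal(nrow(res$occurrences), 0L)
  expect_equal(res$stats$alignments, 0)
  # single-character pattern: left half empty, still correct
  expect_equal(split_find_all("A", "ABA")$occurrences$start, c(0L, 2L))
})

test_that("both anchor-scan conventions return the same occurrences", {
  cases <- random_cases(200, all_alphabets$size4, seed = 42)
  for (cs in cases) {
    w <- split_find_all(cs$pattern, cs$text, anchor_scan = "window")
    p <- split_find_all(cs$pattern, cs$text, anchor_scan = "p2")
    expect_identical(w$occurrences$start, p$occurrences$start)
    # p2 scan examines n - m2 + 1 anchors, window scan n - m + 1
    m <- nchar(cs$pattern); n <- nchar(cs$text)
    expect_equal(w$stats$alignments, n - m + 1)
    expect_equal(p$stats$alignments, n - ceiling(m / 2) + 1)
  }
})

test_that("search stats satisfy their accounting invariants", {
  cases <- random_cases(300, all_alphabets$size2, seed = 7)
  for (cs in cases) {
    res <- split_find_all(cs$pattern, cs$text)
    m <- nchar(cs$pattern); n <- nchar(cs$text)
    st <- res$stats
    expect_equal(st$alignments, n - m + 1)
    expect_equal(st$anchor_cmps, st$alignments)
    expect_equal(st$total_cmps, st$anchor_cmps + st$p2_cmps + st$p1_cmps)
    expect_gte(st$total_cmps, st$alignments)
    expect_lte(st$total_cmps, m * st$alignments)
    expect_equal(st$matches, nrow(res$occurrences))
  }
})

test_that("every trace window satisfies the left-half mapping identity", {
  cases <- random_cases(50, all_alphabets$size4, seed = 11)
  for (cs in cases) {
    m <- nchar(cs$pattern)
    if (m < 2) next           # mapping needs a nonempty left half window
    m1 <- m %/% 2; m2 <- m - m1
    res <- split_find_all(cs$pattern, cs$text, trace = TRUE)
    i0 <- res$trace$i0
    s <- i0 - m + 1
    expect_equal(map_left_window(i0, m2), s + m1 - 1)
  }
})

test_that("occurrences are sound and reported in ascending order", {
  cases <- random_cases(200, all_alphabets$size2, seed = 99)
  for (cs in cases) {
    occ <- split_find_all(cs$pattern, cs$text)$occurrences
    expect_false(is.unsorted(occ$start, strictly = TRUE))
    for (s in occ$start) {
      expect_equal(substr(cs$text, s + 1, s + nchar(cs$pattern)), cs$pattern)
    }
  }
})

test_that("byte mode and code-point mode agree on pure ASCII", {
  cases <- random_cases(100, all_alphabets$size64, seed = 5)
  for (cs in cases) {
    cp <- split_find_all(cs$pattern, cs$text, mode = "codepoint")
    by <- split_find_all(cs$pattern, cs$text, mode = "byte")
    expect_identical(cp$occurrences$start, by$occurrences$start)
  }
})

test_that("multibyte patterns match per code point, not per byte", {
  text <- "naïve café naïve"
  res <- split_find_all("naïve", text)
  expect_equal(res$occurrences$start, c(0L, 11L))
  expect_equal(res$occurrences$end - res$occurrences$start,
               rep(nchar("naïve"), 2))
})

test_that("case folding is optional and off by default", {
  expect_equal(nrow(split_find_all("ogem", "HELOGEMLED")$occurrences), 0L)
  expect_equal(
    split_find_all("ogem", "HELOGEMLED", ignore_case = TRUE)$occurrences$start,
    3L)
})
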