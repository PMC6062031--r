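test_that("read_text decodes plain files in both modes", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("HELOGEMLED", f, sep = "")
  txt <- read_text(f)
  expect_s3_class(txt, "corpus_text")
  expect_equal(txt$n, 10L)
  expect_equal(as.character(txt), "HELOGEMLED")
  expect_equal(read_text(f, mode = "byte")$n, 10L)  # pure ASCII

  # one 2-byte UTF-8 character: one code point, two bytes
  g <- withr::local_tempfile(fileext = ".txt")
  writeBin(charToRaw("é"), g)
  expect_equal(read_text(g)$n, 1L)
  expect_equal(read_text(g, mode = "byte")$n, 2L)

  expect_error(read_text(file.path(tempdir(), "absent-8271.txt")),
               "not found")
})

test_that("read_text reports the offset of undecodable bytes", {
  f <- withr::local_tempfile(fileext = ".bin")
  writeBin(c(charToRaw("AB"), as.raw(0xFF), charToRaw("CD")), f)
  expect_error(read_text(f), "offset 2")
  expect_equal(read_text(f, mode = "byte")$n, 5L)  # byte mode accepts anything
})

test_that("searching a file gives the same hits in byte and code-point mode", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("the quick brown fox", "jumps over the lazy dog"), f)
  for (pat in c("the", "o", "quick")) {
    expect_identical(
      split_find_all(pat, read_text(f))$occurrences$start,
      split_find_all(pat, read_text(f, mode = "byte"),
                     mode = "byte")$occurrences$start)
  }
})

test_that("FASTA reading handles wrapping, order and empty records", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 first record", "ACGT", "ACGT",
               ">r2", "GGGG"), f)
  recs <- read_fasta(f)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "r1")
  expect_equal(recs[[1]]$description, "first record")
  expect_equal(nchar(recs[[1]]$sequence), 8L)
  expect_equal(recs[[2]]$id, "r2")

  # wrapped 60-column record of known total length 150
  g <- withr::local_tempfile(fileext = ".fa")
  seq150 <- as.character(gen_uniform_text("dna", 150, seed = 3))
  writeLines(c(">long", substring(seq150, c(1, 61, 121), c(60, 120, 150))), g)
  expect_equal(nchar(read_fasta(g)[[1]]$sequence), 150L)

  # empty sequence under a header is skipped with a warning
  h <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">empty", ">kept", "ACGT"), h)
  expect_warning(recs <- read_fasta(h), "empty")
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "kept")
})

test_that("FASTA round-trips through write_fasta", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- vapply(1:3, function(i)
    as.character(gen_uniform_text("dna", 37 * i, seed = i)), "")
  writeLines(unlist(lapply(1:3, function(i)
    c(paste0(">s", i, " desc", i), seqs[i]))), f)
  recs <- read_fasta(f)
  g <- withr::local_tempfile(fileext = ".fa")
  write_fasta(recs, g, width = 60)
  back <- read_fasta(g)
  expect_equal(back, recs)
})

test_that("reverse_complement is a case-preserving involution", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AAC"), "GTT")
  expect_equal(reverse_complement("acGTn"), "nACgt")
  withr::with_seed(4, {
    for (i in 1:20) {
      s <- rand_string(sample(1:50, 1), c("A", "C", "G", "T", "N", "a", "g"))
      expect_equal(reverse_complement(reverse_complement(s)), s)
    }
  })
  expect_error(reverse_complement("ACXGT"), "'X' at position 3")
})

test_that("pattern lists keep order and internal spaces", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("OGEM", "", "EM"), f)
  expect_equal(read_patterns(f), c("OGEM", "EM"))

  g <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Good, the", "that Adam"), g)
  expect_equal(read_patterns(g), c("Good, the", "that Adam"))

  h <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("", ""), h)
  expect_error(read_patterns(h), "no usable patterns")
})

test_that("search_fasta scans records independently, optionally both strands", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "TTTGGATCCTTT", ">r2", "AAAA"), f)
  hits <- search_fasta("GGATCC", f, both_strands = TRUE)
  # palindromic site: one window, strands coincide
  expect_equal(hits$source_id, "r1")
  expect_equal(hits$start, 3L)
  expect_equal(hits$strand, "+/-")

  g <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "AAACCCAAA"), g)
  plus_only <- search_fasta("CCC", g)
  expect_equal(plus_only$strand, "+")
  both <- search_fasta("GGG", g, both_strands = TRUE)  # rc "CCC" hits minus
  expect_equal(both$strand, "-")
  expect_equal(both$start, 3L)  # plus-strand coordinates
})

test_that("occurrence writers keep coordinate conventions consistent", {
  res <- split_find_all("AA", "AAAA")
  m <- 2L

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_occurrences(res, tsv, format = "tsv")
  tab <- read.delim(tsv, comment.char = "#")
  expect_equal(tab$end - tab$start, rep(m, 3))
  write_occurrences(res, tsv, format = "tsv", one_based = TRUE)
  tab1 <- read.delim(tsv, comment.char = "#")
  expect_equal(tab1$start, tab$start + 1L)        # 1-based inclusive
  expect_equal(tab1$end - tab1$start, rep(m - 1L, 3))

  js <- withr::local_tempfile(fileext = ".json")
  write_occurrences(res, js, format = "json")
  back <- jsonlite::fromJSON(js)
  expect_equal(back$occurrences$start, res$occurrences$start)
  expect_equal(back$occurrences$end - back$occurrences$start, rep(m, 3))
  expect_equal(back$stats$total_cmps, res$stats$total_cmps)

  # BED needs a strand column, i.e. a FASTA search
  expect_error(write_occurrences(res, tempfile(), format = "bed"),
               "FASTA")
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1", "XXXACGTXXX"), f)
  hits <- search_fasta("ACGT", f)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_occurrences(hits, bed, format = "bed")
  fields <- strsplit(readLines(bed), "\t")[[1]]
  expect_equal(fields[1:4], c("r1", "3", "7", "ACGT"))

  # empty occurrence set still yields a valid payload with stats
  empty <- split_find_all("ZZ", "HELLO")
  write_occurrences(empty, js, format = "json")
  back <- jsonlite::fromJSON(js)
  expect_equal(length(back$occurrences), 0L)
  expect_true(is.numeric(back$stats$total_cmps))
})
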