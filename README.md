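# splitmatch

Exact pattern matching by **pattern splitting**, for anyone who needs every
(possibly overlapping) occurrence of a query in a text — motif scanning in
FASTA sequences, grep-like search in natural-language corpora of any script
— together with instrumented implementations of the classical comparators
and a benchmark harness whose metrics are portable across machines.

## The method

The query `p` (length `m`) is split into a left half `p1` of length
`m1 = ⌊m/2⌋` and a right half `p2` of length `m2 = ⌈m/2⌉` (the right half
gets the extra character when `m` is odd). At each alignment of the
pattern against the text:

1. the **anchor** — the last character of `p2` — is compared against the
   text character at the window's last index `i0`; a miss costs one
   comparison and the window advances by one;
2. on an anchor hit the rest of `p2` is verified right to left;
3. if `p2` matched, the left-half window is located in constant time at
   `pmap = i0 − m2` (the last index of the `p1` window, equal to
   `s + m1 − 1` for a window starting at `s`) and `p1` is verified there.

The shift is always exactly +1 — **no shift tables, no preprocessing, zero
auxiliary space** — so the reported occurrence set is identical to brute
force, overlaps included, while the anchor filters most windows after a
single comparison. The package also ships instrumented brute force,
Boyer–Moore (strong good suffix + bad character), Horspool and Quick
Search as correctness oracles and benchmark arms.

Because wall-clock time and heap profiles are properties of a machine
rather than an algorithm, every search returns exact **character
comparison counts** (split by phase), **alignments examined**, and an
**auxiliary-space proxy** (precomputed table entries: 0 for split and
brute force, >0 for the table-driven algorithms). These are the quantities
the tests assert.

## Worked example

Searching `OGEM` in `HELOGEMLED` with the trace enabled, using the
right-half scan convention (`anchor_scan = "p2"`):

```r
library(splitmatch)
res <- split_find_all("OGEM", "HELOGEMLED", anchor_scan = "p2", trace = TRUE)
res
#> <match_result: 'OGEM' (m = 4) vs 10 symbols, algorithm = split>
#>   1 occurrence(s); 9 alignment(s), 12 comparison(s)
#>   source_id pattern start end
#> 1      text    OGEM     3   7
res$trace
#>   i0 symbol anchor_hit char
#> 1  1     69      FALSE    E
#> 2  2     76      FALSE    L
#> 3  3     79      FALSE    O
#> 4  4     71      FALSE    G
#> 5  5     69      FALSE    E
#> 6  6     77       TRUE    M
#> 7  7     76      FALSE    L
#> 8  8     69      FALSE    E
#> 9  9     68      FALSE    D
```

The anchor `M` misses `E, L, O, G, E` and hits at text index `i0 = 6` on
the sixth window examined; the remaining right-half character `E` matches
(1 comparison), the left-half window is mapped to `pmap = 6 − 2 = 4` and
`OG` is verified there (2 comparisons). The single occurrence is reported
0-based half-open as `[3, 7)`. With the default `anchor_scan = "window"`
convention the same occurrence is found in `n − m + 1 = 7` alignments and
10 comparisons.

A pair of constructed fixtures shows the comparison accounting — and that
neither algorithm universally dominates: on 1000 `A`s, pattern `AAB`
costs split 998 comparisons vs 2994 for brute force; pattern `BAA`
reverses the numbers exactly.

Other entry points: `brute_force_find_all()` / `horspool_find_all()` /
`boyer_moore_find_all()` / `quick_search_find_all()`, FASTA search with
strand support (`search_fasta()`, BED/TSV/JSON writers), seeded synthetic
corpora (`gen_uniform_text()`, `gen_zipf_text()`, `plant_pattern()`,
`sample_patterns()`) and the benchmark harness (`run_suite()`,
`write_report()`, YAML configs). A command-line front end lives at
`inst/cli/splitmatch.R`:

```sh
Rscript inst/cli/splitmatch.R search GGATCC genome.fa --fasta --both-strands --format bed
Rscript inst/cli/splitmatch.R benchmark --config suite.yaml --format markdown
```

## Layout

- `R/`, `src/` — package code (search kernels in C++ via Rcpp)
- `tests/testthat/` — unit, property and acceptance suites (brute-force
  and exhaustive-shift oracles live in `helper-oracle.R`)
- `vignettes/split-matching.Rmd` — the methods vignette
- `inst/cli/splitmatch.R` — command-line front end
- `scripts/acceptance.R` — reproduction script
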