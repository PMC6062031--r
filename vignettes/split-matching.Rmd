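---
title: "Split-based exact pattern matching: method, instrumentation and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-based exact pattern matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splitmatch)
```

## The method

Exact pattern matching asks for every position at which a query pattern `p`
of length `m` occurs verbatim in a text `t` of length `n`, overlapping
occurrences included. The classical table-driven algorithms (Boyer–Moore,
Horspool, Quick Search) buy their speed with a preprocessing phase that
stores shift tables; the split method studied here takes the opposite
trade: **no preprocessing and no auxiliary tables at all**, at the price of
a unit shift per alignment.

The pattern is divided into a left half `p1` of length `m1 = floor(m/2)`
and a right half `p2` of length `m2 = ceiling(m/2)`; for odd `m` the right
half receives the extra character, and for `m = 1` the left half is empty.
At each alignment:

1. **Anchor.** The last character of `p2` is compared against the text
   character under the window's last position (`i0`). A mismatch costs one
   comparison and the window advances by one.
2. **Right-half verification.** On an anchor hit, the remaining `m2 - 1`
   characters of `p2` are verified right to left.
3. **Left-half mapping and verification.** If `p2` matched, the last index
   of the left-half window is obtained in constant time as
   `pmap = i0 - m2`, which for a window starting at `s` equals
   `s + m1 - 1`; `p1` is then verified right to left from `pmap`.

The window advances by exactly one position after every outcome — anchor
miss, partial mismatch, or full match — which is what makes the reported
occurrence set identical to brute force, overlaps included.

### The anchor-scan ambiguity

Two readings of the scan exist, and `split_find_all()` implements both:

* `anchor_scan = "window"` (default): the anchor visits only positions
  where the *full* pattern fits, `i0 = m-1 .. n-1`. Every search then
  examines exactly `n - m + 1` alignments, spends exactly one anchor
  comparison per alignment, and the stats invariants
  (`alignments = anchor_cmps = n - m + 1`,
  `alignments <= total_cmps <= m * alignments`) hold. This is the
  convention all instrumentation guarantees are stated against.
* `anchor_scan = "p2"`: the right half alone slides from the text start,
  `i0 = m2-1 .. n-1`, and a full `p2` match is promoted to an occurrence
  only when the left half also fits inside the text. This is the scan that
  reproduces the classic worked trace for the query `OGEM` in
  `HELOGEMLED` — anchors `E, L, O, G, E, M` with the first hit on the
  sixth window — at the cost of `n - m2 + 1` anchor comparisons.

Both conventions provably return the same occurrence set (a property the
test suite checks on hundreds of randomized cases); only the comparison
accounting and the trace differ. The narrative descriptions of this method
in the literature mix the two conventions (and also describe the text
sweep once as right-to-left while tracing it left-to-right); we follow the
left-to-right worked trace, report occurrences in ascending order, and
expose the scan-start choice as an explicit argument rather than guessing.

Two further readings were genuinely open. The restart rule after a match
or mismatch ("resume from the last matching position `i0`") would loop
forever if taken literally, so the resume point is `i0 + 1` — i.e. a unit
shift. And whether the left half is verified character by character or "as
a block" does not change the occurrence set, only the attribution of
comparisons to `p1`; we verify character by character, right to left, and
stop at the first mismatch, so `p1_cmps` is the number of left-half
characters actually inspected.

```{r worked}
res <- split_find_all("OGEM", "HELOGEMLED", anchor_scan = "p2", trace = TRUE)
res$occurrences
res$trace
```

## Instrumentation as the portable metric

Wall-clock milliseconds and JVM heap profiles are properties of a machine,
a runtime and a garbage collector, not of an algorithm, so this package
asserts none of them. Every search returns a `search_stats` record:

* `alignments` — windows examined;
* `anchor_cmps`, `p2_cmps`, `p1_cmps` — character comparisons attributed
  to the anchor, the rest of the right half, and the left half;
* `total_cmps` — their sum; for the baselines the whole count is reported
  in `total_cmps` with the phase fields at zero.

The memory claim is restated in its literally testable form as the
**auxiliary-space proxy** `aux_space()`: the number of precomputed table
entries an algorithm stores for a given pattern. The split method and
brute force store none (0); Horspool and Quick Search store one entry per
distinct relevant character plus the default entry; Boyer–Moore stores its
bad-character entries plus `m` good-suffix entries. Wall time is still
*recorded* by the harness (mean over repeats) for orientation, but no test
or acceptance quantity depends on it.

Two constructed fixtures pin down the instrumentation and show that
neither algorithm dominates: on a text of 1000 `A`s, the pattern `AAB`
(mismatch in the right half) costs the split search one anchor comparison
per window, `n - m + 1 = 998` comparisons total, while brute force spends
3 per window (2994); the mirrored pattern `BAA` reverses the two numbers
exactly, because the split search now matches the whole right half before
discovering the mismatch in the left half.

## Comparator baselines

Brute force (left-to-right verification, unit shift) is the ground truth.
Horspool shifts on the text character under the window's last position
(shifts in `[1, m]`, default `m`); Quick Search verifies left to right and
shifts on the character just *after* the window (shifts in `[1, m + 1]`,
default `m + 1`); Boyer–Moore verifies right to left and shifts by the
maximum of the strong good-suffix shift and the bad-character shift,
floored at one, advancing by the pattern period after a full match so that
overlapping occurrences survive. The good-suffix table is built with the
classical linear-time suffixes-array construction, and its correctness is
anchored not to any textbook formulation but to an exhaustive oracle that
tries every shift and keeps the smallest consistent one — checked for every
binary pattern up to length 8 and every DNA pattern up to length 5, plus a
seeded sample of longer DNA patterns (scope chosen to keep the default
test run fast at equal evidential value; the construction is
length-independent).

Variants whose defining details live outside the scope of this package
(Turbo-BM memory matches, BM/KMP hybrids, pivot-character methods, hashing
and bit-parallel families) are intentionally absent; the benchmark's
algorithm registry is name-keyed and pluggable (`register_algorithm()`) so
they can be added without touching the harness.

## Text model: code points, bytes, case

Texts are decoded to Unicode code points by default and all comparisons
are per code point, so a multibyte character is one symbol. A byte mode is
provided (`mode = "byte"`) in which the raw bytes are the symbols — useful
for reproducing byte-level behaviour of single-byte-encoding
implementations; for pure-ASCII data the two modes give identical
occurrence sets (tested). No Unicode normalization is applied by default:
what you search is exactly what was decoded. `read_text(nfc = TRUE)`
opts into NFC via stringi for texts where composed/decomposed variants
must unify. Searches are case-sensitive by default with an
`ignore_case` flag (simple lowercase folding; ASCII-only in byte mode).
Newlines are normalised to `\n` on read and are ordinary searchable
symbols; patterns may contain spaces but pattern files cannot carry
embedded newlines (one pattern per line).

Coordinates are 0-based half-open everywhere internally and in JSON/BED
output; the TSV writer has a 1-based inclusive option for spreadsheet
audiences. FASTA records are searched independently (no cross-record
matches), with optional reverse-complement scanning reported on the minus
strand in plus-strand coordinates.

## The synthetic corpus generators

The generators emulate, at desk scale, the kinds of corpora this family of
algorithms is usually benchmarked on:

* `gen_uniform_text()` — i.i.d. uniform symbols over alphabets of size 2,
  4 (DNA), 20 (protein) or 64 (a large character inventory), the standard
  sizes for worst-case-ish and biological texts;
* `gen_zipf_text()` — a space-separated pseudo-word stream whose
  rank-frequency law is Zipf with exponent 1 (the classic natural-language
  value), emulating bible-like natural texts where a few function words
  dominate;
* `plant_pattern()` — overwrites `k` seeded non-overlapping windows with
  the pattern. Crucially the ground truth is *not* the `k` planted
  positions but the brute-force oracle's occurrence set on the modified
  text, which also captures accidental occurrences and overlaps created
  where planted windows touch;
* `sample_patterns()` — seeded substrings in the three query-length
  categories used throughout: short (1–4), medium (5–8), long (9–16,
  i.e. "more than 8"). A variant category boundary of 4–7 for "medium"
  appears in parts of the literature; the prose definition 5–8 is the one
  implemented, and this discrepancy is surfaced here rather than silently
  resolved.

All generators are pure functions of their parameters and seed
(byte-identical reruns, caller's RNG untouched). What they deliberately do
**not** model: real orthography, word-length and punctuation statistics of
any specific language, diacritic sequences, or the byte streams of any
published corpus. Passing the randomized suites therefore demonstrates
algorithmic correctness and instrumentation accuracy, not performance on
any particular natural-language dataset.

## Benchmark harness

`run_suite()` executes the full corpus × pattern × algorithm grid, runs
every cell `repeats = 10` times (the conventional repeat count for mean
timing), reports the mean wall time, and carries the deterministic metrics
— `total_cmps`, `alignments`, `occurrences`, `aux_space` — which are
invariant across repeats and across machines. A failing algorithm aborts
its cell with a logged diagnostic, never the suite. Suites can be declared
in a YAML/JSON config (`read_bench_config()` / `run_config()`); reports
render as CSV, JSON or a markdown table grouped corpus × pattern with one
column per algorithm.

```{r bench}
corpora <- list(dna = gen_uniform_text("dna", 20000, seed = 1),
                words = gen_zipf_text(500, 3000, seed = 2))
rec <- run_suite(corpora, c("ACG", "the"), repeats = 3)
rec[rec$pattern == "ACG" & rec$corpus == "dna",
    c("algorithm", "total_cmps", "alignments", "occurrences", "aux_space")]
```

## Numerical and design choices

* **Problem sizes.** The randomized correctness suites use 1000 seeded
  cases per alphabet with `m <= 12`, `n <= 300`; planted-pattern recovery
  uses a 100 kb DNA corpus and a 10-kword Zipf stream. These sizes give
  full code-path coverage (anchor miss/hit, partial and full verification,
  overlaps, text boundaries) with a test suite that runs in about a
  minute.
* **Seeds.** Every stochastic test and generator call takes an explicit
  seed; generators restore the caller's RNG state.
* **Degenerate inputs.** Empty pattern: error (no defined split). Pattern
  longer than text: empty result with zero alignments, not an error.
  Empty text: likewise. `m = 1`: the left half is empty and its
  verification vacuously succeeds.
* **Tie-breaks.** Within both halves verification runs right to left and
  stops at the first mismatch; after a full match every algorithm advances
  by a completeness-preserving shift (unit for split/brute, table-driven
  `>= 1` for the rest, pattern period for Boyer–Moore).
* **Half split.** `m1 = floor(m/2)` / `m2 = ceiling(m/2)` always;
  the split is not tuned per pattern or corpus.

## Known limitations

Single pattern, exact matches only — no mismatches, no multi-pattern sets,
no keyword spotting. The split search is deliberately table-free; giving
it a skip rule would change the method under test. The auxiliary-space
proxy counts table entries, not bytes, and says nothing about runtime
allocator behaviour. Wall-clock numbers produced by the harness are
environment-specific orientation values, never assertions.
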