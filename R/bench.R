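# Name-keyed, pluggable algorithm registry. Each entry is a search function
# with signature (pattern, text, ignore_case, mode) returning a
# match_result, plus an auxiliary-space accounting function.
the_registry <- new.env(parent = emptyenv())

register_builtin_algorithms <- function() {
  register_algorithm("split", split_find_all, aux_space_fn = function(p) 0L)
  register_algorithm("brute", brute_force_find_all,
                     aux_space_fn = function(p) 0L)
  register_algorithm("horspool", horspool_find_all,
    aux_space_fn = function(p) length(build_horspool_table(p)$shifts) + 1L)
  register_algorithm("bm", boyer_moore_find_all,
    aux_space_fn = function(p) {
      sym <- resolve_pattern(p)
      length(unique(sym)) + 1L + length(sym)   # bad-char (+default) + good-suffix
    })
  register_algorithm("qs", quick_search_find_all,
    aux_space_fn = function(p) length(build_quick_search_table(p)$shifts) + 1L)
}

#' Register a search algorithm
#'
#' The benchmark harness looks algorithms up by name, so excluded or future
#' comparators can be plugged in without touching the harness.
#'
#' @param name Registry key.
#' @param fn Function `(pattern, text, ignore_case = FALSE, mode = ...)`
#'   returning a `match_result`.
#' @param aux_space_fn Function of the pattern returning the number of
#'   precomputed table entries the algorithm stores (0 for table-free
#'   algorithms).
#' @return `name`, invisibly.
#' @export
register_algorithm <- function(name, fn, aux_space_fn = function(p) 0L) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, list(fn = fn, aux_space = aux_space_fn), envir = the_registry)
  invisible(name)
}

#' @rdname register_algorithm
#' @export
list_algorithms <- function() sort(ls(the_registry))

algorithm_fn <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    stop("unknown algorithm '", name, "'; registered: ",
         paste(list_algorithms(), collapse = ", "))
  }
  get(name, envir = the_registry)$fn
}

#' Pattern-length category
#'
#' The benchmark's three query classes: short (1-4 characters), medium
#' (5-8) and long (9 or more).
#'
#' @param length Pattern length(s), >= 1.
#' @return Character vector in `{"short","medium","long"}`.
#' @examples
#' categorize_pattern(c(2, 6, 9))
#' @export
categorize_pattern <- function(length) {
  length <- as.integer(length)
  if (any(length < 1L)) stop("pattern length must be >= 1")
  ifelse(length <= 4L, "short", ifelse(length <= 8L, "medium", "long"))
}

#' Auxiliary-space proxy
#'
#' Portable stand-in for heap profiling: the number of precomputed table
#' entries an algorithm stores for a given pattern. The split algorithm and
#' brute force store none; Horspool and Quick Search store one entry per
#' distinct relevant character plus the default; Boyer-Moore additionally
#' stores `m` good-suffix entries.
#'
#' @param algorithm Registered algorithm name.
#' @param pattern The query pattern.
#' @return Nonnegative integer count of table entries.
#' @examples
#' aux_space("split", "OGEM")     # 0
#' aux_space("horspool", "OGEM")  # 3 entries + default
#' @export
aux_space <- function(algorithm, pattern) {
  if (!exists(algorithm, envir = the_registry, inherits = FALSE)) {
    stop("unknown algorithm '", algorithm, "'")
  }
  as.integer(get(algorithm, envir = the_registry)$aux_space(pattern))
}

#' Run a benchmark suite
#'
#' Reproduces the corpus x pattern x algorithm experimental design with
#' portable metrics. Every cell is run `repeats` times; the mean wall time
#' over the repeats is recorded, but the asserted metrics are the
#' deterministic ones: total character comparisons, alignments examined,
#' occurrences and the auxiliary-space proxy (identical across repeats).
#' An algorithm that fails on a cell aborts that cell with a logged
#' diagnostic, not the suite.
#'
#' @param corpora Named list of [corpus_text()] objects (or character
#'   scalars, which are converted).
#' @param patterns Character vector of query patterns.
#' @param algorithms Registry names, default all registered.
#' @param repeats Runs per cell (>= 1), default 10.
#' @param ignore_case Case-fold before matching.
#' @return Data frame of class `benchmark_report`: one row per cell with
#'   columns `corpus`, `pattern`, `category`, `algorithm`, `repeats`,
#'   `mean_time_s`, `total_cmps`, `alignments`, `occurrences`, `aux_space`.
#' @export
run_suite <- function(corpora, patterns,
                      algorithms = list_algorithms(), repeats = 10L,
                      ignore_case = FALSE) {
  stopifnot(repeats >= 1L, length(patterns) >= 1L)
  if (inherits(corpora, "corpus_text")) corpora <- list(corpora)
  if (is.null(names(corpora))) {
    names(corpora) <- vapply(seq_along(corpora), function(i) {
      x <- corpora[[i]]
      if (inherits(x, "corpus_text")) x$source_id else paste0("corpus", i)
    }, "")
  }
  if (any(!nzchar(patterns))) stop("patterns must be nonempty")
  rows <- list()
  for (ci in names(corpora)) {
    txt <- corpora[[ci]]
    if (!inherits(txt, "corpus_text")) txt <- corpus_text(txt, source_id = ci)
    for (pat in patterns) {
      for (algo in algorithms) {
        fn <- algorithm_fn(algo)
        cell <- tryCatch({
          times <- numeric(repeats)
          res <- NULL
          for (r in seq_len(repeats)) {
            t0 <- proc.time()[["elapsed"]]
            res <- fn(pat, txt, ignore_case = ignore_case)
            times[r] <- proc.time()[["elapsed"]] - t0
          }
          data.frame(
            corpus = ci, pattern = pat,
            category = categorize_pattern(nchar(pat)),
            algorithm = algo, repeats = as.integer(repeats),
            mean_time_s = mean(times),
            total_cmps = res$stats$total_cmps,
            alignments = res$stats$alignments,
            occurrences = res$stats$matches,
            aux_space = aux_space(algo, pat),
            stringsAsFactors = FALSE)
        }, error = function(e) {
          message("benchmark cell (", ci, ", '", pat, "', ", algo,
                  ") failed: ", conditionMessage(e))
          NULL
        })
        if (!is.null(cell)) rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_report", class(out))
  out
}

#' Write a benchmark report
#'
#' CSV and JSON carry one row per record; the markdown variant groups rows
#' by corpus and pattern with one comparison-count column per algorithm,
#' mirroring the usual corpus x pattern x algorithm result tables.
#'
#' @param records A `benchmark_report` data frame from [run_suite()].
#' @param path Output path.
#' @param format `"csv"`, `"json"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, format = c("csv", "json", "markdown")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "csv") {
    utils::write.csv(records, path, row.names = FALSE)
  } else if (format == "json") {
    writeLines(jsonlite::toJSON(records, dataframe = "rows", digits = NA),
               path)
  } else {
    algos <- unique(records$algorithm)
    header <- c("corpus", "pattern", "category",
                paste0(algos, "_cmps"), paste0(algos, "_aux"))
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(header)), collapse = "|"),
                      "|"))
    if (nrow(records)) {
      keys <- unique(records[c("corpus", "pattern", "category")])
      for (i in seq_len(nrow(keys))) {
        sub <- records[records$corpus == keys$corpus[i] &
                       records$pattern == keys$pattern[i], , drop = FALSE]
        cmps <- vapply(algos, function(a) {
          v <- sub$total_cmps[sub$algorithm == a]
          if (length(v)) format(v, scientific = FALSE) else "-"
        }, "")
        aux <- vapply(algos, function(a) {
          v <- sub$aux_space[sub$algorithm == a]
          if (length(v)) as.character(v) else "-"
        }, "")
        lines <- c(lines, paste0(
          "| ", paste(c(keys$corpus[i], keys$pattern[i], keys$category[i],
                        cmps, aux), collapse = " | "), " |"))
      }
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a declarative benchmark configuration
#'
#' YAML (or JSON, which YAML subsumes) description of a suite: a list of
#' `corpora` (each with `kind` = uniform/zipf/file, and the matching
#' parameters), either literal `patterns` or a `sample` spec
#' (category/count per corpus), the `algorithms`, `repeats` and `seed`.
#'
#' @param path Config file path.
#' @return The parsed configuration list.
#' @export
read_bench_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  # YAML 1.1 reads the bare key `n` as boolean FALSE; undo that so corpus
  # sizes can be written naturally
  cfg$corpora <- lapply(cfg$corpora, function(cc) {
    names(cc)[names(cc) == "FALSE"] <- "n"
    cc
  })
  cfg
}

#' Execute a benchmark configuration
#'
#' @param config List from [read_bench_config()] (or built in code).
#' @return A `benchmark_report` from [run_suite()].
#' @export
run_config <- function(config) {
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  corpora <- list()
  for (i in seq_along(config$corpora)) {
    cc <- config$corpora[[i]]
    id <- if (is.null(cc$id)) paste0("corpus", i) else cc$id
    corpora[[id]] <- switch(
      cc$kind,
      uniform = gen_uniform_text(cc$alphabet, cc$n, seed = seed + i,
                                 source_id = id),
      zipf = gen_zipf_text(cc$vocab_size, cc$n_words,
                           exponent = if (is.null(cc$exponent)) 1 else cc$exponent,
                           seed = seed + i, source_id = id),
      file = read_text(cc$path,
                       encoding = if (is.null(cc$encoding)) "UTF-8" else cc$encoding),
      stop("unknown corpus kind '", cc$kind, "'"))
  }
  patterns <- config$patterns
  if (is.null(patterns)) {
    sp <- config$sample
    if (is.null(sp)) stop("config needs either `patterns` or a `sample` spec")
    patterns <- unique(unlist(lapply(corpora, function(txt) {
      unlist(lapply(sp$categories, function(cat) {
        sample_patterns(txt, cat, count = sp$count, seed = seed)
      }))
    })))
  }
  algorithms <- if (is.null(config$algorithms)) list_algorithms() else
    unlist(config$algorithms)
  repeats <- if (is.null(config$repeats)) 10L else as.integer(config$repeats)
  run_suite(corpora, patterns, algorithms = algorithms, repeats = repeats)
}
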