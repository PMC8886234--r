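#' Read a gene expression matrix
#'
#' Reads a tab-separated expression matrix whose first column holds gene
#' identifiers and whose header row holds sample identifiers. Values must be
#' numeric and, for linear-scale data, non-negative.
#'
#' @param path Path to a TSV file (first column gene IDs, one column per
#'   sample).
#' @param log_scale Logical; declare the stored values as already
#'   log-transformed (negative values are then permitted).
#' @return A tibble with a `gene` column followed by one numeric column per
#'   sample.
#' @seealso [read_sample_groups()], [validate_expression()]
#' @export
read_expression <- function(path, log_scale = FALSE) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene"
  expr$gene <- as.character(expr$gene)
  bad <- !vapply(expr[-1], is.numeric, logical(1))
  if (any(bad)) {
    abort(paste0(
      "non-numeric expression values in column(s): ",
      paste(names(expr[-1])[bad], collapse = ", ")
    ))
  }
  if (anyDuplicated(expr$gene) > 0) {
    dup <- unique(expr$gene[duplicated(expr$gene)])
    abort(paste0("duplicate gene identifiers: ", paste(head(dup, 5), collapse = ", ")))
  }
  m <- expr_matrix(expr)
  if (anyNA(m)) abort("missing values in expression matrix")
  if (!log_scale && any(m < 0)) abort("negative values in linear-scale expression matrix")
  tibble::as_tibble(expr)
}

#' Read a sample-to-group map
#'
#' Reads a two-column TSV mapping sample identifiers to group labels
#' (`normal` for reference samples, any other label for a tumor subtype).
#' When `expr` is supplied, every expression sample must be present in the
#' map; a missing sample is an error naming that sample.
#'
#' @param path Path to a TSV with columns `sample` and `group`.
#' @param expr Optional expression tibble to validate against.
#' @return A tibble with columns `sample` and `group`.
#' @export
read_sample_groups <- function(path, expr = NULL) {
  groups <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(groups) < 2) abort("group map must have two columns: sample, group")
  names(groups)[1:2] <- c("sample", "group")
  groups <- tibble::tibble(
    sample = as.character(groups$sample),
    group = as.character(groups$group)
  )
  if (!is.null(expr)) validate_expression(expr, groups)
  groups
}

#' Validate an expression matrix against a group map
#'
#' Checks the joint invariants needed by the differential stages: unique
#' genes, numeric non-missing values, every sample labelled exactly once,
#' and at least one normal and one tumor sample.
#'
#' @inheritParams read_sample_groups
#' @param groups Tibble with columns `sample` and `group`.
#' @return Invisibly, the list of normal/tumor sample IDs.
#' @export
validate_expression <- function(expr, groups) {
  expr_matrix(expr) # gene uniqueness + numeric checks
  invisible(split_groups(expr, groups))
}

#' Read a directed influence network
#'
#' Reads an edge list as either a two-column TSV (`from`, `to`) or a
#' three-column SIF line format (`source interaction target`). Duplicate
#' directed edges are dropped with a warning; self-loops are dropped with a
#' message.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with character columns `from` and `to`; no duplicate
#'   edges, no self-loops.
#' @export
read_network <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort("empty network file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  # drop a header line if present
  first <- tolower(trimws(fields[[1]]))
  has_header <- length(first) >= 2 && all(first[c(1, length(first))] %in%
    c("from", "to", "source", "target"))
  start <- if (has_header) 2L else 1L
  if (start > length(fields)) abort("network file contains only a header")
  fields <- fields[seq(start, length(fields))]
  n_fields <- lengths(fields)
  bad <- which(!n_fields %in% c(2L, 3L))
  if (length(bad) > 0) {
    abort(paste0("malformed network line ", bad[1] + start - 1L,
                 ": expected 2 (TSV) or 3 (SIF) fields"))
  }
  if (length(unique(n_fields)) > 1) {
    abort("mixed 2- and 3-column lines in network file")
  }
  from <- vapply(fields, `[[`, character(1), 1L)
  to <- vapply(fields, function(f) f[[length(f)]], character(1))
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    bad <- which(!nzchar(from) | !nzchar(to))[1]
    abort(paste0("malformed network line ", bad + start - 1L, ": empty gene identifier"))
  }
  edges <- tibble::tibble(from = from, to = to)
  loops <- edges$from == edges$to
  if (any(loops)) {
    inform(paste0("dropped ", sum(loops), " self-loop(s)"))
    edges <- edges[!loops, ]
  }
  dups <- duplicated(edges)
  if (any(dups)) {
    warn(paste0("dropped ", sum(dups), " duplicate edge(s)"))
    edges <- edges[!dups, ]
  }
  edges
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated as set name,
#' description, then member genes. Empty sets are skipped with a warning;
#' duplicate members within a set are deduplicated.
#'
#' @param path Path to a `.gmt` file.
#' @return A long tibble with columns `set_id`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::map(lines, function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || all(!nzchar(f[-(1:2)]))) {
      warn(paste0("skipping empty gene set: ", f[1]))
      return(NULL)
    }
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    tibble::tibble(set_id = f[1], description = f[2], gene = genes)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) abort("no non-empty gene sets in GMT file")
  out
}

#' Read a drug-to-target table
#'
#' Two-column TSV (`drug`, `target gene`), one target per line, header
#' optional. Drugs with no targets do not occur in this format; downstream
#' enrichment flags drugs whose targets fall outside the analysis universe.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `drug` and `gene`.
#' @export
read_drug_targets <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (ncol(tab) < 2) abort("drug-target file must have two columns: drug, target")
  names(tab)[1:2] <- c("drug", "gene")
  dplyr::distinct(tibble::tibble(drug = tab$drug, gene = tab$gene))
}

#' Read a binary mutation matrix
#'
#' Tab-separated genes-by-tumor-samples matrix of 0/1 non-silent mutation
#' indicators; layout matches [read_expression()].
#'
#' @param path Path to the TSV file.
#' @return A tibble with a `gene` column followed by one 0/1 column per
#'   tumor sample.
#' @export
read_mutations <- function(path) {
  mut <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(mut)[1] <- "gene"
  mut$gene <- as.character(mut$gene)
  m <- expr_matrix(mut)
  if (anyNA(m) || !all(m %in% c(0, 1))) {
    abort("mutation matrix must contain only 0/1 values")
  }
  tibble::as_tibble(mut)
}

#' Read a survival table
#'
#' TSV with columns `sample`, `time` (positive follow-up time) and `event`
#' (1 = death/event observed, 0 = censored).
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample`, `time`, `event`.
#' @export
read_survival <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("sample", "time", "event") %in% names(tab))) {
    abort("survival file must have columns sample, time, event")
  }
  tab <- tibble::tibble(
    sample = as.character(tab$sample),
    time = as.numeric(tab$time),
    event = as.integer(tab$event)
  )
  if (anyNA(tab$time) || any(tab$time <= 0)) abort("survival times must be > 0")
  if (!all(tab$event %in% c(0L, 1L))) abort("event flags must be 0 or 1")
  if (anyDuplicated(tab$sample) > 0) abort("duplicate sample identifiers in survival table")
  tab
}

#' Write a result bundle with a JSON run manifest
#'
#' Writes every tibble in `results` as a TSV (and every character vector as
#' a plain text file) under `dir`, together with `manifest.json` recording
#' the configuration, seed, input checksums and output file list, so a run
#' can be reproduced bit-for-bit.
#'
#' @param dir Output directory (created if needed).
#' @param results Named list of tibbles/character vectors.
#' @param config Named list echoed into the manifest.
#' @param seed Integer RNG seed used for the run (may be NULL).
#' @param inputs Named character vector of input file paths to checksum.
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(dir, results, config = list(), seed = NULL, inputs = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (name in names(results)) {
    x <- results[[name]]
    if (is.data.frame(x)) {
      f <- file.path(dir, paste0(name, ".tsv"))
      readr::write_tsv(x, f, progress = FALSE)
    } else {
      f <- file.path(dir, paste0(name, ".txt"))
      readr::write_lines(as.character(x), f)
    }
    files <- c(files, basename(f))
  }
  manifest <- list(
    package = "dysnet",
    version = as.character(packageVersion("dysnet")),
    config = config,
    seed = seed,
    inputs = as.list(if (length(inputs)) tools::md5sum(inputs) else character()),
    outputs = as.list(setNames(unname(tools::md5sum(file.path(dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
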