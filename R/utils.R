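# Internal helpers shared across modules.

# Convert a tidy expression tibble (gene + one numeric column per sample)
# into a genes x samples numeric matrix with dimnames.
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "gene" %in% names(expr))
  genes <- as.character(expr$gene)
  if (anyDuplicated(genes) > 0) {
    dup <- unique(genes[duplicated(genes)])
    abort(paste0("duplicate gene identifiers: ", paste(head(dup, 5), collapse = ", ")))
  }
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  if (!is.numeric(m)) abort("expression values must be numeric")
  rownames(m) <- genes
  m
}

# Validate groups against an expression tibble and split samples into the
# normal set and a single tumor set. `groups` is a tibble(sample, group);
# the label "normal" marks reference samples, any single other label marks
# the tumor subtype for this run.
split_groups <- function(expr, groups) {
  stopifnot(is.data.frame(groups), all(c("sample", "group") %in% names(groups)))
  samples <- setdiff(names(expr), "gene")
  missing <- setdiff(samples, groups$sample)
  if (length(missing) > 0) {
    abort(paste0("sample(s) missing from group map: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(groups$sample) > 0) {
    abort("duplicate sample identifiers in group map")
  }
  grp <- setNames(as.character(groups$group), groups$sample)[samples]
  tumor_labels <- setdiff(unique(grp), "normal")
  if (!"normal" %in% grp) abort("no sample labelled 'normal' in group map")
  if (length(tumor_labels) == 0) abort("no tumor-labelled samples in group map")
  if (length(tumor_labels) > 1) {
    abort(paste0(
      "one tumor subtype per run: found labels ",
      paste(tumor_labels, collapse = ", "),
      "; subset the group map first"
    ))
  }
  list(
    normal = samples[grp == "normal"],
    tumor = samples[grp == tumor_labels],
    tumor_label = tumor_labels
  )
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(paste0("`", name, "` must be a positive number"))
  }
  invisible(x)
}

# Edge tibble validation: two character columns from/to.
as_edge_tbl <- function(network) {
  stopifnot(is.data.frame(network))
  if (!all(c("from", "to") %in% names(network))) {
    abort("network must have columns `from` and `to`")
  }
  tibble::tibble(from = as.character(network$from), to = as.character(network$to))
}

network_nodes <- function(network) {
  unique(c(network$from, network$to))
}
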