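#' Gene dysregulation scores
#'
#' A gene's dysregulation score d is the sum of dysregulation strengths
#' over its outgoing edges retained in the dysregulated network. Genes that
#' appear in the DN only as targets score 0. Genes are ranked by descending
#' score (ties broken by gene ID ascending) and the cumulative normalized
#' score is accumulated over that order.
#'
#' @param dn A `dysnet_dn` object from [build_dn()].
#' @return A tibble: `gene`, `d`, `n_out` (DN out-degree), `rank`,
#'   `cum_share` (cumulative fraction of the total score).
#' @export
dysregulation_scores <- function(dn) {
  stopifnot(inherits(dn, "dysnet_dn"))
  if (nrow(dn$edges) == 0) abort("empty dysregulated network: no edges passed the thresholds")
  sources <- dn$edges |>
    dplyr::group_by(gene = .data$from) |>
    dplyr::summarise(d = sum(.data$ds), n_out = dplyr::n(), .groups = "drop")
  sinks <- setdiff(unique(dn$edges$to), sources$gene)
  scores <- dplyr::bind_rows(
    sources,
    tibble::tibble(gene = sinks, d = 0, n_out = 0L)
  ) |>
    dplyr::arrange(dplyr::desc(.data$d), .data$gene) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  cum_share = cumsum(.data$d) / sum(.data$d))
  scores
}

#' Select key genes by the cumulative-score rule
#'
#' Returns the shortest prefix of the score ranking whose cumulative
#' normalized dysregulation score reaches `fraction` (default 0.6, i.e.
#' the genes jointly carrying 60\% of the total score). The boundary gene
#' is included (cum_share >= fraction).
#'
#' @param scores Score tibble from [dysregulation_scores()].
#' @param fraction Cumulative-share cutoff in (0, 1].
#' @return Character vector of key genes in rank order.
#' @export
select_key_genes <- function(scores, fraction = 0.6) {
  stopifnot(all(c("gene", "d", "cum_share") %in% names(scores)))
  if (fraction <= 0 || fraction > 1) abort("`fraction` must be in (0, 1]")
  if (sum(scores$d) <= 0) abort("all dysregulation scores are zero")
  scores <- dplyr::arrange(scores, .data$rank)
  cut <- which(scores$cum_share >= fraction - 1e-12)[1]
  scores$gene[seq_len(cut)]
}

#' Extract the key dysregulated network
#'
#' The KDN is the subnetwork of the key genes and their dysregulated
#' interactions. `mode = "out_edges"` (default) keeps every DN edge whose
#' source is a key gene — matching the score definition, which sums over
#' out-edges; `mode = "induced"` keeps only edges with both endpoints key.
#'
#' @param dn A `dysnet_dn` object.
#' @param key_genes Character vector of key genes (subset of DN genes).
#' @param mode `"out_edges"` or `"induced"`.
#' @return An object of class `dysnet_kdn`: list with `key_genes`, `edges`,
#'   `mode`, and the parent `dn` parameters.
#' @export
extract_kdn <- function(dn, key_genes, mode = c("out_edges", "induced")) {
  stopifnot(inherits(dn, "dysnet_dn"))
  mode <- match.arg(mode)
  if (length(key_genes) == 0) abort("empty key-gene set")
  dn_genes <- unique(c(dn$edges$from, dn$edges$to))
  if (!all(key_genes %in% dn_genes)) {
    abort("key genes must belong to the dysregulated network")
  }
  edges <- if (mode == "out_edges") {
    dn$edges[dn$edges$from %in% key_genes, ]
  } else {
    dn$edges[dn$edges$from %in% key_genes & dn$edges$to %in% key_genes, ]
  }
  structure(
    list(key_genes = key_genes, edges = edges, mode = mode, params = dn$params),
    class = "dysnet_kdn"
  )
}

#' @export
print.dysnet_kdn <- function(x, ...) {
  cat("Key dysregulated network (mode: ", x$mode, ")\n", sep = "")
  cat("  key genes:", length(x$key_genes), "\n")
  cat("  edges:    ", nrow(x$edges), "\n")
  invisible(x)
}

#' Topology summary of a (key) dysregulated network
#'
#' Reports gene and edge counts, the average total degree `2 E / N` over
#' genes incident to at least one retained edge, and the average
#' betweenness centrality (directed shortest-path counts, unnormalized).
#'
#' @param x A `dysnet_dn`, `dysnet_kdn`, or edge tibble (`from`, `to`).
#' @return A one-row tibble: `n_genes`, `n_edges`, `avg_degree`,
#'   `avg_betweenness`.
#' @export
network_summary <- function(x) {
  edges <- if (inherits(x, c("dysnet_dn", "dysnet_kdn"))) x$edges else as_edge_tbl(x)
  if (nrow(edges) == 0) abort("no edges to summarize")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = TRUE)
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  tibble::tibble(
    n_genes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    avg_degree = 2 * igraph::ecount(g) / igraph::vcount(g),
    avg_betweenness = mean(btw)
  )
}

#' Dysregulation score versus DN out-degree
#'
#' Per-gene table of the dysregulation score and the out-degree in the DN,
#' with their Pearson correlation as the `pearson_r` attribute (NA when
#' fewer than two scored genes). Scores grow with out-degree by
#' construction; hub regulators dominate the score distribution.
#'
#' @param scores Score tibble from [dysregulation_scores()].
#' @return A tibble `gene`, `d`, `out_degree` with attribute `pearson_r`.
#' @export
score_outdegree_table <- function(scores) {
  out <- tibble::tibble(gene = scores$gene, d = scores$d,
                        out_degree = scores$n_out)
  r <- if (nrow(out) >= 2 && sd(out$d) > 0 && sd(out$out_degree) > 0) {
    cor(out$d, out$out_degree)
  } else {
    NA_real_
  }
  attr(out, "pearson_r") <- r
  out
}
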