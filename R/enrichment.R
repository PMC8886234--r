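#' Hypergeometric over-representation test
#'
#' Upper-tail hypergeometric test of the overlap between a query gene set
#' and a target gene set within a finite universe:
#' p = P(X >= overlap) with X ~ Hypergeometric(universe, target, query).
#' The enrichment score is `-log10(p)`.
#'
#' @param query Character vector of query genes (subset of `universe`).
#' @param target Character vector of target genes (subset of `universe`).
#' @param universe Character vector, the background gene universe.
#' @return A one-row tibble: `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `score`.
#' @export
hypergeom_test <- function(query, target, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query <- unique(query)
  target <- unique(target)
  bad <- setdiff(query, universe)
  if (length(bad) > 0) {
    abort(paste0("query gene(s) outside the universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  bad <- setdiff(target, universe)
  if (length(bad) > 0) {
    abort(paste0("target gene(s) outside the universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  k <- length(intersect(query, target))
  p <- if (k == 0) 1 else phyper(k - 1, length(target),
                                 length(universe) - length(target),
                                 length(query), lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  tibble::tibble(
    overlap = k, set_size = length(target), query_size = length(query),
    universe_size = length(universe), p_value = p, score = -log10(p)
  )
}

#' Pathway enrichment of a gene list
#'
#' Applies [hypergeom_test()] to every set of a gene-set collection,
#' filters at `alpha` and ranks by ascending p-value. Set members outside
#' the universe are ignored (the test is conditioned on the universe).
#'
#' @param gene_sets Long tibble (`set_id`, `description`, `gene`), e.g.
#'   from [read_gmt()].
#' @param query Character vector of query genes (e.g. key genes).
#' @param universe Background gene universe.
#' @param alpha Report sets with p <= `alpha` (default 0.05; use 1 for all).
#' @return A tibble, one row per reported set, sorted by `p_value`.
#' @export
pathway_enrichment <- function(gene_sets, query, universe, alpha = 0.05) {
  stopifnot(all(c("set_id", "gene") %in% names(gene_sets)))
  if (nrow(gene_sets) == 0) abort("empty gene-set collection")
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  res <- gene_sets |>
    dplyr::group_by(.data$set_id) |>
    dplyr::group_modify(function(df, key) {
      members <- intersect(unique(df$gene), universe)
      desc <- if ("description" %in% names(df)) df$description[1] else NA_character_
      if (length(members) == 0) {
        return(tibble::tibble(description = desc, overlap = 0L, set_size = 0L,
                              query_size = length(query),
                              universe_size = length(universe),
                              p_value = 1, score = 0))
      }
      dplyr::bind_cols(tibble::tibble(description = desc),
                       hypergeom_test(query, members, universe))
    }) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$p_value <= alpha) |>
    dplyr::arrange(.data$p_value, .data$set_id)
  res
}

#' Drug-target enrichment in the key dysregulated network
#'
#' Scores each drug by the hypergeometric enrichment of its expanded
#' target set — the drug's targets plus their first-order influence-network
#' neighbors (direction-agnostic) — against the key-network gene set. The
#' score is `-log10(p)`. Drugs with no target in the universe are flagged
#' untestable (`p = NA`).
#'
#' @param drug_targets Tibble (`drug`, `gene`), e.g. from
#'   [read_drug_targets()].
#' @param network Edge tibble used for neighbor expansion.
#' @param kdn_genes Character vector of key-network genes.
#' @param universe Background gene universe.
#' @param expand_neighbors Include first-order network neighbors of the
#'   targets (default TRUE).
#' @return A tibble, one row per drug: `drug`, `n_targets`,
#'   `expanded_size`, `overlap`, `p_value`, `score`, `testable`; sorted by
#'   descending score.
#' @export
drug_target_enrichment <- function(drug_targets, network, kdn_genes, universe,
                                   expand_neighbors = TRUE) {
  stopifnot(all(c("drug", "gene") %in% names(drug_targets)))
  network <- as_edge_tbl(network)
  universe <- unique(universe)
  kdn_genes <- intersect(unique(kdn_genes), universe)
  res <- drug_targets |>
    dplyr::group_by(.data$drug) |>
    dplyr::group_modify(function(df, key) {
      targets <- intersect(unique(df$gene), universe)
      if (length(targets) == 0) {
        return(tibble::tibble(n_targets = 0L, expanded_size = 0L, overlap = 0L,
                              p_value = NA_real_, score = NA_real_,
                              testable = FALSE))
      }
      expanded <- targets
      if (expand_neighbors) {
        nb <- c(network$to[network$from %in% targets],
                network$from[network$to %in% targets])
        expanded <- union(targets, intersect(nb, universe))
      }
      ht <- hypergeom_test(expanded, kdn_genes, universe)
      tibble::tibble(n_targets = length(targets),
                     expanded_size = length(expanded),
                     overlap = ht$overlap, p_value = ht$p_value,
                     score = ht$score, testable = TRUE)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$score))
  res
}
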