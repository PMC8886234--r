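#' Tidy a dysregulated network
#'
#' Returns the per-edge statistics table with an `in_dn` flag marking
#' edges that passed both thresholds.
#'
#' @param x A `dysnet_dn` object.
#' @param ... Unused.
#' @return A tibble, one row per tested edge.
#' @method tidy dysnet_dn
#' @export
tidy.dysnet_dn <- function(x, ...) {
  key <- paste(x$edges$from, x$edges$to)
  dplyr::mutate(tibble::as_tibble(x$stats),
                in_dn = paste(.data$from, .data$to) %in% key)
}

#' One-row summary of a dysregulated network
#'
#' @param x A `dysnet_dn` object.
#' @param ... Unused.
#' @return A one-row tibble with edge/gene counts, thresholds and the
#'   fitted variance-prior parameters.
#' @method glance dysnet_dn
#' @export
glance.dysnet_dn <- function(x, ...) {
  tibble::tibble(
    n_edges_tested = nrow(x$stats),
    n_edges_dn = nrow(x$edges),
    n_genes_dn = length(unique(c(x$edges$from, x$edges$to))),
    n_edges_skipped = x$n_skipped %||% 0L,
    p_threshold = x$params$p_threshold,
    ds_threshold = x$params$ds_threshold,
    method = x$params$method,
    d0 = if (!is.null(x$prior)) x$prior$d0 else NA_real_,
    s0sq = if (!is.null(x$prior)) x$prior$s0sq else NA_real_
  )
}

#' Tidy a key dysregulated network
#'
#' @param x A `dysnet_kdn` object.
#' @param ... Unused.
#' @return The KDN edge tibble.
#' @method tidy dysnet_kdn
#' @export
tidy.dysnet_kdn <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row summary of a key dysregulated network
#'
#' @param x A `dysnet_kdn` object.
#' @param ... Unused.
#' @return A one-row tibble with key-gene count, edge count and topology
#'   summary statistics.
#' @method glance dysnet_kdn
#' @export
glance.dysnet_kdn <- function(x, ...) {
  summ <- network_summary(x)
  tibble::tibble(
    n_key_genes = length(x$key_genes),
    n_edges = nrow(x$edges),
    mode = x$mode,
    avg_degree = summ$avg_degree,
    avg_betweenness = summ$avg_betweenness
  )
}
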