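#' Expression-outlier matrix for tumor samples
#'
#' Flags tumor expression values lying far outside the normal-group
#' reference distribution: outlier(g, s) = 1 when the log expression of
#' gene g in tumor sample s deviates from the normal-group mean by more
#' than `z_threshold` normal-group standard deviations. Genes whose
#' normal-group standard deviation is zero are skipped with a warning.
#'
#' @param expr Expression tibble.
#' @param groups Tibble with columns `sample`, `group`.
#' @param z_threshold Positive z-score cutoff (default 2).
#' @param pseudocount,log_base Log-transform parameters.
#' @return A tibble with a `gene` column and one 0/1 column per tumor
#'   sample.
#' @export
outlier_matrix <- function(expr, groups, z_threshold = 2, pseudocount = 0,
                           log_base = 2) {
  check_positive(z_threshold, "z_threshold")
  m <- expr_matrix(expr)
  sets <- split_groups(expr, groups)
  if (length(sets$normal) < 2) abort("need >= 2 normal samples to estimate the reference")
  mp <- m + pseudocount
  if (any(mp <= 0)) abort("zero expression encountered: use a positive `pseudocount`")
  lm_ <- log(mp, base = log_base)
  ref <- lm_[, sets$normal, drop = FALSE]
  mu <- rowMeans(ref)
  s <- apply(ref, 1, sd)
  degenerate <- s == 0
  if (any(degenerate)) {
    warn(paste0("skipping ", sum(degenerate),
                " gene(s) with zero normal-group standard deviation"))
  }
  keep <- !degenerate
  z <- abs(lm_[keep, sets$tumor, drop = FALSE] - mu[keep]) / s[keep]
  out <- (z > z_threshold) * 1L
  tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)[keep]),
                          tibble::as_tibble(out)))
}

# Coverage sets: for each mutated gene, the outlier events (gene, sample)
# reachable through its mutation instances — an event (h, s) is coverable
# by g iff g is mutated in s and g -> h is a network edge or h == g.
coverage_sets <- function(mutations, outliers, network) {
  network <- as_edge_tbl(network)
  mut <- expr_matrix(mutations)
  out <- expr_matrix(outliers)
  shared <- intersect(colnames(mut), colnames(out))
  if (length(shared) == 0) abort("no shared samples between mutation and outlier matrices")
  mut <- mut[, shared, drop = FALSE]
  out <- out[, shared, drop = FALSE]
  out_events <- which(out == 1L, arr.ind = TRUE)
  event_gene <- rownames(out)[out_events[, 1]]
  event_sample <- shared[out_events[, 2]]
  event_id <- paste(event_gene, event_sample, sep = "\r")
  events_by_sample <- split(seq_along(event_id), event_sample)

  mutated <- rownames(mut)[rowSums(mut) > 0]
  targets <- split(network$to, network$from)
  cov <- purrr::map(setNames(mutated, mutated), function(g) {
    reach <- c(g, targets[[g]])
    samp <- shared[mut[g, ] == 1L]
    idx <- unlist(events_by_sample[samp], use.names = FALSE)
    idx[event_gene[idx] %in% reach]
  })
  list(coverage = cov, n_events = length(event_id),
       mut_samples = rowSums(mut)[mutated])
}

#' Greedy driver-gene ranking by event covering
#'
#' Builds the bipartite structure linking mutation instances to
#' expression-outlier events through the influence network (a mutated gene
#' can explain an outlier event in the same sample when the outlying gene
#' is one of its direct targets, or itself), then greedily ranks genes:
#' repeatedly pick the mutated gene covering the most not-yet-covered
#' events, remove those events, and record the count at selection time.
#' Ties are broken by gene ID ascending.
#'
#' @param mutations Binary mutation tibble (gene x tumor samples).
#' @param outliers Binary outlier tibble from [outlier_matrix()].
#' @param network Edge tibble (`from`, `to`).
#' @return A tibble in selection order: `gene`, `events_covered`,
#'   `samples_mutated`. Attribute `n_events` holds the total event count.
#' @export
greedy_driver_rank <- function(mutations, outliers, network) {
  cs <- coverage_sets(mutations, outliers, network)
  cov <- cs$coverage
  cov <- cov[lengths(cov) > 0]
  if (length(cov) == 0) {
    warn("empty bipartite graph: no outlier event is reachable from a mutation")
    out <- tibble::tibble(gene = character(), events_covered = integer(),
                          samples_mutated = integer())
    attr(out, "n_events") <- cs$n_events
    return(out)
  }
  cov <- cov[order(names(cov))] # tie rule: gene ID ascending
  ranking <- list()
  repeat {
    sizes <- lengths(cov)
    if (length(sizes) == 0 || max(sizes) == 0) break
    pick <- which.max(sizes) # first max in gene-ID order
    g <- names(cov)[pick]
    covered <- cov[[pick]]
    ranking[[length(ranking) + 1]] <- tibble::tibble(
      gene = g, events_covered = length(covered),
      samples_mutated = as.integer(cs$mut_samples[g])
    )
    cov <- cov[-pick]
    cov <- purrr::map(cov, setdiff, covered)
    cov <- cov[lengths(cov) > 0]
  }
  out <- dplyr::bind_rows(ranking)
  attr(out, "n_events") <- cs$n_events
  out
}

#' Overlap between ranked drivers and the key-gene set
#'
#' Compares the top of the driver ranking with the key dysregulated
#' network's gene set: overlap count, Jaccard index, and the mean number
#' of covered events for drivers inside versus outside the key set.
#'
#' @param ranking Driver ranking from [greedy_driver_rank()].
#' @param key_genes Character vector of key genes.
#' @param top_k Number of top-ranked drivers to consider (default: all).
#' @return A one-row tibble: `n_drivers`, `n_key`, `overlap`, `jaccard`,
#'   `mean_events_in_kdn`, `mean_events_out_kdn`.
#' @export
kdn_driver_overlap <- function(ranking, key_genes, top_k = nrow(ranking)) {
  if (top_k > nrow(ranking)) abort("`top_k` exceeds the ranking length")
  top <- ranking[seq_len(top_k), ]
  in_kdn <- top$gene %in% key_genes
  tibble::tibble(
    n_drivers = nrow(top),
    n_key = length(key_genes),
    overlap = sum(in_kdn),
    jaccard = sum(in_kdn) / length(union(top$gene, key_genes)),
    mean_events_in_kdn = if (any(in_kdn)) mean(top$events_covered[in_kdn]) else NA_real_,
    mean_events_out_kdn = if (any(!in_kdn)) mean(top$events_covered[!in_kdn]) else NA_real_
  )
}
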