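# Independent brute-force oracles, deliberately naive implementations.

# Exact hypergeometric upper-tail probability by enumerating every possible
# draw of `n_query` genes from a universe of size `n_universe` containing
# `n_target` marked genes (feasible for n_universe <= 12).
bf_hyper_tail <- function(n_universe, n_target, n_query, k_observed) {
  if (n_query == 0) return(if (k_observed <= 0) 1 else 0)
  draws <- utils::combn(n_universe, n_query)
  marked <- seq_len(n_target)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k_observed)
}

# Betweenness by explicit enumeration of all directed simple paths: for
# every ordered pair (s, t), find all shortest paths and credit each
# intermediate vertex its fraction sigma_st(v) / sigma_st.
bf_betweenness <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- split(edges$to, factor(edges$from, levels = nodes))
  all_paths <- function(s, t) {
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        found[[length(found) + 1]] <<- path
        return()
      }
      for (nx in adj[[last]]) if (!nx %in% path) walk(c(path, nx))
    }
    walk(s)
    found
  }
  btw <- setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(shortest)
    }
  }
  btw
}

# Naive greedy max-coverage replay over named coverage sets (character
# event ids), ties broken by gene ID ascending.
bf_greedy_cover <- function(cov) {
  ranking <- list()
  remaining <- cov
  repeat {
    sizes <- vapply(remaining, length, integer(1))
    if (length(sizes) == 0 || max(sizes) == 0) break
    best <- sort(names(remaining)[sizes == max(sizes)])[1]
    ranking[[length(ranking) + 1]] <- list(gene = best,
                                           covered = length(remaining[[best]]))
    picked <- remaining[[best]]
    remaining[[best]] <- NULL
    remaining <- lapply(remaining, function(s) setdiff(s, picked))
    remaining <- remaining[vapply(remaining, length, integer(1)) > 0]
  }
  ranking
}

# Naive coverage-set construction straight from the definitions: gene g can
# explain outlier event (h, s) iff g is mutated in s and h == g or g -> h.
bf_coverage_sets <- function(mut, out, edges) {
  cov <- list()
  for (g in rownames(mut)) {
    if (sum(mut[g, ]) == 0) next
    ids <- character()
    for (s in colnames(mut)) {
      if (mut[g, s] != 1) next
      if (!s %in% colnames(out)) next
      for (h in rownames(out)) {
        if (out[h, s] == 1 && (h == g || any(edges$from == g & edges$to == h))) {
          ids <- c(ids, paste(h, s))
        }
      }
    }
    if (length(ids) > 0) cov[[g]] <- ids
  }
  cov
}

# Brute-force shortest score-prefix reaching a cumulative share.
bf_key_prefix <- function(d, genes, fraction) {
  ord <- order(-d, genes)
  d <- d[ord]
  genes <- genes[ord]
  total <- sum(d)
  for (k in seq_along(d)) {
    if (sum(d[seq_len(k)]) / total >= fraction - 1e-12) {
      return(genes[seq_len(k)])
    }
  }
  genes
}
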