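#' Simulate a directed influence network with heavy-tailed out-degree
#'
#' Generates a directed simple graph in which per-gene out-degrees follow a
#' heavy-tailed (Pareto-weighted) distribution scaled to a requested mean,
#' and targets are drawn uniformly without replacement. This emulates the
#' hub-dominated topology of curated pathway-derived influence networks:
#' a few regulators with very many targets, most genes with few.
#'
#' @param n_genes Number of genes (>= 10).
#' @param mean_out_degree Target mean out-degree; realized edge count is
#'   within 10\% of `n_genes * mean_out_degree`.
#' @param seed Integer RNG seed.
#' @param tail_exponent Pareto tail exponent for out-degree weights
#'   (smaller = heavier tail).
#' @param gene_ids Optional character vector of gene identifiers.
#' @return A tibble of directed edges (`from`, `to`).
#' @export
simulate_network <- function(n_genes, mean_out_degree, seed = 1,
                             tail_exponent = 1.5, gene_ids = NULL) {
  if (n_genes < 10) abort("`n_genes` must be >= 10")
  check_positive(mean_out_degree, "mean_out_degree")
  if (mean_out_degree >= n_genes) {
    abort("`mean_out_degree` must be smaller than `n_genes`")
  }
  genes <- gene_ids %||% sprintf("g%04d", seq_len(n_genes))
  if (length(genes) != n_genes) abort("`gene_ids` length must equal `n_genes`")
  with_seed(seed, {
    w <- runif(n_genes)^(-1 / tail_exponent) # Pareto(alpha) weights, xm = 1
    k <- pmin(round(w * mean_out_degree / mean(w)), n_genes - 1L)
    # capping heavy-tail draws shrinks the total; rescale the uncapped mass once
    target_total <- round(n_genes * mean_out_degree)
    if (sum(k) < 0.9 * target_total) {
      uncapped <- k < (n_genes - 1L)
      scale_up <- (target_total - sum(k[!uncapped])) / sum(k[uncapped])
      k[uncapped] <- pmin(round(k[uncapped] * scale_up), n_genes - 1L)
    }
    if (abs(sum(k) - target_total) > 0.1 * target_total) {
      abort("infeasible degree request: cannot realize mean out-degree within 10%")
    }
    edges <- purrr::map2(genes, k, function(g, deg) {
      if (deg == 0) return(NULL)
      tibble::tibble(from = g, to = sample(setdiff(genes, g), deg))
    })
    dplyr::bind_rows(edges)
  })
}

#' Simulate normal/tumor expression with planted dysregulated edges
#'
#' Per gene, a log-scale baseline is drawn uniformly on `mu_range` and
#' per-sample log2 values are i.i.d. Normal(mu, sigma). For each planted
#' edge (i, j) the tumor-group mean of the *target* gene j is shifted by
#' `-delta` log units, so the edge's expected dysregulation strength
#' (|mean tumor log-ratio - mean normal log-ratio|) equals `delta`. The
#' returned matrix is on linear scale.
#'
#' Shifting a target gene perturbs every network edge with exactly one
#' shifted endpoint, so the returned ground truth lists *all* such edges as
#' dysregulated (a superset of `planted_edges`). Optional `coshift_edges`
#' shift both endpoints together: both genes become differentially
#' expressed while the edge's log-ratio — and hence its dysregulation
#' strength — is unchanged.
#'
#' @param network Edge tibble (`from`, `to`).
#' @param n_normal,n_tumor Samples per group (>= 2 each).
#' @param planted_edges Tibble of network edges to dysregulate; their
#'   sources must not be shifted genes themselves.
#' @param delta Planted effect in `log_base` units (>= 0).
#' @param sigma Per-sample log-scale standard deviation (> 0).
#' @param seed Integer RNG seed.
#' @param log_base Log base for `delta` (expression is simulated in log2;
#'   deltas in other bases are converted).
#' @param coshift_edges Optional tibble of edges whose two endpoints are
#'   shifted together by `-delta`.
#' @param mu_range Range of per-gene baseline log2 means.
#' @param tumor_label Group label for tumor samples.
#' @return A list with elements `expr` (tibble gene x samples, linear
#'   scale), `groups` (tibble sample/group) and `truth` (list with
#'   `shifted_genes`, `coshift_genes`, `dysregulated_edges`, `delta`).
#' @export
simulate_expression <- function(network, n_normal, n_tumor,
                                planted_edges = NULL, delta = 3, sigma = 0.5,
                                seed = 1, log_base = 2, coshift_edges = NULL,
                                mu_range = c(4, 12), tumor_label = "tumor") {
  network <- as_edge_tbl(network)
  if (n_normal < 2 || n_tumor < 2) abort("need >= 2 samples per group")
  if (delta < 0) abort("`delta` must be >= 0")
  check_positive(sigma, "sigma")
  genes <- network_nodes(network)
  edge_key <- paste(network$from, network$to)

  shifted <- character()
  if (!is.null(planted_edges) && nrow(planted_edges) > 0) {
    planted_edges <- as_edge_tbl(planted_edges)
    if (!all(paste(planted_edges$from, planted_edges$to) %in% edge_key)) {
      abort("planted edge not present in network")
    }
    shifted <- unique(planted_edges$to)
    if (any(planted_edges$from %in% shifted)) {
      abort("planted-edge sources must be distinct from planted targets")
    }
  }
  co_genes <- character()
  if (!is.null(coshift_edges) && nrow(coshift_edges) > 0) {
    coshift_edges <- as_edge_tbl(coshift_edges)
    if (!all(paste(coshift_edges$from, coshift_edges$to) %in% edge_key)) {
      abort("co-shift edge not present in network")
    }
    co_genes <- unique(c(coshift_edges$from, coshift_edges$to))
  }

  delta2 <- delta * log(log_base, base = 2) # planted effect in log2 units
  all_shifted <- union(shifted, co_genes)
  samples <- c(sprintf("N%03d", seq_len(n_normal)), sprintf("T%03d", seq_len(n_tumor)))
  is_tumor <- c(rep(FALSE, n_normal), rep(TRUE, n_tumor))

  vals <- with_seed(seed, {
    mu <- runif(length(genes), mu_range[1], mu_range[2])
    logx <- matrix(rnorm(length(genes) * length(samples), mean = mu, sd = sigma),
                   nrow = length(genes), dimnames = list(genes, samples))
    shift_rows <- genes %in% all_shifted
    logx[shift_rows, is_tumor] <- logx[shift_rows, is_tumor] - delta2
    2^logx
  })

  n_shifted_ends <- (network$from %in% shifted) + (network$to %in% shifted)
  dys <- network[n_shifted_ends == 1L, ]

  list(
    expr = tibble::as_tibble(cbind(tibble::tibble(gene = genes),
                                   tibble::as_tibble(vals))),
    groups = tibble::tibble(sample = samples,
                            group = ifelse(is_tumor, tumor_label, "normal")),
    truth = list(
      shifted_genes = shifted,
      coshift_genes = co_genes,
      dysregulated_edges = dys,
      delta = delta
    )
  )
}

#' Choose planted edges with isolated targets
#'
#' Helper for building recovery benchmarks: greedily picks edges whose
#' targets are distinct and whose sources are never targets, so each
#' planted shift dysregulates a well-defined edge set.
#'
#' @param network Edge tibble.
#' @param n_edges Number of edges to plant.
#' @param seed Integer RNG seed.
#' @return A tibble of planted edges (`from`, `to`).
#' @export
pick_planted_edges <- function(network, n_edges, seed = 1) {
  network <- as_edge_tbl(network)
  with_seed(seed, {
    ord <- sample.int(nrow(network))
    picked_from <- character()
    picked_to <- character()
    keep <- integer()
    for (idx in ord) {
      f <- network$from[idx]
      t <- network$to[idx]
      if (t %in% c(picked_to, picked_from) || f %in% picked_to) next
      keep <- c(keep, idx)
      picked_from <- c(picked_from, f)
      picked_to <- c(picked_to, t)
      if (length(keep) == n_edges) break
    }
    if (length(keep) < n_edges) {
      abort("could not find enough vertex-disjoint edges to plant")
    }
    network[sort(keep), ]
  })
}

#' Simulate a binary mutation matrix with planted drivers
#'
#' Each planted driver gene is mutated in each tumor sample with
#' probability `driver_rate`; every other network gene with probability
#' `passenger_rate`. For every (driver, sample) mutation, the driver's
#' direct network targets are flagged for outlier injection in the paired
#' expression matrix (see [inject_outliers()]).
#'
#' @param network Edge tibble.
#' @param drivers Character vector of driver genes (subset of network nodes).
#' @param tumor_samples Character vector of tumor sample IDs.
#' @param driver_rate,passenger_rate Per-sample mutation probabilities in (0,1].
#' @param seed Integer RNG seed.
#' @return A list with `mutations` (tibble gene x tumor samples, 0/1) and
#'   `injections` (tibble `gene`, `sample` of planned expression outliers).
#' @export
simulate_mutations <- function(network, drivers, tumor_samples,
                               driver_rate = 0.3, passenger_rate = 0.01,
                               seed = 1) {
  network <- as_edge_tbl(network)
  genes <- network_nodes(network)
  if (!all(drivers %in% genes)) abort("drivers must be network genes")
  if (length(drivers) == 0) warn("empty driver set: no planted signal to recover")
  stopifnot(driver_rate > 0, driver_rate <= 1, passenger_rate >= 0, passenger_rate <= 1)
  n_s <- length(tumor_samples)
  with_seed(seed, {
    rate <- ifelse(genes %in% drivers, driver_rate, passenger_rate)
    m <- matrix(rbinom(length(genes) * n_s, 1L, rep(rate, times = n_s)),
                nrow = length(genes), dimnames = list(genes, tumor_samples))
    inj <- purrr::map(drivers, function(d) {
      hit <- tumor_samples[m[d, ] == 1L]
      targets <- network$to[network$from == d]
      if (length(hit) == 0 || length(targets) == 0) return(NULL)
      tidyr::expand_grid(gene = targets, sample = hit)
    })
    list(
      mutations = tibble::as_tibble(cbind(tibble::tibble(gene = genes),
                                          tibble::as_tibble(m))),
      injections = dplyr::distinct(dplyr::bind_rows(inj))
    )
  })
}

#' Inject expression outliers at planned (gene, sample) positions
#'
#' Multiplies the stored expression by `log_base^shift` at each injection
#' position, i.e. adds `shift` log units — use a shift of at least 4 noise
#' standard deviations so injected values are unambiguous outliers.
#'
#' @param expr Expression tibble (linear scale).
#' @param injections Tibble with columns `gene`, `sample`.
#' @param shift Log-scale shift (in `log_base` units).
#' @param log_base Log base of `shift`.
#' @return The modified expression tibble.
#' @export
inject_outliers <- function(expr, injections, shift = 3, log_base = 2) {
  if (is.null(injections) || nrow(injections) == 0) return(expr)
  m <- expr_matrix(expr)
  keep <- injections$gene %in% rownames(m) & injections$sample %in% colnames(m)
  idx <- cbind(match(injections$gene[keep], rownames(m)),
               match(injections$sample[keep], colnames(m)))
  m[idx] <- m[idx] * log_base^shift
  tibble::as_tibble(cbind(tibble::tibble(gene = rownames(m)), tibble::as_tibble(m)))
}

#' Simulate survival times with a planted prognostic gene
#'
#' Event times are exponential with baseline hazard `baseline_hazard`;
#' samples whose expression of `gene` is above the median have their hazard
#' multiplied by `hazard_ratio`. Each subject is independently censored
#' with probability `censor_rate`, at a uniform time before its event.
#'
#' @param expr Expression tibble.
#' @param gene Prognostic gene identifier (must be in `expr`).
#' @param hazard_ratio Hazard multiplier for the high-expression group (> 0).
#' @param censor_rate Probability of censoring in [0, 1).
#' @param seed Integer RNG seed.
#' @param baseline_hazard Baseline exponential hazard (> 0).
#' @param samples Optional subset of samples to simulate (default: all).
#' @return A tibble with columns `sample`, `time`, `event`.
#' @export
simulate_survival <- function(expr, gene, hazard_ratio = 4, censor_rate = 0.2,
                              seed = 1, baseline_hazard = 0.1, samples = NULL) {
  m <- expr_matrix(expr)
  if (!gene %in% rownames(m)) abort(paste0("gene not in expression matrix: ", gene))
  check_positive(hazard_ratio, "hazard_ratio")
  stopifnot(censor_rate >= 0, censor_rate < 1)
  samples <- samples %||% colnames(m)
  x <- m[gene, samples]
  high <- x > median(x) # ties go to the low group
  with_seed(seed, {
    hz <- baseline_hazard * ifelse(high, hazard_ratio, 1)
    t_event <- rexp(length(samples), rate = hz)
    censored <- runif(length(samples)) < censor_rate
    time <- ifelse(censored, runif(length(samples), 0, t_event), t_event)
    tibble::tibble(
      sample = samples,
      time = pmax(time, .Machine$double.eps),
      event = as.integer(!censored)
    )
  })
}

#' Write a complete synthetic fixture bundle
#'
#' Generates a coherent data set — influence network, normal/tumor
#' expression with planted dysregulated edges, mutations with planted
#' drivers and injected expression outliers, pathway and drug-target sets
#' built around the planted signal, and survival times driven by a planted
#' prognostic gene — and writes it as plain TSV/GMT/JSON files.
#'
#' @param dir Output directory.
#' @param n_genes,mean_out_degree Network size parameters.
#' @param n_normal,n_tumor Samples per group.
#' @param n_planted Number of planted dysregulated edges.
#' @param delta,sigma Planted effect and noise SD (log2 units).
#' @param n_drivers Number of planted driver genes.
#' @param driver_rate,passenger_rate Mutation probabilities.
#' @param outlier_shift Log2 shift injected downstream of mutated drivers.
#' @param hazard_ratio Planted prognostic effect.
#' @param censor_rate Censoring probability.
#' @param seed Integer RNG seed for the whole bundle.
#' @return Invisibly, a list with the generated objects and `truth`.
#' @export
simulate_bundle <- function(dir, n_genes = 150, mean_out_degree = 4,
                            n_normal = 20, n_tumor = 20, n_planted = 10,
                            delta = 3, sigma = 0.5, n_drivers = 5,
                            driver_rate = 0.5, passenger_rate = 0.02,
                            outlier_shift = 3, hazard_ratio = 4,
                            censor_rate = 0.2, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  net <- simulate_network(n_genes, mean_out_degree, seed = seed)
  planted <- pick_planted_edges(net, n_planted, seed = seed + 1)
  sim <- simulate_expression(net, n_normal, n_tumor, planted,
                             delta = delta, sigma = sigma, seed = seed + 2)
  drivers <- with_seed(seed + 3, {
    out_deg <- sort(table(net$from), decreasing = TRUE)
    # drivers among well-connected regulators so their mutations have targets
    sample(names(out_deg)[seq_len(min(4 * n_drivers, length(out_deg)))], n_drivers)
  })
  mut <- simulate_mutations(net, drivers, sim$groups$sample[sim$groups$group != "normal"],
                            driver_rate = driver_rate,
                            passenger_rate = passenger_rate, seed = seed + 4)
  expr <- inject_outliers(sim$expr, mut$injections, shift = outlier_shift)
  prognostic <- sim$truth$shifted_genes[1]
  surv <- simulate_survival(expr, prognostic, hazard_ratio = hazard_ratio,
                            censor_rate = censor_rate, seed = seed + 5,
                            samples = sim$groups$sample[sim$groups$group != "normal"])

  genes <- network_nodes(net)
  gene_sets <- with_seed(seed + 6, {
    planted_set <- tibble::tibble(set_id = "PLANTED_TARGETS",
                                  description = "genes shifted in tumors",
                                  gene = sim$truth$shifted_genes)
    random_sets <- purrr::map(1:5, function(i) {
      tibble::tibble(set_id = sprintf("RANDOM_%02d", i),
                     description = "random background set",
                     gene = sample(genes, length(sim$truth$shifted_genes)))
    })
    dplyr::bind_rows(c(list(planted_set), random_sets))
  })
  drug_targets <- with_seed(seed + 7, {
    dplyr::bind_rows(
      tibble::tibble(drug = "drug_planted", gene = head(sim$truth$shifted_genes, 5)),
      tibble::tibble(drug = "drug_random", gene = sample(genes, 5))
    )
  })

  readr::write_tsv(expr, file.path(dir, "expression.tsv"), progress = FALSE)
  readr::write_tsv(sim$groups, file.path(dir, "groups.tsv"), progress = FALSE)
  readr::write_tsv(net, file.path(dir, "network.tsv"), progress = FALSE)
  readr::write_tsv(mut$mutations, file.path(dir, "mutations.tsv"), progress = FALSE)
  readr::write_tsv(drug_targets, file.path(dir, "drug_targets.tsv"), progress = FALSE)
  readr::write_tsv(surv, file.path(dir, "survival.tsv"), progress = FALSE)
  gmt_lines <- gene_sets |>
    dplyr::group_by(.data$set_id, .data$description) |>
    dplyr::summarise(members = paste(.data$gene, collapse = "\t"), .groups = "drop") |>
    dplyr::mutate(line = paste(.data$set_id, .data$description, .data$members, sep = "\t"))
  readr::write_lines(gmt_lines$line, file.path(dir, "gene_sets.gmt"))
  truth <- c(sim$truth, list(driver_genes = sort(drivers), prognostic_gene = prognostic,
                             hazard_ratio = hazard_ratio))
  jsonlite::write_json(
    list(shifted_genes = truth$shifted_genes,
         dysregulated_edges = truth$dysregulated_edges,
         delta = truth$delta, driver_genes = truth$driver_genes,
         prognostic_gene = truth$prognostic_gene, hazard_ratio = truth$hazard_ratio),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(network = net, expr = expr, groups = sim$groups,
                 mutations = mut$mutations, gene_sets = gene_sets,
                 drug_targets = drug_targets, survival = surv, truth = truth))
}
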