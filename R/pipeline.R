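#' Default analysis configuration
#'
#' Returns the default configuration list used by [run_all()]; any YAML
#' config is merged over these values. Thresholds follow the package
#' defaults: dysregulated edges at p <= 1e-4 and ds >= 2 (log2 units),
#' DEGs at p <= 1e-4 and fold change >= 1.5, key genes at 60\% cumulative
#' score, outliers beyond 2 normal-group standard deviations.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    expression = NULL, groups = NULL, network = NULL,
    mutations = NULL, gene_sets = NULL, drug_targets = NULL, survival = NULL,
    out_dir = "dysnet_report",
    log_base = 2, pseudocount = 0,
    edge_p_threshold = 1e-4, ds_threshold = 2,
    deg_p_threshold = 1e-4, deg_fc_threshold = 1.5,
    key_fraction = 0.6, kdn_mode = "out_edges",
    outlier_z_threshold = 2,
    top_k_survival = 10,
    enrichment_alpha = 0.05,
    test_method = "moderated", multiple_testing = "none",
    seed = 1
  )
}

#' Load a YAML analysis configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys
#' are an error; threshold values are validated.
#'
#' @param path Path to a YAML config file.
#' @return Named configuration list.
#' @export
load_config <- function(path) {
  user <- yaml::read_yaml(path)
  defaults <- default_config()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config <- modifyList(defaults, user)
  validate_config(config)
  config
}

#' Validate a configuration list
#'
#' Checks threshold positivity, the key fraction range and the test-method
#' and multiple-testing options; returns the config invisibly.
#'
#' @param config Named configuration list (see [default_config()]).
#' @return Invisibly, the validated config.
#' @export
validate_config <- function(config) {
  for (key in c("edge_p_threshold", "ds_threshold", "deg_p_threshold",
                "deg_fc_threshold", "outlier_z_threshold", "log_base")) {
    if (!is.numeric(config[[key]]) || config[[key]] <= 0) {
      abort(paste0("config `", key, "` must be > 0"))
    }
  }
  if (config$key_fraction <= 0 || config$key_fraction > 1) {
    abort("config `key_fraction` must be in (0, 1]")
  }
  if (!config$test_method %in% c("moderated", "welch")) {
    abort("config `test_method` must be 'moderated' or 'welch'")
  }
  if (!config$multiple_testing %in% c("none", "BH")) {
    abort("config `multiple_testing` must be 'none' or 'BH'")
  }
  invisible(config)
}

#' Run the full dysregulated-network pipeline
#'
#' Executes, in order: dysregulated-network construction, DEG analysis and
#' edge composition, key-gene/key-network extraction, driver ranking
#' (when a mutation matrix is configured), pathway and drug-target
#' enrichment (when gene sets are configured), and top-gene survival
#' analysis (when a survival table is configured). Every stage's table is
#' written as TSV under `out_dir` together with a JSON run manifest
#' capturing config, seed and input checksums.
#'
#' @param config A configuration list (see [default_config()]) or the path
#'   to a YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return Invisibly, a named list with all stage results.
#' @export
run_all <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- load_config(config)
  config <- modifyList(default_config(), config)
  validate_config(config)
  if (!is.null(out_dir)) config$out_dir <- out_dir
  for (key in c("expression", "groups", "network")) {
    if (is.null(config[[key]])) abort(paste0("config `", key, "` is required"))
    if (!file.exists(config[[key]])) {
      abort(paste0("input file not found: ", config[[key]]))
    }
  }
  run_stage <- function(stage, code) {
    tryCatch(force(code), error = function(e) {
      abort(paste0("stage `", stage, "` failed: ", conditionMessage(e)))
    })
  }
  skipped <- character()

  expr <- run_stage("read", read_expression(config$expression))
  groups <- run_stage("read", read_sample_groups(config$groups, expr))
  network <- run_stage("read", read_network(config$network))

  dn <- run_stage("build-dn", build_dn(
    expr, groups, network,
    p_threshold = config$edge_p_threshold, ds_threshold = config$ds_threshold,
    pseudocount = config$pseudocount, log_base = config$log_base,
    method = config$test_method, p_adjust = config$multiple_testing
  ))
  degs <- run_stage("build-dn", deg_test(
    expr, groups, p_threshold = config$deg_p_threshold,
    fc_threshold = config$deg_fc_threshold, pseudocount = config$pseudocount,
    log_base = config$log_base, method = config$test_method
  ))
  composition <- run_stage("build-dn", edge_deg_composition(network, dn, degs))

  scores <- run_stage("key-network", dysregulation_scores(dn))
  key_genes <- run_stage("key-network", select_key_genes(scores, config$key_fraction))
  kdn <- run_stage("key-network", extract_kdn(dn, key_genes, config$kdn_mode))
  summaries <- run_stage("key-network", dplyr::bind_rows(
    dplyr::mutate(network_summary(dn), network = "DN", .before = 1),
    dplyr::mutate(network_summary(kdn), network = "KDN", .before = 1)
  ))

  results <- list(
    edge_stats = dn$stats, dn_edges = dn$edges, deg = degs,
    edge_deg_composition = composition, gene_scores = scores,
    key_genes = key_genes, kdn_edges = kdn$edges, network_summary = summaries
  )
  objects <- list(dn = dn, degs = degs, composition = composition,
                  scores = scores, key_genes = key_genes, kdn = kdn,
                  summaries = summaries)

  universe <- intersect(expr$gene, network_nodes(network))

  if (!is.null(config$mutations)) {
    mutations <- run_stage("drivers", read_mutations(config$mutations))
    outliers <- run_stage("drivers", outlier_matrix(
      expr, groups, z_threshold = config$outlier_z_threshold,
      pseudocount = config$pseudocount, log_base = config$log_base
    ))
    ranking <- run_stage("drivers", greedy_driver_rank(mutations, outliers, network))
    overlap <- run_stage("drivers", kdn_driver_overlap(ranking, key_genes))
    results$driver_ranking <- ranking
    results$kdn_overlap <- overlap
    objects$ranking <- ranking
    objects$overlap <- overlap
  } else {
    skipped <- c(skipped, "drivers")
  }

  if (!is.null(config$gene_sets)) {
    gene_sets <- run_stage("enrich-pathways", read_gmt(config$gene_sets))
    pathways <- run_stage("enrich-pathways", pathway_enrichment(
      gene_sets, key_genes, universe, alpha = config$enrichment_alpha
    ))
    results$pathway_enrichment <- pathways
    objects$pathways <- pathways
  } else {
    skipped <- c(skipped, "enrich-pathways")
  }

  if (!is.null(config$drug_targets)) {
    drug_targets <- run_stage("enrich-drugs", read_drug_targets(config$drug_targets))
    kdn_genes <- unique(c(kdn$key_genes, kdn$edges$to))
    drugs <- run_stage("enrich-drugs", drug_target_enrichment(
      drug_targets, network, kdn_genes, universe
    ))
    results$drug_enrichment <- drugs
    objects$drugs <- drugs
  } else {
    skipped <- c(skipped, "enrich-drugs")
  }

  if (!is.null(config$survival)) {
    surv <- run_stage("survival", read_survival(config$survival))
    logrank <- run_stage("survival", top_gene_survival(
      scores, expr, surv, k = config$top_k_survival
    ))
    results$survival_logrank <- logrank
    objects$logrank <- logrank
  } else {
    skipped <- c(skipped, "survival")
  }

  inputs <- unlist(config[c("expression", "groups", "network", "mutations",
                            "gene_sets", "drug_targets", "survival")])
  manifest <- write_report(
    config$out_dir, results,
    config = c(config, list(skipped_stages = as.list(skipped))),
    seed = config$seed, inputs = inputs
  )
  objects$manifest <- manifest
  objects$results <- results
  invisible(objects)
}
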