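#' Per-sample regulation strength of one edge
#'
#' The regulation strength of gene i on its direct target j in sample s is
#' the log expression ratio `log((g_i + c) / (g_j + c))`: positive when the
#' regulator is expressed above its target, negative otherwise. A
#' pseudocount c > 0 is required when zeros are present.
#'
#' @param expr Expression tibble (`gene` column + sample columns).
#' @param from,to Gene identifiers of the directed edge.
#' @param pseudocount Non-negative pseudocount c.
#' @param log_base Logarithm base (default 2).
#' @return A tibble with columns `sample` and `r`.
#' @export
regulation_strength <- function(expr, from, to, pseudocount = 0, log_base = 2) {
  m <- expr_matrix(expr)
  for (g in c(from, to)) {
    if (!g %in% rownames(m)) abort(paste0("gene not in expression matrix: ", g))
  }
  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  gi <- m[from, ] + pseudocount
  gj <- m[to, ] + pseudocount
  if (any(gi <= 0) || any(gj <= 0)) {
    abort("zero expression encountered: use a positive `pseudocount`")
  }
  tibble::tibble(sample = colnames(m), r = unname(log(gi / gj, base = log_base)))
}

#' Moment fit of the variance prior for the moderated t-test
#'
#' Fits a scaled inverse-chi-square prior (d0 prior degrees of freedom, s0^2
#' prior variance) to a vector of residual variances by matching the mean
#' and variance of log variances to their theoretical log-F moments. When
#' the spread of log variances is at or below the sampling floor
#' `trigamma(df/2)`, complete pooling (`d0 = Inf`) is returned.
#'
#' @param variances Positive residual variances, one per edge/gene (>= 10).
#' @param df Residual degrees of freedom each variance was estimated with.
#' @return A list with elements `d0` and `s0sq`.
#' @export
fit_variance_prior <- function(variances, df) {
  if (length(variances) < 10) {
    abort("need >= 10 variances to fit the prior; use method = \"welch\" instead")
  }
  if (any(variances <= 0) || anyNA(variances)) abort("variances must be positive")
  check_positive(df, "df")
  z <- log(variances)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- var(z) - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0sq <- exp(mean(e))
  }
  list(d0 = d0, s0sq = s0sq)
}

# Newton solve of trigamma(x) = y for x > 0.
trigamma_inverse <- function(y) {
  if (y <= 0) abort("trigamma_inverse requires y > 0")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Vectorized two-group tests on the rows of a matrix.
# Returns per-row mean difference (tumor - normal), t, df, p.
two_group_test <- function(mat, idx_n, idx_t, method = c("moderated", "welch"),
                           prior = NULL) {
  method <- match.arg(method)
  n_n <- length(idx_n)
  n_t <- length(idx_t)
  if (n_n < 2 || n_t < 2) abort("need >= 2 samples per group")
  xn <- mat[, idx_n, drop = FALSE]
  xt <- mat[, idx_t, drop = FALSE]
  mn <- rowMeans(xn)
  mt <- rowMeans(xt)
  ssn <- rowSums((xn - mn)^2)
  sst <- rowSums((xt - mt)^2)
  diff <- mt - mn
  if (method == "welch") {
    vn <- ssn / (n_n - 1)
    vt <- sst / (n_t - 1)
    se2 <- vn / n_n + vt / n_t
    t_stat <- diff / sqrt(se2)
    df <- se2^2 / ((vn / n_n)^2 / (n_n - 1) + (vt / n_t)^2 / (n_t - 1))
    prior_used <- NULL
  } else {
    d <- n_n + n_t - 2
    s2 <- (ssn + sst) / d
    prior_used <- prior %||% fit_variance_prior(s2[s2 > 0], d)
    s2_post <- if (is.infinite(prior_used$d0)) {
      rep(prior_used$s0sq, length(s2))
    } else {
      (prior_used$d0 * prior_used$s0sq + d * s2) / (prior_used$d0 + d)
    }
    t_stat <- diff / sqrt(s2_post * (1 / n_n + 1 / n_t))
    df <- rep(prior_used$d0 + d, length(s2))
  }
  p <- 2 * pt(-abs(t_stat), df = df)
  p[is.na(p)] <- 1 # zero-variance, zero-difference rows
  list(diff = unname(diff), mean_n = unname(mn), mean_t = unname(mt),
       t_stat = unname(t_stat), df = unname(df),
       p_value = unname(pmin(pmax(p, .Machine$double.xmin), 1)),
       prior = prior_used)
}

#' Test one edge's regulation strengths between groups
#'
#' Computes the edge's dysregulation strength — the absolute difference
#' between tumor- and normal-group mean regulation strengths — and a
#' two-sample test on the per-sample log-ratios: either Welch's t-test or
#' the moderated t-test with an empirical-Bayes shrunken variance
#' `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` referred to a Student-t on
#' `d0 + d` degrees of freedom. For the moderated method the prior
#' `(d0, s0sq)` is normally fitted across all edges by [fit_variance_prior()]
#' and passed in; with `d0 = 0` the ordinary pooled t-test is recovered.
#'
#' @param reg Tibble from [regulation_strength()] (`sample`, `r`).
#' @param groups Tibble with columns `sample`, `group`.
#' @param method `"moderated"` or `"welch"`.
#' @param d0,s0sq Optional shared variance-prior parameters for the
#'   moderated method.
#' @return A one-row tibble: `r_bar_tumor`, `r_bar_normal`, `ds`,
#'   `direction`, `t_stat`, `df`, `p_value`.
#' @export
edge_test <- function(reg, groups, method = c("moderated", "welch"),
                      d0 = NULL, s0sq = NULL) {
  method <- match.arg(method)
  stopifnot(all(c("sample", "r") %in% names(reg)))
  grp <- setNames(as.character(groups$group), groups$sample)[reg$sample]
  if (anyNA(grp)) abort("sample(s) in `reg` missing from group map")
  idx_n <- which(grp == "normal")
  idx_t <- which(grp != "normal")
  prior <- if (!is.null(d0)) list(d0 = d0, s0sq = s0sq %||% 1) else NULL
  if (method == "moderated" && is.null(prior)) {
    # single-edge call with no shared prior: fall back to the ordinary
    # pooled t (d0 = 0), which the shrinkage formula reduces to
    prior <- list(d0 = 0, s0sq = 1)
  }
  res <- two_group_test(matrix(reg$r, nrow = 1), idx_n, idx_t, method, prior)
  tibble::tibble(
    r_bar_tumor = res$mean_t, r_bar_normal = res$mean_n,
    ds = abs(res$diff), direction = ifelse(res$diff >= 0, "up", "down"),
    t_stat = res$t_stat, df = res$df, p_value = res$p_value
  )
}

#' Edge-level dysregulation statistics for a whole network
#'
#' Computes, for every network edge with both endpoints measured, the
#' per-sample regulation strengths and the group comparison of
#' [edge_test()], with the moderated test's variance prior fitted across
#' all edges. Edges with unmeasured endpoints are skipped with a message;
#' their count is kept in the `n_skipped` attribute.
#'
#' @param expr Expression tibble.
#' @param groups Tibble with columns `sample`, `group`.
#' @param network Edge tibble (`from`, `to`).
#' @param pseudocount Pseudocount for the log-ratio (see
#'   [regulation_strength()]).
#' @param log_base Logarithm base.
#' @param method `"moderated"` (default) or `"welch"`.
#' @param p_adjust `"none"` (default; raw p-values are thresholded) or
#'   `"BH"` for Benjamini-Hochberg adjustment.
#' @return A tibble with one row per tested edge: `from`, `to`,
#'   `r_bar_tumor`, `r_bar_normal`, `ds`, `direction`, `t_stat`, `df`,
#'   `p_value`. Attributes: `prior` (fitted `d0`, `s0sq` for the moderated
#'   method), `n_skipped`.
#' @export
edge_stats <- function(expr, groups, network, pseudocount = 0, log_base = 2,
                       method = c("moderated", "welch"),
                       p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  network <- as_edge_tbl(network)
  m <- expr_matrix(expr)
  sets <- split_groups(expr, groups)

  measured <- network$from %in% rownames(m) & network$to %in% rownames(m)
  n_skipped <- sum(!measured)
  if (n_skipped > 0) {
    inform(paste0("skipping ", n_skipped, " edge(s) with unmeasured endpoints"))
  }
  edges <- network[measured, ]
  if (nrow(edges) == 0) abort("no network edge has both endpoints in the expression matrix")

  if (pseudocount < 0) abort("`pseudocount` must be >= 0")
  mp <- m + pseudocount
  if (any(mp <= 0)) abort("zero expression encountered: use a positive `pseudocount`")
  lm_ <- log(mp, base = log_base)
  r_mat <- lm_[edges$from, , drop = FALSE] - lm_[edges$to, , drop = FALSE]

  idx_n <- match(sets$normal, colnames(m))
  idx_t <- match(sets$tumor, colnames(m))
  res <- two_group_test(r_mat, idx_n, idx_t, method)
  p <- if (p_adjust == "BH") stats::p.adjust(res$p_value, method = "BH") else res$p_value

  out <- tibble::tibble(
    from = edges$from, to = edges$to,
    r_bar_tumor = res$mean_t, r_bar_normal = res$mean_n,
    ds = abs(res$diff), direction = ifelse(res$diff >= 0, "up", "down"),
    t_stat = res$t_stat, df = res$df, p_value = p
  )
  attr(out, "prior") <- res$prior
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Build the dysregulated network
#'
#' Tests every measurable influence-network edge with [edge_stats()] and
#' retains the edges that pass both thresholds: p-value at or below
#' `p_threshold` and dysregulation strength at or above `ds_threshold`
#' (defaults 1e-4 and 2, i.e. a 4-fold expression-ratio change in log base
#' 2). All edge statistics are kept for reporting regardless of pass/fail.
#'
#' @inheritParams edge_stats
#' @param p_threshold Significance threshold on the (optionally adjusted)
#'   p-value.
#' @param ds_threshold Minimum dysregulation strength in `log_base` units.
#' @return An object of class `dysnet_dn`: a list with `stats` (all tested
#'   edges), `edges` (the retained subset), `params`, `prior`, `n_skipped`.
#' @export
build_dn <- function(expr, groups, network, p_threshold = 1e-4,
                     ds_threshold = 2, pseudocount = 0, log_base = 2,
                     method = c("moderated", "welch"),
                     p_adjust = c("none", "BH")) {
  method <- match.arg(method)
  p_adjust <- match.arg(p_adjust)
  check_positive(p_threshold, "p_threshold")
  if (!is.numeric(ds_threshold) || ds_threshold < 0) {
    abort("`ds_threshold` must be >= 0")
  }
  stats <- edge_stats(expr, groups, network, pseudocount, log_base, method, p_adjust)
  keep <- stats$p_value <= p_threshold & stats$ds >= ds_threshold
  structure(
    list(
      stats = stats,
      edges = stats[keep, ],
      params = list(p_threshold = p_threshold, ds_threshold = ds_threshold,
                    pseudocount = pseudocount, log_base = log_base,
                    method = method, p_adjust = p_adjust),
      prior = attr(stats, "prior"),
      n_skipped = attr(stats, "n_skipped")
    ),
    class = "dysnet_dn"
  )
}

#' @export
print.dysnet_dn <- function(x, ...) {
  cat("Dysregulated network\n")
  cat("  edges tested:  ", nrow(x$stats), "\n", sep = "")
  cat("  edges retained:", nrow(x$edges),
      sprintf(" (p <= %g, ds >= %g)\n", x$params$p_threshold, x$params$ds_threshold),
      sep = "")
  cat("  genes retained: ", length(unique(c(x$edges$from, x$edges$to))), "\n", sep = "")
  if (!is.null(x$prior)) {
    cat(sprintf("  variance prior: d0 = %.3g, s0^2 = %.3g\n",
                x$prior$d0, x$prior$s0sq))
  }
  invisible(x)
}

#' Differentially expressed genes between normal and tumor groups
#'
#' Per-gene two-sample test on log expression (same moderated/Welch
#' machinery as the edge test). A gene is a DEG when its p-value is at or
#' below `p_threshold` and its absolute fold change is at least
#' `fc_threshold` (applied as |log fold change| >= log(fc_threshold)).
#'
#' @inheritParams edge_stats
#' @param p_threshold DEG significance threshold (default 1e-4).
#' @param fc_threshold Minimum fold change on the linear scale (default 1.5).
#' @return A tibble: `gene`, `log_fc` (tumor minus normal mean log
#'   expression), `t_stat`, `df`, `p_value`, `is_deg`.
#' @export
deg_test <- function(expr, groups, p_threshold = 1e-4, fc_threshold = 1.5,
                     pseudocount = 0, log_base = 2,
                     method = c("moderated", "welch")) {
  method <- match.arg(method)
  check_positive(fc_threshold, "fc_threshold")
  m <- expr_matrix(expr)
  sets <- split_groups(expr, groups)
  mp <- m + pseudocount
  if (any(mp <= 0)) abort("zero expression encountered: use a positive `pseudocount`")
  lm_ <- log(mp, base = log_base)
  res <- two_group_test(lm_, match(sets$normal, colnames(m)),
                        match(sets$tumor, colnames(m)), method)
  tibble::tibble(
    gene = rownames(m),
    log_fc = res$diff,
    t_stat = res$t_stat,
    df = res$df,
    p_value = res$p_value,
    is_deg = res$p_value <= p_threshold &
      abs(res$diff) >= log(fc_threshold, base = log_base)
  )
}

#' Edge composition by number of differentially expressed endpoints
#'
#' Classifies background influence-network edges by how many of their two
#' endpoints are DEGs (0, 1 or 2) and reports, per class, the fraction of
#' background edges and the fraction of the class's edges that are
#' dysregulated. Most dysregulated edges are expected in the one-DEG class:
#' two endpoints moving together leave the expression ratio unchanged.
#'
#' @param network Edge tibble of the background influence network.
#' @param dn A `dysnet_dn` object from [build_dn()].
#' @param degs DEG tibble from [deg_test()].
#' @return A tibble with one row per class: `n_deg`, `n_edges`,
#'   `background_fraction`, `n_dysregulated`, `dysregulated_fraction`.
#' @export
edge_deg_composition <- function(network, dn, degs) {
  stopifnot(inherits(dn, "dysnet_dn"))
  network <- as_edge_tbl(network)
  tested <- degs$gene
  network <- network[network$from %in% tested & network$to %in% tested, ]
  deg_set <- degs$gene[degs$is_deg]
  dn_key <- paste(dn$edges$from, dn$edges$to)
  network |>
    dplyr::mutate(
      n_deg = (.data$from %in% deg_set) + (.data$to %in% deg_set),
      in_dn = paste(.data$from, .data$to) %in% dn_key
    ) |>
    dplyr::group_by(n_deg = factor(.data$n_deg, levels = 0:2)) |>
    dplyr::summarise(n_edges = dplyr::n(),
                     n_dysregulated = sum(.data$in_dn), .groups = "drop") |>
    tidyr::complete(.data$n_deg, fill = list(n_edges = 0L, n_dysregulated = 0L)) |>
    dplyr::mutate(
      n_deg = as.integer(as.character(.data$n_deg)),
      background_fraction = .data$n_edges / sum(.data$n_edges),
      dysregulated_fraction = ifelse(.data$n_edges > 0,
                                     .data$n_dysregulated / .data$n_edges, 0)
    ) |>
    dplyr::select("n_deg", "n_edges", "background_fraction",
                  "n_dysregulated", "dysregulated_fraction")
}
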