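#' Kaplan-Meier product-limit estimate
#'
#' Estimates the survival function S(t) = prod over event times t_k <= t of
#' (1 - d_k / n_k), where d_k counts events at t_k and n_k the subjects at
#' risk just before t_k. Tied events drop simultaneously; censored subjects
#' leave the risk set after their time.
#'
#' @param table Survival tibble (`sample`, `time`, `event`).
#' @return A tibble of class `dysnet_km`, one row per distinct observed
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `survival`.
#' @export
km_estimate <- function(table) {
  stopifnot(all(c("time", "event") %in% names(table)))
  if (nrow(table) == 0) abort("empty survival table")
  if (any(table$time <= 0)) abort("survival times must be > 0")
  tab <- table |>
    dplyr::group_by(time = .data$time) |>
    dplyr::summarise(n_event = sum(.data$event == 1),
                     n_censor = sum(.data$event == 0), .groups = "drop") |>
    dplyr::arrange(.data$time)
  n <- nrow(table)
  tab$n_risk <- n - dplyr::lag(cumsum(tab$n_event + tab$n_censor), default = 0)
  tab$survival <- cumprod(1 - tab$n_event / tab$n_risk)
  out <- tab[, c("time", "n_risk", "n_event", "n_censor", "survival")]
  class(out) <- c("dysnet_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic: at each distinct event time the observed
#' events in group A are compared with their hypergeometric expectation
#' given the pooled risk set, and chi2 = (O_A - E_A)^2 / V is referred to a
#' chi-square distribution with 1 degree of freedom. When neither group has
#' any event the comparison is untestable and p = 1 is reported.
#'
#' @param group_a,group_b Survival tibbles (`sample`, `time`, `event`).
#' @return A one-row tibble: `chi2`, `p_value`, `n_a`, `n_b`, `testable`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) == 0 || nrow(group_b) == 0) abort("both groups must be nonempty")
  time <- c(group_a$time, group_b$time)
  event <- c(group_a$event, group_b$event)
  in_a <- c(rep(TRUE, nrow(group_a)), rep(FALSE, nrow(group_b)))
  if (sum(event) == 0) {
    return(tibble::tibble(chi2 = 0, p_value = 1, n_a = nrow(group_a),
                          n_b = nrow(group_b), testable = FALSE))
  }
  ts <- sort(unique(time[event == 1]))
  o_a <- e_a <- v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n_k <- sum(at_risk)
    n_ak <- sum(at_risk & in_a)
    d_k <- sum(time == t & event == 1)
    d_ak <- sum(time == t & event == 1 & in_a)
    o_a <- o_a + d_ak
    e_a <- e_a + d_k * n_ak / n_k
    if (n_k > 1) {
      v <- v + d_k * (n_k - d_k) * n_ak * (n_k - n_ak) / (n_k^2 * (n_k - 1))
    }
  }
  if (v <= 0) {
    return(tibble::tibble(chi2 = 0, p_value = 1, n_a = nrow(group_a),
                          n_b = nrow(group_b), testable = FALSE))
  }
  chi2 <- (o_a - e_a)^2 / v
  tibble::tibble(chi2 = chi2, p_value = pchisq(chi2, df = 1, lower.tail = FALSE),
                 n_a = nrow(group_a), n_b = nrow(group_b), testable = TRUE)
}

#' Median-split survival comparison for one gene
#'
#' Splits the samples shared between the expression matrix and the
#' survival table at the gene's median expression (ties assigned to the
#' low group) and compares the two groups with the log-rank test.
#'
#' @param expr Expression tibble.
#' @param table Survival tibble (`sample`, `time`, `event`).
#' @param gene Gene identifier.
#' @return A one-row tibble: `gene`, `chi2`, `p_value`, `n_high`, `n_low`,
#'   `testable`; the per-sample assignment is kept in the `assignment`
#'   attribute (tibble `sample`, `expr_group`).
#' @export
median_split_survival <- function(expr, table, gene) {
  m <- expr_matrix(expr)
  if (!gene %in% rownames(m)) abort(paste0("gene not in expression matrix: ", gene))
  shared <- intersect(colnames(m), table$sample)
  if (length(shared) < 2) abort("need >= 2 samples shared between expression and survival")
  x <- m[gene, shared]
  high <- x > median(x)
  assignment <- tibble::tibble(sample = shared,
                               expr_group = ifelse(high, "high", "low"))
  tab <- table[match(shared, table$sample), ]
  if (!any(high) || all(high)) {
    out <- tibble::tibble(gene = gene, chi2 = NA_real_, p_value = NA_real_,
                          n_high = sum(high), n_low = sum(!high),
                          testable = FALSE)
  } else {
    lr <- logrank_test(tab[high, ], tab[!high, ])
    out <- tibble::tibble(gene = gene, chi2 = lr$chi2, p_value = lr$p_value,
                          n_high = lr$n_a, n_low = lr$n_b,
                          testable = lr$testable)
  }
  attr(out, "assignment") <- assignment
  out
}

#' Median-split survival for the top-scoring genes
#'
#' Applies [median_split_survival()] to the `k` genes with the highest
#' dysregulation scores and flags the gene with the smallest log-rank
#' p-value. No multiplicity correction is applied across the `k` tests:
#' under the null the minimum of k p-values falls below 0.05 with
#' probability about 1 - 0.95^k, so the flagged minimum must be read as a
#' screening result, not a calibrated significance statement.
#'
#' @param scores Score tibble from [dysregulation_scores()].
#' @param expr Expression tibble.
#' @param table Survival tibble.
#' @param k Number of top genes to test (default 10).
#' @return A tibble, one row per tested gene, with `is_min_p` marking the
#'   smallest testable p-value.
#' @export
top_gene_survival <- function(scores, expr, table, k = 10) {
  if (k < 1) abort("`k` must be >= 1")
  genes <- scores$gene[order(scores$rank)][seq_len(min(k, nrow(scores)))]
  res <- purrr::map(genes, function(g) median_split_survival(expr, table, g)) |>
    dplyr::bind_rows()
  p <- ifelse(res$testable, res$p_value, Inf)
  res$is_min_p <- seq_len(nrow(res)) == which.min(p) & is.finite(p[which.min(p)])
  res
}
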