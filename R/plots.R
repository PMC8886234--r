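#' Volcano-style plot of edge dysregulation statistics
#'
#' Plots each tested edge's signed mean regulation-strength difference
#' against -log10(p), colored by whether the edge entered the dysregulated
#' network; threshold lines mark the ds and p cutoffs.
#'
#' @param object A `dysnet_dn` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dysnet_dn
#' @export
autoplot.dysnet_dn <- function(object, ...) {
  df <- tidy(object)
  df$delta_r <- df$r_bar_tumor - df$r_bar_normal
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_r,
                                   y = -log10(.data$p_value),
                                   color = .data$in_dn)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$params$ds_threshold,
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(object$params$p_threshold),
                        linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean regulation-strength difference (tumor - normal)",
                  y = expression(-log[10](p)), color = "in DN") +
    ggplot2::theme_minimal()
}

#' Cumulative dysregulation-score curve
#'
#' Plots the cumulative normalized dysregulation score against gene rank,
#' with the key-gene cutoff fraction marked; the sharp initial rise shows
#' how few hub genes carry most of the network's dysregulation.
#'
#' @param scores Score tibble from [dysregulation_scores()].
#' @param fraction Cutoff fraction to mark (default 0.6).
#' @return A ggplot object.
#' @export
plot_cumulative_score <- function(scores, fraction = 0.6) {
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$rank, y = .data$cum_share)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = fraction, linetype = "dashed") +
    ggplot2::labs(x = "gene rank (descending score)",
                  y = "cumulative normalized dysregulation score") +
    ggplot2::theme_minimal()
}

#' Dysregulation score versus out-degree scatter plot
#'
#' @param scores Score tibble from [dysregulation_scores()].
#' @return A ggplot object.
#' @export
plot_score_outdegree <- function(scores) {
  df <- score_outdegree_table(scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$out_degree, y = .data$d)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "out-degree in DN", y = "dysregulation score") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier step curve
#'
#' @param object A `dysnet_km` curve from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dysnet_km
#' @export
autoplot.dysnet_km <- function(object, ...) {
  df <- dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                         tibble::as_tibble(object)[, c("time", "survival")])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves for a median-split gene
#'
#' Draws the high- and low-expression group survival curves for one gene
#' (high in red, low in black).
#'
#' @param expr Expression tibble.
#' @param table Survival tibble.
#' @param gene Gene identifier.
#' @return A ggplot object.
#' @export
plot_km_split <- function(expr, table, gene) {
  res <- median_split_survival(expr, table, gene)
  assignment <- attr(res, "assignment")
  tab <- dplyr::inner_join(table, assignment, by = "sample")
  curves <- tab |>
    dplyr::group_by(.data$expr_group) |>
    dplyr::group_modify(function(df, key) {
      km <- km_estimate(df)
      dplyr::bind_rows(tibble::tibble(time = 0, survival = 1),
                       tibble::as_tibble(km)[, c("time", "survival")])
    }) |>
    dplyr::ungroup()
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                       color = .data$expr_group)) +
    ggplot2::geom_step() +
    ggplot2::scale_color_manual(values = c(high = "red", low = "black")) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = gene, x = "time", y = "survival probability",
                  color = "expression") +
    ggplot2::theme_minimal()
}

#' Bar plot of enrichment scores
#'
#' @param enrichment Enrichment tibble from [pathway_enrichment()] or
#'   [drug_target_enrichment()].
#' @param top Number of top rows to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, top = 20) {
  label_col <- if ("set_id" %in% names(enrichment)) "set_id" else "drug"
  df <- utils::head(dplyr::arrange(enrichment, dplyr::desc(.data$score)), top)
  df$label <- factor(df[[label_col]], levels = rev(df[[label_col]]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL) +
    ggplot2::theme_minimal()
}
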