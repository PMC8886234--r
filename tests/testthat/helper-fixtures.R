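# Shared fixture builders for the test suite.

# Wrap a genes x samples matrix as a tidy expression tibble.
make_expr <- function(mat) {
  tibble::tibble(gene = rownames(mat)) |>
    dplyr::bind_cols(tibble::as_tibble(mat))
}

make_groups <- function(samples, groups) {
  tibble::tibble(sample = samples, group = groups)
}

edges_tbl <- function(from, to) tibble::tibble(from = from, to = to)

# Hand-built 5-gene, 6-edge, 4-sample fixture with power-of-two expression
# values so every log2 ratio is an exact small integer. Samples n1, n2 are
# normal; t1, t2 tumor.
hand_fixture <- function() {
  mat <- rbind(
    A = c(8, 16, 64, 32),
    B = c(2, 4, 2, 4),
    C = c(4, 4, 8, 8),
    D = c(16, 8, 2, 4),
    E = c(1, 2, 4, 8)
  )
  colnames(mat) <- c("n1", "n2", "t1", "t2")
  list(
    expr = make_expr(mat),
    groups = make_groups(colnames(mat), c("normal", "normal", "tumor", "tumor")),
    network = edges_tbl(
      from = c("A", "A", "B", "C", "D", "A"),
      to   = c("B", "C", "C", "D", "E", "E")
    ),
    # hand-computed per-edge values (log2, pseudocount 0):
    #   edge   r per sample        r_bar_N  r_bar_D  ds
    #   A->B   2, 2, 5, 3          2        4        2
    #   A->C   1, 2, 3, 2          1.5      2.5      1
    #   B->C  -1, 0, -2, -1       -0.5     -1.5      1
    #   C->D  -2, -1, 2, 1        -1.5      1.5      3
    #   D->E   4, 2, -1, -1        3       -1        4
    #   A->E   3, 3, 4, 2          3        3        0
    expected = tibble::tibble(
      from = c("A", "A", "B", "C", "D", "A"),
      to = c("B", "C", "C", "D", "E", "E"),
      r_bar_normal = c(2, 1.5, -0.5, -1.5, 3, 3),
      r_bar_tumor = c(4, 2.5, -1.5, 1.5, -1, 3),
      ds = c(2, 1, 1, 3, 4, 0)
    ),
    # gene scores over all 6 edges: d = sum of ds over out-edges
    expected_d = c(A = 3, B = 1, C = 3, D = 4, E = 0)
  )
}

# A small random survival table.
rand_surv <- function(n, seed, censor = 0.3) {
  withr::with_seed(seed, tibble::tibble(
    sample = sprintf("s%03d", seq_len(n)),
    time = round(rexp(n, rate = 0.2), 3) + 0.001,
    event = as.integer(runif(n) > censor)
  ))
}
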