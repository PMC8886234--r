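bin_tbl <- function(mat) make_expr(mat)

test_that("outlier matrix applies the normal-reference z rule", {
  withr::with_seed(61, {
    mat <- 2^matrix(rnorm(40 * 30, mean = 8, sd = 0.5), nrow = 40,
                    dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:30)))
    groups <- make_groups(colnames(mat), rep(c("normal", "tumor"), c(15, 15)))
    expr <- make_expr(mat)

    # a tumor value equal to the normal mean is never an outlier
    ref_mean <- mean(log2(mat["g01", 1:15]))
    mat2 <- mat
    mat2["g01", 16] <- 2^ref_mean
    om <- outlier_matrix(make_expr(mat2), groups, z_threshold = 2)
    expect_equal(om$s16[om$gene == "g01"], 0)

    # a planted 6-sigma shift is flagged
    s_ref <- sd(log2(mat["g02", 1:15]))
    mat3 <- mat
    mat3["g02", 17] <- 2^(mean(log2(mat["g02", 1:15])) + 6 * s_ref)
    om3 <- outlier_matrix(make_expr(mat3), groups, z_threshold = 2)
    expect_equal(om3$s17[om3$gene == "g02"], 1)

    # constant normal reference is skipped with a warning
    mat4 <- mat
    mat4["g03", 1:15] <- 64
    expect_warning(om4 <- outlier_matrix(make_expr(mat4), groups), "zero normal-group")
    expect_false("g03" %in% om4$gene)
  })
})

test_that("null outlier rate approaches the two-sided normal tail", {
  withr::with_seed(62, {
    n_genes <- 400
    mat <- 2^matrix(rnorm(n_genes * 250, mean = 8, sd = 0.5), nrow = n_genes,
                    dimnames = list(sprintf("g%03d", 1:n_genes),
                                    sprintf("s%03d", 1:250)))
    groups <- make_groups(colnames(mat), rep(c("normal", "tumor"), c(50, 200)))
    om <- outlier_matrix(make_expr(mat), groups, z_threshold = 2)
    rate <- mean(as.matrix(om[-1]))
    # reference mean/sd are estimated from 50 normals, so the flagging
    # statistic is t-like rather than exactly normal; allow a band around
    # 2 * pnorm(-2) ~= 4.55%
    expect_gt(rate, 0.035)
    expect_lt(rate, 0.065)
  })
})

test_that("greedy ranking covers events once and follows the tie rule", {
  net <- edges_tbl(c("m1", "m1", "m1", "m1", "m2"),
                   c("a", "b", "c", "d", "e"))
  mut <- bin_tbl(matrix(c(1, 0), nrow = 2, ncol = 1,
                        dimnames = list(c("m1", "m2"), "s1")))
  out <- bin_tbl(matrix(1, nrow = 4, ncol = 1,
                        dimnames = list(c("a", "b", "c", "d"), "s1")))
  rk <- greedy_driver_rank(mut, out, net)
  expect_equal(rk$gene, "m1")
  expect_equal(rk$events_covered, 4L)

  # two mutated genes with disjoint event sets rank by coverage size
  mut2 <- bin_tbl(matrix(1, 2, 1, dimnames = list(c("m1", "m2"), "s1")))
  out2 <- bin_tbl(matrix(1, 5, 1, dimnames = list(c("a", "b", "c", "e", "f"), "s1")))
  net2 <- edges_tbl(c("m1", "m1", "m1", "m2", "m2"),
                    c("a", "b", "c", "e", "f"))
  rk2 <- greedy_driver_rank(mut2, out2, net2)
  expect_equal(rk2$gene, c("m1", "m2"))
  expect_equal(rk2$events_covered, c(3L, 2L))

  # a mutated gene covers its own outlier in the same sample
  mut3 <- bin_tbl(matrix(1, 1, 1, dimnames = list("m1", "s1")))
  out3 <- bin_tbl(matrix(1, 1, 1, dimnames = list("m1", "s1")))
  rk3 <- greedy_driver_rank(mut3, out3, edges_tbl("x", "y"))
  expect_equal(rk3$events_covered, 1L)

  # empty bipartite graph warns and returns an empty ranking
  out4 <- bin_tbl(matrix(0, 1, 1, dimnames = list("a", "s1")))
  expect_warning(rk4 <- greedy_driver_rank(mut3, out4, edges_tbl("x", "y")),
                 "empty bipartite")
  expect_equal(nrow(rk4), 0L)
})

test_that("greedy ranking matches the brute-force oracle on random instances", {
  withr::with_seed(71, {
    for (i in 1:60) {
      n_mut <- sample(2:5, 1)
      n_exp <- sample(3:6, 1)
      n_s <- sample(2:3, 1)
      mut_genes <- sprintf("m%d", seq_len(n_mut))
      exp_genes <- sprintf("e%d", seq_len(n_exp))
      samples <- sprintf("s%d", seq_len(n_s))
      mut_m <- matrix(rbinom(n_mut * n_s, 1, 0.5), n_mut,
                      dimnames = list(mut_genes, samples))
      out_m <- matrix(rbinom(n_exp * n_s, 1, 0.5), n_exp,
                      dimnames = list(exp_genes, samples))
      pairs <- expand.grid(from = mut_genes, to = exp_genes,
                           stringsAsFactors = FALSE)
      net <- tibble::as_tibble(pairs[runif(nrow(pairs)) < 0.4, ])
      oracle <- bf_greedy_cover(bf_coverage_sets(mut_m, out_m, net))
      if (length(oracle) == 0) {
        expect_warning(got <- greedy_driver_rank(bin_tbl(mut_m), bin_tbl(out_m), net),
                       "empty bipartite")
        expect_equal(nrow(got), 0L)
        next
      }
      got <- greedy_driver_rank(bin_tbl(mut_m), bin_tbl(out_m), net)
      # first pick equals the exhaustive max-coverage choice, and the whole
      # greedy replay agrees
      expect_equal(got$gene[1], oracle[[1]]$gene)
      expect_equal(got$gene, vapply(oracle, `[[`, character(1), "gene"))
      expect_equal(got$events_covered,
                   vapply(oracle, function(x) as.integer(x$covered), integer(1)))
      expect_true(all(diff(got$events_covered) <= 0))
    }
  })
})

test_that("ranking is invariant to input row order", {
  withr::with_seed(73, {
    mut_m <- matrix(rbinom(12, 1, 0.6), 4,
                    dimnames = list(paste0("m", 1:4), paste0("s", 1:3)))
    out_m <- matrix(rbinom(15, 1, 0.6), 5,
                    dimnames = list(paste0("e", 1:5), paste0("s", 1:3)))
    net <- tidyr::expand_grid(from = paste0("m", 1:4), to = paste0("e", 1:5)) |>
      dplyr::slice_sample(prop = 0.5)
    base <- greedy_driver_rank(bin_tbl(mut_m), bin_tbl(out_m), net)
    perm <- greedy_driver_rank(bin_tbl(mut_m[sample(4), ]),
                               bin_tbl(out_m[sample(5), ]),
                               dplyr::slice_sample(net, prop = 1))
    expect_equal(base, perm, ignore_attr = TRUE)
  })
})

test_that("planted drivers are recovered and overlap the key network", {
  net <- simulate_network(1000, 5, seed = 81)
  out_deg <- sort(table(net$from), decreasing = TRUE)
  drivers <- withr::with_seed(82, sample(names(out_deg)[1:80], 20))
  sim <- simulate_expression(net, 40, 200, seed = 83, sigma = 0.5)
  mut <- simulate_mutations(net, drivers,
                            sim$groups$sample[sim$groups$group != "normal"],
                            driver_rate = 0.3, passenger_rate = 0.01, seed = 84)
  expr <- inject_outliers(sim$expr, mut$injections, shift = 3)
  om <- outlier_matrix(expr, sim$groups, z_threshold = 2)
  rk <- greedy_driver_rank(mut$mutations, om, net)
  top40 <- rk$gene[1:40]
  expect_gte(mean(drivers %in% top40), 0.8)

  # drivers inside a key set cover more events than those outside when the
  # key set holds the planted drivers
  ov <- kdn_driver_overlap(rk, key_genes = drivers, top_k = 40)
  expect_equal(ov$overlap, sum(drivers %in% top40))
  expect_gt(ov$mean_events_in_kdn, ov$mean_events_out_kdn)

  # degenerate overlap cases
  ov2 <- kdn_driver_overlap(rk, key_genes = character(0), top_k = 10)
  expect_equal(ov2$overlap, 0L)
  expect_error(kdn_driver_overlap(rk, drivers, top_k = nrow(rk) + 1), "exceeds")
})
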