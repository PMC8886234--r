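test_that("regulation strength matches hand-computed log ratios", {
  fx <- hand_fixture()
  r <- regulation_strength(fx$expr, "A", "B")
  expect_equal(r$r, c(2, 2, 5, 3), tolerance = 1e-12)

  # equal expression gives r = 0; reversing the edge negates every entry
  r_cc <- regulation_strength(fx$expr, "C", "C")
  expect_equal(r_cc$r, rep(0, 4))
  r_rev <- regulation_strength(fx$expr, "B", "A")
  expect_equal(r_rev$r, -r$r, tolerance = 1e-12)

  # analytic single-ratio case and pseudocount guard
  expr0 <- make_expr(matrix(c(8, 2, 0, 4), 2, 2,
                            dimnames = list(c("x", "y"), c("s1", "s2"))))
  expect_equal(regulation_strength(expr0, "x", "y", pseudocount = 1)$r[1],
               log2(9 / 3))
  expect_error(regulation_strength(expr0, "x", "y"), "pseudocount")
})

test_that("edge statistics reproduce the hand fixture exactly", {
  fx <- hand_fixture()
  st <- edge_stats(fx$expr, fx$groups, fx$network, method = "welch")
  st <- st[match(paste(fx$expected$from, fx$expected$to), paste(st$from, st$to)), ]
  expect_equal(st$r_bar_normal, fx$expected$r_bar_normal, tolerance = 1e-12)
  expect_equal(st$r_bar_tumor, fx$expected$r_bar_tumor, tolerance = 1e-12)
  expect_equal(st$ds, fx$expected$ds, tolerance = 1e-12)
  expect_equal(st$ds, abs(st$r_bar_tumor - st$r_bar_normal), tolerance = 1e-15)
  expect_equal(st$direction,
               ifelse(st$r_bar_tumor >= st$r_bar_normal, "up", "down"))
})

test_that("group exchange preserves ds and flips direction; common scaling is a no-op", {
  fx <- hand_fixture()
  st <- edge_stats(fx$expr, fx$groups, fx$network, method = "welch")
  flipped <- fx$groups
  flipped$group <- ifelse(flipped$group == "normal", "tumor", "normal")
  st_fl <- edge_stats(fx$expr, flipped, fx$network, method = "welch")
  expect_equal(st$ds, st_fl$ds, tolerance = 1e-12)
  swap <- st$ds > 0
  expect_true(all(st$direction[swap] != st_fl$direction[swap]))

  scaled <- fx$expr
  scaled[-1] <- scaled[-1] * 37.5
  st_sc <- edge_stats(scaled, fx$groups, fx$network, method = "welch")
  expect_equal(st$ds, st_sc$ds, tolerance = 1e-12)
  expect_equal(st$p_value, st_sc$p_value, tolerance = 1e-12)
})

test_that("welch edge test agrees with the reference t implementation", {
  withr::with_seed(42, {
    for (i in 1:20) {
      x <- rnorm(8 + i %% 5)
      y <- rnorm(11, mean = i / 10)
      reg <- tibble::tibble(sample = sprintf("s%02d", seq_along(c(x, y))),
                            r = c(x, y))
      groups <- make_groups(reg$sample,
                            c(rep("normal", length(x)), rep("tumor", length(y))))
      got <- edge_test(reg, groups, method = "welch")
      ref <- t.test(y, x)
      expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    }
  })
  # strongly separated groups: tail probability is tiny
  reg <- tibble::tibble(sample = sprintf("s%02d", 1:40),
                        r = c(rnorm(20), rnorm(20, 3)))
  groups <- make_groups(reg$sample, rep(c("normal", "tumor"), each = 20))
  expect_lt(edge_test(reg, groups, method = "welch")$p_value, 1e-4)
})

test_that("moderated test reduces to the pooled t at d0 = 0 and matches limma", {
  skip_if_not_installed("limma")
  withr::with_seed(7, {
    x <- rnorm(10)
    y <- rnorm(12, 1)
    reg <- tibble::tibble(sample = sprintf("s%02d", 1:22), r = c(x, y))
    groups <- make_groups(reg$sample, rep(c("normal", "tumor"), c(10, 12)))
    got <- edge_test(reg, groups, method = "moderated", d0 = 0)
    ref <- t.test(y, x, var.equal = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)

    # whole-matrix moderated pipeline against limma's eBayes
    n_edges <- 200
    mat <- matrix(rnorm(n_edges * 22, sd = sqrt(rchisq(n_edges, 5) / 5)),
                  nrow = n_edges)
    mat[1:20, 11:22] <- mat[1:20, 11:22] + 1.5
    design <- cbind(1, rep(c(0, 1), c(10, 12)))
    fit <- limma::eBayes(limma::lmFit(mat, design))
    prior <- fit_variance_prior(fit$sigma^2, fit$df.residual[1])
    expect_equal(prior$d0, fit$df.prior, tolerance = 1e-6)
    expect_equal(prior$s0sq, fit$s2.prior, tolerance = 1e-6)
    res <- dysnet:::two_group_test(mat, 1:10, 11:22, "moderated")
    expect_equal(res$t_stat, unname(fit$t[, 2]), tolerance = 1e-8)
    expect_equal(res$p_value, unname(fit$p.value[, 2]), tolerance = 1e-8)
  })
})

test_that("variance-prior moment fit recovers simulated hyperparameters", {
  # complete pooling when all variances are identical
  prior <- fit_variance_prior(rep(2, 100), df = 10)
  expect_equal(prior$d0, Inf)

  withr::with_seed(123, {
    d0 <- 4
    s0sq <- 1
    d <- 20
    sigma2 <- s0sq * d0 / rchisq(10000, d0)
    s2 <- sigma2 * rchisq(10000, d) / d
    fit <- fit_variance_prior(s2, d)
    expect_gt(fit$d0, 3)
    expect_lt(fit$d0, 5)
    expect_gt(fit$s0sq, 0.9)
    expect_lt(fit$s0sq, 1.1)

    # heavy over-dispersion across orders of magnitude: small finite d0
    wild <- 10^runif(5000, -3, 3)
    expect_lt(fit_variance_prior(wild, d)$d0, 1)
  })
  expect_error(fit_variance_prior(rep(1, 5), 10), "welch")
})

test_that("build_dn retains exactly the threshold-passing edges", {
  net <- simulate_network(200, 4, seed = 21)
  planted <- pick_planted_edges(net, 6, seed = 22)
  sim <- simulate_expression(net, 40, 40, planted, delta = 3, sigma = 0.5, seed = 23)
  dn <- build_dn(sim$expr, sim$groups, net)
  keep <- dn$stats$p_value <= 1e-4 & dn$stats$ds >= 2
  expect_equal(dn$edges, dn$stats[keep, ]) # re-filtering is idempotent
  expect_gt(nrow(dn$edges), 0)

  # an infinite ds threshold empties the DN
  dn_inf <- build_dn(sim$expr, sim$groups, net, ds_threshold = Inf)
  expect_equal(nrow(dn_inf$edges), 0L)

  # edges with unmeasured endpoints are skipped and counted
  net_extra <- dplyr::bind_rows(net, edges_tbl("ghost", net$to[1]))
  expect_message(dn2 <- build_dn(sim$expr, sim$groups, net_extra), "skipping 1")
  expect_equal(dn2$n_skipped, 1L)
  expect_equal(nrow(dn2$stats), nrow(net))
  expect_error(
    build_dn(sim$expr, sim$groups, edges_tbl("ghost1", "ghost2")),
    "no network edge"
  )
})

test_that("deg_test flags planted fold changes and honors thresholds", {
  net <- edges_tbl(paste0("g", 1:30), paste0("g", c(2:30, 1)))
  sim <- simulate_expression(net, 100, 100, seed = 31, sigma = 0.5)
  # plant a 4-fold (2 log2 units) shift on one gene
  expr <- sim$expr
  tumor <- sim$groups$sample[sim$groups$group != "normal"]
  expr[expr$gene == "g5", tumor] <- expr[expr$gene == "g5", tumor] * 4
  degs <- deg_test(expr, sim$groups)
  expect_true(degs$is_deg[degs$gene == "g5"])
  expect_equal(degs$log_fc[degs$gene == "g5"], 2, tolerance = 0.5)
  expect_false(any(degs$is_deg[degs$gene != "g5"]))

  # fc_threshold 1 leaves significance to the p-value alone
  degs1 <- deg_test(expr, sim$groups, fc_threshold = 1)
  expect_equal(degs1$is_deg, degs1$p_value <= 1e-4)
})

test_that("edge DEG composition classifies endpoints and sums to one", {
  fx <- hand_fixture()
  dn <- build_dn(fx$expr, fx$groups, fx$network, method = "welch",
                 p_threshold = 1, ds_threshold = 2)
  # force DEG status: no gene is a DEG
  degs <- tibble::tibble(gene = c("A", "B", "C", "D", "E"),
                         log_fc = 0, t_stat = 0, df = 2, p_value = 1,
                         is_deg = FALSE)
  comp <- edge_deg_composition(fx$network, dn, degs)
  expect_equal(comp$background_fraction, c(1, 0, 0))
  expect_equal(sum(comp$background_fraction), 1)

  degs$is_deg <- TRUE
  comp2 <- edge_deg_composition(fx$network, dn, degs)
  expect_equal(comp2$background_fraction, c(0, 0, 1))

  # planted one-endpoint shifts concentrate dysregulated edges in class 1
  net <- simulate_network(300, 4, seed = 41)
  planted <- pick_planted_edges(net, 10, seed = 42)
  sim <- simulate_expression(net, 80, 80, planted, delta = 3, sigma = 0.5, seed = 43)
  dn <- build_dn(sim$expr, sim$groups, net)
  degs <- deg_test(sim$expr, sim$groups)
  comp3 <- edge_deg_composition(net, dn, degs)
  expect_equal(comp3$n_deg[which.max(comp3$n_dysregulated)], 1L)
})
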