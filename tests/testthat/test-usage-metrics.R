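test_that("compute_pau is a proportion with the zero-sum missing convention", {
  expect_equal(compute_pau(c(30, 70)), c(0.3, 0.7))
  expect_equal(compute_pau(5), 1)
  expect_equal(compute_pau(c(0, 0)), c(NA_real_, NA_real_))
  expect_error(compute_pau(c(-1, 2)), "negative")
  ## conservation over random inputs
  set.seed(1)
  for (i in 1:50) {
    tpm <- stats::rexp(sample(1:6, 1))
    expect_equal(sum(compute_pau(tpm)), 1)
  }
})

test_that("delta_usage is the group mean difference, antisymmetric in group order", {
  v <- c(a = 0.8, b = 0.6, c = 0.2, d = 0.4)
  ga <- group_assignment(names(v), c("t", "t", "n", "n"), levels = c("t", "n"))
  expect_equal(as.numeric(delta_usage(v, ga)), 0.4)
  ga_swap <- group_assignment(names(v), c("t", "t", "n", "n"),
                              levels = c("n", "t"))
  expect_equal(as.numeric(delta_usage(v, ga_swap)), -0.4)
  expect_equal(as.numeric(delta_usage(c(a = 0.5, b = 0.5, c = 0.5, d = 0.5),
                                      ga)), 0)
  ## entirely-missing group errors
  v2 <- c(a = NA, b = NA, c = 0.2, d = 0.4)
  expect_error(delta_usage(v2, ga), "no non-missing")
})

test_that("Mann-Whitney p matches the exhaustive permutation oracle (no ties)", {
  v <- c(1, 2, 3, 4, 5, 6)
  names(v) <- paste0("s", 1:6)
  ga <- group_assignment(names(v), rep(c("a", "b"), each = 3))
  res <- test_diff(v, ga)
  expect_equal(res$p, 0.1)            # 2 of the 20 assignments fully separate
  expect_equal(res$p, mw_permutation_p(v[1:3], v[4:6]))

  ## p is invariant under swapping group labels
  ga_swap <- group_assignment(names(v), rep(c("b", "a"), each = 3),
                              levels = c("a", "b"))
  expect_equal(test_diff(v, ga_swap)$p, res$p)

  set.seed(99)
  sizes <- list(c(2, 2), c(3, 3), c(2, 5), c(4, 4), c(5, 5), c(6, 3),
                c(8, 8), c(8, 2), c(7, 5))
  for (sz in sizes) {
    for (rep in 1:4) {
      x <- stats::rnorm(sz[1]); y <- stats::rnorm(sz[2])  # ties a.s. absent
      v <- c(x, y); names(v) <- paste0("s", seq_along(v))
      ga <- group_assignment(names(v), rep(c("a", "b"), times = sz))
      expect_equal(test_diff(v, ga)$p, mw_permutation_p(x, y),
                   tolerance = 1e-12)
    }
  }
})

test_that("Kruskal-Wallis handles >2 groups and degenerate ties", {
  v <- c(1, 5, 2, 8, 3, 9, 4, 7, 6)
  names(v) <- paste0("s", 1:9)
  ga <- group_assignment(names(v), rep(c("a", "b", "c"), each = 3))
  res <- test_diff(v, ga)
  expect_equal(res$method, "kruskal-wallis")
  ref <- stats::kruskal.test(split(unname(v), rep(c("a", "b", "c"), each = 3)))
  expect_equal(res$p, ref$p.value)

  v_tied <- stats::setNames(rep(0.5, 9), names(v))
  res_tied <- test_diff(v_tied, ga)
  expect_equal(res_tied$statistic, 0)
  expect_equal(res_tied$p, 1)

  expect_error(test_diff(c(a = 1, b = 2, c = 3),
                         group_assignment(c("a", "b", "c"),
                                          c("x", "x", "y"))),
               ">= 2 groups")
})

test_that("BH adjustment applies the step-up formula with monotone enforcement", {
  expect_equal(adjust_bh(0.01), 0.01)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("trend calls gate on both effect size and significance", {
  expect_equal(classify_trend(0.3, 0.001), "lengthened")
  expect_equal(classify_trend(-0.3, 0.001), "shortened")
  expect_equal(classify_trend(0.05, 0.001), "unchanged")   # effect gate
  expect_equal(classify_trend(0.3, 0.2), "unchanged")      # significance gate
  expect_equal(classify_trend(c(0.3, -0.15, 0), c(0.01, 0.01, 0.01)),
               c("lengthened", "shortened", "unchanged"))
})

test_that("top/bottom split is deterministic with lexicographic tie-breaks", {
  v <- stats::setNames(c(0.1, 0.9), c("a", "b"))
  sp <- top_bottom_split(v, n = 1)
  expect_equal(sp$sample_id[sp$group == "low"], "a")
  expect_equal(sp$sample_id[sp$group == "high"], "b")

  set.seed(3)
  v <- stats::setNames(round(stats::runif(70), 1), sprintf("s%02d", 1:70))
  sp1 <- top_bottom_split(v, n = 30)
  sp2 <- top_bottom_split(v[sample(names(v))], n = 30)  # order-insensitive
  expect_identical(sp1$sample_id[order(sp1$sample_id)],
                   sp2$sample_id[order(sp2$sample_id)])
  expect_identical(sp1$group[order(sp1$sample_id)],
                   sp2$group[order(sp2$sample_id)])
  expect_true(max(v[sp1$sample_id[sp1$group == "low"]]) <=
                min(v[sp1$sample_id[sp1$group == "high"]]))
  expect_error(top_bottom_split(v[1:50], n = 30), "need >= 60")
})

test_that("diff_usage recovers injected shortening and reports the contract columns", {
  sim <- gen_usage(n_features = 100, n_per_group = 20, frac_affected = 0.2,
                   delta = -0.3, noise_sd = 0.1, seed = 5)
  res <- diff_usage(sim$usage, sim$groups)
  expect_equal(names(res),
               c("feature_id", "gene_symbol", "mean_g1", "mean_g2", "delta",
                 "statistic", "p", "q", "trend", "n1", "n2"))
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_equal(res$delta, res$mean_g1 - res$mean_g2)
  aff <- res$feature_id %in% sim$truth$feature_id[sim$truth$affected]
  expect_gt(mean(res$trend[aff] == "shortened"), 0.9)
  expect_lt(mean(res$trend[!aff] != "unchanged"), 0.08)
  ## skipped features are reported, not dropped silently
  vals <- sim$usage$values[1:5, ]
  vals[1, sim$groups$sample_id[sim$groups$group == "g1"]] <- NA
  um <- usage_matrix(vals, "PDUI")
  res2 <- diff_usage(um, sim$groups)
  expect_equal(attr(res2, "skipped"), rownames(vals)[1])
})
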