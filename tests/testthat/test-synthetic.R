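test_that("gen_usage is deterministic per seed and respects declared ranges", {
  a <- gen_usage(n_features = 30, n_per_group = 10, seed = 42)
  b <- gen_usage(n_features = 30, n_per_group = 10, seed = 42)
  expect_identical(a$usage$values, b$usage$values)
  expect_identical(a$truth, b$truth)
  c_ <- gen_usage(n_features = 30, n_per_group = 10, seed = 43)
  expect_false(identical(a$usage$values, c_$usage$values))

  v <- a$usage$values
  expect_true(all(v >= 0 & v <= 1, na.rm = TRUE))
  expect_equal(dim(v), c(30, 20))
  ## truth invariants: nulls carry zero effect
  expect_true(all(a$truth$true_delta[!a$truth$affected] == 0))
  expect_error(gen_usage(n_features = 0), "empty design")
  expect_error(gen_usage(delta = -1.5), "\\[-1, 1\\]")
})

test_that("null generation keeps the false-positive rate near alpha", {
  sim <- gen_usage(n_features = 300, n_per_group = 20, frac_affected = 0,
                   seed = 9)
  res <- diff_usage(sim$usage, sim$groups)
  expect_true(all(sim$truth$true_delta == 0))
  ## BH at 5% on all-null data: expected discoveries ~ 0
  expect_lt(mean(res$q < 0.05), 0.05)
  ## raw p approximately uniform: type-I near alpha within binomial error
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.04)
})

test_that("coupled expression hits its target correlation", {
  set.seed(1)
  u <- stats::runif(200, 0.2, 0.8)
  names(u) <- sprintf("s%03d", 1:200)
  expect_equal(stats::cor(u, gen_coupled_expression(u, 1, seed = 2)), 1)
  ok <- 0
  for (seed in 1:20) {
    r_obs <- stats::cor(u, gen_coupled_expression(u, 0.7, seed = seed))
    if (r_obs >= 0.6 && r_obs <= 0.8) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)
})

test_that("coupled survival at hr = 1 gives nominal log-rank rejection", {
  set.seed(5)
  u <- stats::setNames(stats::runif(100, 0.2, 0.8), sprintf("s%03d", 1:100))
  rej <- 0; n_rep <- 200
  for (seed in 1:n_rep) {
    sv <- gen_coupled_survival(u, hr = 1, seed = seed)
    sp <- median_split(u)
    grp <- sp$group[match(sv$sample_id, sp$sample_id)]
    if (logrank(sv$time, sv$event, grp)$p < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / n_rep - 0.05), 0.04)
  ## censoring lands near its target rate
  cens <- mean(1 - gen_coupled_survival(u, hr = 1, censor_rate = 0.2,
                                        seed = 1)$event)
  expect_lt(abs(cens - 0.2), 0.12)
})

test_that("fixture writing is parseable, warning-free and complete", {
  sim <- gen_usage(n_features = 10, n_per_group = 4, missing_rate = 0.1,
                   seed = 13)
  dir <- tempfile()
  for (d in c("qapa", "dapars", "generic")) {
    paths <- write_fixture(sim, d, dir)
    expect_true(all(file.exists(paths)))
    ds <- expect_warning(switch(d, qapa = parse_qapa(paths["data"]),
                                dapars = parse_dapars(paths["data"]),
                                generic = parse_generic(paths["data"])),
                         regexp = NA)
    expect_equal(ncol(ds$usage$values), 8)
    truth <- .read_tsv_oracle(paths["truth"])
    expect_equal(truth$feature_id, sim$truth$feature_id)
  }
  ## QAPA dialect: per-gene PAU complements sum to 1 where defined
  ds <- parse_qapa(write_fixture(sim, "qapa", dir)["data"])
  for (g in unique(ds$sites$gene_id)) {
    rows <- ds$sites$site_id[ds$sites$gene_id == g]
    sums <- colSums(ds$usage$values[rows, ])
    expect_true(all(is.na(sums) | abs(sums - 1) < 1e-9))
  }
  ## DaPars dialect: NA cells at roughly the stated missing rate
  dd <- parse_dapars(write_fixture(sim, "dapars", dir)["data"])
  expect_gt(mean(is.na(dd$usage$values)), 0.02)
  expect_lt(mean(is.na(dd$usage$values)), 0.25)
})
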