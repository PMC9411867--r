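test_that("median_split sends ties at the median to the low group", {
  v <- stats::setNames(c(0.1, 0.2, 0.8, 0.9), letters[1:4])
  sp <- median_split(v)
  expect_setequal(sp$sample_id[sp$group == "low"], c("a", "b"))
  expect_setequal(sp$sample_id[sp$group == "high"], c("c", "d"))

  v2 <- stats::setNames(c(0.1, 0.5, 0.9), letters[1:3])
  sp2 <- median_split(v2)
  expect_setequal(sp2$sample_id[sp2$group == "low"], c("a", "b"))
  expect_setequal(sp2$sample_id[sp2$group == "high"], "c")

  expect_error(median_split(stats::setNames(rep(0.3, 3), letters[1:3])),
               "split undefined")
})

test_that("km_estimate matches hand product-limit arithmetic", {
  ## no censoring: steps 1 -> 2/3 -> 1/3 -> 0, median at 2
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$curve$surv, c(2/3, 1/3, 0))
  expect_equal(km$median, 2)

  ## all censored: flat curve, median undefined
  km2 <- km_estimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(all(km2$curve$surv == 1))
  expect_true(is.na(km2$median))

  ## one censored at 2: risk sets {3}, then {1} -> S(1)=2/3, S(3)=0
  km3 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  hand <- hand_km(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km3$curve$surv, hand$surv)
  expect_equal(km3$curve$surv[km3$curve$time == 1], 2/3)
  expect_equal(km3$curve$surv[km3$curve$time == 3], 0)

  ## no censoring: product-limit equals the empirical survival function
  set.seed(12)
  t <- stats::rexp(40)
  km4 <- km_estimate(t, rep(1, 40))
  emp <- vapply(km4$curve$time, function(x) mean(t > x), numeric(1))
  expect_equal(km4$curve$surv, emp)
})

test_that("logrank matches a hand-computed chi-square and is label-symmetric", {
  ## two small groups, risk sets tabulated by hand over event times
  time <- c(1, 3, 5, 2, 4, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  grp <- factor(rep(c("low", "high"), each = 3), levels = c("low", "high"))
  ## hand log-rank over event times t = 1,2,3,4,6 (5 censored at 5):
  ## O-E for group low summed over risk sets, V the hypergeometric variance
  o_e <- 0; v <- 0
  for (t in c(1, 2, 3, 4, 6)) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & grp == "low")
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == "low")
    o_e <- o_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  hand_chisq <- o_e^2 / v
  res <- logrank(time, event, grp)
  expect_equal(res$chi_square, hand_chisq)
  expect_equal(res$p, stats::pchisq(hand_chisq, 1, lower.tail = FALSE))

  swapped <- logrank(time, event, factor(grp, levels = c("high", "low")))
  expect_equal(swapped$chi_square, res$chi_square)
  expect_equal(swapped$p, res$p)
  expect_equal(swapped$hr, 1 / res$hr)

  ## identical groups: no signal
  same <- logrank(rep(c(1, 2, 3), 2), rep(1, 6),
                  factor(rep(c("a", "b"), each = 3)))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p, 1)
  expect_equal(same$hr, 1)
})

test_that("the O/E hazard-ratio estimate recovers a true ratio of 2", {
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    t1 <- stats::rexp(200, 1); t2 <- stats::rexp(200, 2)
    c1 <- stats::rexp(200, 0.25); c2 <- stats::rexp(200, 0.25) # ~20% censored
    time <- c(pmin(t1, c1), pmin(t2, c2))
    event <- as.integer(c(t1 <= c1, t2 <= c2))
    grp <- factor(rep(c("low", "high"), each = 200),
                  levels = c("low", "high"))
    hr <- logrank(time, event, grp)$hr
    if (hr >= 1.6 && hr <= 2.5) ok <- ok + 1
  }
  expect_gte(ok / 20, 0.9)
})

test_that("survival_by_apa composes split and test with missingness bookkeeping", {
  set.seed(44)
  n <- 24
  u <- stats::setNames(stats::runif(n, 0.1, 0.9), sprintf("s%02d", 1:n))
  ## usage deterministically orders survival, no censoring -> strong signal
  cl <- clinical_table(data.frame(sample_id = names(u),
                                  survival_time = round(1000 * u),
                                  event = 1L))
  res <- survival_by_apa(u, cl)
  expect_lt(res$p, 0.01)
  expect_equal(sum(res$n), n)

  ## missing usage and missing clinical samples are dropped and recorded
  u2 <- u; u2[1] <- NA
  cl2 <- cl[-2, ]
  class(cl2) <- class(cl)
  res2 <- survival_by_apa(u2, cl2)
  expect_setequal(res2$dropped, names(u)[1:2])
  expect_equal(sum(res2$n), n - 2)

  expect_error(survival_by_apa(stats::setNames(rep(0.5, n), names(u)), cl),
               "split undefined")
})
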