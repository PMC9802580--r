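mk_cohort <- function(expression, time, event) {
  survival_cohort(data.frame(
    sample = sprintf("s%03d", seq_along(expression)),
    expression = expression, time = time, event = event))
}

test_that("cohort validation enforces the record invariants", {
  df <- data.frame(sample = c("a", "a"), expression = 1:2,
                   time = c(1, 2), event = c(0, 1))
  expect_error(survival_cohort(df), "duplicate sample")
  expect_error(mk_cohort(1:2, c(-1, 2), c(0, 1)), "non-negative")
  expect_error(mk_cohort(1:2, c(1, 2), c(0, 2)), "event indicator")
})

test_that("median split sends ties to the low group", {
  sp <- median_split(mk_cohort(c(1, 2, 3, 4), c(10, 20, 30, 40), rep(1, 4)))
  expect_identical(sort(sp$high$expression), c(3, 4))
  expect_identical(sort(sp$low$expression), c(1, 2))

  sp2 <- median_split(mk_cohort(c(1, 2, 2, 5), 1:4, rep(1, 4)))
  expect_equal(sp2$cutoff, 2)
  expect_equal(nrow(sp2$low), 3L)  # both ties at the median fall low
  expect_identical(sp2$high$expression, 5)

  expect_error(median_split(mk_cohort(c(1, 2, 3), 1:3, rep(1, 3))),
               "at least 4")
  expect_error(median_split(mk_cohort(rep(2, 6), 1:6, rep(1, 6))),
               "no median split")
})

test_that("median split partitions any cohort cleanly", {
  set.seed(71)
  for (i in 1:10) {
    n <- 101L
    coh <- mk_cohort(rnorm(n), rexp(n), rbinom(n, 1, 0.7))
    sp <- median_split(coh)
    expect_equal(nrow(sp$high) + nrow(sp$low), n)
    expect_true(max(sp$low$expression) <= min(sp$high$expression))
    expect_true(max(sp$low$expression) <= sp$cutoff)
  }
})

test_that("product-limit estimate matches hand-enumerated risk sets", {
  # times (2, 4, 5), events (1, 1, 0): risk sets 3 -> 2 -> 1
  km <- km_estimate(mk_cohort(1:3, c(2, 4, 5), c(1, 1, 0)))
  expect_equal(km_survival_at(km, c(2, 4, 10)), c(2 / 3, 1 / 3, 1 / 3),
               tolerance = 1e-12)
  expect_equal(km_survival_at(km, 1), 1)

  all_censored <- km_estimate(mk_cohort(1:4, c(1, 2, 3, 4), rep(0, 4)))
  expect_true(all(all_censored$survival == 1))
})

test_that("KM curves are invariant to record duplication and non-increasing", {
  set.seed(73)
  coh <- mk_cohort(rnorm(20), rexp(20, 0.1), rbinom(20, 1, 0.6))
  km1 <- km_estimate(coh)
  doubled <- coh
  doubled$sample <- paste0(doubled$sample, "_b")
  km2 <- km_estimate(survival_cohort(rbind(as.data.frame(coh),
                                           as.data.frame(doubled))))
  tt <- sort(unique(coh$time))
  expect_equal(km_survival_at(km2, tt), km_survival_at(km1, tt),
               tolerance = 1e-12)
  expect_true(all(diff(km1$survival) <= 1e-12))
  expect_true(all(km1$survival >= 0 & km1$survival <= 1))
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(79)
  t <- rexp(50, 0.2)
  km <- km_estimate(mk_cohort(rnorm(50), t, rep(1, 50)))
  grid <- sort(t)
  expect_equal(km_survival_at(km, grid),
               vapply(grid, function(x) mean(t > x), numeric(1)),
               tolerance = 1e-12)
})

test_that("log-rank is symmetric, null on identical groups, scale-free", {
  g <- mk_cohort(rnorm(10), rexp(10), rep(1, 10))
  g2 <- g; g2$sample <- paste0(g2$sample, "_2")
  same <- logrank_test(g, g2)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  expect_equal(sum(same$observed), sum(same$expected), tolerance = 1e-9)

  set.seed(83)
  a <- mk_cohort(rnorm(15), rexp(15, 0.3), rbinom(15, 1, 0.8))
  b <- mk_cohort(rnorm(15), rexp(15, 0.6), rbinom(15, 1, 0.8))
  ab <- logrank_test(a, b); ba <- logrank_test(b, a)
  expect_equal(ab$chi_square, ba$chi_square, tolerance = 1e-12)
  expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)

  a3 <- a; a3$time <- a3$time * 7.5
  b3 <- b; b3$time <- b3$time * 7.5
  expect_equal(logrank_test(a3, b3)$chi_square, ab$chi_square,
               tolerance = 1e-12)

  nil1 <- mk_cohort(1:4, c(1, 2, 3, 4), rep(0, 4))
  nil2 <- mk_cohort(5:8, c(1, 2, 3, 4), rep(0, 4))
  expect_error(logrank_test(nil1, nil2), "at least one event")
})

test_that("null log-rank p-values are approximately uniform", {
  set.seed(89)
  pvals <- vapply(1:1000, function(i) {
    g1 <- mk_cohort(rnorm(40), rexp(40, 0.05), rep(1, 40))
    g2 <- mk_cohort(rnorm(40), rexp(40, 0.05), rep(1, 40))
    logrank_test(g1, g2)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
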