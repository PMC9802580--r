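mk_bip <- function(agents, targets) {
  build_bipartite(edge_table(agents, targets, kind = "mirna"),
                  unique(targets))
}

test_that("agents rank by degree with alphabetical tie-break", {
  bip <- mk_bip(c("m1", "m1", "m2"), c("KA", "KB", "KA"))
  r <- rank_agents(bip)
  expect_identical(r$label, c("m1", "m2"))
  expect_identical(r$degree, c(2L, 1L))

  flat <- mk_bip(c("mz", "ma", "mk"), c("KA", "KB", "KC"))
  expect_identical(rank_agents(flat)$label, c("ma", "mk", "mz"))

  none <- suppressWarnings(
    build_bipartite(edge_table("m1", "ZZ", kind = "mirna"), "KA"))
  expect_error(rank_agents(none), "no links")
})

test_that("union coverage matches set union and validates agents", {
  bip <- mk_bip(c("m1", "m1", "m2", "m2"), c("KA", "KB", "KB", "KC"))
  cov <- union_coverage(bip, c("m1", "m2"))
  expect_identical(cov$covered, c("KA", "KB", "KC"))
  expect_equal(cov$coverage_fraction, 1)

  empty <- union_coverage(bip, character(0))
  expect_length(empty$covered, 0L)
  expect_equal(empty$coverage_fraction, 0)

  expect_error(union_coverage(bip, c("m1", "mX")), "mX")
})

test_that("top-k coverage is monotone non-decreasing in k", {
  set.seed(41)
  for (i in 1:15) {
    bip <- random_bipartite(sample(4:10, 1), sample(4:10, 1))
    fr <- vapply(seq_along(bip$agents),
                 function(k) top_k_coverage(bip, k)$coverage_fraction,
                 numeric(1))
    expect_true(all(diff(fr) >= -1e-12))
  }
})

test_that("greedy cover picks maximal marginal gains", {
  bip <- mk_bip(c("m1", "m1", "m1", "m2", "m2", "m3"),
                c("KA", "KB", "KC", "KA", "KB", "KD"))
  g <- greedy_cover(bip, 2)
  expect_identical(g$selected, c("m1", "m3"))
  expect_length(g$covered, 4L)
  # exhaustive check: no 2-subset does better
  best <- max(vapply(utils::combn(bip$agents, 2, simplify = FALSE),
                     function(s) length(union_coverage(bip, s)$covered),
                     numeric(1)))
  expect_equal(length(g$covered), best)

  all_in <- greedy_cover(bip, length(bip$agents))
  expect_identical(all_in$covered, sort(unique(bip$links$kinase)))
})

test_that("greedy with k = 1 picks the maximum-degree agent", {
  set.seed(43)
  for (i in 1:10) {
    bip <- random_bipartite(sample(3:9, 1), sample(3:9, 1))
    expect_identical(greedy_cover(bip, 1)$selected,
                     rank_agents(bip)$label[1])
  }
})

test_that("greedy coverage dominates degree ranking and nears the optimum", {
  set.seed(47)
  for (i in 1:100) {
    bip <- random_bipartite(sample(3:10, 1), sample(3:10, 1),
                            p = runif(1, 0.15, 0.5))
    k <- sample(seq_along(bip$agents), 1)
    greedy <- greedy_cover(bip, k)
    degree_based <- top_k_coverage(bip, k)
    expect_gte(length(greedy$covered), length(degree_based$covered))
  }
  # (1 - 1/e) bound against the brute-force optimum on small instances
  set.seed(53)
  for (i in 1:20) {
    bip <- random_bipartite(sample(3:8, 1), sample(3:8, 1))
    k <- sample(seq_along(bip$agents), 1)
    opt <- max(vapply(utils::combn(bip$agents, k, simplify = FALSE),
                      function(s) length(union_coverage(bip, s)$covered),
                      numeric(1)))
    expect_gte(length(greedy_cover(bip, k)$covered), (1 - exp(-1)) * opt)
  }
})
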