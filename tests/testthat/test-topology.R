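test_that("degree centrality counts neighbours or sums weights", {
  star <- toy_net(rep("C", 4), c("L1", "L2", "L3", "L4"))
  k <- degree_centrality(star)
  expect_equal(unname(k["C"]), 4)
  expect_true(all(k[c("L1", "L2", "L3", "L4")] == 1))

  wet <- edge_table(c("A", "A"), c("B", "C"), weight = c(0.5, 2),
                    kind = "ppi")
  wnet <- build_ppi(wet, c("A", "B", "C"))
  expect_equal(unname(degree_centrality(wnet, weighted = TRUE)["A"]), 2.5)
  expect_equal(unname(degree_centrality(wnet, weighted = FALSE)["A"]), 2)
})

test_that("betweenness matches hand values on path and cycle", {
  path <- toy_net(c("A", "B"), c("B", "C"))
  cb <- betweenness_centrality(path)
  expect_equal(unname(cb["B"]), 1)
  expect_equal(unname(cb["A"]), 0)
  expect_equal(unname(cb["C"]), 0)

  # C4: the two shortest paths across each diagonal pair tie, giving each
  # intermediate node 1/2 from exactly one pair
  c4 <- toy_net(c("A", "B", "C", "A"), c("B", "C", "D", "D"))
  expect_equal(unname(betweenness_centrality(c4)), rep(0.5, 4))
})

test_that("betweenness handles disconnected graphs and leaves", {
  two_comp <- toy_net(c("A", "B", "X"), c("B", "C", "Y"))
  cb <- betweenness_centrality(two_comp)
  expect_equal(unname(cb["B"]), 1)  # unreachable pairs contribute 0
  expect_equal(unname(cb[c("X", "Y")]), c(0, 0))

  set.seed(31)
  for (i in 1:5) {
    net <- random_net(10, 0.3)
    k <- degree_centrality(net)
    cb <- betweenness_centrality(net)
    expect_true(all(cb[k == 1] == 0))
  }
})

test_that("Brandes equals the brute-force path-enumeration oracle", {
  set.seed(17)
  for (i in 1:12) {
    net <- random_net(sample(4:12, 1), runif(1, 0.2, 0.6))
    expect_equal(betweenness_centrality(net), brute_betweenness(net),
                 tolerance = 1e-12)
  }
})

test_that("Brandes agrees with igraph on a larger graph", {
  library(igraph)
  set.seed(19)
  net <- random_net(30, 0.15)
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes)
  ref <- igraph::betweenness(g, directed = FALSE, weights = NA)
  expect_equal(betweenness_centrality(net)[net$nodes],
               ref[net$nodes], tolerance = 1e-10)
})

test_that("normalized betweenness divides by the endpoint-pair count", {
  path <- toy_net(c("A", "B"), c("B", "C"))
  expect_equal(unname(betweenness_centrality(path, normalized = TRUE)["B"]),
               1)  # (n-1)(n-2)/2 = 1 for n = 3
  star <- toy_net(rep("C", 4), c("L1", "L2", "L3", "L4"))
  expect_equal(unname(betweenness_centrality(star, normalized = TRUE)["C"]),
               1)  # the centre lies on every pair's unique path
})

test_that("adding an edge never decreases a degree", {
  set.seed(23)
  for (i in 1:10) {
    net <- random_net(8, 0.3)
    k0 <- degree_centrality(net)
    pairs <- t(combn(net$nodes, 2))
    have <- paste(net$edges$from, net$edges$to)
    cand <- pairs[!paste(pairs[, 1], pairs[, 2]) %in% have, , drop = FALSE]
    if (nrow(cand) == 0) next
    add <- cand[1, ]
    net2 <- build_ppi(edge_table(c(net$edges$from, add[1]),
                                 c(net$edges$to, add[2]), kind = "ppi"),
                      net$nodes)
    k1 <- degree_centrality(net2)
    expect_true(all(k1[names(k0)] >= k0))
  }
})

test_that("hub ranking sorts by degree, then betweenness, then label", {
  # P5 path: B, C, D tie on degree 2; C sits on more shortest paths, and
  # the residual B/D tie breaks alphabetically
  net <- toy_net(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
  ct <- centrality_table(net)
  expect_identical(rank_hubs(ct, 2), c("C", "B"))

  single <- toy_net("A", "B")
  expect_identical(rank_hubs(centrality_table(single), 1), "A")
  expect_warning(all_of_them <- rank_hubs(centrality_table(single), 10),
                 "exceeds")
  expect_length(all_of_them, 2L)
})
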