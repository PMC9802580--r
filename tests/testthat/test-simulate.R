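test_that("catalogue generation plants the exact overlap and is seeded", {
  cfg <- sim_config(seed = 5L)
  cats <- gen_gene_catalogues(cfg)
  expect_length(cats$kinome, 650L)
  expect_length(cats$disease_genes, 474L)
  expect_length(intersect(cats$kinome$members, cats$disease_genes$members),
                21L)
  expect_length(cats$literature, 41L)
  expect_length(intersect(cats$literature$members,
                          cats$disease_genes$members), 0L)

  again <- gen_gene_catalogues(sim_config(seed = 5L))
  expect_identical(again, cats)

  disjoint <- gen_gene_catalogues(small_sim_config(overlap = 0L))
  expect_length(intersect(disjoint$kinome$members,
                          disjoint$disease_genes$members), 0L)

  expect_error(sim_config(n_kinome = 10, n_disease_genes = 5, overlap = 6,
                          n_literature = 2), "overlap")
})

test_that("planted hubs get the top degree by construction", {
  seeds <- sprintf("SYNH%03d", 1:20)
  cfg <- small_sim_config(planted_hub = seeds[7])
  net <- build_ppi(gen_ppi(cfg, seeds), seeds)
  k <- degree_centrality(net)
  expect_equal(unname(k[seeds[7]]), 19)
  expect_equal(max(k), 19)
})

test_that("Erdos-Renyi generation matches its expected edge count", {
  seeds <- sprintf("SYNE%03d", 1:10)
  cfg0 <- small_sim_config()
  cfg0$ppi_model$p <- 0
  expect_equal(nrow(gen_ppi(cfg0, seeds)), 0L)

  # at the default density, mean observed edges over 100 seeds should sit
  # within 3 standard errors of the binomial mean choose(56,2) * p = 196
  nodes56 <- sprintf("SYNE%03d", 1:56)
  p <- 196 / choose(56, 2)
  counts <- vapply(1:100, function(s) {
    nrow(gen_ppi(sim_config(seed = s), nodes56))
  }, numeric(1))
  se <- sqrt(choose(56, 2) * p * (1 - p)) / sqrt(100)
  expect_lte(abs(mean(counts) - 196), 3 * se)
})

test_that("preferential attachment produces heavy-tailed connected graphs", {
  seeds <- sprintf("SYNP%03d", 1:40)
  cfg <- small_sim_config(
    ppi_model = list(model = "preferential_attachment", m = 2L))
  et <- gen_ppi(cfg, seeds)
  net <- build_ppi(et, seeds)
  expect_equal(length(net$nodes), 40L)
  k <- degree_centrality(net)
  expect_gt(max(k), stats::median(k))  # hubs emerge
})

test_that("planted agents take the top bipartite rank", {
  kin <- sprintf("SYNKQ%02d", 1:36)
  cfg <- small_sim_config(
    planted_agent = list(label = "syn-miR-STAR", degree = 17L))
  bip <- build_bipartite(gen_bipartite(cfg, kin, "mirna"), kin)
  r <- rank_agents(bip)
  expect_identical(r$label[1], "syn-miR-STAR")
  expect_equal(r$degree[1], 17L)
  expect_lt(r$degree[2], 17L)
})

test_that("cohort generation respects censoring and hazard settings", {
  cfg <- small_sim_config()
  cfg$survival$censoring_rate <- 0
  coh <- gen_cohort(cfg)
  expect_equal(nrow(coh), 60L)
  expect_true(all(coh$event == 1L))

  cfg2 <- small_sim_config()
  coh2 <- gen_cohort(cfg2)
  expect_identical(coh2, gen_cohort(small_sim_config()))  # determinism
})

test_that("generator substreams are independent of one another", {
  cfg_a <- small_sim_config()
  cfg_b <- small_sim_config()
  cfg_b$survival$hazard_ratio <- 5  # survival tunables must not move the PPI
  seeds <- sprintf("SYNS%03d", 1:15)
  expect_identical(gen_ppi(cfg_a, seeds), gen_ppi(cfg_b, seeds))
  expect_identical(gen_bipartite(cfg_a, seeds, "drug"),
                   gen_bipartite(cfg_b, seeds, "drug"))
})

test_that("fixture directories are byte-identical across reruns", {
  cfg <- small_sim_config(seed = 99L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_fixtures(cfg, d1)
  p2 <- write_fixtures(cfg, d2)
  for (nm in names(p1)) {
    expect_identical(readLines(p1[[nm]]), readLines(p2[[nm]]),
                     label = sprintf("fixture %s", nm))
  }
})

test_that("planted structure is recovered through the analysis path", {
  seeds <- sprintf("SYNR%03d", 1:25)
  hub_hits <- vapply(1:25, function(s) {
    cfg <- small_sim_config(seed = s, planted_hub = seeds[3])
    net <- build_ppi(gen_ppi(cfg, seeds), seeds)
    rank_hubs(centrality_table(net), 1) == seeds[3]
  }, logical(1))
  expect_true(all(hub_hits))
})
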