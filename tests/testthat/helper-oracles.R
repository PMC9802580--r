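# Independent oracles and small fixture builders used across the suite.

# Build an interaction_network from parallel endpoint vectors.
toy_net <- function(from, to, nodes = NULL) {
  if (is.null(nodes)) nodes <- union(from, to)
  build_ppi(edge_table(from, to, kind = "ppi"), nodes)
}

# Random connected-ish Erdos-Renyi network with at least one edge.
random_net <- function(n, p) {
  labels <- sprintf("N%02d", seq_len(n))
  repeat {
    pairs <- combn(labels, 2L)
    pick <- runif(ncol(pairs)) < p
    if (any(pick)) break
  }
  toy_net(pairs[1L, pick], pairs[2L, pick])
}

# Brute-force betweenness oracle: enumerate every shortest path between
# every unordered node pair by expanding the BFS predecessor DAG, and
# credit interior nodes with 1 / (number of shortest paths for that pair).
brute_betweenness <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  idx <- seq_len(n); names(idx) <- nodes
  adj <- vector("list", n)
  for (i in idx) adj[[i]] <- integer(0)
  for (e in seq_len(nrow(net$edges))) {
    a <- idx[[net$edges$from[e]]]; b <- idx[[net$edges$to[e]]]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  cb <- numeric(n)
  enumerate_paths <- function(preds, s, t) {
    if (t == s) return(list(s))
    out <- list()
    for (p in preds[[t]]) {
      for (sub in enumerate_paths(preds, s, p)) out <- c(out, list(c(sub, t)))
    }
    out
  }
  for (s in seq_len(n - 1L)) {
    # BFS predecessor DAG from s
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- s; head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        if (dist[w] == dist[v] + 1L) preds[[w]] <- c(preds[[w]], v)
      }
    }
    for (t in seq(s + 1L, n)) {
      if (dist[t] < 0L) next  # different components contribute nothing
      paths <- enumerate_paths(preds, s, t)
      for (pth in paths) {
        interior <- pth[-c(1L, length(pth))]
        for (u in interior) cb[u] <- cb[u] + 1 / length(paths)
      }
    }
  }
  names(cb) <- nodes
  cb
}

# Benjamini-Hochberg step-up, written out directly from the definition.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- p[o] * m / seq_len(m)
  adj_sorted <- rev(cummin(rev(adj_sorted)))
  adj_sorted <- pmin(adj_sorted, 1)
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# All permutations of 1..n (recursive; only used for tiny n).
all_permutations <- function(n) {
  perm_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (sub in perm_of(v[-i])) out <- c(out, list(c(v[i], sub)))
    }
    out
  }
  perm_of(seq_len(n))
}

# Random bipartite network over na agents and nk kinases.
random_bipartite <- function(na, nk, p = 0.3) {
  agents <- sprintf("AG%02d", seq_len(na))
  kin <- sprintf("SYNKX%02d", seq_len(nk))
  repeat {
    grid <- expand.grid(a = agents, k = kin, stringsAsFactors = FALSE)
    pick <- runif(nrow(grid)) < p
    if (any(pick)) break
  }
  build_bipartite(edge_table(grid$a[pick], grid$k[pick], kind = "mirna"), kin)
}

# Small simulation config for fast end-to-end tests.
small_sim_config <- function(seed = 42L, ...) {
  args <- list(seed = seed, n_kinome = 60L, n_disease_genes = 40L,
               overlap = 10L, n_literature = 8L,
               ppi_model = list(model = "erdos_renyi", p = 0.25),
               n_agents = 30L, max_agent_degree = 8L,
               n_terms = 5L, term_size_range = c(5L, 15L),
               survival = list(n_per_group = 30L, baseline_hazard = 1 / 100,
                               hazard_ratio = 2, censoring_rate = 1 / 400))
  args <- utils::modifyList(args, list(...))
  do.call(sim_config, args)
}
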