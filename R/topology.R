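# Network topology: degree centrality, exact betweenness centrality
# (Brandes' algorithm), and the hub-ranking rule used to pick target genes.

adjacency_list <- function(net) {
  nodes <- net$nodes
  idx <- seq_along(nodes)
  names(idx) <- nodes
  adj <- vector("list", length(nodes))
  for (i in idx) adj[[i]] <- integer(0)
  if (nrow(net$edges)) {
    fi <- idx[net$edges$from]
    ti <- idx[net$edges$to]
    for (e in seq_along(fi)) {
      adj[[fi[e]]] <- c(adj[[fi[e]]], ti[e])
      adj[[ti[e]]] <- c(adj[[ti[e]]], fi[e])
    }
  }
  adj
}

#' Degree centrality
#'
#' Unweighted degree k is the number of interactions a node makes; the
#' weighted variant sums the edge weights w(a,b) over the node's neighbour
#' set. Integer-valued hub degrees reported alongside the networks here use
#' the unweighted form.
#'
#' @param net an `interaction_network`.
#' @param weighted sum edge weights instead of counting neighbours.
#' @return named numeric vector over `net$nodes`.
#' @export
degree_centrality <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  if (length(net$nodes) == 0L)
    stop("network has no nodes", call. = FALSE)
  k <- numeric(length(net$nodes))
  names(k) <- net$nodes
  if (nrow(net$edges)) {
    w <- if (weighted) net$edges$weight else rep(1, nrow(net$edges))
    for (e in seq_len(nrow(net$edges))) {
      k[net$edges$from[e]] <- k[net$edges$from[e]] + w[e]
      k[net$edges$to[e]] <- k[net$edges$to[e]] + w[e]
    }
  }
  k
}

#' Betweenness centrality (exact, Brandes' algorithm)
#'
#' For node u, the sum over unordered pairs of distinct endpoints (both
#' different from u) of the fraction of shortest paths between the pair
#' that pass through u. Shortest paths are unweighted (hop count); each
#' unordered pair is counted once, matching Cytoscape's NetworkAnalyzer
#' convention; pairs in different components contribute 0.
#'
#' @param net an `interaction_network`.
#' @param normalized divide by (n-1)(n-2)/2, the number of endpoint pairs.
#' @return named numeric vector over `net$nodes`.
#' @export
betweenness_centrality <- function(net, normalized = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  nodes <- net$nodes
  n <- length(nodes)
  if (n == 0L) stop("network has no nodes", call. = FALSE)
  cb <- numeric(n)
  adj <- adjacency_list(net)
  for (s in seq_len(n)) {
    # single-source shortest-path counts (BFS)
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- c(s); head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # dependency accumulation in reverse BFS order
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + (sigma[v] / sigma[w]) * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb <- cb / 2  # each unordered pair was accumulated from both endpoints
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    if (denom > 0) cb <- cb / denom
  }
  names(cb) <- nodes
  cb
}

#' Per-node centrality table
#'
#' Degree and betweenness for every node, the ingredients of the hub rule.
#'
#' @inheritParams degree_centrality
#' @return data.frame with columns `node`, `degree`, `betweenness`, sorted
#'   by degree descending, betweenness descending, then node label.
#' @export
centrality_table <- function(net, weighted = FALSE) {
  k <- degree_centrality(net, weighted = weighted)
  cb <- betweenness_centrality(net)
  out <- data.frame(node = net$nodes, degree = as.numeric(k),
                    betweenness = as.numeric(cb),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$degree, -out$betweenness, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hub genes
#'
#' Hubs are the nodes with the highest degree of connectivity; betweenness
#' centrality breaks degree ties, and the node label breaks the rest
#' deterministically.
#'
#' @param ct a [centrality_table()] data.frame (or an `interaction_network`,
#'   in which case the table is computed first).
#' @param top_n how many hubs to return (>= 1).
#' @return character vector of the `top_n` highest-ranked node labels; if
#'   `top_n` exceeds the node count the full ranking is returned with a
#'   warning.
#' @export
rank_hubs <- function(ct, top_n = 5L) {
  if (inherits(ct, "interaction_network")) ct <- centrality_table(ct)
  stopifnot(is.data.frame(ct),
            all(c("node", "degree", "betweenness") %in% names(ct)))
  if (top_n < 1L) stop("top_n must be >= 1", call. = FALSE)
  ord <- order(-ct$degree, -ct$betweenness, ct$node)
  ranked <- ct$node[ord]
  if (top_n > length(ranked)) {
    warning(sprintf("top_n = %d exceeds the %d available nodes; returning all",
                    top_n, length(ranked)), call. = FALSE)
    return(ranked)
  }
  ranked[seq_len(top_n)]
}
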