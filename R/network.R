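# Construction of the unipartite kinase PPI and the bipartite
# (disease/miRNA/drug vs kinase) association networks.

new_interaction_network <- function(edges, nodes) {
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges
#'
#' @param net an `interaction_network` or `bipartite_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) {
  if (inherits(net, "interaction_network")) return(length(net$nodes))
  if (inherits(net, "bipartite_network"))
    return(length(net$agents) + length(net$kinases))
  stop("not a network object", call. = FALSE)
}

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  if (inherits(net, "interaction_network")) return(nrow(net$edges))
  if (inherits(net, "bipartite_network")) return(nrow(net$links))
  stop("not a network object", call. = FALSE)
}

#' Build the induced PPI network on a seed set
#'
#' Keeps only edges whose *both* endpoints are seeds, removes self-loops,
#' and collapses duplicates keeping the maximum weight. Nodes are the seeds
#' that retain at least one edge (seeds isolated within the induced
#' subgraph are reported by [drop_isolates()], not carried as nodes here).
#' The result is invariant to row order and to swapping endpoint columns.
#'
#' @param edges an [edge_table] of kind `"ppi"`.
#' @param seeds a [gene_set] or character vector of seed symbols.
#' @return an `interaction_network` with elements `nodes` (sorted character)
#'   and `edges` (data.frame `from`, `to`, `weight`, with `from < to`).
#' @export
build_ppi <- function(edges, seeds) {
  stopifnot(inherits(edges, "edge_table"))
  if (edge_kind(edges) != "ppi")
    stop("build_ppi needs an edge table of kind 'ppi'", call. = FALSE)
  members <- as_members(seeds)
  keep <- edges$source %in% members & edges$target %in% members &
    edges$source != edges$target
  if (!any(keep))
    stop("induced PPI network is empty: no edge has both endpoints in the seed set",
         call. = FALSE)
  e <- edges[keep, , drop = FALSE]
  # edge_table already canonicalizes from < to and dedups for kind = ppi
  ed <- data.frame(from = e$source, to = e$target, weight = e$weight,
                   stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(ed$from, ed$to)
  ed <- ed[ord, , drop = FALSE]
  rownames(ed) <- NULL
  new_interaction_network(ed, nodes = sort(unique(c(ed$from, ed$to))))
}

new_bipartite_network <- function(links, agents, kinases, linked_kinases,
                                  kind) {
  structure(list(agents = agents, kinases = kinases, links = links,
                 linked_kinases = linked_kinases, kind = kind),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(
    "<bipartite_network> (%s) %d agents, %d kinases (%d linked), %d links\n",
    x$kind, length(x$agents), length(x$kinases), length(x$linked_kinases),
    nrow(x$links)))
  invisible(x)
}

#' Build an agent-kinase bipartite network
#'
#' Restricts an association table (disease-gene, miRNA-gene or drug-gene)
#' to links whose target belongs to the supplied kinase set. By default
#' kinases without any link stay on the kinase side and the linked subset
#' is reported separately (`linked_kinases`); set
#' `prune_isolated_kinases = TRUE` to keep only linked kinases.
#'
#' @param assoc an [edge_table] of kind `"disease"`, `"mirna"` or `"drug"`.
#' @param kinases a [gene_set] or character vector of kinase symbols.
#' @param prune_isolated_kinases drop unlinked kinases from the kinase side.
#' @return a `bipartite_network` with elements `agents`, `kinases`,
#'   `linked_kinases` and `links` (data.frame `agent`, `kinase`, `weight`).
#' @export
build_bipartite <- function(assoc, kinases, prune_isolated_kinases = FALSE) {
  stopifnot(inherits(assoc, "edge_table"))
  if (!edge_kind(assoc) %in% c("disease", "mirna", "drug"))
    stop("build_bipartite needs an edge table of kind disease/mirna/drug",
         call. = FALSE)
  members <- as_members(kinases)
  keep <- assoc$target %in% members
  if (!any(keep))
    warning("no association targets a supplied kinase; network has 0 links",
            call. = FALSE)
  links <- data.frame(agent = assoc$source[keep], kinase = assoc$target[keep],
                      weight = assoc$weight[keep], stringsAsFactors = FALSE,
                      row.names = NULL)
  ord <- order(links$agent, links$kinase)
  links <- links[ord, , drop = FALSE]
  rownames(links) <- NULL
  linked <- sort(unique(links$kinase))
  new_bipartite_network(
    links = links,
    agents = sort(unique(links$agent)),
    kinases = if (prune_isolated_kinases) linked else members,
    linked_kinases = linked,
    kind = edge_kind(assoc)
  )
}

#' Degree tally for one side of a bipartite network
#'
#' Counts links per agent or per kinase, sorted by degree descending with
#' alphabetical tie-break. Nodes of that side with no links appear with
#' degree 0.
#'
#' @param bip a `bipartite_network`.
#' @param side `"agent"` or `"kinase"`.
#' @return data.frame with columns `label` and `degree`.
#' @export
side_degree_table <- function(bip, side = c("agent", "kinase")) {
  stopifnot(inherits(bip, "bipartite_network"))
  side <- match.arg(side)
  labels <- if (side == "agent") bip$agents else bip$kinases
  hits <- if (side == "agent") bip$links$agent else bip$links$kinase
  deg <- integer(length(labels))
  names(deg) <- labels
  if (length(hits)) {
    tab <- table(hits)
    deg[names(tab)] <- as.integer(tab)
  }
  out <- data.frame(label = labels, degree = as.integer(deg),
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$degree, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
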