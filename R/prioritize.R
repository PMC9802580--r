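# Agent prioritization on bipartite networks: plain degree ranking (the
# reproduction path) and greedy maximum coverage (an optional comparator).

agent_neighbours <- function(bip) {
  split(bip$links$kinase, bip$links$agent)
}

new_coverage_report <- function(ranked_agents, selected, covered, n_kinases,
                                method) {
  structure(
    list(ranked_agents = ranked_agents, selected = selected,
         covered = covered,
         coverage_fraction = if (n_kinases > 0) length(covered) / n_kinases
                             else 0,
         n_kinases = n_kinases, method = method),
    class = "coverage_report"
  )
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> (%s) %d agent(s) cover %d / %d kinases (%.1f%%)\n",
              x$method, length(x$selected), length(x$covered), x$n_kinases,
              100 * x$coverage_fraction))
  invisible(x)
}

#' Rank agents by bipartite degree
#'
#' Orders the agent side (miRNAs, drugs or diseases) by number of kinase
#' links, descending, with alphabetical tie-break.
#'
#' @param bip a `bipartite_network` with at least one link.
#' @return data.frame with columns `label`, `degree`.
#' @export
rank_agents <- function(bip) {
  stopifnot(inherits(bip, "bipartite_network"))
  if (nrow(bip$links) == 0L)
    stop("bipartite network has no links; nothing to rank", call. = FALSE)
  side_degree_table(bip, side = "agent")
}

#' Union coverage of an agent set
#'
#' The kinases hit by at least one selected agent, as a set and as a
#' fraction of the network's kinase side.
#'
#' @param bip a `bipartite_network`.
#' @param agents character vector of agent labels; must all exist in `bip`.
#' @return a `coverage_report` with `ranked_agents` (full degree ranking),
#'   `selected`, `covered` (sorted kinase symbols), `coverage_fraction`.
#' @export
union_coverage <- function(bip, agents) {
  stopifnot(inherits(bip, "bipartite_network"))
  agents <- as.character(agents)
  unknown <- setdiff(agents, bip$agents)
  if (length(unknown))
    stop("unknown agent label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  covered <- sort(unique(bip$links$kinase[bip$links$agent %in% agents]))
  new_coverage_report(
    ranked_agents = if (nrow(bip$links)) rank_agents(bip) else NULL,
    selected = agents, covered = covered,
    n_kinases = length(bip$kinases), method = "degree"
  )
}

#' Top-k degree prioritization
#'
#' The reproduction path: rank agents by degree and report the union
#' coverage of the top k.
#'
#' @param bip a `bipartite_network` with at least one link.
#' @param k how many top agents to select.
#' @return a `coverage_report`.
#' @export
top_k_coverage <- function(bip, k = 5L) {
  ranking <- rank_agents(bip)
  k <- min(k, nrow(ranking))
  union_coverage(bip, ranking$label[seq_len(k)])
}

#' Greedy maximum coverage
#'
#' Classic greedy set-cover heuristic, included as a clearly-labelled
#' optional comparator to plain degree ranking (never the default): pick,
#' k times, the agent covering the most yet-uncovered kinases, ties broken
#' by label. Stops early if all coverable kinases are covered.
#'
#' @param bip a `bipartite_network` with at least one link.
#' @param k number of agents to select (>= 1).
#' @return a `coverage_report` with `method = "greedy"`.
#' @export
greedy_cover <- function(bip, k) {
  stopifnot(inherits(bip, "bipartite_network"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (nrow(bip$links) == 0L)
    stop("bipartite network has no links; nothing to cover", call. = FALSE)
  nb <- agent_neighbours(bip)
  agents <- sort(names(nb))
  selected <- character(0)
  covered <- character(0)
  for (step in seq_len(min(k, length(agents)))) {
    gains <- vapply(agents, function(a) {
      if (a %in% selected) return(-1L)
      length(setdiff(nb[[a]], covered))
    }, integer(1))
    best_gain <- max(gains)
    if (best_gain <= 0L) break
    pick <- min(agents[gains == best_gain])  # alphabetical tie-break
    selected <- c(selected, pick)
    covered <- union(covered, nb[[pick]])
  }
  new_coverage_report(
    ranked_agents = rank_agents(bip), selected = selected,
    covered = sort(covered), n_kinases = length(bip$kinases),
    method = "greedy"
  )
}
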