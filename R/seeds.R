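# Seed-gene selection: database intersection, literature union, and
# removal of kinases that make no PPI connection to another seed.

new_seed_report <- function(db_hits, literature_hits, combined,
                            connected = NULL, dropped_isolates = NULL) {
  structure(
    list(db_hits = db_hits, literature_hits = literature_hits,
         combined = combined, connected = connected,
         dropped_isolates = dropped_isolates),
    class = "seed_report"
  )
}

#' @export
print.seed_report <- function(x, ...) {
  cat("<seed_report>\n")
  cat(sprintf("  database hits:   %d\n", length(x$db_hits)))
  cat(sprintf("  literature hits: %d\n", length(x$literature_hits)))
  cat(sprintf("  combined seeds:  %d\n", length(x$combined)))
  if (!is.null(x$connected)) {
    cat(sprintf("  PPI-connected:   %d\n", length(x$connected)))
    cat(sprintf("  dropped isolates: %d\n", length(x$dropped_isolates)))
  }
  invisible(x)
}

#' Intersect a kinome catalogue with a disease gene list
#'
#' Identifies database-supported seed kinases as the set intersection of a
#' kinome catalogue and a disease-associated gene list, under normalized
#' symbol comparison.
#'
#' @param kinome a [gene_set] (or character vector) of kinase symbols.
#' @param disease_genes a [gene_set] (or character vector) of
#'   disease-associated genes.
#' @param name label for the result.
#' @return a [gene_set] of shared symbols. An empty intersection is allowed
#'   but triggers a warning.
#' @export
seed_intersect <- function(kinome, disease_genes, name = "db_hits") {
  k <- as_members(kinome); d <- as_members(disease_genes)
  if (length(k) == 0L || length(d) == 0L)
    stop("both input gene sets must be nonempty", call. = FALSE)
  hits <- intersect(k, d)
  if (length(hits) == 0L)
    warning("kinome and disease gene list are disjoint", call. = FALSE)
  gene_set(hits, name = name)
}

#' Combine database and literature seed sources
#'
#' Union of database-derived and literature-curated seed kinases. The two
#' sources are expected to be disjoint (so that set sizes add); any overlap
#' is reported with a warning and logged in the report.
#'
#' @param db [gene_set] of database-derived seeds.
#' @param literature [gene_set] of literature-curated seeds.
#' @return a `seed_report` with `db_hits`, `literature_hits` and `combined`
#'   filled in (`connected` is completed by [drop_isolates()]).
#' @export
combine_seeds <- function(db, literature) {
  db_m <- as_members(db); lit_m <- as_members(literature)
  overlap <- intersect(db_m, lit_m)
  if (length(overlap) > 0L)
    warning(sprintf(
      "database and literature seed sources overlap in %d gene(s): %s",
      length(overlap), paste(utils::head(overlap, 10L), collapse = ", ")),
      call. = FALSE)
  new_seed_report(
    db_hits = gene_set(db_m, "db_hits"),
    literature_hits = gene_set(lit_m, "literature_hits"),
    combined = gene_set(c(db_m, lit_m), "combined_seeds")
  )
}

#' Drop seeds isolated in the induced PPI
#'
#' A seed is connected when it has at least one PPI edge to *another* seed,
#' i.e. connectivity is judged on the subgraph induced by the seed set;
#' edges to genes outside the seed set do not count. Idempotent: applying
#' it to its own `connected` set changes nothing.
#'
#' @param seeds a [gene_set], character vector, or `seed_report` (its
#'   `combined` set is used).
#' @param ppi an [edge_table] of kind `"ppi"`.
#' @return a `seed_report` with `connected` and `dropped_isolates` filled in.
#' @export
drop_isolates <- function(seeds, ppi) {
  stopifnot(inherits(ppi, "edge_table"))
  if (edge_kind(ppi) != "ppi")
    stop("drop_isolates needs an edge table of kind 'ppi'", call. = FALSE)
  if (inherits(seeds, "seed_report")) {
    report <- seeds
    members <- report$combined$members
  } else {
    members <- as_members(seeds)
    gs <- gene_set(members, "combined_seeds")
    report <- new_seed_report(db_hits = gs,
                              literature_hits = gene_set(character(0),
                                                         "literature_hits"),
                              combined = gs)
  }
  keep <- ppi$source %in% members & ppi$target %in% members &
    ppi$source != ppi$target
  touched <- unique(c(ppi$source[keep], ppi$target[keep]))
  report$connected <- gene_set(touched, "connected_seeds")
  report$dropped_isolates <- gene_set(setdiff(members, touched),
                                      "dropped_isolates")
  report
}

#' Full seed selection in one call
#'
#' Convenience wrapper chaining [seed_intersect()], [combine_seeds()] and
#' [drop_isolates()].
#'
#' @inheritParams seed_intersect
#' @param literature [gene_set] of literature-curated seeds.
#' @param ppi an [edge_table] of kind `"ppi"`.
#' @return a complete `seed_report`.
#' @export
select_seeds <- function(kinome, disease_genes, literature, ppi) {
  db <- seed_intersect(kinome, disease_genes)
  report <- combine_seeds(db, literature)
  drop_isolates(report, ppi)
}
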