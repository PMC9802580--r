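# Over-representation analysis: hypergeometric upper-tail test per term
# with Benjamini-Hochberg adjustment across the collection.

#' Hypergeometric over-representation test for one term
#'
#' Tests whether a query gene set overlaps an annotation term more than
#' expected from random draws out of the background universe. The p-value
#' is the upper tail P\[X >= overlap\] for
#' X ~ Hypergeometric(universe_size, term_size, query_size) — the
#' Fisher-exact core of standard enrichment tools.
#'
#' @param query a [gene_set] or character vector; must be contained in the
#'   universe.
#' @param term a [gene_set] or character vector; must be contained in the
#'   universe.
#' @param universe background [gene_set] or character vector.
#' @param term_name label used in the output row.
#' @return one-row data.frame: `term`, `overlap`, `term_size`, `query_size`,
#'   `universe_size`, `p_value`.
#' @export
hypergeom_test <- function(query, term, universe, term_name = "term") {
  q <- as_members(query); t <- as_members(term); u <- as_members(universe)
  bad_q <- setdiff(q, u)
  if (length(bad_q))
    stop("query genes outside the universe: ",
         paste(utils::head(bad_q, 10L), collapse = ", "), call. = FALSE)
  bad_t <- setdiff(t, u)
  if (length(bad_t))
    stop("term genes outside the universe: ",
         paste(utils::head(bad_t, 10L), collapse = ", "), call. = FALSE)
  overlap <- length(intersect(q, t))
  p <- stats::phyper(overlap - 1, m = length(t), n = length(u) - length(t),
                     k = length(q), lower.tail = FALSE)
  data.frame(term = term_name, overlap = overlap, term_size = length(t),
             query_size = length(q), universe_size = length(u),
             p_value = p, stringsAsFactors = FALSE)
}

#' Enrichment of a query set against an annotation collection
#'
#' One hypergeometric test per term against the collection's universe,
#' Benjamini-Hochberg adjustment across all tested terms, rows sorted by
#' raw p ascending (term label breaks ties). The significance flag uses the
#' *raw* p-value against `alpha` — the convention of the web tools this
#' replaces — while the adjusted p-value is always reported alongside.
#' Terms with zero overlap are kept (p = 1) so the number of tests stays
#' stable for the adjustment.
#'
#' @param query a [gene_set] or character vector contained in the universe.
#' @param coll an [annotation_collection].
#' @param alpha raw-p significance threshold (default 0.05).
#' @param method multiple-testing method for [stats::p.adjust()] (default
#'   `"BH"`).
#' @return data.frame with one row per term: `term`, `overlap`, `term_size`,
#'   `query_size`, `universe_size`, `p_value`, `adjusted_p`, `significant`.
#' @export
enrich <- function(query, coll, alpha = 0.05, method = "BH") {
  stopifnot(inherits(coll, "annotation_collection"))
  rows <- lapply(names(coll$terms), function(tn) {
    hypergeom_test(query, coll$terms[[tn]], coll$universe, term_name = tn)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = method)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
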