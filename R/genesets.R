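#' Normalize gene symbols
#'
#' Gene identifiers are compared as uppercased, whitespace-stripped
#' HGNC-style symbols throughout the package; no alias or identifier
#' mapping is performed. Empty strings are dropped.
#'
#' @param x character vector of raw gene symbols.
#' @return character vector of normalized symbols (duplicates retained).
#' @examples
#' normalize_genes(c("akt1", " AKT1 ", "mTOR", ""))
#' @export
normalize_genes <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[nzchar(x) & !is.na(x)]
}

#' Construct a gene set
#'
#' A named collection of normalized gene symbols (a kinome catalogue, a
#' disease gene list, a seed set, ...). Members are uppercased,
#' whitespace-stripped, deduplicated and stored sorted so that identical
#' collections compare equal regardless of input order.
#'
#' @param members character vector of gene symbols (normalized on entry).
#' @param name short label for the set.
#' @return an object of class `gene_set` with elements `name`, `members`
#'   and `n_duplicates_collapsed` (how many input symbols collapsed during
#'   normalization).
#' @examples
#' gene_set(c("akt1", "AKT1 ", "MTOR"), name = "demo")
#' @export
gene_set <- function(members, name = "gene_set") {
  stopifnot(is.character(name), length(name) == 1L)
  members <- normalize_genes(members)
  n_dup <- sum(duplicated(members))
  structure(
    list(name = name,
         members = sort(unique(members)),
         n_duplicates_collapsed = n_dup),
    class = "gene_set"
  )
}

#' @export
length.gene_set <- function(x) length(x$members)

#' @export
as.character.gene_set <- function(x, ...) x$members

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x)))
  show <- utils::head(x$members, 6L)
  cat(" ", paste(show, collapse = ", "),
      if (length(x) > 6L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

# Accept either a gene_set or a character vector where a set of symbols is
# expected; always returns the normalized member vector.
as_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else sort(unique(normalize_genes(x)))
}

#' Construct an annotation collection (GMT semantics)
#'
#' A named term -> gene-set mapping plus a background universe, the input
#' of over-representation analysis. When no universe is supplied it
#' defaults to the union of all term members.
#'
#' @param terms named list; each element a character vector of gene symbols
#'   (or a [gene_set]).
#' @param universe optional background [gene_set] or character vector. Every
#'   term must be a subset of the universe when one is supplied.
#' @return an object of class `annotation_collection` with elements `terms`
#'   (named list of normalized symbol vectors) and `universe` (a `gene_set`).
#' @export
annotation_collection <- function(terms, universe = NULL) {
  if (length(terms) == 0L)
    stop("annotation collection needs at least one term", call. = FALSE)
  nm <- names(terms)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("every term must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate term names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  terms <- lapply(terms, as_members)
  if (is.null(universe)) {
    universe <- gene_set(unlist(terms, use.names = FALSE), name = "universe")
  } else {
    universe <- if (inherits(universe, "gene_set")) universe
                else gene_set(universe, name = "universe")
    for (tn in nm) {
      extra <- setdiff(terms[[tn]], universe$members)
      if (length(extra))
        stop(sprintf("term '%s' has members outside the universe: %s",
                     tn, paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(terms = terms, universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("<annotation_collection> %d terms, universe of %d genes\n",
              length(x$terms), length(x$universe)))
  invisible(x)
}
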