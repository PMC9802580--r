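# Readers/writers for every plain-text format the pipeline touches.
# Dialect: tab-separated, UTF-8, '#' comment lines, no quoting.

EDGE_KINDS <- c("ppi", "disease", "mirna", "drug")

read_text_lines <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  readLines(path, warn = FALSE, encoding = "UTF-8")
}

is_content_line <- function(lines) {
  trimmed <- trimws(lines)
  nzchar(trimmed) & !startsWith(trimmed, "#")
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comment lines are ignored.
#' Symbols are normalized (uppercased, whitespace-stripped) and duplicates
#' collapsed with a message reporting the count.
#'
#' @param path file path.
#' @param name label for the resulting set (default: file name).
#' @return a [gene_set].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- read_text_lines(path)
  lines <- lines[is_content_line(lines)]
  gs <- gene_set(lines, name = name)
  if (length(gs) == 0L)
    stop(sprintf("gene list '%s' is empty after filtering", path),
         call. = FALSE)
  if (gs$n_duplicates_collapsed > 0L)
    message(sprintf("read_gene_list: collapsed %d duplicate symbol(s) in %s",
                    gs$n_duplicates_collapsed, path))
  gs
}

#' Write a gene list
#'
#' @param genes a [gene_set] or character vector.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as_members(genes), path, useBytes = TRUE)
  invisible(path)
}

# Normalize source labels: gene symbols for PPI rows, verbatim trimmed
# strings for bipartite agents (disease names, miRNA ids, drug names).
normalize_source <- function(x, kind) {
  if (kind == "ppi") normalize_genes(x) else trimws(x)
}

#' Construct an edge table
#'
#' The in-memory form of every association table the pipeline consumes:
#' gene-gene PPI edges or agent-gene (disease/miRNA/drug) association
#' pairs. Target genes are always normalized symbols; source labels are
#' normalized symbols for `kind = "ppi"` and verbatim trimmed strings
#' otherwise. Duplicate pairs collapse keeping the maximum weight; for PPI
#' tables (a,b) and (b,a) are the same edge.
#'
#' @param source,target character vectors of endpoint labels.
#' @param weight optional numeric weights (>= 0); defaults to 1.
#' @param kind one of `"ppi"`, `"disease"`, `"mirna"`, `"drug"`.
#' @return an object of class `edge_table`: a data.frame with columns
#'   `source`, `target`, `weight` and attributes `kind` and
#'   `n_duplicates_collapsed`.
#' @export
edge_table <- function(source, target, weight = NULL, kind = "ppi") {
  kind <- match.arg(kind, EDGE_KINDS)
  source <- as.character(source); target <- as.character(target)
  if (length(source) != length(target))
    stop("source and target lengths differ", call. = FALSE)
  if (any(!nzchar(trimws(source))) || any(!nzchar(trimws(target))))
    stop("rows with empty source or target labels are not allowed",
         call. = FALSE)
  source <- normalize_source(source, kind)
  target <- toupper(trimws(target))
  if (is.null(weight)) weight <- rep(1, length(source))
  weight <- as.numeric(weight)
  weight[is.na(weight)] <- 1
  if (any(weight < 0))
    stop("negative edge weights are not allowed", call. = FALSE)
  if (kind == "ppi") {
    a <- pmin(source, target)
    b <- pmax(source, target)
    source <- a; target <- b
  }
  key <- paste(source, target, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    w <- tapply(weight, key, max)
    keep <- !duplicated(key)
    source <- source[keep]; target <- target[keep]
    weight <- as.numeric(w[paste(source, target, sep = "\r")])
  }
  ord <- order(source, target)
  out <- data.frame(source = source[ord], target = target[ord],
                    weight = weight[ord], stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, kind = kind, n_duplicates_collapsed = n_dup,
            class = c("edge_table", "data.frame"))
}

edge_kind <- function(et) attr(et, "kind")

#' Read a TSV edge table
#'
#' Expects at least two tab-separated columns (source, target) and an
#' optional third numeric weight column (default weight 1). `#` comment
#' lines are ignored. Duplicate pairs collapse keeping the maximum weight,
#' with the collapsed count reported; for `kind = "ppi"` the pair (a,b)
#' equals (b,a).
#'
#' @param path file path.
#' @inheritParams edge_table
#' @return an [edge_table].
#' @export
read_edge_table <- function(path, kind = "ppi") {
  kind <- match.arg(kind, EDGE_KINDS)
  lines <- read_text_lines(path)
  keep <- is_content_line(lines)
  idx <- which(keep)
  if (length(idx) == 0L)
    stop(sprintf("edge table '%s' is empty after filtering", path),
         call. = FALSE)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  src <- character(length(idx)); tgt <- character(length(idx))
  wt <- rep(1, length(idx))
  for (i in seq_along(idx)) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L || !nzchar(f[1L]) || !nzchar(f[2L]))
      stop(sprintf("line %d of %s: need non-empty source and target fields",
                   idx[i], path), call. = FALSE)
    src[i] <- f[1L]; tgt[i] <- f[2L]
    if (length(f) >= 3L && nzchar(f[3L])) {
      w <- suppressWarnings(as.numeric(f[3L]))
      if (is.na(w))
        stop(sprintf("line %d of %s: non-numeric weight '%s'",
                     idx[i], path, f[3L]), call. = FALSE)
      wt[i] <- w
    }
  }
  et <- edge_table(src, tgt, wt, kind = kind)
  n_dup <- attr(et, "n_duplicates_collapsed")
  if (n_dup > 0L)
    message(sprintf("read_edge_table: collapsed %d duplicate pair(s) in %s",
                    n_dup, path))
  et
}

#' Write an edge table as TSV
#'
#' Inverse of [read_edge_table()] on normalized content: writing then
#' reading back with the same `kind` reproduces the table.
#'
#' @param et an [edge_table].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(et, path) {
  stopifnot(inherits(et, "edge_table"))
  lines <- sprintf("%s\t%s\t%s", et$source, et$target,
                   format(et$weight, trim = TRUE, digits = 15,
                          scientific = FALSE))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' One line per edge, Cytoscape simple-interaction format. The relation
#' token is `pp` for protein-protein edges and `assoc` for bipartite
#' agent-kinase links. Lines are emitted in deterministic lexicographic
#' order.
#'
#' @param net an `interaction_network` or `bipartite_network`.
#' @param path optional output file; when `NULL` the lines are returned only.
#' @return character vector of SIF lines, invisibly when `path` is given.
#' @export
write_sif <- function(net, path = NULL) {
  if (inherits(net, "interaction_network")) {
    if (nrow(net$edges) == 0L)
      stop("cannot export an empty network", call. = FALSE)
    lines <- sprintf("%s pp %s", net$edges$from, net$edges$to)
  } else if (inherits(net, "bipartite_network")) {
    if (nrow(net$links) == 0L)
      stop("cannot export an empty network", call. = FALSE)
    lines <- sprintf("%s assoc %s", net$links$agent, net$links$kinase)
  } else {
    stop("write_sif expects an interaction_network or bipartite_network",
         call. = FALSE)
  }
  lines <- sort(lines)
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

#' Read a GMT gene-set collection
#'
#' Broad dialect: per line, a term name, a description and one or more
#' gene symbols, tab-separated. The background universe defaults to the
#' union of all term members unless supplied.
#'
#' @param path file path.
#' @param universe optional background [gene_set] or character vector.
#' @return an [annotation_collection].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- read_text_lines(path)
  idx <- which(is_content_line(lines))
  if (length(idx) == 0L)
    stop(sprintf("GMT file '%s' is empty", path), call. = FALSE)
  terms <- list()
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("line %d of %s: GMT lines need >= 3 fields", i, path),
           call. = FALSE)
    tn <- trimws(f[1L])
    if (tn %in% names(terms))
      stop(sprintf("line %d of %s: duplicate term name '%s'", i, path, tn),
           call. = FALSE)
    terms[[tn]] <- normalize_genes(f[-c(1L, 2L)])
  }
  annotation_collection(terms, universe = universe)
}

#' Write an annotation collection as GMT
#'
#' @param coll an [annotation_collection].
#' @param path output file path.
#' @param descriptions optional named character vector of term descriptions
#'   (defaults to `"na"`).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(coll, path, descriptions = NULL) {
  stopifnot(inherits(coll, "annotation_collection"))
  nm <- names(coll$terms)
  desc <- rep("na", length(nm))
  if (!is.null(descriptions)) {
    hit <- nm %in% names(descriptions)
    desc[hit] <- descriptions[nm[hit]]
  }
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], coll$terms[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a data frame as a plain TSV table
#'
#' Tab-separated, header row, no quoting or row names; the dialect every
#' tabular output of the pipeline uses.
#'
#' @param rows a data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a survival cohort table
#'
#' TSV with header columns `sample`, `expression`, `time`, `event`
#' (follow-up time in days; event flag 1 = event observed, 0 = censored).
#'
#' @param path file path.
#' @return a [survival_cohort].
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("sample", "expression", "time", "event")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop(sprintf("cohort table '%s' lacks column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  survival_cohort(df[, need])
}
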