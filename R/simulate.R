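# Seeded synthetic-data generators producing every input the pipeline
# consumes, with planted structure (known hubs, known top agents, known
# hazard ratio) so each stage can be verified against ground truth.
#
# One root seed drives independent per-generator substreams, so adding or
# re-running one generator never perturbs another's output.

SYN_STREAMS <- c(catalogues = 11L, ppi = 23L, disease = 31L, mirna = 37L,
                 drug = 41L, annotations = 43L, cohort = 47L)

substream_seed <- function(seed, stream) {
  offset <- SYN_STREAMS[[stream]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(expr)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. The defaults
#' emulate the statistical shape of a kinase comorbidity study: a
#' 650-symbol kinome catalogue sharing 21 symbols with a 474-symbol
#' disease gene list, 41 additional literature-curated seeds disjoint from
#' the shared 21, an Erdos-Renyi PPI at the density of a 56-node /
#' 196-edge network, heavy-tailed bipartite agent degrees capped at 17,
#' and exponential survival with a group hazard ratio of 2.
#'
#' @param seed integer root seed; every generator derives its own
#'   substream from it.
#' @param n_kinome,n_disease_genes,overlap catalogue sizes and their shared
#'   symbol count (`overlap <= min(n_kinome, n_disease_genes)`).
#' @param n_literature number of literature-curated seeds, drawn from the
#'   kinome outside the shared symbols (so sources are disjoint).
#' @param ppi_model list: `model = "erdos_renyi"` with edge probability `p`,
#'   or `model = "preferential_attachment"` with attachment count `m`.
#' @param planted_hub optional node label to wire to every other seed
#'   (guaranteed maximum degree).
#' @param n_agents number of bipartite agents (diseases/miRNAs/drugs).
#' @param agent_degree_exponent exponent of the truncated power law the
#'   agent degrees are drawn from (P(d) proportional to d^-exponent).
#' @param max_agent_degree truncation point of the degree law.
#' @param planted_agent optional `list(label =, degree =)`: that agent gets
#'   exactly `degree` targets and every other agent is capped below it.
#' @param n_terms,term_size_range annotation-collection shape for the
#'   enrichment stage.
#' @param survival list: `n_per_group`, `baseline_hazard` (events/day),
#'   `hazard_ratio` (> 0, high- vs low-expression group),
#'   `censoring_rate` (independent exponential censoring; 0 disables).
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_kinome = 650L, n_disease_genes = 474L,
                       overlap = 21L, n_literature = 41L,
                       ppi_model = list(model = "erdos_renyi",
                                        p = 196 / choose(56, 2)),
                       planted_hub = NULL,
                       n_agents = 788L, agent_degree_exponent = 2.2,
                       max_agent_degree = 17L, planted_agent = NULL,
                       n_terms = 20L, term_size_range = c(5L, 50L),
                       survival = list(n_per_group = 100L,
                                       baseline_hazard = 1 / 500,
                                       hazard_ratio = 2,
                                       censoring_rate = 1 / 2000)) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (overlap > min(n_kinome, n_disease_genes))
    stop("overlap exceeds the smaller catalogue", call. = FALSE)
  if (n_literature > n_kinome - overlap)
    stop("not enough kinome-only symbols for the literature set",
         call. = FALSE)
  stopifnot(ppi_model$model %in% c("erdos_renyi", "preferential_attachment"))
  if (ppi_model$model == "erdos_renyi")
    stopifnot(ppi_model$p >= 0, ppi_model$p <= 1)
  if (!is.null(planted_agent))
    stopifnot(is.list(planted_agent),
              all(c("label", "degree") %in% names(planted_agent)),
              planted_agent$degree >= 1)
  stopifnot(survival$hazard_ratio > 0, survival$baseline_hazard > 0,
            survival$censoring_rate >= 0, survival$n_per_group >= 2)
  structure(
    list(seed = as.integer(seed), n_kinome = as.integer(n_kinome),
         n_disease_genes = as.integer(n_disease_genes),
         overlap = as.integer(overlap),
         n_literature = as.integer(n_literature),
         ppi_model = ppi_model, planted_hub = planted_hub,
         n_agents = as.integer(n_agents),
         agent_degree_exponent = agent_degree_exponent,
         max_agent_degree = as.integer(max_agent_degree),
         planted_agent = planted_agent,
         n_terms = as.integer(n_terms),
         term_size_range = as.integer(term_size_range),
         survival = survival),
    class = "sim_config"
  )
}

# Synthetic symbols carry a reserved SYN prefix so they can never collide
# with real HGNC symbols.
syn_symbols <- function(prefix, n) sprintf("SYN%s%04d", prefix, seq_len(n))

#' Generate kinome and disease-gene catalogues with known overlap
#'
#' Produces a synthetic kinome, a synthetic disease gene list sharing
#' exactly `cfg$overlap` symbols with it, and a literature seed list drawn
#' from the kinome-only symbols (disjoint from the shared ones).
#'
#' @param cfg a [sim_config()].
#' @return list of [gene_set]s: `kinome`, `disease_genes`, `literature`.
#' @export
gen_gene_catalogues <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  shared <- syn_symbols("SH", cfg$overlap)
  kin_only <- syn_symbols("KN", cfg$n_kinome - cfg$overlap)
  dis_only <- syn_symbols("DG", cfg$n_disease_genes - cfg$overlap)
  literature <- with_stream(cfg$seed, "catalogues",
                            sort(sample(kin_only, cfg$n_literature)))
  list(
    kinome = gene_set(c(shared, kin_only), "kinome"),
    disease_genes = gene_set(c(shared, dis_only), "disease_genes"),
    literature = gene_set(literature, "literature")
  )
}

#' Generate a synthetic PPI edge table
#'
#' Erdos-Renyi G(n, p) or preferential attachment on the given seed
#' symbols. When `cfg$planted_hub` is set, that node is wired to every
#' other seed, guaranteeing it the top degree.
#'
#' @param cfg a [sim_config()].
#' @param seeds a [gene_set] or character vector of node symbols.
#' @return an [edge_table] of kind `"ppi"`.
#' @export
gen_ppi <- function(cfg, seeds) {
  stopifnot(inherits(cfg, "sim_config"))
  nodes <- as_members(seeds)
  n <- length(nodes)
  if (n < 2L) stop("need at least 2 seed nodes", call. = FALSE)
  hub <- cfg$planted_hub
  if (!is.null(hub)) {
    hub <- normalize_genes(hub)
    if (!hub %in% nodes)
      stop("planted hub is not among the seeds", call. = FALSE)
  }
  edges <- with_stream(cfg$seed, "ppi", {
    if (cfg$ppi_model$model == "erdos_renyi") {
      pairs <- utils::combn(nodes, 2L)
      pick <- stats::runif(ncol(pairs)) < cfg$ppi_model$p
      data.frame(source = pairs[1L, pick], target = pairs[2L, pick],
                 stringsAsFactors = FALSE)
    } else {
      m <- cfg$ppi_model$m
      stopifnot(m >= 1, m < n)
      perm <- sample(nodes)
      src <- character(0); tgt <- character(0)
      deg <- integer(n); names(deg) <- perm
      # seed clique on the first m + 1 arrivals
      init <- utils::combn(perm[seq_len(m + 1L)], 2L)
      src <- init[1L, ]; tgt <- init[2L, ]
      for (v in init[1L, ]) deg[v] <- deg[v] + 1L
      for (v in init[2L, ]) deg[v] <- deg[v] + 1L
      if (n > m + 1L) for (i in seq(m + 2L, n)) {
        existing <- perm[seq_len(i - 1L)]
        att <- sample(existing, m, prob = deg[existing] + 1)
        src <- c(src, rep(perm[i], m)); tgt <- c(tgt, att)
        deg[perm[i]] <- deg[perm[i]] + m
        for (v in att) deg[v] <- deg[v] + 1L
      }
      data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
    }
  })
  if (!is.null(hub)) {
    others <- setdiff(nodes, hub)
    edges <- rbind(edges, data.frame(source = hub, target = others,
                                     stringsAsFactors = FALSE))
  }
  if (nrow(edges) == 0L)
    return(structure(
      data.frame(source = character(0), target = character(0),
                 weight = numeric(0), stringsAsFactors = FALSE),
      kind = "ppi", n_duplicates_collapsed = 0L,
      class = c("edge_table", "data.frame")))
  edge_table(edges$source, edges$target, kind = "ppi")
}

#' Generate a synthetic bipartite association table
#'
#' Agent degrees are drawn from a truncated power law
#' P(d) proportional to d^-`agent_degree_exponent` on
#' 1..`max_agent_degree`, emulating the heavy-tailed agent degrees of real
#' disease/miRNA/drug association tables; each agent then links to that
#' many distinct random kinases. When `cfg$planted_agent` is set, that
#' agent receives exactly its target count and all other agents are capped
#' one below it, guaranteeing it the top rank.
#'
#' @param cfg a [sim_config()].
#' @param kinases a [gene_set] or character vector of target symbols.
#' @param kind `"disease"`, `"mirna"` or `"drug"` (also selects the RNG
#'   substream so the three tables are independent).
#' @return an [edge_table] of the requested kind.
#' @export
gen_bipartite <- function(cfg, kinases, kind = c("mirna", "disease", "drug")) {
  stopifnot(inherits(cfg, "sim_config"))
  kind <- match.arg(kind)
  targets <- as_members(kinases)
  if (length(targets) == 0L) stop("no target kinases", call. = FALSE)
  dmax <- min(cfg$max_agent_degree, length(targets))
  planted <- cfg$planted_agent
  if (!is.null(planted) && planted$degree > length(targets))
    stop("planted agent degree exceeds the kinase count", call. = FALSE)
  prefix <- c(disease = "SYNDIS_", mirna = "syn-miR-", drug = "SYNDRUG_")[[kind]]
  labels <- sprintf("%s%04d", prefix, seq_len(cfg$n_agents))
  with_stream(cfg$seed, kind, {
    degs <- sample(seq_len(dmax), cfg$n_agents, replace = TRUE,
                   prob = seq_len(dmax)^(-cfg$agent_degree_exponent))
    if (!is.null(planted)) degs <- pmin(degs, max(planted$degree - 1L, 1L))
    src <- rep(labels, degs)
    tgt <- unlist(lapply(degs, function(d) sample(targets, d)),
                  use.names = FALSE)
    if (!is.null(planted)) {
      src <- c(src, rep(planted$label, planted$degree))
      tgt <- c(tgt, sample(targets, planted$degree))
    }
    edge_table(src, tgt, kind = kind)
  })
}

#' Generate a synthetic annotation collection
#'
#' `cfg$n_terms` terms with sizes uniform over `cfg$term_size_range`,
#' sampled from the supplied universe; input for the enrichment stage.
#'
#' @param cfg a [sim_config()].
#' @param universe a [gene_set] or character vector.
#' @return an [annotation_collection] with the supplied universe.
#' @export
gen_annotations <- function(cfg, universe) {
  stopifnot(inherits(cfg, "sim_config"))
  u <- as_members(universe)
  lo <- min(cfg$term_size_range); hi <- max(cfg$term_size_range)
  if (hi > length(u))
    stop("term sizes exceed the universe", call. = FALSE)
  with_stream(cfg$seed, "annotations", {
    sizes <- sample(seq(lo, hi), cfg$n_terms, replace = TRUE)
    terms <- lapply(sizes, function(s) sample(u, s))
    names(terms) <- sprintf("SYNTERM_%03d", seq_len(cfg$n_terms))
    annotation_collection(terms, universe = u)
  })
}

#' Generate a synthetic survival cohort with a known hazard ratio
#'
#' Expression values are standard normal; the cohort splits at its median
#' into a low group with exponential event times at `baseline_hazard` and a
#' high group at `baseline_hazard * hazard_ratio`. Independent exponential
#' censoring at `censoring_rate` is applied when nonzero.
#'
#' @param cfg a [sim_config()].
#' @param gene label recorded on the cohort (attribute `gene`).
#' @return a [survival_cohort] of `2 * cfg$survival$n_per_group` samples.
#' @export
gen_cohort <- function(cfg, gene = "SYNSH0001") {
  stopifnot(inherits(cfg, "sim_config"))
  sv <- cfg$survival
  n <- 2L * as.integer(sv$n_per_group)
  cohort <- with_stream(cfg$seed, "cohort", {
    expression <- stats::rnorm(n)
    high <- expression > stats::median(expression)
    rate <- sv$baseline_hazard * ifelse(high, sv$hazard_ratio, 1)
    t_event <- stats::rexp(n, rate = rate)
    if (sv$censoring_rate > 0) {
      t_cens <- stats::rexp(n, rate = sv$censoring_rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    data.frame(sample = sprintf("SYNSAMPLE%04d", seq_len(n)),
               expression = expression, time = time, event = event,
               stringsAsFactors = FALSE)
  })
  out <- survival_cohort(cohort)
  attr(out, "gene") <- gene
  out
}

#' Write a complete fixture directory
#'
#' Runs every generator off one [sim_config()] and writes all files the
#' pipeline consumes: `kinome.txt`, `disease_genes.txt`, `literature.txt`,
#' `ppi.tsv`, `disease.tsv`, `mirna.tsv`, `drug.tsv`, `annotations.gmt`,
#' `cohort.tsv` and a `sim_config.yaml` echo. Byte-identical for identical
#' configurations.
#'
#' @param cfg a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written file paths, invisibly.
#' @export
write_fixtures <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cats <- gen_gene_catalogues(cfg)
  seeds <- gene_set(union(
    intersect(cats$kinome$members, cats$disease_genes$members),
    cats$literature$members), "combined_seeds")
  ppi <- gen_ppi(cfg, seeds)
  paths <- c(
    kinome = file.path(outdir, "kinome.txt"),
    disease_genes = file.path(outdir, "disease_genes.txt"),
    literature = file.path(outdir, "literature.txt"),
    ppi = file.path(outdir, "ppi.tsv"),
    disease = file.path(outdir, "disease.tsv"),
    mirna = file.path(outdir, "mirna.tsv"),
    drug = file.path(outdir, "drug.tsv"),
    gmt = file.path(outdir, "annotations.gmt"),
    cohort = file.path(outdir, "cohort.tsv"),
    config = file.path(outdir, "sim_config.yaml")
  )
  write_gene_list(cats$kinome, paths[["kinome"]])
  write_gene_list(cats$disease_genes, paths[["disease_genes"]])
  write_gene_list(cats$literature, paths[["literature"]])
  write_edge_table(ppi, paths[["ppi"]])
  for (kind in c("disease", "mirna", "drug"))
    write_edge_table(gen_bipartite(cfg, seeds, kind = kind), paths[[kind]])
  write_gmt(gen_annotations(cfg, cats$kinome), paths[["gmt"]])
  write_table(as.data.frame(gen_cohort(cfg)), paths[["cohort"]])
  cfg_echo <- unclass(cfg)
  cfg_echo$planted_agent <- if (is.null(cfg$planted_agent)) NULL else
    cfg$planted_agent
  writeLines(yaml::as.yaml(cfg_echo), paths[["config"]])
  invisible(paths)
}
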