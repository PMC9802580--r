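# Full-pipeline orchestration: seed selection -> PPI + hubs -> disease
# bipartite -> enrichment -> miRNA / drug prioritization -> survival,
# with per-stage logging, input digests and a run manifest.

`%||%` <- function(x, y) if (is.null(x)) y else x

default_run_params <- function() {
  list(top_hubs = 5L, top_mirnas = 5L, top_drugs = 3L,
       enrich_alpha = 0.05, survival_alpha = 0.1,
       weighted_degree = FALSE, survival_gene = NA_character_)
}

validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config))
    stop("config must be a list or a YAML file path", call. = FALSE)
  if (is.null(config$inputs) || !is.list(config$inputs))
    stop("config field 'inputs' (named list of file paths) is required",
         call. = FALSE)
  required <- c("kinome", "disease_genes", "literature", "ppi")
  missing_inputs <- setdiff(required, names(config$inputs))
  if (length(missing_inputs))
    stop("config$inputs lacks required field(s): ",
         paste(missing_inputs, collapse = ", "), call. = FALSE)
  for (nm in required) {
    if (!file.exists(config$inputs[[nm]]))
      stop(sprintf("config$inputs$%s: file not found: %s",
                   nm, config$inputs[[nm]]), call. = FALSE)
  }
  params <- default_run_params()
  for (nm in names(config$params %||% list())) {
    if (!nm %in% names(params))
      stop(sprintf("config$params has unknown field '%s'", nm), call. = FALSE)
    params[[nm]] <- config$params[[nm]]
  }
  config$params <- params
  config
}

stage_log <- function(...) message(sprintf(...))

run_stage <- function(manifest, name, fun) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(fun(), error = function(e) {
    warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            call. = FALSE)
    structure(list(message = conditionMessage(e)), class = "stage_failure")
  })
  elapsed <- proc.time()[["elapsed"]] - t0
  status <- if (inherits(result, "stage_failure")) "failed" else "ok"
  manifest$stages[[name]] <- list(status = status, seconds = round(elapsed, 3))
  if (status == "failed")
    manifest$stages[[name]]$error <- result$message
  list(manifest = manifest, result = result,
       ok = !inherits(result, "stage_failure"))
}

#' Run the full comorbidity-network analysis
#'
#' Orchestrates every stage from plain-text inputs: seed selection
#' (database intersection, literature union, isolate removal), induced PPI
#' construction with degree/betweenness hub ranking, the disease-kinase
#' bipartite network with per-side degree tables, over-representation
#' analysis of the connected seeds, miRNA and drug prioritization by
#' degree with top-k union coverage, and a median-split log-rank survival
#' screen. The disease, miRNA, drug, enrichment and survival branches are
#' isolated: failure or absence of one is reported in the manifest and
#' does not abort the others.
#'
#' @param config a list, or path to a YAML file, with fields:
#'   * `inputs`: named file paths — required `kinome`, `disease_genes`,
#'     `literature`, `ppi`; optional `disease`, `mirna`, `drug`, `gmt`,
#'     `cohort`.
#'   * `params` (optional): `top_hubs` (5), `top_mirnas` (5), `top_drugs`
#'     (3), `enrich_alpha` (0.05), `survival_alpha` (0.1),
#'     `weighted_degree` (FALSE), `survival_gene` (label only).
#' @param outdir output directory; all stage outputs (TSV/SIF/JSON) plus
#'   `manifest.json` are written there.
#' @return the run manifest (also written as JSON), a list with the config
#'   echo, input digests, per-stage status/counts/timings, output file
#'   digests and package version. Stage results are attached as the
#'   `"results"` attribute.
#' @export
full_run <- function(config, outdir) {
  config <- validate_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  params <- config$params
  inputs <- config$inputs
  present <- names(inputs)[vapply(inputs, function(p)
    is.character(p) && file.exists(p), logical(1))]

  manifest <- list(
    tool = "comorbnet",
    version = as.character(utils::packageVersion("comorbnet")),
    config = list(inputs = inputs[present], params = params),
    input_digests = as.list(unname_digests(tools::md5sum(
      vapply(present, function(nm) inputs[[nm]], character(1))))),
    stages = list(), counts = list(), outputs = list()
  )
  names(manifest$input_digests) <- present
  results <- list()

  # --- seed selection ------------------------------------------------
  st <- run_stage(manifest, "seed_selection", function() {
    kinome <- read_gene_list(inputs$kinome, "kinome")
    disease_genes <- read_gene_list(inputs$disease_genes, "disease_genes")
    literature <- read_gene_list(inputs$literature, "literature")
    ppi_edges <- read_edge_table(inputs$ppi, kind = "ppi")
    report <- select_seeds(kinome, disease_genes, literature, ppi_edges)
    list(report = report, ppi_edges = ppi_edges)
  })
  manifest <- st$manifest
  if (!st$ok) {
    manifest <- finalize_manifest(manifest, outdir, results)
    stop("seed selection failed; cannot continue", call. = FALSE)
  }
  report <- st$result$report
  ppi_edges <- st$result$ppi_edges
  results$seed_report <- report
  manifest$counts$seed_selection <- list(
    db_hits = length(report$db_hits),
    literature_hits = length(report$literature_hits),
    combined = length(report$combined),
    connected = length(report$connected),
    dropped_isolates = length(report$dropped_isolates))
  seed_tsv <- file.path(outdir, "seed_report.tsv")
  write_table(data.frame(
    gene = report$combined$members,
    source = ifelse(report$combined$members %in% report$db_hits$members,
                    "database", "literature"),
    connected = report$combined$members %in% report$connected$members),
    seed_tsv)
  manifest$outputs[["seed_report.tsv"]] <- unname(tools::md5sum(seed_tsv))
  stage_log("seed_selection: %d db + %d literature -> %d combined, %d connected",
            length(report$db_hits), length(report$literature_hits),
            length(report$combined), length(report$connected))

  # --- PPI + topology ------------------------------------------------
  st <- run_stage(manifest, "ppi_topology", function() {
    net <- build_ppi(ppi_edges, report$connected)
    ct <- centrality_table(net, weighted = isTRUE(params$weighted_degree))
    hubs <- rank_hubs(ct, top_n = params$top_hubs)
    list(net = net, ct = ct, hubs = hubs)
  })
  manifest <- st$manifest
  hubs <- character(0)
  if (st$ok) {
    net <- st$result$net; ct <- st$result$ct; hubs <- st$result$hubs
    results$ppi <- net; results$centrality <- ct; results$hubs <- hubs
    manifest$counts$ppi <- list(nodes = n_nodes(net), edges = n_edges(net),
                                hubs = length(hubs))
    sif <- file.path(outdir, "ppi.sif")
    write_sif(net, sif)
    ct_out <- ct
    ct_out$rank <- seq_len(nrow(ct_out))
    ct_out$is_hub <- ct_out$node %in% hubs
    ct_tsv <- file.path(outdir, "centrality.tsv")
    write_table(ct_out, ct_tsv)
    manifest$outputs[["ppi.sif"]] <- unname(tools::md5sum(sif))
    manifest$outputs[["centrality.tsv"]] <- unname(tools::md5sum(ct_tsv))
    stage_log("ppi_topology: %d nodes, %d edges; top hubs: %s",
              n_nodes(net), n_edges(net), paste(hubs, collapse = ", "))
  }

  # --- bipartite branches (disease / miRNA / drug) --------------------
  branch_spec <- list(
    disease = list(kind = "disease", top = NA_integer_),
    mirna = list(kind = "mirna", top = params$top_mirnas),
    drug = list(kind = "drug", top = params$top_drugs)
  )
  for (branch in names(branch_spec)) {
    path <- inputs[[branch]]
    if (is.null(path) || !is.character(path) || !file.exists(path)) {
      warning(sprintf("input '%s' missing; branch skipped", branch),
              call. = FALSE)
      manifest$stages[[paste0(branch, "_branch")]] <-
        list(status = "skipped", reason = "input missing")
      next
    }
    st <- run_stage(manifest, paste0(branch, "_branch"), function() {
      assoc <- read_edge_table(path, kind = branch_spec[[branch]]$kind)
      bip <- build_bipartite(assoc, report$connected)
      out <- list(bip = bip,
                  agent_degrees = side_degree_table(bip, "agent"),
                  kinase_degrees = side_degree_table(bip, "kinase"))
      topn <- branch_spec[[branch]]$top
      if (!is.na(topn) && nrow(bip$links) > 0L)
        out$coverage <- top_k_coverage(bip, k = topn)
      out
    })
    manifest <- st$manifest
    if (!st$ok) next
    bip <- st$result$bip
    results[[paste0(branch, "_network")]] <- bip
    results[[paste0(branch, "_coverage")]] <- st$result$coverage
    manifest$counts[[branch]] <- list(
      agents = length(bip$agents),
      linked_kinases = length(bip$linked_kinases),
      links = n_edges(bip))
    if (!is.null(st$result$coverage)) {
      cov <- st$result$coverage
      manifest$counts[[branch]]$top_k <- length(cov$selected)
      manifest$counts[[branch]]$covered_kinases <- length(cov$covered)
      manifest$counts[[branch]]$coverage_fraction <-
        round(cov$coverage_fraction, 6)
    }
    for (side in c("agent", "kinase")) {
      f <- file.path(outdir, sprintf("%s_%s_degrees.tsv", branch, side))
      write_table(st$result[[paste0(side, "_degrees")]], f)
      manifest$outputs[[basename(f)]] <- unname(tools::md5sum(f))
    }
    if (n_edges(bip) > 0L) {
      f <- file.path(outdir, sprintf("%s_network.sif", branch))
      write_sif(bip, f)
      manifest$outputs[[basename(f)]] <- unname(tools::md5sum(f))
    }
    stage_log("%s_branch: %d agents, %d linked kinases, %d links",
              branch, length(bip$agents), length(bip$linked_kinases),
              n_edges(bip))
  }

  # --- enrichment -----------------------------------------------------
  if (!is.null(inputs$gmt) && file.exists(inputs$gmt %||% "")) {
    st <- run_stage(manifest, "enrichment", function() {
      coll <- read_gmt(inputs$gmt)
      query <- gene_set(intersect(report$connected$members,
                                  coll$universe$members), "query")
      if (length(query) == 0L)
        stop("no connected seed is part of the annotation universe")
      enrich(query, coll, alpha = params$enrich_alpha)
    })
    manifest <- st$manifest
    if (st$ok) {
      enr <- st$result
      results$enrichment <- enr
      manifest$counts$enrichment <- list(
        terms_tested = nrow(enr),
        significant = sum(enr$significant))
      f <- file.path(outdir, "enrichment.tsv")
      write_table(enr, f)
      manifest$outputs[["enrichment.tsv"]] <- unname(tools::md5sum(f))
      stage_log("enrichment: %d terms, %d significant at raw p < %g",
                nrow(enr), sum(enr$significant), params$enrich_alpha)
    }
  } else {
    manifest$stages$enrichment <- list(status = "skipped",
                                       reason = "input missing")
  }

  # --- survival -------------------------------------------------------
  if (!is.null(inputs$cohort) && file.exists(inputs$cohort %||% "")) {
    st <- run_stage(manifest, "survival", function() {
      cohort <- read_cohort(inputs$cohort)
      survival_screen(cohort, alpha = params$survival_alpha)
    })
    manifest <- st$manifest
    if (st$ok) {
      scr <- st$result
      results$survival <- scr
      manifest$counts$survival <- list(
        n_high = scr$n_high, n_low = scr$n_low,
        chi_square = round(scr$logrank$chi_square, 6),
        p_value = signif(scr$logrank$p_value, 6),
        significant = scr$logrank$significant)
      for (grp in c("high", "low")) {
        f <- file.path(outdir, sprintf("km_%s.tsv", grp))
        write_table(as.data.frame(scr[[paste0(grp, "_curve")]]), f)
        manifest$outputs[[basename(f)]] <- unname(tools::md5sum(f))
      }
      f <- file.path(outdir, "logrank.json")
      jsonlite::write_json(scr$logrank[c("observed", "expected",
                                         "chi_square", "p_value",
                                         "significant", "alpha")],
                           f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      manifest$outputs[["logrank.json"]] <- unname(tools::md5sum(f))
      stage_log("survival: chi-square = %.3f, p = %.4g",
                scr$logrank$chi_square, scr$logrank$p_value)
    }
  } else {
    manifest$stages$survival <- list(status = "skipped",
                                     reason = "input missing")
  }

  manifest <- finalize_manifest(manifest, outdir, results)
  manifest
}

unname_digests <- function(x) { names(x) <- NULL; x }

finalize_manifest <- function(manifest, outdir, results) {
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(manifest, "results") <- results
  attr(manifest, "path") <- path
  manifest
}

#' Strip timing fields from a manifest
#'
#' Reruns on identical inputs produce identical manifests except for the
#' per-stage wall-clock times; this helper removes them so manifests can be
#' compared for idempotence.
#'
#' @param manifest a manifest list as returned by [full_run()].
#' @return the manifest without `seconds` fields or attached results.
#' @export
manifest_without_timings <- function(manifest) {
  manifest$stages <- lapply(manifest$stages, function(s) {
    s$seconds <- NULL
    s
  })
  attributes(manifest) <- list(names = names(manifest))
  manifest
}
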