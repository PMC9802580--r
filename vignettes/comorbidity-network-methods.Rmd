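---
title: "Methods: network-based comorbidity analysis of disease-associated kinases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network-based comorbidity analysis of disease-associated kinases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

## The problem

Kinases dysregulated in a primary disease (here, an amyotrophic lateral
sclerosis-associated kinase set is the motivating case) are frequently
implicated in other disorders, cancers in particular. A network view makes
that comorbidity structure explicit: kinases become nodes of a
protein-protein interaction (PPI) network, and diseases, miRNAs and drugs
become the *agent* side of bipartite association networks whose links
record curated agent-gene associations. Three questions follow:

1. Which kinases are *hubs* of the PPI network, i.e. candidates whose
   perturbation touches the largest part of the disease-causing network?
2. Which agents (miRNAs as therapeutic leads, drugs for repurposing) cover
   the largest share of the kinase set?
3. Is a hub kinase's expression associated with patient survival?

`comorbnet` implements the complete analysis as composable R functions plus
a synthetic-data generator, so every stage is testable against planted
ground truth without any database download.

## Seed selection

Seeds are assembled in three steps, each a set operation on normalized
(uppercased, whitespace-stripped) symbols:

* `seed_intersect(kinome, disease_genes)` — kinases with database support
  for the primary disease.
* `combine_seeds(db, literature)` — union with a literature-curated list.
  The two sources are expected to be disjoint so the sizes add; an overlap
  is not an error but is flagged loudly, because it changes the arithmetic
  of every downstream count.
* `drop_isolates(seeds, ppi)` — a seed is kept only if it has at least one
  PPI edge to *another* seed. Connectivity is judged on the induced
  subgraph: an edge from a seed to a non-seed gene does not rescue it.
  This matches the convention of building the PPI "between the selected"
  genes and makes the operation idempotent.

No alias or identifier mapping is performed: symbols are compared
literally. This is deterministic and dependency-free; when two synonyms
denote one gene (e.g. the GNB2L1/RACK1 pair) a translation table must be
applied upstream.

## Network construction

`build_ppi()` induces an undirected, self-loop-free, deduplicated graph on
the seed set; duplicate rows collapse keeping the maximum weight, and
(a, b) equals (b, a). `build_bipartite()` restricts an association table to
links targeting the supplied kinases. Agent labels (disease names, miRNA
ids, drug names) are matched as verbatim trimmed strings — no ontology
normalization is attempted, a documented limitation for free-text disease
vocabularies.

By default unlinked kinases remain on the kinase side and the linked
subset is reported separately (`linked_kinases`); coverage denominators
therefore depend on which kinase set a network is built on, and the
pipeline builds the miRNA/drug networks on the PPI-connected seed set.

## Centrality and hub ranking

Degree centrality is the neighbour count, or with `weighted = TRUE` the
sum of edge weights over the neighbour set. The default is unweighted:
hub degrees reported by comparable analyses are integer interaction
counts, and weights (e.g. interaction confidences) are carried but not
summed unless asked for.

Betweenness centrality of node $u$ is

$$C_b(u) = \sum_{s \ne u \ne t} \frac{p(s, u, t)}{p(s, t)},$$

the sum over endpoint pairs of the fraction of shortest paths through
$u$. Three conventions needed fixing:

* **Unordered pairs, counted once.** The summation is ambiguous about
  ordered pairs; we count each unordered pair once, the convention of
  Cytoscape's NetworkAnalyzer, which this module replaces. Values are raw
  by default, with `normalized = TRUE` dividing by $(n-1)(n-2)/2$.
* **Hop-count shortest paths.** Path *counts*, not weighted costs, even
  when edge weights exist.
* **Disconnected pairs contribute 0** rather than erroring — real PPI
  subnetworks have components.

The implementation is Brandes' exact accumulation algorithm; the test
suite checks it for exact equality against a brute-force oracle that
enumerates every shortest path on random graphs of up to 12 nodes, and
against an independent graph library on larger graphs.

`rank_hubs()` sorts by degree descending, breaks ties by betweenness
descending (both criteria of the hub definition), and finally by label so
results are deterministic. Whether hubs should be computed on the full
connected seed network or on the disease-linked subnetwork is genuinely
open in this style of analysis; the functions accept any
`interaction_network`, and `full_run()` ranks hubs on the connected seed
PPI.

## Agent prioritization

`rank_agents()` orders the agent side by degree (label-ascending
tie-break); `top_k_coverage()` reports the union of the top-k agents'
kinase neighbourhoods and the covered fraction. This plain degree ranking
is the reproduction path. `greedy_cover()` — classic greedy maximum
coverage, picking the agent with the largest marginal gain — ships as a
clearly labelled optional comparator, never the default: property tests
confirm it dominates degree ranking and stays within $(1 - 1/e)$ of the
exhaustive optimum on small instances.

## Over-representation analysis

`hypergeom_test()` computes the upper-tail probability
$P[X \ge \text{overlap}]$ with
$X \sim \mathrm{Hypergeometric}(N_\text{universe}, n_\text{term},
n_\text{query})$ — the Fisher-exact core of standard enrichment web tools,
re-implemented in-package so no web service is needed. `enrich()` applies
it per term, adjusts across terms by Benjamini-Hochberg, and sorts by raw
p. Two deliberate choices:

* The significance flag uses **raw p < alpha (default 0.05)** — the display
  convention of the tools this replaces — while the BH-adjusted value is
  always reported alongside, for statistical honesty.
* Zero-overlap terms are kept (p = 1) rather than dropped, so the number
  of tests entering BH is stable.
* The universe defaults to the union of all term genes and is
  overridable; analyses that fed their query into a web tool rarely state
  their universe, so the default is conservative and explicit.

## Survival screening

`median_split()` dichotomizes a cohort at the median expression value;
ties go to the low group (a convention the upstream web portals leave
unstated; fixing it makes splits deterministic). `km_estimate()` is the
Kaplan-Meier product-limit estimator and `logrank_test()` the two-group
Mantel-Haenszel log-rank test with the hypergeometric variance and no
tied-time correction beyond pooling events at identical times; both are
computed via the `survival` package, behind stable interfaces that return
plain data frames. The default significance threshold for the screen flag
is **p < 0.1**, the lenient convention of exploratory prognostic-marker
screens, configurable via `alpha`.

External patient cohorts (e.g. TCGA-derived survival pages) are out of
scope: the cohort is a file input, and the synthetic generator provides
cohorts with a known hazard ratio instead.

## The synthetic-data generator

`sim_config()` fixes the study conditions; all generators derive
independent RNG substreams from one root seed, so adding or rerunning one
generator never perturbs another and identical configurations yield
byte-identical fixture files. Defaults emulate the shape of a kinase
comorbidity study:

| parameter | default | rationale |
|---|---|---|
| `n_kinome`, `n_disease_genes`, `overlap` | 650, 474, 21 | catalogue sizes and intersection of the motivating study |
| `n_literature` | 41 | literature seeds, drawn disjoint from the 21 so 21 + 41 = 62 |
| `ppi_model` | Erdős–Rényi, p = 196/C(56,2) | density of a 56-node, 196-edge kinase PPI |
| `agent_degree_exponent`, `max_agent_degree` | 2.2, 17 | truncated power law; heavy-tailed agent degrees with the observed maximum |
| `n_agents` | 788 | miRNA-table scale |
| `survival` | n = 100/group, baseline hazard 1/500 per day, HR 2, censoring 1/2000 per day | exponential times at a clinically plausible event scale, light independent censoring |

Planted structure provides ground truth: `planted_hub` wires one node to
every other seed (guaranteed top degree), and `planted_agent` receives
exactly its target count while all other agents are capped below it.
Recovery tests require the planted element to be ranked first in at least
99 of 100 seeded replicates.

What the generator does **not** emulate: PPI degree correlations and
clustering of real interactomes (Erdős–Rényi edges are independent;
`preferential_attachment` is available when a heavy-tailed PPI is wanted),
agent-kinase preferences (targets are uniform), realistic disease/miRNA
vocabularies, and non-proportional hazards. Passing tests therefore
demonstrate correctness of the *computations* under controlled conditions,
not biological validity on real tables. Synthetic symbols carry a reserved
`SYN` prefix so they can never collide with real HGNC symbols.

Because Erdős–Rényi isolates are rare at the default density
(expected ≈ 62·(1−p)^61 ≈ 0.02 nodes), synthetic runs typically keep all
62 seeds connected; the isolate-removal logic is exercised by dedicated
tests with sparse graphs instead.

## Pipeline orchestration

`full_run(config, outdir)` executes the stages in dependency order:
seed selection → PPI + hub ranking → disease branch → enrichment → miRNA
branch → drug branch → survival. The disease, miRNA, drug, enrichment and
survival branches are isolated — these are parallel screens off the same
seed set, so a missing or broken input skips that branch with a warning
and the manifest records it, while the others complete. The manifest
(JSON) carries the config echo, MD5 digests of every input and output,
per-stage counts and wall-clock times; reruns on identical inputs are
byte-identical apart from the timing fields
(`manifest_without_timings()` strips them for comparison). All thresholds
(top-5 hubs, top-5 miRNAs, top-3 drugs, enrichment alpha 0.05, survival
alpha 0.1) live in the config with those values as defaults.

## Problem sizes in the test suite

Fast feedback drives the choices: oracle-equality betweenness tests use 30
random graphs of up to 12 nodes (brute-force path enumeration is
exponential beyond that); degree identities use 100 random instances;
planted-structure recovery uses 100 replicates at full catalogue scale;
log-rank calibration uses 1000 null cohorts of 100 samples per group and
power is measured on 500 cohorts of 200 per group; end-to-end pipeline
tests run a reduced configuration (60-gene kinome, 30 agents) that
preserves every code path.

## Known limitations

* Symbol matching is literal; synonym pairs must be resolved upstream.
* Disease names are free text; the same disease spelled two ways is two
  agents.
* The hypergeometric test assumes genes are exchangeable under the null —
  co-annotation and gene-length biases are not modelled.
* The log-rank screen at p < 0.1 is exploratory; it controls neither FDR
  across genes nor confounding, and no hazard-ratio confidence intervals
  are produced.
* Greedy coverage is a heuristic with the usual $(1 - 1/e)$ guarantee;
  exact maximum coverage is NP-hard and only the tests solve it, by brute
  force, on tiny instances.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
paths <- write_fixtures(cfg, "fixtures")
manifest <- full_run(list(inputs = as.list(paths[c(
  "kinome", "disease_genes", "literature", "ppi",
  "disease", "mirna", "drug", "gmt", "cohort")])), "results")
str(manifest$counts)
```
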