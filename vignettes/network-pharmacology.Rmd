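---
title: "Methods: ADME screening, core-PPI hub analysis and term enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ADME screening, core-PPI hub analysis and term enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herbnet)
```

# The problem

A multi-herb formula contains hundreds of compounds acting on overlapping
protein targets; no single-target assay explains its pharmacology. The
network-pharmacology approach implemented here connects the formula to a
disease through a chain of filters and graph constructions:

1. **ADME screen** — keep compounds plausible as orally absorbed,
   brain-penetrant drugs;
2. **target mapping** — collect precomputed compound–target predictions for
   the surviving compounds and build the compound–target bipartite network;
3. **disease intersection** — compare the formula's target union with a
   disease gene list;
4. **PPI assembly** — expand both the formula's targets and the disease
   genes over a background interactome, and intersect the two networks into
   a *core* PPI network;
5. **hub screening** — rank core-network proteins by six topological
   features and keep those above every feature's median;
6. **enrichment** — test the surviving candidates for pathway
   overrepresentation, grouping redundant terms by kappa agreement.

Because the compound and interaction databases behind such studies are
licensed, versioned and online, the package ships a synthetic-data
generator that emulates all five inputs with *planted*, exactly known
structure. Every downstream stage can therefore be validated against
ground truth, offline and reproducibly.

# Stage models and parameters

## ADME screening

Five per-compound parameters are thresholded, all inclusively (`>=`):

| parameter | meaning                                   | unit   | default floor |
|-----------|-------------------------------------------|--------|---------------|
| OB        | oral bioavailability                      | %      | 30            |
| DL        | drug-likeness score                       | —      | 0.18          |
| Caco-2    | intestinal permeability score             | —      | −0.4          |
| BBB       | blood–brain-barrier penetration score     | —      | −0.3          |
| HL        | half-life                                 | hours  | 4             |

All five comparisons are inclusive because the screening criteria are
stated as "at least" thresholds wherever they are written down; boundary
compounds (e.g. OB exactly 30) pass. Records with missing or non-numeric
ADME values raise a validation error naming the compound and field rather
than silently failing the screen — silent drops would corrupt the counts
the rest of the pipeline reports.

Compounds failing the screen can be *rescued* by a whitelist of ids with
literature support. The whitelist is data, not computation: the package
implements the mechanism (a rescue set disjoint from the ADME-passed set)
and reports both partitions separately.

## Target mapping and the bipartite network

Compound–target associations arrive as a table (compound, target, herb,
source, optional score). Model-predicted rows can be filtered by strict
score floors (support-vector machine > 0.7, random forest > 0.8, the
conventional cut-offs for such predictors); database-sourced rows pass
unfiltered. Gene symbols are upper-cased and trimmed; no alias resolution
is attempted, since that would require a live identifier service.

The compound–target network keeps one edge per distinct (compound, target)
pair — herb provenance is an attribute of the association table, not a
reason to duplicate edges. Its node count therefore equals the number of
active compounds with at least one target plus the number of distinct
targets.

## PPI expansion and the core network

Both seed sets (formula targets, disease genes) are expanded over the
background interactome by taking the subgraph induced on the seeds plus
all nodes within distance `depth` (default 1). Induced-subgraph semantics
— edges among added neighbors are kept — was chosen because it is the
only self-consistent reading of "a network of the seeds and their
interactors"; expansion tools differ here and rarely document their rule.

The two expanded networks are merged by **intersection** (nodes and edges
present in both). Intersection is the default because the result is
described as a *core* network: it is necessarily no larger than either
input, which only intersection guarantees. Union is available as an
option. After intersection, nodes left without edges are dropped by
default — centrality screening on isolated nodes is meaningless, and
interactive network tools behave the same way.

## The six topological features

The feature definitions are frozen to the conventions of the CytoNCA
family of centrality tools, because the median thresholds of the hub
screen are only interpretable on these scales:

- **DC** — degree.
- **BC** — betweenness, undirected and *unnormalized*: each unordered
  pair (s,t) contributes the fraction of its shortest paths through v.
- **CC** — closeness with the Wasserman–Faust component correction:
  `cc(v) = (r/(n−1)) · (r/Σd)` with `r` the number of nodes reachable
  from v and Σd the sum of their distances; an isolated node scores 0.
  On a connected graph this is the familiar `(n−1)/Σd`. The correction
  keeps values comparable across components of a disconnected graph.
- **EC** — the principal eigenvector of the adjacency matrix,
  nonnegative, Euclidean norm 1.
- **NC** — sum over incident edges of the edge clustering coefficient
  `z(v,u)/(min(deg v, deg u) − 1)`, where `z` counts triangles on the
  edge; the coefficient is defined as 0 when the denominator is 0 (a
  degree-1 endpoint cannot close a triangle).
- **LAC** — the mean, over v's neighbors, of their degree within the
  subgraph induced by v's neighborhood.

Normalized betweenness and harmonic closeness are deliberately rejected.

### Numerical choices

Eigenvector centrality is computed by power iteration from the all-ones
vector (deterministic, tie-free) with tolerance `1e-10` on the max-norm
change and a 1000-iteration cap; exceeding the cap is an error carrying
the iteration count, never a silent partial result. Iteration runs on the
shifted operator `A + I`: the shift leaves eigenvectors unchanged but
prevents the period-2 oscillation that plain power iteration exhibits on
bipartite-like graphs (a star is the smallest example). On disconnected
graphs the iteration converges onto the component with the largest
leading eigenvalue, and when two components tie exactly the result is the
projection of the start vector onto the shared eigenspace — a documented
property, not an error. An edgeless graph has no meaningful eigenvector;
`centrality_eigenvector()` errors, and the table constructor records an
all-zero column flagged `ec_degenerate`.

Degree and betweenness are delegated to igraph, whose undirected
unnormalized betweenness matches the convention above; closeness, NC and
LAC are computed in the package because no installed library implements
these exact forms. All six are checked against independent brute-force
oracles (breadth-first path enumeration, dense eigen-solve, direct
triangle counting) on hundreds of random graphs of up to 12 nodes at
tolerance 1e-8 in the test suite.

## Hub screening

`median_thresholds()` takes the per-feature medians of the centrality
table (even counts use the midpoint of the central pair — the standard
convention, and the one that produces fractional medians on integer
features). `filter_hubs()` keeps nodes that beat every threshold, with a
**strictly greater** comparison by default. The classical
double-median-degree rule ("a hub's degree exceeds twice the median
degree", strict per *exceeds*) is exposed both on its own and as an
optional degree prefilter (`degree_prefilter_multiplier = 2`), because
the two rules' composition is genuinely open: sources quote both without
stating an order. Both orderings are selectable and the criteria used are
always written alongside the candidate list.

## Enrichment and kappa grouping

Each term is tested by the right-tail hypergeometric probability
`P[X ≥ k]` of drawing `k` term members in `n` candidates from a
universe of `N` genes — enrichment only, since depleted terms are not of
interest here. The default universe is all genes in the annotation
collection, substitutable by the core network's node set; the choice is
exposed because published analyses rarely state their background.
Correction defaults to Benjamini–Hochberg with Holm (step-down
Bonferroni) selectable; significance is `p_adj ≤ alpha` (default 0.05).

Significant terms are grouped by single-linkage clustering on pairwise
Cohen's kappa of their membership indicators over the universe, at the
threshold 0.4 — the documented default of the functional-grouping tools
this reproduces. Each group is represented by its lowest-p member. In the
degenerate kappa case (expected agreement 1), kappa is defined as 1 for
identical sets and 0 otherwise.

# The synthetic study

`synth_config()` describes a complete synthetic study; its defaults are
the package's reference conditions:

- **Formula side**: 16 herbs, 200 compounds in many-to-many herb
  membership, 15 % planted to pass all five ADME criteria, 10 whitelist
  rescues. Passing values are drawn uniformly from
  `[threshold, threshold + span]`; each failing compound violates exactly
  one parameter by default, with the violated parameter cycling through
  all five so that every criterion is some record's sole failure — this
  guarantees boundary coverage for the screen's tests.
- **Interactome**: 400 nodes under preferential attachment (3 edges per
  step), giving the heavy-tailed degree profile real interactomes show —
  hub screening is only meaningful on a skewed degree distribution. An
  Erdős–Rényi background is available for null experiments.
- **Planted module**: 40 nodes whose induced density is raised to 0.9 —
  a deliberately strong disease module against a sparse background, sized
  so that the intersected core network (typically 100–200 nodes) contains
  the module plus a comparable amount of background.
- **Disease genes**: 40, of which 60 % are placed inside the module.
- **Targets**: 60 distinct interactome nodes, every one mapped to at
  least one active compound (so the target-union count is planted
  exactly).
- **Annotations**: 50 terms of 10–40 genes; one planted term samples its
  members with 20-fold odds for module genes, i.e. roughly two-thirds of
  its members come from the module — emulating a pathway that
  characterizes the module rather than one merely tilted toward it.

Gene and compound identifiers are synthetic (`G000001`, `CPD00001`,
`TERM001`) to avoid implying real accessions. A fixed seed makes every
generated file byte-identical across runs; all randomness flows from the
single config seed.

The generator also has a **reference-scale** mode,
`gen_reference_study()`, which plants the tabulated marginal counts of a
published 16-herb study — 1005 compounds with 63 ADME passes and 31
rescues (94 active), a 287-target union, 1846 distinct compound–target
associations, and a 354-gene disease list sharing exactly 41 symbols with
the targets — so the screening and network stages can be exercised at
full scale. These tables are synthetic stand-ins: the planted counts are
recovered by running the pipeline, not asserted from constants, but the
compound chemistry and identifiers are generated.

## What the generator does not emulate

Real TCMSP-style chemistry and the empirical distributions of ADME
predictors; literature-curated interactome structure beyond a heavy
degree tail (no date/bait biases, no confidence scores); correlated,
hierarchical annotation terms (terms here are independent draws); gene
identifier aliasing. Consequently, passing the planted-truth tests shows
that the pipeline's logic is correct and its statistics behave as
designed — it does not show that any particular biological conclusion
drawn from real databases is right.

# Test and verification scales

The test suite validates the centrality implementations against
brute-force oracles on 200 random graphs of up to 12 nodes, the
hypergeometric tail against exact big-integer rational arithmetic over
all valid count tuples with universes up to 60 genes, and planted-truth
recovery end to end: the ADME pass-count must be recovered exactly, the
planted term must rank first by p value, and the hub survivors' Jaccard
overlap with the planted module, averaged over 20 seeds, must reach 0.6.
These sizes keep the full suite within a few tens of seconds while
exercising every code path; the pipeline itself has no size-dependent
logic.

# Known limitations

- Symbol matching is exact after case-folding; no alias tables.
- The interactome is unweighted and undirected; interaction type and
  direction fields in SIF files are parsed but ignored.
- Betweenness-based screening on graphs much larger than a few thousand
  nodes will be slow in this pure-R/igraph implementation; the intended
  scale is the few-hundred-node core networks the generator produces.
- The kappa grouping is single-linkage and therefore can chain; the
  threshold is exposed precisely because chaining behavior depends on it.

# A minimal run

```{r example, eval = FALSE}
dir <- tempfile("study_")
inputs <- write_synthetic_inputs(synth_config(seed = 1), dir)
report <- run_pipeline(pipeline_config(input_dir = dir, seed = 1))
str(report$counts)
```
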