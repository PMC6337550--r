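## PPI assembly: expand seed gene sets over a background interactome and
## merge the resulting drug-side and disease-side networks into a core
## protein-protein-interaction (core PPI) network.

#' Seed-expand a PPI network from an interactome
#'
#' Takes the subgraph induced on the seeds plus every node within graph
#' distance `depth` of any seed. `depth = 0` is the induced subgraph on the
#' seeds themselves; the default `depth = 1` adds direct interactors, the
#' behavior interactome plugins typically use. Edges among added neighbors
#' are included (induced-subgraph semantics).
#'
#' @param interactome Background igraph network with named vertices.
#' @param seeds Character vector of seed gene symbols; seeds missing from
#'   the interactome are reported and skipped.
#' @param depth Expansion radius, 0, 1 or 2.
#' @return An igraph network.
#' @export
expand_seeds <- function(interactome, seeds, depth = 1) {
  stopifnot(depth %in% 0:2)
  seeds <- unique(trimws(as.character(seeds)))
  seeds <- seeds[nzchar(seeds)]
  if (length(seeds) == 0) {
    warning("empty seed set: returning empty network")
    return(make_network(character(0), provenance = "seed expansion (empty)"))
  }
  present <- intersect(seeds, igraph::V(interactome)$name)
  absent <- setdiff(seeds, present)
  if (length(absent) > 0)
    message(length(absent), " of ", length(seeds),
            " seeds absent from the interactome")
  if (length(present) == 0) {
    warning("no seeds present in the interactome: returning empty network")
    return(make_network(character(0), provenance = "seed expansion (empty)"))
  }
  nodes <- unique(unlist(lapply(
    igraph::ego(interactome, order = depth, nodes = present), names)))
  g <- igraph::induced_subgraph(interactome, nodes)
  g$provenance <- sprintf("seed expansion (%d seeds, depth %d)",
                          length(present), depth)
  g
}

#' Merge two PPI networks
#'
#' `intersection` (the default) keeps the nodes and edges present in both
#' inputs — the "core" network, necessarily no larger than either input —
#' and by default drops nodes left without edges. `union` combines both.
#'
#' @param a,b igraph networks with named vertices.
#' @param mode `"intersection"` or `"union"`.
#' @param drop_isolated Drop degree-0 nodes after an intersection merge.
#' @return The merged igraph network.
#' @export
merge_networks <- function(a, b, mode = c("intersection", "union"),
                           drop_isolated = TRUE) {
  mode <- match.arg(mode)
  stopifnot(igraph::is_simple(a), igraph::is_simple(b))
  ea <- edge_keys(a); eb <- edge_keys(b)
  if (mode == "intersection") {
    nodes <- intersect(igraph::V(a)$name, igraph::V(b)$name)
    keys <- intersect(ea, eb)
    edges <- if (length(keys) > 0)
      do.call(rbind, strsplit(keys, "|", fixed = TRUE)) else NULL
    g <- make_network(nodes, edges, provenance = "merge: intersection")
    if (drop_isolated && igraph::vcount(g) > 0)
      g <- igraph::delete_vertices(g, igraph::V(g)[igraph::degree(g) == 0])
  } else {
    nodes <- union(igraph::V(a)$name, igraph::V(b)$name)
    keys <- union(ea, eb)
    edges <- if (length(keys) > 0)
      do.call(rbind, strsplit(keys, "|", fixed = TRUE)) else NULL
    g <- make_network(nodes, edges, provenance = "merge: union")
  }
  g
}
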