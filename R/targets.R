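## Compound-target mapping: load and filter precomputed compound->target
## association tables, summarize targets per herb, intersect the formula's
## target union with a disease gene list, and build the compound-target
## bipartite network.

#' Load a compound-target association table
#'
#' Expected TSV columns: `compound_id`, `target_symbol`, `herb`, `source`
#' (one of model/sea/tcmsp/synthetic; `svm`/`rf` mark model predictions
#' scored by support-vector machine or random forest), optional `score`.
#' Duplicate (compound, target, herb) triples are collapsed. When score
#' floors are supplied, model rows are kept only if their score strictly
#' exceeds the floor for their method; unscored sources pass unfiltered.
#'
#' @param path Path to the TSV.
#' @param svm_min Optional strict score floor for `source == "svm"` rows.
#' @param rf_min Optional strict score floor for `source == "rf"` rows.
#' @return A `target_map` data frame.
#' @export
load_target_map <- function(path, svm_min = NULL, rf_min = NULL) {
  if (!file.exists(path)) stop("target map not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nzchar(lines) & nf < 3)
  if (length(bad) > 0)
    stop("malformed target-map line ", bad[1], " in ", path,
         ": fewer than 3 tab-separated fields")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  target_map(df, svm_min = svm_min, rf_min = rf_min)
}

#' Construct a target map from a data frame
#'
#' @param df Data frame with at least `compound_id`, `target_symbol`, `herb`.
#' @inheritParams load_target_map
#' @return A `target_map` data frame (deduplicated, symbols normalized).
#' @export
target_map <- function(df, svm_min = NULL, rf_min = NULL) {
  need <- c("compound_id", "target_symbol", "herb")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("target map lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df) == 0) {
    warning("empty target map")
  } else {
    if (any(!nzchar(trimws(df$target_symbol))))
      stop("target map contains empty target symbols")
    df$target_symbol <- toupper(trimws(df$target_symbol))
  }
  if (!"source" %in% names(df)) df$source <- "synthetic"
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!is.null(svm_min))
    df <- df[df$source != "svm" | (!is.na(df$score) & df$score > svm_min), ,
             drop = FALSE]
  if (!is.null(rf_min))
    df <- df[df$source != "rf" | (!is.na(df$score) & df$score > rf_min), ,
             drop = FALSE]
  df <- df[!duplicated(df[, need]), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("target_map", "data.frame")
  df
}

#' Per-herb target sets and their union
#'
#' Restricts the map to active compounds (when given), splits targets by
#' contributing herb, and reports the union across herbs. Because herbs
#' share compounds and compounds share targets, per-herb sizes generally
#' sum to more than the union.
#'
#' @param map A `target_map`.
#' @param active Optional `active_set` (or character vector of compound
#'   ids) restricting the map.
#' @return List with `per_herb` (named list of target vectors), `sizes`,
#'   `union`, `n_union`, and `shared` (targets contributed by >1 herb).
#' @export
per_herb_targets <- function(map, active = NULL) {
  if (!is.null(active)) {
    ids <- if (inherits(active, "active_set")) active_ids(active)
           else as.character(active)
    map <- map[map$compound_id %in% ids, , drop = FALSE]
  }
  per_herb <- lapply(split(map$target_symbol, map$herb), unique)
  per_herb <- lapply(per_herb, sort)
  u <- sort(unique(map$target_symbol))
  counts <- table(unlist(lapply(per_herb, unique)))
  list(per_herb = per_herb,
       sizes = vapply(per_herb, length, integer(1)),
       union = u, n_union = length(u),
       shared = sort(names(counts)[counts > 1]))
}

#' Intersect formula targets with a disease gene list
#'
#' Symbols on both sides are upper-cased and trimmed before the exact set
#' intersection.
#'
#' @param formula_targets Character vector of the formula's targets.
#' @param disease_genes Character vector of disease-related genes.
#' @return Sorted character vector of shared targets.
#' @export
intersect_disease <- function(formula_targets, disease_genes) {
  sort(intersect(normalize_symbols(formula_targets),
                 normalize_symbols(disease_genes)))
}

#' Build the compound-target bipartite network
#'
#' Nodes are active compounds with at least one mapped target plus their
#' targets; edges are distinct (compound, target) pairs, collapsed across
#' herbs (herb provenance is a property of the map, not of the edge set).
#'
#' @param active An `active_set` or character vector of active compound ids.
#' @param map A `target_map`.
#' @param include_isolated_compounds Keep active compounds without targets
#'   as isolated nodes (default `FALSE`).
#' @return An igraph bipartite graph; vertex attribute `kind` is
#'   `"compound"` or `"target"`, logical `type` follows igraph's bipartite
#'   convention (`TRUE` for targets).
#' @export
build_ct_network <- function(active, map, include_isolated_compounds = FALSE) {
  ids <- if (inherits(active, "active_set")) active_ids(active)
         else as.character(active)
  sub <- map[map$compound_id %in% ids, c("compound_id", "target_symbol"),
             drop = FALSE]
  sub <- sub[!duplicated(sub), , drop = FALSE]
  compounds <- if (include_isolated_compounds) ids
               else sort(unique(sub$compound_id))
  targets <- sort(unique(sub$target_symbol))
  clash <- intersect(compounds, targets)
  if (length(clash) > 0)
    stop("identifier used as both compound and target: ", clash[1])
  g <- make_network(c(compounds, targets),
                    cbind(sub$compound_id, sub$target_symbol),
                    provenance = "compound-target network")
  kind <- ifelse(igraph::V(g)$name %in% targets, "target", "compound")
  g <- igraph::set_vertex_attr(g, "kind", value = kind)
  igraph::set_vertex_attr(g, "type", value = kind == "target")
}
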