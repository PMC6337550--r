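## Readers and writers for the plain-text formats the pipeline exchanges:
## SIF edge lists, GraphML, one-symbol-per-line gene lists, GMT gene-set
## collections, and the TSV tables for compounds and compound-target maps.
## Graphs are igraph objects with a `name` vertex attribute throughout.

#' Canonical undirected edge keys of a network
#'
#' Each edge is encoded as `"A|B"` with the two endpoint names sorted, so
#' edge sets of different graphs can be compared with plain set operations.
#'
#' @param g An igraph object with named vertices.
#' @return Character vector, one key per edge.
#' @export
edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g, names = TRUE)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
}

#' Build an undirected simple network from node and edge sets
#'
#' @param nodes Character vector of node names (may be empty).
#' @param edges Two-column character matrix or data frame of endpoints;
#'   self-loops and duplicate edges are removed.
#' @param provenance Free-text provenance stored as a graph attribute.
#' @return An igraph object.
#' @export
make_network <- function(nodes, edges = NULL, provenance = "") {
  nodes <- unique(as.character(nodes))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (!is.null(edges) && NROW(edges) > 0) {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    missing <- setdiff(unique(c(em)), nodes)
    if (length(missing) > 0)
      g <- igraph::add_vertices(g, length(missing), name = missing)
    g <- igraph::add_edges(g, t(em))
    g <- igraph::simplify(g)
  }
  g$provenance <- provenance
  g
}

#' Read a network from a SIF file
#'
#' Dialect: whitespace-separated `node relation node` (one interaction per
#' line); the relation token is preserved in no way beyond parsing — edges
#' are undirected and untyped. Lines with a single token declare isolated
#' nodes, as Cytoscape's SIF allows.
#'
#' @param path Path to the SIF file.
#' @return An igraph object.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop("SIF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nt <- lengths(toks)
  bad <- which(nt == 2)
  if (length(bad) > 0)
    stop("malformed SIF line ", bad[1], " in ", path,
         ": expected 1 or >=3 whitespace-separated fields")
  singles <- unlist(lapply(toks[nt == 1], `[`, 1))
  edges <- do.call(rbind, lapply(toks[nt >= 3], function(x) {
    cbind(x[1], x[seq(3, length(x))])
  }))
  nodes <- unique(c(singles, if (!is.null(edges)) c(edges)))
  make_network(nodes, edges, provenance = path)
}

#' Write a network as SIF
#'
#' Edges are written as `A pp B`; isolated nodes as bare names.
#'
#' @param g igraph object with named vertices.
#' @param path Output path.
#' @param relation Relation token (default `"pp"`, protein-protein).
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path, relation = "pp") {
  el <- igraph::as_edgelist(g, names = TRUE)
  lines <- character(0)
  if (nrow(el) > 0) lines <- paste(el[, 1], relation, el[, 2], sep = "\t")
  iso <- setdiff(igraph::V(g)$name,
                 if (nrow(el) > 0) unique(c(el)) else character(0))
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Read a network from GraphML
#'
#' Directed GraphML is read as undirected with a warning; multi-edges and
#' self-loops are simplified away.
#'
#' @param path Path to a GraphML file.
#' @return An igraph object.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) stop("GraphML file not found: ", path)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::is_directed(g)) {
    warning("directed GraphML read as undirected: ", path)
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  igraph::simplify(g)
}

#' Write a network as GraphML
#' @param g igraph object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a gene list (one symbol per line)
#'
#' Symbols are upper-cased and whitespace-trimmed; blanks and duplicates
#' dropped.
#'
#' @param path Path to the list.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  normalize_symbols(readLines(path, warn = FALSE))
}

#' @rdname read_gene_list
#' @param genes Character vector to write.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

## shared symbol normalization: upper-case, trimmed, deduplicated
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  unique(x[nzchar(x)])
}

#' Read a GMT gene-set collection
#'
#' Standard GMT semantics (term, description, tab-separated members). Lines
#' with fewer than three fields are an error. The default universe is the
#' union of all members; pass `universe` to substitute e.g. a network's
#' node set.
#'
#' @param path Path to a .gmt file.
#' @param universe Optional background gene universe.
#' @return A `gene_set_collection`: list with `terms` (named list of member
#'   vectors), `descriptions` (named character) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nzchar(trimws(lines)) & nf < 3)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1], " in ", path, ": fewer than 3 fields")
  terms <- fgsea::gmtPathways(path)
  desc <- vapply(strsplit(lines[nzchar(trimws(lines))], "\t", fixed = TRUE),
                 `[`, character(1), 2)
  names(desc) <- names(terms)
  gene_set_collection(terms, descriptions = desc, universe = universe)
}

#' Construct a gene-set collection
#'
#' @param terms Named list of member gene vectors.
#' @param descriptions Optional named character vector of term descriptions.
#' @param universe Optional background universe; defaults to the union of
#'   all members.
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(terms, descriptions = NULL, universe = NULL) {
  stopifnot(is.list(terms), !is.null(names(terms)))
  if (anyDuplicated(names(terms)))
    stop("duplicate term ids in gene-set collection")
  terms <- lapply(terms, normalize_symbols)
  if (is.null(universe)) universe <- unique(unlist(terms, use.names = FALSE))
  else universe <- normalize_symbols(universe)
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(terms)), names(terms))
  structure(list(terms = terms,
                 descriptions = descriptions[names(terms)],
                 universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x$terms), "terms,",
      length(x$universe), "universe genes\n")
  invisible(x)
}

#' Write a gene-set collection as GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(id) {
    paste(c(id, collection$descriptions[[id]] %||% "",
            collection$terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a compound table
#'
#' Expected TSV columns: `compound_id`, `name`, `herbs` (semicolon-separated),
#' `ob`, `dl`, `caco2`, `bbb`, `hl`, `whitelisted` (0/1).
#'
#' @param path Path to compounds.tsv.
#' @return Data frame with one row per compound.
#' @export
read_compounds <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("compound_id", "name", "herbs", "ob", "dl", "caco2", "bbb", "hl")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("compound table ", path, " lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$compound_id))
    stop("duplicate compound_id in ", path)
  if (!"whitelisted" %in% names(df)) df$whitelisted <- 0L
  df
}

#' @rdname read_compounds
#' @param compounds Compound data frame to write.
#' @export
write_compounds <- function(compounds, path) {
  utils::write.table(compounds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
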