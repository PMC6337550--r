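## Six topological features for hub screening, with the conventions of the
## CytoNCA centrality toolbox frozen:
##
##   DC   degree centrality: incident edge count.
##   BC   betweenness, undirected and unnormalized: for node v, the sum over
##        unordered pairs {s,t} (v excluded) of the fraction of shortest
##        s-t paths through v.
##   CC   closeness with the Wasserman-Faust component correction:
##        cc(v) = (r/(n-1)) * (r / sum of distances to reachable nodes),
##        r = number of nodes reachable from v (v excluded); isolated -> 0.
##        On a connected graph this reduces to (n-1)/sum(d).
##   EC   eigenvector centrality: principal adjacency eigenvector,
##        nonnegative, Euclidean norm 1.
##   NC   network centrality: sum over incident edges of the edge clustering
##        coefficient ecc(v,u) = z(v,u)/min(deg v - 1, deg u - 1), z = number
##        of triangles on the edge; ecc = 0 when the denominator is 0.
##   LAC  local average connectivity: mean degree of v's neighbors within
##        the subgraph induced by the neighborhood; isolated -> 0.
##
## Normalized betweenness and harmonic closeness are deliberately NOT used:
## the median thresholds of the hub screen are defined on these scales.

#' Degree centrality
#' @param g igraph network (simple, undirected).
#' @return Named numeric vector over nodes.
#' @export
centrality_degree <- function(g) {
  d <- igraph::degree(g, loops = FALSE)
  setNames(as.numeric(d), igraph::V(g)$name)
}

#' Betweenness centrality (undirected, unnormalized)
#' @inheritParams centrality_degree
#' @return Named numeric vector over nodes.
#' @export
centrality_betweenness <- function(g) {
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  setNames(as.numeric(b), igraph::V(g)$name)
}

#' Closeness centrality with component correction
#'
#' Wasserman-Faust form: the reciprocal mean distance to reachable nodes,
#' down-weighted by the reachable fraction `r/(n-1)`, so values on
#' disconnected graphs remain comparable across components.
#'
#' @inheritParams centrality_degree
#' @return Named numeric vector in `[0, 1]`.
#' @export
centrality_closeness <- function(g) {
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n == 0) return(setNames(numeric(0), character(0)))
  if (n == 1) return(setNames(0, nm))
  D <- igraph::distances(g)
  cc <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, numeric(1))
  setNames(cc, nm)
}

#' Eigenvector centrality by power iteration
#'
#' Returns the principal eigenvector of the adjacency matrix, nonnegative
#' and scaled to Euclidean norm 1. Iteration runs on the shifted operator
#' A + I from an all-ones start vector; the shift leaves the eigenvector
#' unchanged while preventing the sign oscillation bipartite graphs induce
#' in plain power iteration. On disconnected graphs the mass concentrates
#' on the component with the largest leading eigenvalue.
#'
#' @inheritParams centrality_degree
#' @param tol Convergence tolerance on the max-norm change per iteration.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   iteration count.
#' @return Named numeric vector, unit Euclidean norm.
#' @export
centrality_eigenvector <- function(g, tol = 1e-10, max_iter = 1000) {
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0)
    stop("eigenvector centrality undefined: network has no edges")
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  x <- rep(1 / sqrt(n), n)
  for (iter in seq_len(max_iter)) {
    y <- as.numeric(A %*% x) + x       # (A + I) x
    nrm <- sqrt(sum(y * y))
    if (nrm == 0) stop("power iteration collapsed to the zero vector")
    y <- y / nrm
    if (max(abs(y - x)) < tol) {
      y[abs(y) < tol] <- 0
      return(setNames(y, igraph::V(g)$name))
    }
    x <- y
  }
  stop("eigenvector centrality did not converge after ", max_iter,
       " iterations (tol ", format(tol), ")")
}

## integer neighbor lists, 1-based, self excluded
neighbor_list <- function(g) {
  lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
}

#' Network centrality (sum of edge clustering coefficients)
#'
#' For each incident edge (v,u), the edge clustering coefficient is the
#' triangle count on the edge divided by `min(deg(v), deg(u)) - 1`, taken
#' as 0 when that denominator is 0 (a degree-1 endpoint cannot close a
#' triangle). NC(v) is the sum over v's incident edges.
#'
#' @inheritParams centrality_degree
#' @return Named numeric vector over nodes.
#' @export
centrality_network <- function(g) {
  nb <- neighbor_list(g)
  deg <- lengths(nb)
  n <- igraph::vcount(g)
  nc <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] == 0) next
    for (u in nb[[v]]) {
      den <- min(deg[v], deg[u]) - 1
      if (den <= 0) next
      z <- length(intersect(nb[[v]], nb[[u]]))
      nc[v] <- nc[v] + z / den
    }
  }
  setNames(nc, igraph::V(g)$name)
}

#' Local average connectivity
#'
#' Mean, over v's neighbors, of each neighbor's degree within the subgraph
#' induced by v's neighborhood; 0 for isolated nodes.
#'
#' @inheritParams centrality_degree
#' @return Named numeric vector over nodes.
#' @export
centrality_lac <- function(g) {
  nb <- neighbor_list(g)
  n <- igraph::vcount(g)
  lac <- numeric(n)
  for (v in seq_len(n)) {
    k <- length(nb[[v]])
    if (k == 0) next
    # twice the edge count inside the neighborhood = sum of within-degrees
    within <- sum(vapply(nb[[v]], function(u)
      length(intersect(nb[[u]], nb[[v]])), integer(1)))
    lac[v] <- within / k
  }
  setNames(lac, igraph::V(g)$name)
}

#' Compute all six topological features
#'
#' @inheritParams centrality_degree
#' @param ec_tol,ec_max_iter Passed to [centrality_eigenvector()].
#' @return A `centrality_table` data frame with columns `node`, `dc`, `bc`,
#'   `cc`, `ec`, `nc`, `lac`, rows ordered by node name. If the eigenvector
#'   is undefined (edgeless network) the `ec` column is all zero and the
#'   attribute `ec_degenerate` is set.
#' @export
centrality_table <- function(g, ec_tol = 1e-10, ec_max_iter = 1000) {
  if (igraph::vcount(g) == 0) stop("empty network")
  ec_degenerate <- FALSE
  ec <- tryCatch(
    centrality_eigenvector(g, tol = ec_tol, max_iter = ec_max_iter),
    error = function(e) {
      if (igraph::ecount(g) > 0) stop(e)
      ec_degenerate <<- TRUE
      setNames(numeric(igraph::vcount(g)), igraph::V(g)$name)
    })
  tab <- data.frame(node = igraph::V(g)$name,
                    dc = centrality_degree(g),
                    bc = centrality_betweenness(g),
                    cc = centrality_closeness(g),
                    ec = ec,
                    nc = centrality_network(g),
                    lac = centrality_lac(g),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "ec_degenerate") <- ec_degenerate
  class(tab) <- c("centrality_table", "data.frame")
  tab
}
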