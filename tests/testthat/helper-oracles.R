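# Brute-force, base-R oracles for the six topological features, written
# against adjacency matrices and deliberately independent of the package's
# igraph-based code paths. Intended for graphs of ~12 nodes or fewer.

# adjacency matrix of a named igraph (node order = vertex order)
adj_of <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g))
}

graph_of <- function(A, names = NULL) {
  n <- nrow(A)
  if (is.null(names)) names <- sprintf("n%02d", seq_len(n))
  edges <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  herbnet::make_network(names, cbind(names[edges[, 1]], names[edges[, 2]]))
}

# BFS distances and shortest-path counts from every source
oracle_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)   # number of shortest paths
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sig <- rep(0, n); sig[s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(A[v, ] > 0)) {
          if (is.infinite(d[u])) {
            d[u] <- d[v] + 1
            nxt <- c(nxt, u)
          }
          if (d[u] == d[v] + 1) sig[u] <- sig[u] + sig[v]
        }
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- d
    S[s, ] <- sig
  }
  list(D = D, S = S)
}

oracle_betweenness <- function(A) {
  n <- nrow(A)
  ps <- oracle_paths(A)
  D <- ps$D; S <- ps$S
  bc <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq(s + 1, n)) {
        if (s == v || t == v || is.infinite(D[s, t])) next
        if (D[s, v] + D[v, t] == D[s, t] && S[s, t] > 0)
          bc[v] <- bc[v] + S[s, v] * S[v, t] / S[s, t]
      }
    }
  }
  bc
}

oracle_closeness <- function(A) {
  n <- nrow(A)
  D <- oracle_paths(A)$D
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]; d <- d[is.finite(d)]
    r <- length(d)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(d))
  }, numeric(1))
}

# dense symmetric eigen-solve; returns leading eigenvalues/vectors so the
# caller can handle a degenerate leading eigenspace
oracle_eigen <- function(A) {
  e <- eigen(A, symmetric = TRUE)
  list(values = e$values, vectors = e$vectors)
}

oracle_nc <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  nc <- numeric(n)
  for (v in seq_len(n)) {
    for (u in which(A[v, ] > 0)) {
      den <- min(deg[v], deg[u]) - 1
      if (den <= 0) next
      z <- sum(A[v, ] * A[u, ])   # common neighbors = triangles on edge
      nc[v] <- nc[v] + z / den
    }
  }
  nc
}

oracle_lac <- function(A) {
  n <- nrow(A)
  lac <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) next
    lac[v] <- sum(A[nb, nb]) / length(nb)
  }
  lac
}

rand_adj <- function(n, p) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(runif(sum(up)) < p)
  A + t(A)
}

# check the implementation's six features against all oracles on one graph
expect_matches_oracles <- function(A, tol = 1e-8) {
  g <- graph_of(A)
  tab <- herbnet::centrality_table(g, ec_max_iter = 50000)
  ord <- match(igraph::V(g)$name, tab$node)
  tab <- tab[ord, ]
  expect_equal(tab$dc, rowSums(A), tolerance = tol, ignore_attr = TRUE)
  expect_equal(tab$bc, oracle_betweenness(A), tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(tab$cc, oracle_closeness(A), tolerance = tol,
               ignore_attr = TRUE)
  expect_equal(tab$nc, oracle_nc(A), tolerance = tol, ignore_attr = TRUE)
  expect_equal(tab$lac, oracle_lac(A), tolerance = tol, ignore_attr = TRUE)
  if (sum(A) > 0) {
    e <- oracle_eigen(A)
    lam <- e$values[1]
    gap <- if (length(e$values) > 1) lam - e$values[2] else Inf
    v <- tab$ec
    expect_equal(sqrt(sum(v^2)), 1, tolerance = tol)
    expect_true(all(v >= -tol))
    if (gap > 1e-6) {
      ref <- e$vectors[, 1]
      if (sum(ref) < 0) ref <- -ref
      expect_equal(v, ref, tolerance = tol, ignore_attr = TRUE)
    } else {
      # degenerate leading eigenspace: the eigenvector is not unique, so
      # require the implementation's vector to satisfy A v = lambda v
      expect_lt(max(abs(A %*% v - lam * v)), 1e-6)
    }
  }
}
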