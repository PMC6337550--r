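k4 <- make_network(letters[1:4], t(combn(letters[1:4], 2)))
path3 <- make_network(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
star4 <- make_network(c("c0", paste0("l", 1:4)),
                      cbind("c0", paste0("l", 1:4)))
tri <- make_network(c("x", "y", "z"),
                    rbind(c("x", "y"), c("y", "z"), c("z", "x")))

cvec <- function(v, g) v[igraph::V(g)$name]

test_that("degree matches hand values on canonical graphs", {
  expect_equal(unname(centrality_degree(k4)), rep(3, 4))
  expect_equal(cvec(centrality_degree(star4), star4),
               c(c0 = 4, l1 = 1, l2 = 1, l3 = 1, l4 = 1))
  edgeless <- make_network(letters[1:3])
  expect_equal(unname(centrality_degree(edgeless)), rep(0, 3))
})

test_that("betweenness follows the unnormalized undirected convention", {
  bc <- centrality_betweenness(path3)
  expect_equal(unname(bc[c("a", "b", "c")]), c(0, 1, 0))
  # all C(4,2) leaf pairs route through the star center
  expect_equal(unname(centrality_betweenness(star4)["c0"]), 6)
  expect_equal(unname(centrality_betweenness(k4)), rep(0, 4))
})

test_that("closeness uses the component-corrected form", {
  cc <- centrality_closeness(path3)
  expect_equal(unname(cc[c("a", "b", "c")]), c(2 / 3, 1, 2 / 3))
  expect_equal(unname(centrality_closeness(k4)), rep(1, 4))
  # two disconnected edges: reachable fraction 1/3, mean distance 1
  two_edges <- make_network(letters[1:4],
                            rbind(c("a", "b"), c("c", "d")))
  expect_equal(unname(centrality_closeness(two_edges)), rep(1 / 3, 4))
  lone <- make_network("a")
  expect_equal(unname(centrality_closeness(lone)), 0)
})

test_that("eigenvector centrality gives closed-form values on symmetric graphs", {
  # vertex-transitive graphs: all entries 1/sqrt(n)
  expect_equal(unname(centrality_eigenvector(k4)), rep(0.5, 4),
               tolerance = 1e-8)
  cyc5 <- make_network(paste0("v", 1:5),
                       cbind(paste0("v", 1:5), paste0("v", c(2:5, 1))))
  expect_equal(unname(centrality_eigenvector(cyc5)), rep(1 / sqrt(5), 5),
               tolerance = 1e-8)
  ec <- centrality_eigenvector(star4)
  expect_equal(unname(ec["c0"]), 1 / sqrt(2), tolerance = 1e-8)
  expect_equal(unname(ec[paste0("l", 1:4)]), rep(1 / (2 * sqrt(2)), 4),
               tolerance = 1e-8)
  expect_error(centrality_eigenvector(make_network(letters[1:3])),
               "no edges")
  # K4's all-ones start is already exact, so use an asymmetric graph
  expect_error(centrality_eigenvector(path3, max_iter = 1),
               "did not converge")
})

test_that("network centrality sums edge clustering coefficients", {
  expect_equal(unname(centrality_network(tri)), rep(2, 3))
  expect_equal(unname(centrality_network(star4)), rep(0, 5))
  expect_equal(unname(centrality_network(k4)), rep(3, 4))
})

test_that("local average connectivity averages within-neighborhood degree", {
  expect_equal(unname(centrality_lac(tri)), rep(1, 3))
  expect_equal(unname(centrality_lac(star4))[1], 0)
  expect_equal(unname(centrality_lac(k4)), rep(2, 4))
})

test_that("the K4 feature vector is (3, 0, 1, 0.5, 3, 2) for every node", {
  tab <- centrality_table(k4)
  for (f in c("dc", "bc", "cc", "ec", "nc", "lac")) {
    expected <- c(dc = 3, bc = 0, cc = 1, ec = 0.5, nc = 3, lac = 2)[[f]]
    expect_equal(tab[[f]], rep(expected, 4), tolerance = 1e-8,
                 label = paste("feature", f))
  }
})

test_that("a single isolated node yields the all-zero row with a flag", {
  tab <- centrality_table(make_network("solo"))
  expect_equal(unlist(tab[1, -1]), c(dc = 0, bc = 0, cc = 0, ec = 0,
                                     nc = 0, lac = 0))
  expect_true(attr(tab, "ec_degenerate"))
  expect_error(centrality_table(make_network(character(0))), "empty")
})

test_that("all six features match brute-force oracles on random graphs", {
  set.seed(2024)
  for (i in 1:40) {
    A <- rand_adj(sample(2:12, 1), runif(1, 0.1, 0.9))
    expect_matches_oracles(A)
  }
})

test_that("features are invariant under node relabeling", {
  set.seed(99)
  A <- rand_adj(10, 0.4)
  g <- graph_of(A)
  perm <- sample(10)
  g2 <- graph_of(A[perm, perm], names = igraph::V(g)$name[perm])
  t1 <- centrality_table(g, ec_max_iter = 50000)
  t2 <- centrality_table(g2, ec_max_iter = 50000)
  expect_equal(t1[order(t1$node), ], t2[order(t2$node), ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("tree betweenness totals sum over pairs of (path length - 1)", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    tree <- igraph::sample_tree(n)
    tree <- igraph::set_vertex_attr(tree, "name",
                                    value = sprintf("t%02d", 1:n))
    bc <- centrality_betweenness(tree)
    D <- igraph::distances(tree)
    expect_equal(sum(bc), sum(D[upper.tri(D)] - 1))
  }
})
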