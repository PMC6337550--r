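test_that("hypergeometric tail matches closed-form values", {
  # all 5 draws hit a 5-member term in a 20-gene universe: 1/C(20,5)
  expect_equal(hypergeom_p(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_p(0, 7, 3, 30), 1)
  expect_equal(hypergeom_p(1, 10, 1, 10), 1)  # term = universe
  expect_error(hypergeom_p(6, 5, 5, 20), "inconsistent")
  expect_error(hypergeom_p(1, 25, 5, 20), "inconsistent")
})

test_that("corrections reproduce Holm arithmetic and preserve order", {
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "bonferroni_step_down"),
               c(0.03, 0.04, 0.04))
  expect_equal(adjust_p(0.2), 0.2)
  expect_equal(adjust_p(rep(0.04, 5)), rep(0.04, 5))
  expect_equal(adjust_p(rep(0.04, 5), "bonferroni_step_down"), rep(0.2, 5))
  p <- c(0.001, 0.5, 0.02)
  expect_equal(order(adjust_p(p)), order(p))
  expect_error(adjust_p(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("kappa reproduces 2x2 contingency arithmetic", {
  u <- as.character(1:8)
  expect_equal(kappa_agreement(c("1", "2"), c("1", "2"), u), 1)
  # half-overlap: p_o = p_e = 1/2 -> kappa 0
  expect_equal(kappa_agreement(as.character(1:4), as.character(3:6), u), 0)
  # complementary sets covering the universe -> -1
  expect_equal(kappa_agreement(as.character(1:4), as.character(5:8), u), -1)
  # symmetry
  a <- as.character(c(1, 2, 3)); b <- as.character(c(3, 7))
  expect_equal(kappa_agreement(a, b, u), kappa_agreement(b, a, u))
  # degenerate p_e = 1: identical full-universe sets vs a proper subset
  expect_equal(kappa_agreement(u, u, u), 1)
  expect_equal(kappa_agreement(u, u[1:4], u), 0)
  expect_error(kappa_agreement("a", "b", character(0)), "empty universe")
})

test_that("a planted term is recovered as the top significant hit", {
  cfg <- synth_config(seed = 21, interactome_nodes = 200,
                      planted_module_size = 30, n_terms = 30)
  g <- gen_interactome(cfg)
  col <- gen_annotations(cfg, g)
  res <- enrich_and_group(g$planted_module, col, alpha = 0.05)
  expect_equal(res$results$term_id[1], attr(col, "planted_term"))
  expect_true(res$results$significant[1])
  expect_equal(res$results$group_id[1], 1L)
})

test_that("disjoint significant terms form singleton groups; duplicates merge", {
  u <- sprintf("G%03d", 1:100)
  col <- gene_set_collection(
    list(A = u[1:10], A2 = u[1:10], B = u[51:60],
         bg1 = u[c(1:3, 20:40)], bg2 = u[c(55, 61:85)]),
    universe = u)
  cand <- u[c(1:10, 51:60)]
  res <- enrich_and_group(cand, col, alpha = 0.05, kappa_threshold = 0.4)
  sig <- res$results$term_id[res$results$significant]
  expect_true(all(c("A", "A2", "B") %in% sig))
  gid <- setNames(res$results$group_id, res$results$term_id)
  expect_equal(gid[["A"]], gid[["A2"]])   # kappa(A, A2) = 1
  expect_false(gid[["A"]] == gid[["B"]])  # disjoint, kappa ~ < 0.4
  reps <- vapply(res$groups, `[[`, character(1), "representative")
  expect_true(all(reps %in% sig))
  # each representative is its group's lowest-p member
  for (grp in res$groups) {
    ps <- res$results$p[match(grp$terms, res$results$term_id)]
    expect_equal(grp$representative, grp$terms[which.min(ps)])
  }
})

test_that("raising alpha never removes significant terms; raising kappa never merges groups", {
  cfg <- synth_config(seed = 22, interactome_nodes = 150,
                      planted_module_size = 25, n_terms = 20)
  g <- gen_interactome(cfg)
  col <- gen_annotations(cfg, g)
  cand <- g$planted_module
  r1 <- enrich_and_group(cand, col, alpha = 0.01)
  r2 <- enrich_and_group(cand, col, alpha = 0.10)
  sig1 <- r1$results$term_id[r1$results$significant]
  sig2 <- r2$results$term_id[r2$results$significant]
  expect_true(all(sig1 %in% sig2))
  rk1 <- enrich_and_group(cand, col, alpha = 0.10, kappa_threshold = 0.2)
  rk2 <- enrich_and_group(cand, col, alpha = 0.10, kappa_threshold = 0.6)
  expect_gte(length(rk2$groups), length(rk1$groups))
  # grouping is invariant to term input order
  colr <- gene_set_collection(rev(col$terms),
                              descriptions = col$descriptions,
                              universe = col$universe)
  rr <- enrich_and_group(cand, colr, alpha = 0.10, kappa_threshold = 0.2)
  part <- function(r) {
    s <- lapply(r$groups, function(g) sort(g$terms))
    s[order(vapply(s, `[`, character(1), 1))]
  }
  expect_equal(part(rr), part(rk1))
})

test_that("candidates outside the universe are an error; empty significance is a message", {
  u <- sprintf("G%03d", 1:50)
  col <- gene_set_collection(list(A = u[1:10]), universe = u)
  expect_error(enrich_and_group("ZZZ", col), "universe")
  expect_message(r <- enrich_and_group(u[30:40], col, alpha = 1e-12),
                 "no term significant")
  expect_length(r$groups, 0)
})
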