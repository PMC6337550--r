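test_that("config validation rejects bad fields by name", {
  expect_error(synth_config(pass_fraction = 1.2), "pass_fraction")
  expect_error(synth_config(n_compounds = -1), "n_compounds")
  expect_error(synth_config(planted_module_size = 50,
                            interactome_nodes = 40),
               "planted_module_size")
  expect_error(synth_config(planted_term_enrichment = 0.5),
               "planted_term_enrichment")
})

test_that("compound generator plants the exact ADME pass count", {
  cfg <- synth_config(seed = 1, n_compounds = 100, pass_fraction = 0.2,
                      n_whitelist = 5)
  tab <- gen_compound_table(cfg)
  expect_equal(sum(passes_adme(tab)), 20)
  expect_equal(sum(tab$whitelisted), 5)
  # whitelist rescues are drawn from the failing compounds only
  expect_true(all(!passes_adme(tab[tab$whitelisted == 1, ])))
  res <- screen_compounds(tab)
  expect_equal(res$n_passed, 20)
  expect_equal(res$n_active, 25)
})

test_that("each ADME parameter is the sole violator for some compound", {
  cfg <- synth_config(seed = 2, n_compounds = 60, pass_fraction = 0.2)
  tab <- gen_compound_table(cfg)
  fails <- tab[!passes_adme(tab), ]
  thr <- adme_thresholds()
  below <- cbind(ob = fails$ob < thr$ob_min, dl = fails$dl < thr$dl_min,
                 caco2 = fails$caco2 < thr$caco2_min,
                 bbb = fails$bbb < thr$bbb_min, hl = fails$hl < thr$hl_min)
  sole <- below[rowSums(below) == 1, , drop = FALSE]
  expect_setequal(colnames(sole)[colSums(sole) > 0],
                  c("ob", "dl", "caco2", "bbb", "hl"))
})

test_that("generators are deterministic in the seed and vary across seeds", {
  cfg <- synth_config(seed = 1, n_compounds = 50)
  expect_identical(gen_compound_table(cfg), gen_compound_table(cfg))
  cfg2 <- synth_config(seed = 2, n_compounds = 50)
  t1 <- gen_compound_table(cfg); t2 <- gen_compound_table(cfg2)
  expect_false(isTRUE(all.equal(t1[, c("ob", "dl", "caco2", "bbb", "hl")],
                                t2[, c("ob", "dl", "caco2", "bbb", "hl")])))
  g1 <- gen_interactome(cfg); g1b <- gen_interactome(cfg)
  expect_identical(edge_keys(g1), edge_keys(g1b))
  d1 <- gen_disease_genes(cfg, g1)
  expect_identical(d1, gen_disease_genes(cfg, g1))
})

test_that("synthetic input bundle is byte-identical across runs", {
  cfg <- synth_config(seed = 5, n_compounds = 40, interactome_nodes = 80,
                      planted_module_size = 15, n_targets = 20,
                      n_disease_genes = 15, n_terms = 10)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_inputs(cfg, d1)
  write_synthetic_inputs(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("interactome plants a module at the requested density", {
  cfg <- synth_config(seed = 3, interactome_nodes = 100,
                      planted_module_size = 20,
                      planted_module_density = 0.8)
  g <- gen_interactome(cfg)
  expect_true(igraph::is_simple(g))
  mod <- g$planted_module
  expect_length(mod, 20)
  sub <- igraph::induced_subgraph(g, mod)
  expect_gte(igraph::ecount(sub) / choose(20, 2), 0.8)
})

test_that("density 1 plants a complete subgraph (K20 has 190 edges)", {
  cfg <- synth_config(seed = 4, interactome_nodes = 100,
                      planted_module_size = 20, planted_module_density = 1)
  sub <- igraph::induced_subgraph(gen_interactome(cfg),
                                  gen_interactome(cfg)$planted_module)
  expect_equal(igraph::ecount(sub), choose(20, 2))
})

test_that("Erdos-Renyi with p = 0 and no planted module is edgeless", {
  cfg <- synth_config(seed = 1, interactome_model = "erdos_renyi", er_p = 0,
                      planted_module_size = 0, interactome_nodes = 30,
                      n_disease_genes = 10, disease_overlap = 0)
  g <- gen_interactome(cfg)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 30)
})

test_that("disease gene overlap with the module is planted exactly", {
  cfg <- synth_config(seed = 6, interactome_nodes = 100,
                      planted_module_size = 20, n_disease_genes = 10)
  g <- gen_interactome(cfg)
  full <- gen_disease_genes(synth_config(seed = 6, interactome_nodes = 100,
                                         planted_module_size = 20,
                                         n_disease_genes = 10,
                                         disease_overlap = 1), g)
  expect_length(intersect(full, g$planted_module), 10)
  none <- gen_disease_genes(synth_config(seed = 6, interactome_nodes = 100,
                                         planted_module_size = 20,
                                         n_disease_genes = 10,
                                         disease_overlap = 0), g)
  expect_length(intersect(none, g$planted_module), 0)
  expect_error(gen_disease_genes(
    synth_config(seed = 6, interactome_nodes = 100, planted_module_size = 5,
                 n_disease_genes = 10, disease_overlap = 1), g2 <-
      gen_interactome(synth_config(seed = 6, interactome_nodes = 100,
                                   planted_module_size = 5))),
    "disease_overlap")
})

test_that("target map covers all planted targets over active compounds", {
  cfg <- synth_config(seed = 7, n_compounds = 60, pass_fraction = 0.3,
                      n_whitelist = 4, n_targets = 25,
                      interactome_nodes = 100)
  tab <- gen_compound_table(cfg)
  g <- gen_interactome(cfg)
  map <- gen_target_map(cfg, tab, g)
  act <- screen_compounds(tab)
  ht <- per_herb_targets(map, act)
  expect_equal(ht$n_union, 25)
  expect_true(all(map$compound_id %in% active_ids(act)))
  expect_true(all(map$target_symbol %in% igraph::V(g)$name))
})

test_that("planted term has the smallest hypergeometric p for module genes", {
  cfg <- synth_config(seed = 8, interactome_nodes = 150,
                      planted_module_size = 30, n_terms = 25)
  g <- gen_interactome(cfg)
  col <- gen_annotations(cfg, g)
  expect_true(all(lengths(col$terms) >= 1))
  expect_true(all(unlist(col$terms) %in% col$universe))
  # exhaustive per-term p for the module as query set
  ps <- vapply(col$terms, function(m) {
    hypergeom_p(length(intersect(m, g$planted_module)), length(m),
                length(g$planted_module), length(col$universe))
  }, numeric(1))
  expect_equal(names(which.min(ps)), attr(col, "planted_term"))
})

test_that("enrichment multiplier 1 builds the planted term like any other", {
  cfg <- synth_config(seed = 9, interactome_nodes = 150,
                      planted_module_size = 30, n_terms = 25,
                      planted_term_enrichment = 1)
  g <- gen_interactome(cfg)
  col <- gen_annotations(cfg, g)
  frac <- vapply(col$terms, function(m)
    mean(m %in% g$planted_module), numeric(1))
  pl <- attr(col, "planted_term")
  # planted fraction within the range spanned by null terms
  expect_lte(frac[[pl]], max(frac[names(frac) != pl]))
})
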