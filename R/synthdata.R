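## Synthetic study generator. Every pipeline input — compound table with
## ADME parameters, compound-target map, background interactome, disease
## gene list, annotation collection — is generated with planted, exactly
## known structure: a fixed ADME pass-count, a dense interactome module, a
## controlled disease-gene overlap with that module, and one term enriched
## for module genes. Downstream stages can therefore be tested against
## ground truth without any database access. Symbols are synthetic
## (G000001, CPD00001, HERB01, TERM001) by design.

#' Configuration for the synthetic study
#'
#' Defaults describe a desk-scale study with a strong planted signal: a
#' 16-herb formula, a scale-free 400-node interactome carrying a 40-node
#' module of internal density 0.9 (a disease module far denser than the
#' preferential-attachment background), disease genes placed mostly inside
#' the module, and one annotation term enriched for module genes (the
#' default odds multiplier of 20 makes roughly two-thirds of the planted
#' term's members module genes, emulating a pathway that characterizes
#' the module).
#'
#' @param seed Integer seed; fully determines every generated input.
#' @param n_herbs Number of herbs in the formula.
#' @param n_compounds Number of compounds in the pool.
#' @param pass_fraction Fraction of compounds planted to pass all five
#'   ADME criteria; exactly `round(pass_fraction * n_compounds)` pass.
#' @param n_whitelist Number of ADME-failing compounds flagged as
#'   literature-rescue whitelist members.
#' @param n_targets Number of distinct protein targets mapped to active
#'   compounds (all drawn from interactome nodes).
#' @param interactome_nodes Background interactome size.
#' @param interactome_model `"scale_free"` (preferential attachment) or
#'   `"erdos_renyi"`.
#' @param pa_m Edges attached per step under the scale-free model.
#' @param er_p Edge probability under the Erdos-Renyi model.
#' @param planted_module_size Nodes in the planted dense module (0 disables
#'   planting).
#' @param planted_module_density Minimum induced edge density of the module.
#' @param n_disease_genes Disease gene list length.
#' @param disease_overlap Fraction of disease genes placed inside the
#'   planted module.
#' @param n_terms Number of annotation terms.
#' @param planted_term_enrichment Odds multiplier favoring module genes in
#'   the planted term's membership (1 = no planting).
#' @return A validated `synth_config` object.
#' @export
synth_config <- function(seed = 1,
                         n_herbs = 16,
                         n_compounds = 200,
                         pass_fraction = 0.15,
                         n_whitelist = 10,
                         n_targets = 60,
                         interactome_nodes = 400,
                         interactome_model = c("scale_free", "erdos_renyi"),
                         pa_m = 3,
                         er_p = 0.02,
                         planted_module_size = 40,
                         planted_module_density = 0.9,
                         n_disease_genes = 40,
                         disease_overlap = 0.6,
                         n_terms = 50,
                         planted_term_enrichment = 20) {
  cfg <- list(seed = as.integer(seed), n_herbs = n_herbs,
              n_compounds = n_compounds, pass_fraction = pass_fraction,
              n_whitelist = n_whitelist, n_targets = n_targets,
              interactome_nodes = interactome_nodes,
              interactome_model = match.arg(interactome_model),
              pa_m = pa_m, er_p = er_p,
              planted_module_size = planted_module_size,
              planted_module_density = planted_module_density,
              n_disease_genes = n_disease_genes,
              disease_overlap = disease_overlap,
              n_terms = n_terms,
              planted_term_enrichment = planted_term_enrichment)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  chk_count <- function(field, min = 0) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < min ||
        v != round(v))
      stop("invalid synth_config field '", field, "': must be an integer >= ",
           min)
  }
  chk_prop <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0 || v > 1)
      stop("invalid synth_config field '", field, "': must lie in [0, 1]")
  }
  for (f in c("n_herbs", "n_compounds", "n_whitelist", "n_targets",
              "interactome_nodes", "planted_module_size",
              "n_disease_genes", "n_terms"))
    chk_count(f)
  chk_count("n_herbs", min = 1)
  chk_count("pa_m", min = 1)
  for (f in c("pass_fraction", "planted_module_density", "disease_overlap",
              "er_p"))
    chk_prop(f)
  if (!is.numeric(cfg$planted_term_enrichment) ||
      cfg$planted_term_enrichment < 1)
    stop("invalid synth_config field 'planted_term_enrichment': must be >= 1")
  if (cfg$planted_module_size > cfg$interactome_nodes)
    stop("invalid synth_config field 'planted_module_size': exceeds ",
         "'interactome_nodes'")
  invisible(cfg)
}

gene_names <- function(n) sprintf("G%06d", seq_len(n))

#' Generate the compound table
#'
#' Plants exactly `round(pass_fraction * n_compounds)` compounds passing
#' all five ADME criteria. Passing values are drawn uniformly from
#' `[threshold, threshold + span]`; each failing compound violates exactly
#' `n_violations` parameters (the sole-violator parameter cycles through
#' all five, so every criterion is some record's only failure), with the
#' rest drawn from passing ranges. Herb membership is many-to-many.
#' `n_whitelist` failing compounds are flagged as whitelist rescues.
#'
#' @param config A [synth_config()].
#' @param n_violations Number of sub-threshold parameters per failing
#'   compound (>= 1).
#' @return Compound data frame (see [read_compounds()] for columns).
#' @export
gen_compound_table <- function(config, n_violations = 1) {
  stopifnot(inherits(config, "synth_config"), n_violations >= 1)
  set.seed(config$seed + 101L)
  n <- config$n_compounds
  n_pass <- round(config$pass_fraction * n)
  thr <- adme_thresholds()
  lo <- c(ob = thr$ob_min, dl = thr$dl_min, caco2 = thr$caco2_min,
          bbb = thr$bbb_min, hl = thr$hl_min)
  span <- c(ob = 70, dl = 0.8, caco2 = 1.5, bbb = 1.2, hl = 20)
  fail_lo <- c(ob = 0, dl = 0, caco2 = -2, bbb = -2, hl = 0)

  herbs <- sprintf("HERB%02d", seq_len(config$n_herbs))
  herb_sets <- vapply(seq_len(n), function(i) {
    paste(sort(sample(herbs, sample(1:min(3, config$n_herbs), 1))),
          collapse = ";")
  }, character(1))

  vals <- sapply(names(lo), function(p) runif(n, lo[p], lo[p] + span[p]))
  vals <- matrix(vals, nrow = n, dimnames = list(NULL, names(lo)))
  pass_idx <- sort(sample(n, n_pass))
  fail_idx <- setdiff(seq_len(n), pass_idx)
  if (length(fail_idx) > 0) {
    first_violation <- rep_len(seq_along(lo), length(fail_idx))
    for (j in seq_along(fail_idx)) {
      i <- fail_idx[j]
      viol <- first_violation[j]
      if (n_violations > 1)
        viol <- unique(c(viol, sample(seq_along(lo),
                                      min(n_violations, 5) - 1)))
      for (p in viol)
        vals[i, p] <- runif(1, fail_lo[p],
                            lo[p] - 1e-6 * max(1, abs(lo[p])))
    }
  }
  whitelisted <- integer(n)
  if (config$n_whitelist > 0) {
    if (config$n_whitelist > length(fail_idx))
      stop("invalid synth_config field 'n_whitelist': exceeds the number ",
           "of ADME-failing compounds")
    whitelisted[sample(fail_idx, config$n_whitelist)] <- 1L
  }
  df <- data.frame(compound_id = sprintf("CPD%05d", seq_len(n)),
                   name = sprintf("compound-%04d", seq_len(n)),
                   herbs = herb_sets,
                   ob = vals[, "ob"], dl = vals[, "dl"],
                   caco2 = vals[, "caco2"], bbb = vals[, "bbb"],
                   hl = vals[, "hl"],
                   whitelisted = whitelisted,
                   stringsAsFactors = FALSE)
  stopifnot(sum(passes_adme(df, thr)) == n_pass)  # planted truth holds
  df
}

#' Generate the background interactome
#'
#' Simple undirected graph under the configured background model, with a
#' planted node subset of size `planted_module_size` whose induced edge
#' density is raised to at least `planted_module_density` by adding
#' missing within-module edges. The module's node names are stored in the
#' graph attribute `planted_module`.
#'
#' @param config A [synth_config()].
#' @return igraph network with vertex names `G000001...`.
#' @export
gen_interactome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 202L)
  n <- config$interactome_nodes
  g <- switch(config$interactome_model,
              scale_free = igraph::sample_pa(n, m = config$pa_m,
                                             directed = FALSE),
              erdos_renyi = igraph::sample_gnp(n, p = config$er_p))
  g <- igraph::simplify(g)
  g <- igraph::set_vertex_attr(g, "name", value = gene_names(n))
  module <- character(0)
  s <- config$planted_module_size
  if (s >= 2) {
    need <- ceiling(config$planted_module_density * choose(s, 2))
    if (need > choose(s, 2))
      stop("invalid synth_config field 'planted_module_density': requires ",
           need, " edges but the module supports at most ", choose(s, 2))
    module <- sort(sample(igraph::V(g)$name, s))
    idx <- match(module, igraph::V(g)$name)
    pairs <- t(combn(idx, 2))
    have <- igraph::get_edge_ids(g, t(pairs)) > 0
    n_add <- need - sum(have)
    if (n_add > 0) {
      missing <- pairs[!have, , drop = FALSE]
      add <- missing[sample(nrow(missing), n_add), , drop = FALSE]
      g <- igraph::add_edges(g, t(add))
    }
  } else if (s == 1) {
    module <- sample(igraph::V(g)$name, 1)
  }
  g <- igraph::simplify(g)
  g$planted_module <- module
  g$provenance <- sprintf("synthetic interactome (%s, seed %d)",
                          config$interactome_model, config$seed)
  g
}

#' Generate the disease gene list
#'
#' `round(disease_overlap * n_disease_genes)` genes are sampled from the
#' planted module, the rest from non-module interactome nodes.
#'
#' @param config A [synth_config()].
#' @param interactome Network from [gen_interactome()].
#' @return Character vector of disease gene symbols.
#' @export
gen_disease_genes <- function(config, interactome) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 303L)
  module <- interactome$planted_module %||% character(0)
  n_in <- round(config$disease_overlap * config$n_disease_genes)
  if (n_in > length(module))
    stop("invalid synth_config field 'disease_overlap': requires ", n_in,
         " module genes but the planted module has ", length(module))
  outside <- setdiff(igraph::V(interactome)$name, module)
  n_out <- config$n_disease_genes - n_in
  if (n_out > length(outside))
    stop("invalid synth_config field 'n_disease_genes': needs ", n_out,
         " non-module genes but only ", length(outside), " exist")
  sample(c(sample(module, n_in), sample(outside, n_out)))
}

#' Generate the compound-target map
#'
#' Targets are `n_targets` distinct interactome nodes; every active
#' compound (planted ADME pass or whitelist rescue) receives at least one
#' target and every target is used by at least one active compound, so the
#' union of targets over active compounds equals `n_targets` exactly.
#' Each association is attributed to one of the compound's herbs.
#'
#' @param config A [synth_config()].
#' @param compounds Table from [gen_compound_table()].
#' @param interactome Network from [gen_interactome()].
#' @return A `target_map` data frame.
#' @export
gen_target_map <- function(config, compounds, interactome) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 404L)
  active <- compounds[passes_adme(compounds) | compounds$whitelisted == 1L, ]
  if (nrow(active) == 0) stop("no active compounds to map targets for")
  if (config$n_targets > igraph::vcount(interactome))
    stop("invalid synth_config field 'n_targets': exceeds interactome size")
  targets <- sort(sample(igraph::V(interactome)$name, config$n_targets))
  # cover every target, then every compound, then add density
  rows <- data.frame(compound_id = sample(active$compound_id,
                                          length(targets), replace = TRUE),
                     target_symbol = targets, stringsAsFactors = FALSE)
  uncovered <- setdiff(active$compound_id, rows$compound_id)
  if (length(uncovered) > 0)
    rows <- rbind(rows, data.frame(
      compound_id = uncovered,
      target_symbol = sample(targets, length(uncovered), replace = TRUE)))
  extra_per <- pmax(0, sample(0:5, nrow(active), replace = TRUE))
  for (i in seq_len(nrow(active))) {
    if (extra_per[i] == 0) next
    rows <- rbind(rows, data.frame(
      compound_id = active$compound_id[i],
      target_symbol = sample(targets, extra_per[i])))
  }
  rows <- rows[!duplicated(rows), , drop = FALSE]
  herb_of <- strsplit(active$herbs, ";", fixed = TRUE)
  names(herb_of) <- active$compound_id
  rows$herb <- vapply(rows$compound_id, function(id) {
    h <- herb_of[[id]]
    h[sample.int(length(h), 1)]
  }, character(1))
  rows$source <- "synthetic"
  rows$score <- round(runif(nrow(rows), 0.7, 1), 4)
  target_map(rows)
}

#' Generate the annotation collection
#'
#' `n_terms` gene sets over the interactome node universe. Exactly one
#' planted term samples its members with odds multiplied by
#' `planted_term_enrichment` for planted-module genes; all other terms
#' sample uniformly. With multiplier 1 the planted term is constructed
#' like any other.
#'
#' @param config A [synth_config()].
#' @param interactome Network from [gen_interactome()].
#' @return A [gene_set_collection()]; the planted term id is stored in
#'   attribute `planted_term`.
#' @export
gen_annotations <- function(config, interactome) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 505L)
  universe <- igraph::V(interactome)$name
  module <- interactome$planted_module %||% character(0)
  w <- ifelse(universe %in% module, config$planted_term_enrichment, 1)
  ids <- sprintf("TERM%03d", seq_len(config$n_terms))
  planted <- if (config$n_terms > 0) sample(ids, 1) else NA_character_
  sizes <- sample(10:min(40, length(universe)), config$n_terms,
                  replace = TRUE)
  terms <- lapply(seq_len(config$n_terms), function(i) {
    if (ids[i] == planted && config$planted_term_enrichment > 1)
      sample(universe, sizes[i], prob = w)
    else
      sample(universe, sizes[i])
  })
  names(terms) <- ids
  desc <- setNames(sprintf("synthetic pathway %03d", seq_len(config$n_terms)),
                   ids)
  if (!is.na(planted)) desc[planted] <- "synthetic pathway (planted)"
  col <- gene_set_collection(terms, descriptions = desc, universe = universe)
  attr(col, "planted_term") <- planted
  col
}

#' Generate and write the full synthetic input bundle
#'
#' Writes `compounds.tsv`, `compound_targets.tsv`, `disease_genes.txt`,
#' `interactome.sif`, `annotations.gmt` and `truth.json` (the planted
#' ground truth) into `dir`.
#'
#' @param config A [synth_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the generated objects and the `truth`
#'   record.
#' @export
write_synthetic_inputs <- function(config, dir) {
  stopifnot(inherits(config, "synth_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  compounds <- gen_compound_table(config)
  interactome <- gen_interactome(config)
  disease <- gen_disease_genes(config, interactome)
  map <- gen_target_map(config, compounds, interactome)
  annotations <- gen_annotations(config, interactome)

  write_compounds(compounds, file.path(dir, "compounds.tsv"))
  write_tsv(as.data.frame(map), file.path(dir, "compound_targets.tsv"))
  write_gene_list(disease, file.path(dir, "disease_genes.txt"))
  write_sif(interactome, file.path(dir, "interactome.sif"))
  write_gmt(annotations, file.path(dir, "annotations.gmt"))

  truth <- list(
    seed = config$seed,
    n_adme_pass = round(config$pass_fraction * config$n_compounds),
    n_whitelist = config$n_whitelist,
    n_active = round(config$pass_fraction * config$n_compounds) +
      config$n_whitelist,
    n_targets = config$n_targets,
    planted_module = interactome$planted_module,
    n_disease_in_module = round(config$disease_overlap *
                                  config$n_disease_genes),
    planted_term = attr(annotations, "planted_term"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = config, compounds = compounds,
                 interactome = interactome, disease = disease,
                 map = map, annotations = annotations, truth = truth))
}
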