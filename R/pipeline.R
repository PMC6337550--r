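## End-to-end orchestration: read the five inputs, run every stage in
## order, write all intermediate artifacts and a machine-readable run
## report whose counts follow the narrative order of the underlying
## analysis (compounds collected / passed / active, targets, disease
## intersection, network sizes, feature medians, hub candidates,
## significant terms).

#' Pipeline configuration
#'
#' @param input_dir Directory holding the standard input file names (as
#'   written by [write_synthetic_inputs()]); individual paths override it.
#' @param compounds,targets,disease,interactome,annotations Input paths.
#' @param whitelist Optional path to a file of whitelist compound ids (one
#'   per line); by default the compound table's `whitelisted` column is
#'   used.
#' @param out_dir Output directory for artifacts and the run report.
#' @param adme [adme_thresholds()] for the screen.
#' @param svm_min,rf_min Optional strict score floors for model-predicted
#'   target associations.
#' @param depth Seed-expansion radius for both PPI networks.
#' @param merge_mode `"intersection"` (core network) or `"union"`.
#' @param hub_comparison,hub_combination,degree_prefilter_multiplier Hub
#'   screening options, see [hub_criteria()].
#' @param alpha,kappa_threshold,correction Enrichment options, see
#'   [enrich_and_group()].
#' @param enrichment_universe `"annotations"` (collection universe) or
#'   `"network"` (core-PPI node set).
#' @param seed Seed recorded in the provenance block.
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input_dir = NULL,
                            compounds = file.path(input_dir, "compounds.tsv"),
                            targets = file.path(input_dir,
                                                "compound_targets.tsv"),
                            disease = file.path(input_dir,
                                                "disease_genes.txt"),
                            interactome = file.path(input_dir,
                                                    "interactome.sif"),
                            annotations = file.path(input_dir,
                                                    "annotations.gmt"),
                            whitelist = NULL,
                            out_dir = tempfile("herbnet_run_"),
                            adme = adme_thresholds(),
                            svm_min = NULL, rf_min = NULL,
                            depth = 1,
                            merge_mode = "intersection",
                            hub_comparison = "strictly_greater",
                            hub_combination = "all",
                            degree_prefilter_multiplier = 0,
                            alpha = 0.05, kappa_threshold = 0.4,
                            correction = "benjamini_hochberg",
                            enrichment_universe = c("annotations", "network"),
                            seed = 1) {
  cfg <- list(paths = list(compounds = compounds, targets = targets,
                           disease = disease, interactome = interactome,
                           annotations = annotations, whitelist = whitelist),
              out_dir = out_dir, adme = adme,
              svm_min = svm_min, rf_min = rf_min, depth = depth,
              merge_mode = merge_mode,
              hub_comparison = hub_comparison,
              hub_combination = hub_combination,
              degree_prefilter_multiplier = degree_prefilter_multiplier,
              alpha = alpha, kappa_threshold = kappa_threshold,
              correction = correction,
              enrichment_universe = match.arg(enrichment_universe),
              seed = as.integer(seed))
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: ADME screen -> per-herb targets -> disease intersection ->
#' compound-target network -> drug-side PPI -> disease-side PPI -> core
#' merge -> six-feature centrality -> median hub filter -> enrichment with
#' kappa grouping. Every intermediate artifact is written under
#' `config$out_dir`, together with `report.json` carrying stage counts and
#' a provenance block (config hash, seed). A stage failure aborts with the
#' stage name; artifacts written so far are retained.
#'
#' @param config A [pipeline_config()].
#' @return The run report, invisibly a list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in setdiff(names(config$paths), "whitelist")) {
    p <- config$paths[[nm]]
    if (is.null(p) || !file.exists(p))
      stop("pipeline input '", nm, "' not found at path: ",
           if (is.null(p)) "<unset>" else p)
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  compounds <- stage("read_compounds", read_compounds(config$paths$compounds))
  whitelist <- if (!is.null(config$paths$whitelist))
    stage("read_whitelist", readLines(config$paths$whitelist, warn = FALSE))
  else NULL
  active <- stage("screen", screen_compounds(compounds, config$adme,
                                             whitelist = whitelist))
  write_tsv(active$active, file.path(out, "active_compounds.tsv"))

  map <- stage("targets", load_target_map(config$paths$targets,
                                          svm_min = config$svm_min,
                                          rf_min = config$rf_min))
  herb_targets <- stage("targets", per_herb_targets(map, active))
  write_tsv(data.frame(herb = names(herb_targets$sizes),
                       n_targets = as.integer(herb_targets$sizes)),
            file.path(out, "per_herb_targets.tsv"))

  disease <- stage("disease", read_gene_list(config$paths$disease))
  shared <- stage("disease", intersect_disease(herb_targets$union, disease))
  write_gene_list(shared, file.path(out, "shared_targets.txt"))

  ct <- stage("ct_network", build_ct_network(active, map))
  write_graphml(ct, file.path(out, "compound_target_network.graphml"))

  interactome <- stage("interactome", read_sif(config$paths$interactome))
  drug_ppi <- stage("ppi_drug",
                    expand_seeds(interactome, herb_targets$union,
                                 depth = config$depth))
  disease_ppi <- stage("ppi_disease",
                       expand_seeds(interactome, disease,
                                    depth = config$depth))
  core <- stage("merge", merge_networks(drug_ppi, disease_ppi,
                                        mode = config$merge_mode))
  write_sif(drug_ppi, file.path(out, "drug_ppi.sif"))
  write_sif(disease_ppi, file.path(out, "disease_ppi.sif"))
  write_sif(core, file.path(out, "core_ppi.sif"))

  table <- stage("centrality", centrality_table(core))
  write_tsv(table, file.path(out, "centrality.tsv"))

  criteria <- stage("hubs", median_thresholds(
    table, comparison = config$hub_comparison,
    combination = config$hub_combination,
    degree_prefilter_multiplier = config$degree_prefilter_multiplier))
  candidates <- stage("hubs", filter_hubs(table, criteria))
  write_gene_list(candidates, file.path(out, "candidates.txt"))
  jsonlite::write_json(list(thresholds = as.list(criteria$thresholds),
                            comparison = criteria$comparison,
                            combination = criteria$combination),
                       file.path(out, "criteria.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  annotations <- stage("annotations", read_gmt(config$paths$annotations))
  universe <- if (config$enrichment_universe == "network")
    igraph::V(core)$name else NULL
  enr <- stage("enrich", enrich_and_group(
    candidates, annotations, alpha = config$alpha,
    kappa_threshold = config$kappa_threshold,
    correction = config$correction, universe = universe))
  write_tsv(enr$results, file.path(out, "enrichment.tsv"))
  jsonlite::write_json(lapply(enr$groups, function(g)
    list(representative = g$representative, terms = g$terms)),
    file.path(out, "groups.json"), auto_unbox = TRUE, pretty = TRUE)

  cfg_json <- jsonlite::toJSON(unclass(config)[setdiff(names(config),
                                                       "out_dir")],
                               auto_unbox = TRUE, digits = NA, null = "null",
                               force = TRUE)
  cfg_file <- file.path(out, "config.json")
  writeLines(cfg_json, cfg_file)
  medians <- vapply(six_features, function(f) stats::median(table[[f]]),
                    numeric(1))
  report <- list(
    provenance = list(config_hash = unname(tools::md5sum(cfg_file)),
                      seed = config$seed),
    counts = list(
      compounds_collected = nrow(compounds),
      adme_passed = active$n_passed,
      rescued = active$n_rescued,
      active_compounds = active$n_active,
      formula_targets = herb_targets$n_union,
      disease_genes = length(disease),
      shared_targets = length(shared),
      ct_network = list(nodes = igraph::vcount(ct),
                        edges = igraph::ecount(ct)),
      drug_ppi = list(nodes = igraph::vcount(drug_ppi),
                      edges = igraph::ecount(drug_ppi)),
      disease_ppi = list(nodes = igraph::vcount(disease_ppi),
                         edges = igraph::ecount(disease_ppi)),
      core_ppi = list(nodes = igraph::vcount(core),
                      edges = igraph::ecount(core)),
      feature_medians = as.list(medians),
      hub_candidates = length(candidates),
      significant_terms = sum(enr$results$significant),
      term_groups = length(enr$groups)),
    top_terms = utils::head(enr$results$term_id, 5),
    candidates = candidates)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
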