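## A synthetic replica of the study's tabulated inputs at full scale.
## The original supplementary compound/target tables are not redistributed
## here; this generator plants their published marginal counts — 1005
## compounds of which 63 pass the ADME screen and 31 are whitelist rescues
## (94 active), a 287-target union over the active compounds, 1846 distinct
## compound-target associations, and a 354-gene disease list sharing
## exactly 41 symbols with the formula's targets — so that every count the
## screening and network stages report can be recomputed end to end.
## All identifiers are synthetic.

#' Generate the reference-scale synthetic study
#'
#' @param seed Integer seed.
#' @param n_compounds,n_pass,n_rescued Compound pool size and planted
#'   screen outcome.
#' @param n_targets Distinct targets over active compounds.
#' @param n_ct_edges Distinct compound-target associations.
#' @param n_disease Disease gene list length.
#' @param n_shared Planted size of the target/disease intersection.
#' @param n_herbs Herbs in the formula.
#' @return List with `compounds`, `map` (target map), `disease` (gene
#'   vector), `whitelist` ids, and the planted `truth` counts.
#' @export
gen_reference_study <- function(seed = 1, n_compounds = 1005, n_pass = 63,
                                n_rescued = 31, n_targets = 287,
                                n_ct_edges = 1846, n_disease = 354,
                                n_shared = 41, n_herbs = 16) {
  stopifnot(n_pass + n_rescued <= n_compounds, n_shared <= n_targets,
            n_shared <= n_disease,
            n_ct_edges <= (n_pass + n_rescued) * n_targets,
            n_ct_edges >= max(n_pass + n_rescued, n_targets))
  cfg <- synth_config(seed = seed, n_herbs = n_herbs,
                      n_compounds = n_compounds,
                      pass_fraction = n_pass / n_compounds,
                      n_whitelist = n_rescued)
  compounds <- gen_compound_table(cfg)
  set.seed(seed + 606L)
  active_ids <- compounds$compound_id[passes_adme(compounds) |
                                        compounds$whitelisted == 1L]
  n_active <- length(active_ids)
  targets <- sprintf("T%05d", seq_len(n_targets))

  # distinct (compound, target) pairs: cover all targets, then all
  # compounds, then fill to the planted edge count
  pair_id <- function(ci, ti) (ci - 1L) * n_targets + ti
  ci <- sample.int(n_active, n_targets, replace = TRUE)
  ti <- seq_len(n_targets)
  uncovered <- setdiff(seq_len(n_active), ci)
  if (length(uncovered) > 0) {
    ci <- c(ci, uncovered)
    ti <- c(ti, sample.int(n_targets, length(uncovered), replace = TRUE))
  }
  used <- unique(pair_id(ci, ti))
  pool <- setdiff(seq_len(n_active * n_targets), used)
  extra <- sample(pool, n_ct_edges - length(used))
  all_pairs <- c(used, extra)
  ci <- ((all_pairs - 1L) %/% n_targets) + 1L
  ti <- ((all_pairs - 1L) %% n_targets) + 1L

  herb_of <- strsplit(compounds$herbs[match(active_ids,
                                            compounds$compound_id)],
                      ";", fixed = TRUE)
  map <- target_map(data.frame(
    compound_id = active_ids[ci],
    target_symbol = targets[ti],
    herb = vapply(ci, function(i) {
      h <- herb_of[[i]]
      h[sample.int(length(h), 1)]
    }, character(1)),
    source = "synthetic", score = NA_real_,
    stringsAsFactors = FALSE))

  shared <- sample(targets, n_shared)
  disease <- sample(c(shared, sprintf("D%05d", seq_len(n_disease - n_shared))))

  list(compounds = compounds, map = map, disease = disease,
       whitelist = compounds$compound_id[compounds$whitelisted == 1L],
       truth = list(n_compounds = n_compounds, n_pass = n_pass,
                    n_rescued = n_rescued, n_active = n_active,
                    n_targets = n_targets, n_ct_edges = n_ct_edges,
                    n_disease = n_disease, n_shared = n_shared))
}
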