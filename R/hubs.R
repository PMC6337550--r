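## Hub screening on the core PPI network. Two rules are exposed:
##  - the six-feature median filter: keep nodes whose DC, BC, CC, EC, NC and
##    LAC all (by default strictly) exceed the per-feature medians;
##  - the classical double-median-degree rule: a node is a hub when its
##    degree exceeds twice the median degree.
## The degree rule can also serve as an optional prefilter before the
## six-feature screen; the two rules' composition is configurable because
## reasonable pipelines differ here.

six_features <- c("dc", "bc", "cc", "ec", "nc", "lac")

#' Hub-screening criteria
#'
#' @param thresholds Named numeric vector/list with one finite threshold per
#'   feature (`dc`, `bc`, `cc`, `ec`, `nc`, `lac`) when `combination="all"`.
#' @param comparison `"strictly_greater"` (default) or `"at_least"`.
#' @param combination Require `"all"` features (default) or `"any"`.
#' @param degree_prefilter_multiplier When `> 0`, nodes are first required
#'   to have degree strictly greater than multiplier x median degree
#'   (2 reproduces the double-median-degree hub definition); 0 disables.
#' @return A `hub_criteria` object.
#' @export
hub_criteria <- function(thresholds,
                         comparison = c("strictly_greater", "at_least"),
                         combination = c("all", "any"),
                         degree_prefilter_multiplier = 0) {
  comparison <- match.arg(comparison)
  combination <- match.arg(combination)
  thresholds <- unlist(thresholds)
  if (combination == "all") {
    miss <- setdiff(six_features, names(thresholds))
    if (length(miss) > 0)
      stop("thresholds missing for feature(s): ", paste(miss, collapse = ", "))
    thresholds <- thresholds[six_features]
  }
  if (any(!is.finite(thresholds)))
    stop("non-finite hub threshold(s)")
  stopifnot(is.numeric(degree_prefilter_multiplier),
            degree_prefilter_multiplier >= 0)
  structure(list(thresholds = thresholds, comparison = comparison,
                 combination = combination,
                 degree_prefilter_multiplier = degree_prefilter_multiplier),
            class = "hub_criteria")
}

#' Median thresholds from a centrality table
#'
#' Per-feature medians (even counts take the midpoint of the central pair,
#' the usual convention, which is how fractional medians arise on integer
#' features).
#'
#' @param table A [centrality_table()].
#' @param ... Passed to [hub_criteria()] (comparison, combination,
#'   prefilter).
#' @return A `hub_criteria` with the six medians as thresholds.
#' @export
median_thresholds <- function(table, ...) {
  if (nrow(table) == 0) stop("empty centrality table")
  med <- vapply(six_features, function(f) stats::median(table[[f]]),
                numeric(1))
  hub_criteria(med, ...)
}

#' Double-median-degree hubs
#'
#' Nodes whose degree strictly exceeds twice the median degree
#' ("exceeds", hence strict).
#'
#' @param g igraph network with named vertices, or a (optionally named)
#'   numeric degree vector.
#' @return Character vector of hub node names (indices as names when an
#'   unnamed degree vector is given).
#' @export
double_median_degree_hubs <- function(g) {
  d <- if (is.numeric(g)) {
    if (length(g) == 0) stop("empty degree vector")
    setNames(g, names(g) %||% as.character(seq_along(g)))
  } else {
    if (igraph::vcount(g) == 0) stop("empty network")
    centrality_degree(g)
  }
  names(d)[d > 2 * stats::median(d)]
}

#' Filter hub candidates from a centrality table
#'
#' Applies the optional degree prefilter, then keeps nodes whose features
#' satisfy the criteria's comparison against every (or any) threshold.
#'
#' @param table A [centrality_table()].
#' @param criteria A [hub_criteria()], e.g. from [median_thresholds()].
#' @return Character vector of surviving node names.
#' @export
filter_hubs <- function(table, criteria) {
  stopifnot(inherits(criteria, "hub_criteria"))
  if (criteria$degree_prefilter_multiplier > 0) {
    cut <- criteria$degree_prefilter_multiplier * stats::median(table$dc)
    table <- table[table$dc > cut, , drop = FALSE]
  }
  if (nrow(table) == 0) return(character(0))
  feats <- names(criteria$thresholds)
  cmp <- if (criteria$comparison == "strictly_greater") `>` else `>=`
  hit <- vapply(feats, function(f) cmp(table[[f]], criteria$thresholds[[f]]),
                logical(nrow(table)))
  hit <- matrix(hit, nrow = nrow(table))
  keep <- if (criteria$combination == "all") rowSums(hit) == length(feats)
          else rowSums(hit) > 0
  table$node[keep]
}
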