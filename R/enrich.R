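## Term enrichment of candidate targets with kappa-statistic term grouping,
## after the functional-grouping behavior of the ClueGO tool: per-term
## right-tailed hypergeometric tests, multiple-testing correction, and
## single-linkage clustering of significant terms by Cohen's kappa
## agreement of their gene memberships.

#' Right-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the chance of drawing at
#' least `k` members of a size-`K` term in a size-`n` query from a
#' size-`N` universe. Delegates to the log-space-stable distribution
#' function in `stats`.
#'
#' @param k Observed overlap count.
#' @param K Term size.
#' @param n Query (candidate set) size.
#' @param N Universe size.
#' @return The enrichment p value (vectorized over its arguments).
#' @export
hypergeom_p <- function(k, K, n, N) {
  bad <- k < 0 | k > pmin(K, n) | K > N | n > N | K < 0 | n < 0 | N < 1
  if (any(bad))
    stop("inconsistent hypergeometric counts at index ", which(bad)[1],
         ": k=", k[which(bad)[1]], " K=", K[which(bad)[1]],
         " n=", n[which(bad)[1]], " N=", N[which(bad)[1]])
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Multiple-testing correction
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @param method `"benjamini_hochberg"` (default) or
#'   `"bonferroni_step_down"` (Holm).
#' @return Adjusted p values in input order.
#' @export
adjust_p <- function(p, method = c("benjamini_hochberg",
                                   "bonferroni_step_down")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = switch(method,
                                     benjamini_hochberg = "BH",
                                     bonferroni_step_down = "holm"))
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Agreement of the two membership indicators on the 2x2 contingency table
#' over all universe genes: kappa = (p_o - p_e) / (1 - p_e). In the
#' degenerate case p_e = 1 (both margins pure), kappa is 1 for identical
#' tables and 0 otherwise.
#'
#' @param a,b Character vectors of member genes (subsets of `universe`).
#' @param universe Background gene universe (non-empty).
#' @return Kappa in `[-1, 1]`.
#' @export
kappa_agreement <- function(a, b, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0) stop("empty universe")
  a <- intersect(unique(a), universe)
  b <- intersect(unique(b), universe)
  n11 <- length(intersect(a, b))
  n10 <- length(a) - n11
  n01 <- length(b) - n11
  n00 <- N - n11 - n10 - n01
  po <- (n11 + n00) / N
  pe <- ((n11 + n10) * (n11 + n01) + (n01 + n00) * (n10 + n00)) / N^2
  if (pe >= 1) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Enrich candidate genes and group significant terms by kappa
#'
#' Each term in the collection is tested for overrepresentation among the
#' candidates by [hypergeom_p()]; p values are corrected by [adjust_p()]
#' and terms with adjusted p at or below `alpha` are significant.
#' Significant terms are then clustered by single linkage on pairwise
#' Cohen's kappa at `kappa_threshold`; each group is represented by its
#' lowest-p member.
#'
#' @param candidates Character vector of candidate genes.
#' @param collection A [gene_set_collection()].
#' @param alpha Significance cut-off on the adjusted p value.
#' @param kappa_threshold Minimum kappa linking two terms into one group.
#' @param correction Correction method, see [adjust_p()].
#' @param universe Optional background override (e.g. a network's node
#'   set); defaults to the collection's universe.
#' @return An `enrichment` object: list with `results` (data frame sorted
#'   by p: term_id, description, k, K, n, N, p, p_adj, significant,
#'   group_id) and `groups` (list of `terms`, `representative`, `kappa`
#'   submatrix).
#' @export
enrich_and_group <- function(candidates, collection, alpha = 0.05,
                             kappa_threshold = 0.4,
                             correction = "benjamini_hochberg",
                             universe = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- if (is.null(universe)) collection$universe
              else normalize_symbols(universe)
  cand <- intersect(normalize_symbols(candidates), universe)
  if (length(cand) == 0)
    stop("no candidate gene lies in the universe")
  terms <- lapply(collection$terms, intersect, universe)
  keep <- lengths(terms) > 0
  terms <- terms[keep]
  N <- length(universe)
  n <- length(cand)
  K <- lengths(terms)
  k <- vapply(terms, function(m) length(intersect(m, cand)), integer(1))
  p <- hypergeom_p(k, K, n, N)
  p_adj <- adjust_p(p, correction)
  res <- data.frame(term_id = names(terms),
                    description = as.character(
                      collection$descriptions[names(terms)]),
                    k = k, K = K, n = n, N = N,
                    p = p, p_adj = p_adj,
                    significant = p_adj <= alpha,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL

  sig <- res$term_id[res$significant]
  res$group_id <- NA_integer_
  groups <- list()
  if (length(sig) == 0) {
    message("no term significant at alpha = ", alpha)
  } else {
    km <- matrix(1, length(sig), length(sig), dimnames = list(sig, sig))
    if (length(sig) > 1) {
      for (i in seq_len(length(sig) - 1)) {
        for (j in seq(i + 1, length(sig))) {
          km[i, j] <- km[j, i] <- kappa_agreement(terms[[sig[i]]],
                                                  terms[[sig[j]]], universe)
        }
      }
    }
    adj <- km >= kappa_threshold
    gg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(gg)$membership
    for (gi in sort(unique(comp))) {
      members <- sig[comp == gi]
      members <- members[order(match(members, res$term_id))]
      groups[[length(groups) + 1]] <- list(
        terms = members,
        representative = members[1],   # res is p-sorted
        kappa = km[members, members, drop = FALSE])
    }
    # order groups by their representative's p; number accordingly
    ord <- order(match(vapply(groups, `[[`, character(1), "representative"),
                       res$term_id))
    groups <- groups[ord]
    for (gi in seq_along(groups))
      res$group_id[res$term_id %in% groups[[gi]]$terms] <- gi
  }
  structure(list(results = res, groups = groups, alpha = alpha,
                 kappa_threshold = kappa_threshold,
                 correction = correction),
            class = "enrichment")
}

#' @export
print.enrichment <- function(x, ...) {
  cat("enrichment:", nrow(x$results), "terms tested,",
      sum(x$results$significant), "significant (alpha =", x$alpha,
      "),", length(x$groups), "kappa groups\n")
  if (any(x$results$significant))
    print(utils::head(x$results[x$results$significant,
                                c("term_id", "k", "K", "p", "p_adj",
                                  "group_id")], 5))
  invisible(x)
}
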