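## ADME-based active-compound screening.
##
## Five per-compound pharmacokinetic filters, all inclusive (>=):
##   OB    oral bioavailability, percent          (default floor 30)
##   DL    drug-likeness score                    (default floor 0.18)
##   Caco-2 intestinal permeability score         (default floor -0.4)
##   BBB   blood-brain-barrier penetration score  (default floor -0.3)
##   HL    half-life, hours                       (default floor 4)
## Compounds failing the screen can still be rescued by a whitelist of
## literature-supported ids; rescued compounds are tracked separately.

#' ADME screening thresholds
#'
#' @param ob_min Minimum oral bioavailability, percent.
#' @param dl_min Minimum drug-likeness score.
#' @param caco2_min Minimum Caco-2 permeability score.
#' @param bbb_min Minimum blood-brain-barrier penetration score.
#' @param hl_min Minimum half-life, hours.
#' @return An `adme_thresholds` object (named list of the five floors).
#' @export
adme_thresholds <- function(ob_min = 30, dl_min = 0.18, caco2_min = -0.4,
                            bbb_min = -0.3, hl_min = 4) {
  t <- list(ob_min = ob_min, dl_min = dl_min, caco2_min = caco2_min,
            bbb_min = bbb_min, hl_min = hl_min)
  bad <- names(t)[!vapply(t, function(x) is.numeric(x) && length(x) == 1 &&
                            is.finite(x), logical(1))]
  if (length(bad) > 0)
    stop("non-finite ADME threshold(s): ", paste(bad, collapse = ", "))
  structure(t, class = "adme_thresholds")
}

adme_params <- c("ob", "dl", "caco2", "bbb", "hl")

#' Test compounds against the five ADME criteria
#'
#' A compound passes iff all five parameters are at or above their floors
#' (inclusive comparisons). Vectorized over the rows of `compounds`.
#'
#' @param compounds Data frame with columns `compound_id`, `ob`, `dl`,
#'   `caco2`, `bbb`, `hl` (see [read_compounds()]).
#' @param thresholds An [adme_thresholds()] object.
#' @return Logical vector, one entry per row.
#' @export
passes_adme <- function(compounds, thresholds = adme_thresholds()) {
  stopifnot(inherits(thresholds, "adme_thresholds"))
  for (p in adme_params) {
    if (!p %in% names(compounds))
      stop("compound table lacks ADME column '", p, "'")
    v <- compounds[[p]]
    if (!is.numeric(v) || anyNA(v)) {
      i <- which(!is.finite(suppressWarnings(as.numeric(v))))[1]
      stop("compound '", compounds$compound_id[i],
           "': ADME field '", p, "' is missing or non-numeric")
    }
  }
  compounds$ob >= thresholds$ob_min &
    compounds$dl >= thresholds$dl_min &
    compounds$caco2 >= thresholds$caco2_min &
    compounds$bbb >= thresholds$bbb_min &
    compounds$hl >= thresholds$hl_min
}

#' Screen a compound table into an active set
#'
#' Partitions compounds into `adme_passed` (all five criteria met) and
#' `rescued` (whitelisted compounds that failed the screen); the active set
#' is their disjoint union. Whitelist ids absent from the table are
#' reported but not fatal.
#'
#' @param compounds Compound data frame.
#' @param thresholds An [adme_thresholds()] object.
#' @param whitelist Character vector of compound ids to rescue; defaults to
#'   ids flagged in a `whitelisted` column when present.
#' @return An `active_set`: list with data frames `adme_passed`, `rescued`,
#'   `active` (with a `status` column) and the three counts.
#' @export
screen_compounds <- function(compounds, thresholds = adme_thresholds(),
                             whitelist = NULL) {
  if (is.null(whitelist)) {
    whitelist <- if ("whitelisted" %in% names(compounds))
      compounds$compound_id[compounds$whitelisted %in% c(1, TRUE)]
    else character(0)
  }
  if (nrow(compounds) == 0) {
    warning("empty compound table: active set is empty")
    empty <- compounds
    return(structure(list(adme_passed = empty, rescued = empty,
                          active = cbind(empty, status = character(0)),
                          n_passed = 0L, n_rescued = 0L, n_active = 0L),
                     class = "active_set"))
  }
  unknown <- setdiff(whitelist, compounds$compound_id)
  if (length(unknown) > 0)
    warning("whitelist ids not in compound table: ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) " ..." else "")
  ok <- passes_adme(compounds, thresholds)
  passed <- compounds[ok, , drop = FALSE]
  rescued <- compounds[!ok & compounds$compound_id %in% whitelist, ,
                       drop = FALSE]
  active <- rbind(cbind(passed, status = rep("adme_passed", nrow(passed))),
                  cbind(rescued, status = rep("rescued", nrow(rescued))))
  rownames(active) <- NULL
  structure(list(adme_passed = passed, rescued = rescued, active = active,
                 n_passed = nrow(passed), n_rescued = nrow(rescued),
                 n_active = nrow(active)),
            class = "active_set")
}

#' @export
print.active_set <- function(x, ...) {
  cat("active_set:", x$n_passed, "ADME-passed +", x$n_rescued,
      "rescued =", x$n_active, "active compounds\n")
  invisible(x)
}

#' Active compound ids of an active set
#' @param active An `active_set`.
#' @return Character vector of compound ids.
#' @export
active_ids <- function(active) {
  stopifnot(inherits(active, "active_set"))
  active$active$compound_id
}
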