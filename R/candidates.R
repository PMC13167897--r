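#' Candidate sets for hierarchy-constrained selection
#'
#' Tracks `G1`, the covariates with any selected main term (time-independent
#' or time-varying), and derives `G2`, the interaction pairs currently
#' eligible under the chosen hierarchy: under strong hierarchy a pair
#' `(j, j')` is eligible only when both covariates are in `G1`; under weak
#' hierarchy when at least one is; with no hierarchy all pairs are eligible
#' from the start.
#'
#' @param P Number of covariates.
#' @param hierarchy One of `"strong"`, `"weak"`, `"none"`.
#' @return An object of class `candidate_sets` with elements `G1` (integer
#'   vector, initially empty), `hierarchy` and `P`.
#' @export
candidate_sets <- function(P, hierarchy = c("strong", "weak", "none")) {
  hierarchy <- match.arg(hierarchy)
  structure(list(G1 = integer(0), hierarchy = hierarchy, P = P),
            class = "candidate_sets")
}

#' Eligible interaction pairs under the hierarchy
#'
#' @param sets A `candidate_sets` object.
#' @return Two-column integer matrix of pairs `(j, jp)` with `j < jp`, in
#'   lexicographic order (the deterministic tie-break order).
#' @export
eligible_pairs <- function(sets) {
  P <- sets$P
  empty <- matrix(integer(0), 0, 2, dimnames = list(NULL, c("j", "jp")))
  if (sets$hierarchy == "none") {
    if (P < 2) return(empty)
    return(all_pairs(P))
  }
  G1 <- sort(sets$G1)
  if (sets$hierarchy == "strong") {
    if (length(G1) < 2) return(empty)
    m <- t(utils::combn(G1, 2))
    colnames(m) <- c("j", "jp")
    return(m)
  }
  # weak: at least one endpoint in G1
  if (length(G1) == 0) return(empty)
  ap <- all_pairs(P)
  keep <- (ap[, 1] %in% G1) | (ap[, 2] %in% G1)
  ap[keep, , drop = FALSE]
}

all_pairs <- function(P) {
  j <- rep(seq_len(P - 1), times = (P - 1):1)
  jp <- unlist(lapply(seq_len(P - 1), function(a) (a + 1):P), use.names = FALSE)
  cbind(j = j, jp = jp)
}

#' Update candidate sets after a selection
#'
#' Selecting a time-independent or time-varying term for covariate `j` adds
#' `j` to `G1`; selecting an interaction leaves `G1` unchanged. The eligible
#' pair set is always re-derived from `G1` via [eligible_pairs()].
#'
#' @param sets A `candidate_sets` object.
#' @param term A term as returned by [select_term()]: list with `type`
#'   (`"TI"`, `"TV"` or `"INT"`) and `j` (and `jp` for interactions).
#' @return The updated `candidate_sets`.
#' @export
update_candidates <- function(sets, term) {
  if (term$type %in% c("TI", "TV") && !(term$j %in% sets$G1)) {
    sets$G1 <- c(sets$G1, term$j)
  }
  sets
}
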