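#' Search a fragment layout for an infinite-integrality-gap witness
#'
#' For K >= 3 the constraint matrix of the count formulation is no longer
#' totally unimodular, and instances are claimed to exist whose LP
#' relaxation has value 0 while the integer optimum is positive — an
#' infinite integrality gap. This function searches a given layout (unit
#' parts) exhaustively for such a witness: it enumerates every consistent
#' 3-color right-hand side (rows summing to the fragment length; any other
#' row already forces a positive LP value), keeps those that are
#' achievable for each color separately but admit no integral 3-coloring
#' (checked by exhaustive search), and confirms candidates against the LP
#' relaxation.
#'
#' The default layout is the classic 4-fragment example
#' `(1,3), (2,5), (3,6), (5,7)` over 7 unit parts, which does exhibit
#' fractional LP vertices. Note, however, that this search is complete for
#' the layout it is given: if it returns no witness, none exists there.
#' See the methods vignette for why small interval layouts round — gap
#' witnesses arise from much larger, hardness-gadget-style instances.
#'
#' @param fragments two-column matrix of intervals (unit-part positions).
#' @param n number of residues/parts (default: max fragment end).
#' @param max_candidates stop after this many integer-infeasible
#'   candidates have been collected and LP-checked.
#' @return list with `witness` (an `hdx_instance`, or `NULL` if the layout
#'   contains none), `n_candidates` (integer-infeasible rhs found),
#'   `min_lp_value` (smallest LP relaxation value among candidates, `Inf`
#'   if there were none).
#' @export
find_gap_witness <- function(fragments = rbind(c(1, 3), c(2, 5), c(3, 6), c(5, 7)),
                             n = NULL, max_candidates = 1000L) {
  fragments <- as.matrix(fragments)
  if (is.null(n)) n <- max(fragments[, 2L])
  nf <- nrow(fragments)
  cand <- .gap_scan_cpp(as.integer(n), as.integer(fragments[, 1L]),
                        as.integer(fragments[, 2L]), as.integer(max_candidates))
  len <- fragments[, 2L] - fragments[, 1L] + 1L
  min_lp <- Inf
  witness <- NULL
  for (r in seq_len(nrow(cand))) {
    b <- cbind(cand[r, seq_len(nf)], cand[r, nf + seq_len(nf)])
    b <- cbind(b, len - rowSums(b))
    inst <- suppressWarnings(hdx_instance(n, fragments, b))
    lpv <- lp_relaxation_value(inst)
    min_lp <- min(min_lp, lpv)
    if (lpv < 1e-6) { witness <- inst; break }
  }
  list(witness = witness, n_candidates = nrow(cand), min_lp_value = min_lp)
}
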