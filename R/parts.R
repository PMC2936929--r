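#' Partition covered residues into parts
#'
#' A part is a maximal contiguous run of residues contained in exactly the
#' same set of fragments; no fragment starts or ends inside a part, so for
#' every fragment \eqn{f} and part \eqn{p} either \eqn{p \subseteq f} or
#' \eqn{p \cap f = \emptyset}. Colors can be permuted freely among the
#' residues of a part without changing any fragment's error, which is why
#' optimal solutions are represented per part. Residues covered by no
#' fragment are excluded (no prediction is possible for them).
#'
#' Parts are restricted to contiguous runs: residues in different runs with
#' coincidentally identical fragment sets form separate parts. This
#' refinement leaves the residue-level solution set unchanged and gives the
#' fragment-to-part incidence matrix the consecutive-ones property that the
#' fragment-graph construction relies on.
#'
#' @param x an `hdx_instance`.
#' @return An `hdx_partition`: list with `parts` (list of residue index
#'   vectors, in left-to-right order), `sizes` (the part-size vector **P**),
#'   `covered` (sorted covered residues), `part_of` (length-n map residue ->
#'   part index, `NA` if uncovered), `A` (the |F| x |P| inclusion matrix),
#'   and `frag_parts` (two-column matrix: first/last part position of each
#'   fragment).
#' @examples
#' inst <- hdx_instance(5, rbind(c(1, 3), c(2, 5)), rbind(c(2, 1), c(1, 3)),
#'                      color_names = c("s", "f"))
#' compute_parts(inst)$parts
#' @export
compute_parts <- function(x) {
  stopifnot(inherits(x, "hdx_instance"))
  Fn <- nrow(x$fragments)
  memb <- matrix(FALSE, max(x$n, 1L), Fn)
  if (Fn) for (f in seq_len(Fn))
    memb[x$fragments[f, 1L]:x$fragments[f, 2L], f] <- TRUE
  covered <- which(rowSums(memb) > 0L)
  part_of <- rep(NA_integer_, x$n)
  parts <- list()
  if (length(covered)) {
    sig <- apply(memb[covered, , drop = FALSE], 1L, function(r) paste(which(r), collapse = ","))
    new_part <- c(TRUE, sig[-1L] != sig[-length(sig)] |
                          diff(covered) != 1L)
    pid <- cumsum(new_part)
    parts <- split(covered, pid)
    names(parts) <- NULL
    part_of[covered] <- pid
  }
  m <- length(parts)
  A <- matrix(0L, Fn, m)
  frag_parts <- matrix(NA_integer_, Fn, 2L, dimnames = list(NULL, c("first", "last")))
  if (Fn && m) for (f in seq_len(Fn)) {
    ps <- part_of[x$fragments[f, 1L]]
    pe <- part_of[x$fragments[f, 2L]]
    A[f, ps:pe] <- 1L
    frag_parts[f, ] <- c(ps, pe)
  }
  structure(list(parts = parts,
                 sizes = vapply(parts, length, integer(1L)),
                 covered = covered, part_of = part_of,
                 A = A, frag_parts = frag_parts),
            class = "hdx_partition")
}

#' @export
print.hdx_partition <- function(x, ...) {
  cat("HDX partition:", length(x$parts), "parts over",
      length(x$covered), "covered residues\n")
  if (length(x$sizes)) cat("  part sizes:", paste(x$sizes, collapse = " "), "\n")
  invisible(x)
}

#' Decompose an instance into independent subproblems
#'
#' Two fragments overlap if they share at least one residue. Connected
#' components of the overlap graph can be solved independently: an
#' assignment on one component's residues does not affect any other
#' component's error, and the optimal total error is the sum of the
#' component optima.
#'
#' @param x an `hdx_instance`.
#' @return list of components, each a list with `fragments` (fragment row
#'   indices), `range` (residue span `c(start, end)`).
#' @export
decompose_subproblems <- function(x) {
  stopifnot(inherits(x, "hdx_instance"))
  Fn <- nrow(x$fragments)
  if (Fn == 0L) return(list())
  ord <- order(x$fragments[, 1L], x$fragments[, 2L])
  comps <- list()
  cur <- ord[1L]
  cur_end <- x$fragments[ord[1L], 2L]
  for (f in ord[-1L]) {
    if (x$fragments[f, 1L] <= cur_end) {
      cur <- c(cur, f)
      cur_end <- max(cur_end, x$fragments[f, 2L])
    } else {
      comps[[length(comps) + 1L]] <- cur
      cur <- f
      cur_end <- x$fragments[f, 2L]
    }
  }
  comps[[length(comps) + 1L]] <- cur
  lapply(comps, function(idx) {
    idx <- sort(idx)
    list(fragments = idx,
         range = c(min(x$fragments[idx, 1L]), max(x$fragments[idx, 2L])))
  })
}

#' Extract one component as a standalone instance
#'
#' @param x an `hdx_instance`.
#' @param component one element of [decompose_subproblems()].
#' @return an `hdx_instance` over the same residue numbering restricted to
#'   the component's fragments.
#' @export
subproblem_instance <- function(x, component) {
  hdx_instance(x$n, x$fragments[component$fragments, , drop = FALSE],
               x$requirements[component$fragments, , drop = FALSE],
               color_names = x$color_names, residue_labels = x$residue_labels)
}
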