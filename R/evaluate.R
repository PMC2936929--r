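#' Error of a residue-level assignment
#'
#' For every fragment \eqn{f} and color \eqn{k} the error is
#' \eqn{e_f^k = | b_f^k - \#\{l \in f : \pi(l) = k\} |}: the surplus or
#' shortage of residues of class \eqn{k} inside the fragment relative to the
#' measured count. The objective minimized by all solvers is the sum of
#' these deviations over fragments and colors.
#'
#' @param x an `hdx_instance`.
#' @param assignment an [hdx_assignment()] defined on every covered residue.
#' @return an `hdx_error_report`: list with `e` (|F| x K matrix) and `total`.
#' @examples
#' inst <- hdx_instance(3, rbind(c(1, 3)), rbind(c(1, 1, 1)))
#' evaluate_assignment(inst, hdx_assignment(c(1, 1, 1)))$total
#' @export
evaluate_assignment <- function(x, assignment) {
  stopifnot(inherits(x, "hdx_instance"))
  part <- compute_parts(x)
  miss <- setdiff(part$covered, as.integer(names(assignment)))
  if (length(miss))
    stop("assignment missing covered residue(s): ", paste(head(miss, 5L), collapse = ", "))
  Fn <- nrow(x$fragments)
  e <- matrix(0L, Fn, x$K, dimnames = list(NULL, x$color_names))
  pi_full <- rep(NA_integer_, x$n)
  pi_full[as.integer(names(assignment))] <- unclass(assignment)
  for (f in seq_len(Fn)) {
    cnt <- tabulate(pi_full[x$fragments[f, 1L]:x$fragments[f, 2L]], nbins = x$K)
    e[f, ] <- abs(x$requirements[f, ] - cnt)
  }
  structure(list(e = e, total = sum(e)), class = "hdx_error_report")
}

#' @export
print.hdx_error_report <- function(x, ...) {
  cat("HDX error report: total error", x$total, "over", nrow(x$e), "fragments\n")
  invisible(x)
}

#' Per-part color counts of an assignment
#'
#' Aggregates a residue-level assignment into the count solution
#' \eqn{y_p^k = \#\{l \in p : \pi(l) = k\}}. The error of an assignment
#' depends on it only through these counts, so the count matrix is the
#' canonical representative of the assignment's equivalence class.
#'
#' @param partition an `hdx_partition`.
#' @param assignment an [hdx_assignment()] covering the partition.
#' @param K number of colors.
#' @return integer |P| x K matrix `y` with row sums equal to the part sizes.
#' @export
counts_from_assignment <- function(partition, assignment, K) {
  m <- length(partition$parts)
  y <- matrix(0L, m, K)
  pi_map <- unclass(assignment)
  res <- as.integer(names(assignment))
  for (p in seq_len(m)) {
    idx <- match(partition$parts[[p]], res)
    if (anyNA(idx)) stop("assignment missing residues of part ", p)
    y[p, ] <- tabulate(pi_map[idx], nbins = K)
  }
  y
}

#' Error of a count solution
#'
#' Same objective as [evaluate_assignment()], computed from per-part counts:
#' \eqn{e_f^k = | b_f^k - \sum_{p \subseteq f} y_p^k |}.
#'
#' @param x an `hdx_instance`.
#' @param partition the partition of `x` (from [compute_parts()]).
#' @param y |P| x K count matrix.
#' @return an `hdx_error_report`.
#' @export
error_from_counts <- function(x, partition, y) {
  cnt <- partition$A %*% y
  e <- abs(x$requirements - cnt)
  structure(list(e = e, total = sum(e)), class = "hdx_error_report")
}

#' One canonical residue assignment of a count solution
#'
#' Within each part, colors are laid out in ascending color order along
#' ascending residue index.
#'
#' @param partition an `hdx_partition`.
#' @param y |P| x K count matrix.
#' @return an [hdx_assignment()].
#' @export
assignment_from_counts <- function(partition, y) {
  res <- integer(0); cols <- integer(0)
  for (p in seq_along(partition$parts)) {
    res <- c(res, partition$parts[[p]])
    cols <- c(cols, rep(seq_len(ncol(y)), times = y[p, ]))
  }
  hdx_assignment(cols, res)
}

#' Number of residue-level assignments in an equivalence class
#'
#' Two assignments are equivalent when one arises from the other by
#' permuting colors within parts; a count solution `y` represents
#' \eqn{\prod_p |p|! / \prod_k y_p^k!} distinct residue-level colorings.
#'
#' @param partition an `hdx_partition`.
#' @param y |P| x K count matrix.
#' @return the expansion count (numeric; exact for realistic sizes).
#' @examples
#' # one part of three residues, one residue per class: 3! = 6 orderings
#' @export
count_expansions <- function(partition, y) {
  if (any(rowSums(y) != partition$sizes))
    stop("row sums of y must equal the part sizes")
  out <- 1
  for (p in seq_along(partition$sizes))
    out <- out * exp(lfactorial(partition$sizes[p]) - sum(lfactorial(y[p, ])))
  round(out)
}

#' Expand a count solution into all equivalent residue assignments
#'
#' Enumerates every residue-level coloring in the equivalence class of `y`
#' (all distinct within-part color orderings). Intended for small parts;
#' the number of expansions is [count_expansions()].
#'
#' @param partition an `hdx_partition`.
#' @param y |P| x K count matrix.
#' @return list of [hdx_assignment()] objects.
#' @export
expand_counts <- function(partition, y) {
  per_part <- lapply(seq_along(partition$parts), function(p)
    multiset_permutations(rep(seq_len(ncol(y)), times = y[p, ])))
  combos <- list(integer(0))
  for (p in seq_along(per_part)) {
    combos <- unlist(lapply(combos, function(pref)
      lapply(per_part[[p]], function(perm) c(pref, perm))), recursive = FALSE)
  }
  res <- unlist(partition$parts)
  lapply(combos, function(cols) hdx_assignment(cols, res))
}

# all distinct orderings of a multiset of color indices
multiset_permutations <- function(v) {
  v <- sort(v)
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (u in unique(v)) {
    rest <- v[-match(u, v)]
    for (tail in multiset_permutations(rest)) out[[length(out) + 1L]] <- c(u, tail)
  }
  out
}
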