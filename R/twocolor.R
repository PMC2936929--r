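#' Two-color requirement reduction
#'
#' For K = 2 the per-part counts of the second color are determined by the
#' first (`y2 = |p| - y1`), and the two error terms of a fragment collapse
#' onto a corridor: with upper target `b = max(b1, F - b2)` and lower target
#' `bbar = min(b1, F - b2)` (componentwise, `F` the fragment sizes), any `y`
#' inside `[bbar, b]` pays the fixed cost `b - bbar`, and each unit above
#' `b` or below `bbar` pays 2. Hence
#' `total error = sum(b - bbar) + 2 * (corridor LP optimum)`.
#'
#' @param b1,b2 per-fragment requirement vectors for the two colors.
#' @param F per-fragment sizes (residues available to the fragment).
#' @return list with `b`, `bbar`, `F`, and `constant = sum(b - bbar)`.
#' @examples
#' reduce_two_color(5, 3, 8)  # consistent counts: b == bbar == 5
#' @export
reduce_two_color <- function(b1, b2, F) {
  if (length(b1) != length(b2) || length(b1) != length(F))
    stop("b1, b2 and F must have equal length")
  if (any(b1 < 0) || any(b2 < 0)) stop("requirements must be nonnegative")
  b <- pmax(b1, F - b2)
  bbar <- pmin(b1, F - b2)
  list(b = b, bbar = bbar, F = F, constant = sum(b - bbar))
}

#' Build the fragment graph of the two-color LP
#'
#' The corridor LP is solved through its dual, a minimum-cost circulation on
#' a graph with |P| + 1 nodes: per part `p` (position i) the arc pair
#' `(i, i+1)` (cost 0) and `(i+1, i)` (cost |p|) encodes `0 <= y_p <= |p|`;
#' per fragment spanning part positions `i..j` the arcs `(j+1, i)` (cost
#' `b_f`, capacity 1) and `(i, j+1)` (cost `-bbar_f`, capacity 1) charge the
#' unit error rates outside the corridor. Optimal y-values are differences
#' of neighboring node potentials of an optimal circulation.
#'
#' @param partition an `hdx_partition`.
#' @param reduction output of [reduce_two_color()].
#' @return an `hdx_fragment_graph`: list with `n_nodes` and an `arcs` data
#'   frame (`tail`, `head`, `capacity`, `cost`, `type`).
#' @export
build_fragment_graph <- function(partition, reduction) {
  m <- length(partition$sizes)
  if (m == 0L)
    return(structure(list(n_nodes = 0L,
                          arcs = data.frame(tail = integer(), head = integer(),
                                            capacity = numeric(), cost = numeric(),
                                            type = character())),
                     class = "hdx_fragment_graph"))
  fp <- partition$frag_parts
  arcs <- rbind(
    data.frame(tail = seq_len(m), head = seq_len(m) + 1L,
               capacity = Inf, cost = 0, type = "part_lower"),
    data.frame(tail = seq_len(m) + 1L, head = seq_len(m),
               capacity = Inf, cost = as.numeric(partition$sizes), type = "part_upper"),
    if (nrow(fp)) data.frame(tail = fp[, "last"] + 1L, head = fp[, "first"],
                             capacity = 1, cost = as.numeric(reduction$b),
                             type = "frag_over"),
    if (nrow(fp)) data.frame(tail = fp[, "first"], head = fp[, "last"] + 1L,
                             capacity = 1, cost = -as.numeric(reduction$bbar),
                             type = "frag_under"))
  structure(list(n_nodes = m + 1L, arcs = arcs), class = "hdx_fragment_graph")
}

#' @export
print.hdx_fragment_graph <- function(x, ...) {
  cat("HDX fragment graph:", x$n_nodes, "nodes,", nrow(x$arcs), "arcs\n")
  invisible(x)
}

#' Export a fragment graph in DOT format
#'
#' @param graph an `hdx_fragment_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph_dot <- function(graph, path) {
  a <- graph$arcs
  lines <- c("digraph fragment_graph {",
             sprintf("  %d -> %d [label=\"cap=%s cost=%g\" class=\"%s\"];",
                     a$tail, a$head, ifelse(is.finite(a$capacity),
                                            format(a$capacity), "inf"),
                     a$cost, a$type),
             "}")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# corridor LP over parts with box bounds [lo, hi] on y:
#   min sum_f (y(f) - b_f)_+ + (bbar_f - y(f))_+ ,  y(f) = sum of y_p over f
# solved via the fragment-graph circulation after shifting y by lo.
twocolor_box_lp <- function(sizes, frag_parts, b, bbar, lo, hi) {
  m <- length(sizes)
  if (m == 0L) return(list(value = 0, y = numeric(0)))
  shift <- vapply(seq_len(nrow(frag_parts)), function(f)
    sum(lo[frag_parts[f, 1L]:frag_parts[f, 2L]]), numeric(1L))
  r <- .frag_lp_cpp(as.numeric(hi - lo),
                    as.integer(frag_parts[, 1L]), as.integer(frag_parts[, 2L]),
                    as.numeric(b) - shift, as.numeric(bbar) - shift,
                    numeric(0))
  list(value = r$value, y = lo + r$y)
}

#' Exact two-color solver via minimum-cost circulation
#'
#' Polynomial-time exact solver for K = 2. The corridor LP's constraint
#' matrix is totally unimodular, so its LP optimum is integral and equals
#' the integer optimum; the reported total error is
#' `constant + 2 * circulation cost`. Among multiple optimal count
#' solutions the lexicographically smallest (by part position, color 1
#' count) is returned.
#'
#' @param x an `hdx_instance` with `K = 2`.
#' @param partition optionally a precomputed partition of `x`.
#' @return list with `optimum` (integer total error), `y` (|P| x 2 counts),
#'   `constant`, `circulation_cost`, `partition`.
#' @export
solve_two_color <- function(x, partition = NULL) {
  stopifnot(inherits(x, "hdx_instance"))
  if (x$K != 2L)
    stop("solve_two_color requires K = 2; use the heuristic or ILP solvers for K > 2")
  if (is.null(partition)) partition <- compute_parts(x)
  m <- length(partition$sizes)
  red <- reduce_two_color(x$requirements[, 1L], x$requirements[, 2L],
                          fragment_lengths(x))
  if (m == 0L)
    return(list(optimum = red$constant, y = matrix(integer(), 0L, 2L),
                constant = red$constant, circulation_cost = 0,
                partition = partition))
  fp <- partition$frag_parts
  base <- twocolor_box_lp(partition$sizes, fp, red$b, red$bbar,
                          rep(0, m), as.numeric(partition$sizes))
  target <- base$value
  # lexicographic refinement: fix parts left to right at their smallest
  # y1 preserving optimality; the box LP value is convex in each bound,
  # so binary search finds the leftmost optimal value
  lo <- rep(0, m); hi <- as.numeric(partition$sizes)
  for (p in seq_len(m)) {
    lo_p <- 0; hi_p <- base$y[p]
    while (lo_p < hi_p) {
      mid <- floor((lo_p + hi_p) / 2)
      l2 <- lo; h2 <- hi; l2[p] <- mid; h2[p] <- mid
      v <- twocolor_box_lp(partition$sizes, fp, red$b, red$bbar, l2, h2)$value
      if (v <= target + 1e-9) hi_p <- mid else lo_p <- mid + 1
    }
    lo[p] <- hi[p] <- lo_p
    base <- twocolor_box_lp(partition$sizes, fp, red$b, red$bbar, lo, hi)
  }
  y1 <- as.integer(round(lo))
  y <- cbind(y1, partition$sizes - y1)
  colnames(y) <- x$color_names
  list(optimum = as.integer(round(red$constant + 2 * target)),
       y = y, constant = red$constant, circulation_cost = target,
       partition = partition)
}
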