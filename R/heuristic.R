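#' Merge all but one color into a two-color instance
#'
#' The recursive heuristic reduces the K-color problem to two colors by
#' keeping color `k` and pooling the remaining classes: the merged
#' right-hand sides are `(b^k, sum of the other b^k')`.
#'
#' @param x an `hdx_instance`.
#' @param k color index to isolate.
#' @return an `hdx_instance` with `K = 2` and colors `(k, "rest")`.
#' @examples
#' inst <- hdx_instance(8, rbind(c(1, 8)), rbind(c(5, 2, 1)))
#' merge_requirements_for_color(inst, 1)$requirements  # (5, 3)
#' @export
merge_requirements_for_color <- function(x, k) {
  stopifnot(inherits(x, "hdx_instance"))
  if (!(k %in% seq_len(x$K))) stop("invalid color index k = ", k)
  if (x$K == 2L && k == 1L) return(x)
  b1 <- x$requirements[, k, drop = FALSE]
  b2 <- rowSums(x$requirements[, -k, drop = FALSE])
  suppressWarnings(hdx_instance(x$n, x$fragments, cbind(b1, b2),
                                color_names = c(x$color_names[k], "rest"),
                                residue_labels = x$residue_labels))
}

#' Recursive color-merging heuristic
#'
#' Fixes colors one at a time in a given order: for the current color `k`
#' the two-color problem "k versus the pooled remaining colors" is solved
#' exactly by the circulation solver on the remaining part capacities;
#' part counts assigned `k` are frozen and removed from the capacities, and
#' the remaining colors are solved recursively. With the default
#' `order = "all"` every permutation of the colors is tried (capped at
#' K <= 4; beyond that a fixed order by descending total requirement is
#' used) and the best result returned. The reported error is always the
#' exact objective of the final counts, never a sum of stage objectives.
#' The heuristic carries no approximation guarantee, but in practice it
#' frequently attains the optimum.
#'
#' @param x an `hdx_instance`.
#' @param order `"all"`, or an integer permutation of `1..K`.
#' @return list with `y` (|P| x K counts), `error` (exact total error),
#'   `order` (the winning permutation), `partition`.
#' @export
heuristic_solve <- function(x, order = "all") {
  stopifnot(inherits(x, "hdx_instance"))
  partition <- compute_parts(x)
  orders <- heuristic_orders(x, order)
  best <- NULL
  for (ord in orders) {
    y <- heuristic_one_order(x, partition, ord)
    err <- error_from_counts(x, partition, y)$total
    if (is.null(best) || err < best$error) {
      best <- list(y = y, error = err, order = ord, partition = partition)
    }
  }
  colnames(best$y) <- x$color_names
  best
}

heuristic_orders <- function(x, order) {
  K <- x$K
  if (identical(order, "all")) {
    if (K <= 4L) {
      perms <- all_permutations(K)
    } else {
      perms <- list(order(-colSums(x$requirements)))
    }
    return(perms)
  }
  ord <- as.integer(order)
  if (!identical(sort(ord), seq_len(K)))
    stop("`order` must be 'all' or a permutation of 1..K")
  list(ord)
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  out <- list()
  for (first in seq_len(K)) {
    for (rest in all_permutations(K - 1L)) {
      tail <- seq_len(K)[-first][rest]
      out[[length(out) + 1L]] <- c(first, tail)
    }
  }
  out
}

# one pass of the heuristic for a fixed color order, at part granularity
heuristic_one_order <- function(x, partition, ord) {
  m <- length(partition$sizes)
  K <- x$K
  y <- matrix(0L, m, K)
  if (m == 0L) return(y)
  caps <- as.numeric(partition$sizes)
  fp <- partition$frag_parts
  remaining <- ord
  while (length(remaining) > 1L) {
    k <- remaining[1L]
    b1 <- as.numeric(x$requirements[, k])
    b2 <- rowSums(x$requirements[, remaining[-1L], drop = FALSE])
    Fv <- vapply(seq_len(nrow(fp)), function(f)
      sum(caps[fp[f, 1L]:fp[f, 2L]]), numeric(1L))
    red <- reduce_two_color(b1, b2, Fv)
    sol <- twocolor_lex_min(caps, fp, red$b, red$bbar)
    y[, k] <- as.integer(round(sol))
    caps <- caps - sol
    remaining <- remaining[-1L]
  }
  y[, remaining] <- as.integer(round(caps))
  y
}

# lexicographically smallest optimal y for the corridor LP under capacities
twocolor_lex_min <- function(caps, frag_parts, b, bbar) {
  m <- length(caps)
  lo <- rep(0, m); hi <- caps
  base <- twocolor_box_lp(caps, frag_parts, b, bbar, lo, hi)
  target <- base$value
  for (p in seq_len(m)) {
    lo_p <- 0; hi_p <- base$y[p]
    while (lo_p < hi_p) {
      mid <- floor((lo_p + hi_p) / 2)
      l2 <- lo; h2 <- hi; l2[p] <- mid; h2[p] <- mid
      v <- twocolor_box_lp(caps, frag_parts, b, bbar, l2, h2)$value
      if (v <= target + 1e-9) hi_p <- mid else lo_p <- mid + 1
    }
    lo[p] <- hi[p] <- lo_p
    base <- twocolor_box_lp(caps, frag_parts, b, bbar, lo, hi)
  }
  lo
}
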