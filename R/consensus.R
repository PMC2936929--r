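#' Discretize exchange rates into classes
#'
#' Reference rates in 1/h are mapped onto the three standard classes with
#' inclusive extreme boundaries: slow for rates <= 0.1 1/h, fast for rates
#' >= 8 1/h, medium in between. Missing rates stay missing.
#'
#' @param rates numeric vector of nonnegative rates (1/h), `NA` = missing.
#' @param slow_max upper rate bound of the slow class (1/h).
#' @param fast_min lower rate bound of the fast class (1/h).
#' @return integer vector of classes (1 = slow, 2 = medium, 3 = fast).
#' @examples
#' discretize_rates(c(0.05, 0.1, 1, 8, 20))  # 1 1 2 3 3
#' @export
discretize_rates <- function(rates, slow_max = 0.1, fast_min = 8) {
  if (any(rates < 0, na.rm = TRUE)) stop("exchange rates must be nonnegative")
  out <- rep(NA_integer_, length(rates))
  out[!is.na(rates) & rates <= slow_max] <- 1L
  out[!is.na(rates) & rates >= fast_min] <- 3L
  out[!is.na(rates) & rates > slow_max & rates < fast_min] <- 2L
  out
}

#' Consensus over an enumerated solution set
#'
#' Condenses all optimal solutions into a single per-part prediction:
#' * `single`: the first solution in canonical order.
#' * `majority`: per part, the |p| residue slots are apportioned to colors
#'   by largest remainder on the (optionally expansion-weighted) summed
#'   counts.
#' * `mean`: per part, each solution's colors are laid out in ascending
#'   order over the residue slots, the weighted mean color ordinal of each
#'   slot is rounded half-to-even, and the resulting slot colors are
#'   re-expressed as counts.
#'
#' Weighting `"class"` gives every equivalence class one vote; `"expanded"`
#' weights each class by the number of residue-level assignments it
#' represents.
#'
#' @param solutions an `hdx_solution_set` (improved level).
#' @param method `"single"`, `"majority"` or `"mean"`.
#' @param weighting `"class"` or `"expanded"`.
#' @return an `hdx_consensus`: list with `y` (|P| x K counts), `method`,
#'   `weighting`, `partition`.
#' @export
consensus <- function(solutions, method = c("single", "majority", "mean"),
                      weighting = c("class", "expanded")) {
  method <- match.arg(method)
  weighting <- match.arg(weighting)
  if (!inherits(solutions, "hdx_solution_set")) stop("need an hdx_solution_set")
  if (solutions$n_solutions == 0L) stop("empty solution set")
  sols <- solutions$solutions
  partition <- solutions$partition
  w <- if (weighting == "expanded") as.numeric(solutions$expansions)
       else rep(1, length(sols))
  K <- ncol(sols[[1L]])
  m <- nrow(sols[[1L]])
  y <- switch(method,
    single = sols[[1L]],
    majority = {
      tot <- Reduce(`+`, Map(function(s, wi) wi * s, sols, w))
      t(vapply(seq_len(m), function(p)
        largest_remainder(tot[p, ], partition$sizes[p]), integer(K)))
    },
    mean = {
      out <- matrix(0L, m, K)
      for (p in seq_len(m)) {
        slots <- vapply(sols, function(s)
          rep(seq_len(K), times = s[p, ]), numeric(partition$sizes[p]))
        slots <- matrix(slots, nrow = partition$sizes[p])
        mean_ord <- as.numeric(slots %*% w) / sum(w)
        cols <- pmin(pmax(round(mean_ord), 1L), K)  # round() = half-to-even
        out[p, ] <- tabulate(cols, nbins = K)
      }
      out
    })
  structure(list(y = matrix(as.integer(y), m, K), method = method,
                 weighting = weighting, partition = partition),
            class = "hdx_consensus")
}

# apportion `seats` by largest remainder of nonnegative scores;
# remainder ties broken by lower color index
largest_remainder <- function(scores, seats) {
  if (seats == 0L) return(integer(length(scores)))
  if (sum(scores) == 0) scores <- rep(1, length(scores))
  quota <- scores / sum(scores) * seats
  base <- floor(quota)
  left <- seats - sum(base)
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(scores))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' @export
print.hdx_consensus <- function(x, ...) {
  cat("HDX consensus (", x$method, ", weighting ", x$weighting, ") over ",
      nrow(x$y), " parts\n", sep = "")
  invisible(x)
}

#' Per-part agreement with a reference assignment
#'
#' Within a part, colors may be permuted freely, so prediction and
#' reference are compared as multisets: the matched count is
#' `sum_k min(predicted_k, reference_k)` (the optimal within-part
#' ordering). Residues with missing reference are excluded from both the
#' match and the denominator. The score is
#' `100 * sum_p matched_p / sum_p compared_p`.
#'
#' @param prediction an `hdx_consensus` (or a |P| x K count matrix).
#' @param reference integer vector of per-residue reference classes over
#'   the whole protein (`NA` = missing), e.g. from [discretize_rates()].
#' @param partition an `hdx_partition` (taken from `prediction` if absent).
#' @return list with `score` (percentage, `NA` when nothing is comparable),
#'   `matched`, `compared`, and a per-part data frame `parts` with symbols
#'   `0` (agree), `X` (disagree), `?` (reference missing).
#' @export
agreement_score <- function(prediction, reference, partition = NULL) {
  if (inherits(prediction, "hdx_consensus")) {
    if (is.null(partition)) partition <- prediction$partition
    y <- prediction$y
  } else y <- prediction
  if (is.null(partition)) stop("a partition is required")
  K <- ncol(y)
  m <- nrow(y)
  matched <- compared <- integer(m)
  for (p in seq_len(m)) {
    ref <- reference[partition$parts[[p]]]
    ref <- ref[!is.na(ref)]
    if (!length(ref)) next
    rc <- tabulate(ref, nbins = K)
    matched[p] <- sum(pmin(y[p, ], rc))
    compared[p] <- length(ref)
  }
  score <- if (sum(compared) == 0L) NA_real_
           else 100 * sum(matched) / sum(compared)
  parts <- data.frame(part = seq_len(m),
                      size = if (m) partition$sizes else integer(0),
                      matched = matched, compared = compared,
                      symbol = ifelse(compared == 0L, "?",
                                      ifelse(matched == compared, "0", "X")))
  list(score = score, matched = sum(matched), compared = sum(compared),
       parts = parts)
}

#' Per-residue comparison table in the style of a single-residue report
#'
#' Expands a consensus prediction to residues (canonical within-part
#' order), aligns it with the reference, and marks each residue `0`
#' (agree), `X` (disagree), `?` (reference missing) or `-` (no prediction).
#'
#' @param prediction an `hdx_consensus`.
#' @param reference per-residue reference classes (`NA` = missing).
#' @param n protein length.
#' @param color_names class labels.
#' @return data frame with residue, predicted, reference, symbol.
#' @export
residue_comparison <- function(prediction, reference, n,
                               color_names = c("slow", "medium", "fast")) {
  pred <- rep(NA_integer_, n)
  part <- prediction$partition
  for (p in seq_len(nrow(prediction$y))) {
    res <- part$parts[[p]]
    pred[res] <- rep(seq_len(ncol(prediction$y)), times = prediction$y[p, ])
  }
  symbol <- ifelse(is.na(pred), "-",
                   ifelse(is.na(reference), "?",
                          ifelse(pred == reference, "0", "X")))
  data.frame(residue = seq_len(n),
             predicted = ifelse(is.na(pred), NA, color_names[pred]),
             reference = ifelse(is.na(reference), NA, color_names[reference]),
             symbol = symbol)
}
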