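#' Build the integer linear program of an instance
#'
#' Two formulations of the minimum-total-error problem:
#' * `basic`: one binary variable per covered residue and color, plus one
#'   error variable per fragment and color; every residue gets exactly one
#'   color, and each fragment/color error bounds the absolute deviation of
#'   the residue count from the requirement.
#' * `improved`: the binaries of each part are aggregated into a single
#'   integer count variable `y_p^k` with bounds `[0, |p|]`; solutions are
#'   equivalence classes of residue assignments, which shrinks the solution
#'   set by the product of within-part multinomials.
#'
#' Both share one engine: the basic formulation is the improved one on the
#' trivial partition of singleton parts.
#'
#' @param x an `hdx_instance`.
#' @param formulation `"improved"` or `"basic"`.
#' @return an `hdx_ilp_model` (sizes, fragment spans in unit coordinates,
#'   requirements, partition, variable bookkeeping).
#' @export
build_ilp <- function(x, formulation = c("improved", "basic")) {
  formulation <- match.arg(formulation)
  partition <- compute_parts(x)
  if (formulation == "improved") {
    sizes <- as.integer(partition$sizes)
    fp <- partition$frag_parts
  } else {
    # singleton units: one per covered residue, in residue order
    sizes <- rep(1L, length(partition$covered))
    pos <- match(seq_len(x$n), partition$covered)
    fp <- cbind(first = pos[x$fragments[, 1L]], last = pos[x$fragments[, 2L]])
    if (nrow(x$fragments) == 0L) fp <- matrix(integer(), 0L, 2L,
                                              dimnames = list(NULL, c("first", "last")))
  }
  structure(list(formulation = formulation, sizes = sizes, frag_parts = fp,
                 b = x$requirements, K = x$K, partition = partition,
                 n_vars = length(sizes) * x$K + nrow(x$fragments) * x$K),
            class = "hdx_ilp_model")
}

#' @export
print.hdx_ilp_model <- function(x, ...) {
  cat("HDX ", x$formulation, "-ILP: ", length(x$sizes) * x$K,
      " count variables, ", nrow(x$b) * x$K, " error variables\n", sep = "")
  invisible(x)
}

# LP relaxation of the (box-restricted) improved model.
#   vars: y (m*K, bounds appended as rows), e (Fn*K)
#   A y^k - e^k <= b^k ; A y^k + e^k >= b^k ; sum_k y_p^k = size_p
# an optional total-error cap supports enumeration at a bound.
ilp_lp_relax <- function(model, lo, hi, error_cap = NULL) {
  m <- length(model$sizes); K <- model$K; Fn <- nrow(model$b)
  nv <- m * K + Fn * K
  yi <- function(p, k) (k - 1L) * m + p
  ei <- function(f, k) m * K + (k - 1L) * Fn + f
  rows <- list(); dir <- character(0); rhs <- numeric(0)
  add <- function(row, d, r) {
    rows[[length(rows) + 1L]] <<- row; dir <<- c(dir, d); rhs <<- c(rhs, r)
  }
  for (k in seq_len(K)) for (f in seq_len(Fn)) {
    row <- numeric(nv)
    row[yi(model$frag_parts[f, 1L]:model$frag_parts[f, 2L], k)] <- 1
    row[ei(f, k)] <- -1
    add(row, "<=", model$b[f, k])
    row[ei(f, k)] <- 1
    add(row, ">=", model$b[f, k])
  }
  for (p in seq_len(m)) {
    row <- numeric(nv); row[yi(p, seq_len(K))] <- 1
    add(row, "==", model$sizes[p])
  }
  for (p in seq_len(m)) for (k in seq_len(K)) {
    if (is.finite(hi[p, k])) {
      row <- numeric(nv); row[yi(p, k)] <- 1
      add(row, "<=", hi[p, k])
    }
    if (lo[p, k] > 0) {
      row <- numeric(nv); row[yi(p, k)] <- 1
      add(row, ">=", lo[p, k])
    }
  }
  obj <- c(numeric(m * K), rep(1, Fn * K))
  if (!is.null(error_cap)) add(obj, "<=", error_cap)
  res <- lp_solve(obj, do.call(rbind, rows), dir, rhs)
  if (res$status != "optimal") return(res)
  res$y <- matrix(res$x[seq_len(m * K)], m, K)
  res
}

#' LP-relaxation value of an instance
#'
#' Solves the linear relaxation of the chosen formulation (no integrality).
#' For K = 2 the relaxation value equals the integer optimum (total
#' unimodularity); for K >= 3 it can be strictly smaller — there are
#' instances with relaxation value 0 but positive integer optimum.
#'
#' @param x an `hdx_instance`.
#' @param formulation `"improved"` or `"basic"`.
#' @return the relaxation optimum (numeric).
#' @export
lp_relaxation_value <- function(x, formulation = "improved") {
  model <- build_ilp(x, formulation)
  m <- length(model$sizes); K <- model$K
  lo <- matrix(0, m, K)
  hi <- matrix(model$sizes, m, K)
  res <- ilp_lp_relax(model, lo, hi)
  if (res$status != "optimal") stop("LP backend did not solve the relaxation: ",
                                    res$status)
  res$value
}

# cheap combinatorial lower bound for a box: each fragment/color must err by
# at least the gap between b and the reachable count interval
ilp_cheap_bound <- function(model, lo, hi) {
  Fn <- nrow(model$b)
  if (Fn == 0L) return(0)
  lb <- 0
  for (f in seq_len(Fn)) {
    span <- model$frag_parts[f, 1L]:model$frag_parts[f, 2L]
    cmin <- colSums(lo[span, , drop = FALSE])
    cmax <- colSums(hi[span, , drop = FALSE])
    lb <- lb + sum(pmax(0, model$b[f, ] - cmax, cmin - model$b[f, ]))
  }
  lb
}

# tighten a box with the linking constraints sum_k y_p^k = size_p;
# returns NULL when the box becomes empty
propagate_box <- function(sizes, lo, hi) {
  repeat {
    nlo <- pmax(lo, sizes - (rowSums(hi) - hi))
    nhi <- pmin(hi, sizes - (rowSums(lo) - lo))
    if (any(nlo > nhi)) return(NULL)
    if (all(nlo == lo) && all(nhi == hi)) return(list(lo = nlo, hi = nhi))
    lo <- nlo; hi <- nhi
  }
}

# shared branch-and-bound engine over the aggregated model.
# mode "solve": return one optimal solution; mode "enumerate": all integral
# solutions with error <= bound. Nodes carry a box [lo, hi]; the LP
# relaxation prunes, fractional-variable branching follows the
# closest-to-0.5 rule, integral relaxations branch on the lowest unfixed
# variable by a <=v / >=v+1 domain split.
ilp_bnb <- function(model, mode = c("solve", "enumerate"), bound = Inf,
                    node_limit = 1e6) {
  mode <- match.arg(mode)
  m <- length(model$sizes); K <- model$K
  sizes <- as.numeric(model$sizes)
  if (m == 0L) {
    opt <- sum(model$b)
    sols <- if (mode == "enumerate" && opt <= bound) list(matrix(integer(), 0L, K))
            else if (mode == "solve") list(matrix(integer(), 0L, K)) else list()
    return(list(optimum = opt, solutions = sols))
  }
  incumbent <- Inf; inc_y <- NULL
  found <- list(); seen <- new.env(hash = TRUE, parent = emptyenv())
  root <- propagate_box(sizes, matrix(0, m, K),
                        matrix(sizes, m, K))
  if (is.null(root)) stop("instance admits no count solution")
  stack <- list(root)
  nodes <- 0L
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) stop("branch-and-bound node limit exceeded")
    lo <- nd$lo; hi <- nd$hi
    cheap <- ilp_cheap_bound(model, lo, hi)
    if (mode == "solve" && cheap >= incumbent) next
    if (mode == "enumerate" && cheap > bound) next
    if (all(lo == hi)) {
      err <- sum(abs(model$b - span_counts(model, lo)))
      if (mode == "solve") {
        if (err < incumbent) { incumbent <- err; inc_y <- lo }
      } else if (err <= bound) {
        key <- paste(as.integer(t(lo)), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          found[[length(found) + 1L]] <- matrix(as.integer(lo), m, K)
        }
      }
      next
    }
    rel <- ilp_lp_relax(model, lo, hi,
                        error_cap = if (mode == "enumerate" && is.finite(bound)) bound)
    if (rel$status == "infeasible") next
    if (rel$status == "failed") {
      rel <- NULL               # fall back to pure domain splitting
    } else {
      lpv <- ceiling(rel$value - 1e-6)
      if (mode == "solve" && lpv >= incumbent) next
      if (mode == "enumerate" && lpv > bound) next
    }
    sel <- select_branch_var(if (is.null(rel)) NULL else rel$y, lo, hi)
    if (mode == "solve" && !is.null(rel) && sel$integral) {
      # integral relaxation: its value is attained by an integral solution
      yint <- round(rel$y)
      if (!is.null(propagate_check(sizes, yint)) &&
          all(yint >= lo - 1e-9) && all(yint <= hi + 1e-9)) {
        err <- sum(abs(model$b - span_counts(model, yint)))
        if (err < incumbent) { incumbent <- err; inc_y <- yint }
        if (err <= ceiling(rel$value - 1e-6)) next
      }
    }
    v <- sel$value
    p <- sel$p; k <- sel$k
    split <- min(max(floor(v + 1e-9), lo[p, k]), hi[p, k] - 1)
    left <- list(lo = lo, hi = hi); left$hi[p, k] <- split
    right <- list(lo = lo, hi = hi); right$lo[p, k] <- split + 1
    for (child in list(right, left)) {
      pb <- propagate_box(sizes, child$lo, child$hi)
      if (!is.null(pb)) stack[[length(stack) + 1L]] <- pb
    }
  }
  if (mode == "solve") {
    if (is.null(inc_y)) stop("no feasible count solution found")
    list(optimum = as.integer(incumbent),
         solutions = list(matrix(as.integer(inc_y), m, K)))
  } else {
    list(optimum = if (length(found))
           min(vapply(found, function(y) sum(abs(model$b - span_counts(model, y))),
                      numeric(1L))) else NA_integer_,
         solutions = canonical_sort(found))
  }
}

span_counts <- function(model, y) {
  Fn <- nrow(model$b)
  out <- matrix(0, Fn, model$K)
  for (f in seq_len(Fn))
    out[f, ] <- colSums(y[model$frag_parts[f, 1L]:model$frag_parts[f, 2L], ,
                          drop = FALSE])
  out
}

propagate_check <- function(sizes, y) {
  if (all(abs(rowSums(y) - sizes) < 1e-9)) y else NULL
}

# branching variable: fractional part closest to 0.5, ties by lowest part
# then color; with an integral (or absent) relaxation, the lowest unfixed
# variable
select_branch_var <- function(ylp, lo, hi) {
  un <- which(hi - lo > 1e-9, arr.ind = TRUE)
  if (!is.null(ylp)) {
    fr <- ylp - floor(ylp + 1e-9)
    frac <- which(fr > 1e-6 & fr < 1 - 1e-6 & hi - lo > 1e-9, arr.ind = TRUE)
    if (nrow(frac)) {
      d <- abs(fr[frac] - 0.5)
      ordx <- order(d, frac[, 1L], frac[, 2L])
      p <- frac[ordx[1L], 1L]; k <- frac[ordx[1L], 2L]
      return(list(p = p, k = k, value = ylp[p, k], integral = FALSE))
    }
  }
  ordx <- order(un[, 1L], un[, 2L])
  p <- un[ordx[1L], 1L]; k <- un[ordx[1L], 2L]
  v <- if (is.null(ylp)) (lo[p, k] + hi[p, k]) / 2 else ylp[p, k]
  list(p = p, k = k, value = v, integral = TRUE)
}

canonical_sort <- function(sols) {
  if (length(sols) <= 1L) return(sols)
  keys <- vapply(sols, function(y) paste(sprintf("%06d", as.integer(t(y))),
                                         collapse = ","), character(1L))
  sols[order(keys)]
}

#' Exact minimum-error solve
#'
#' Branch-and-bound over the chosen ILP formulation with LP relaxations
#' (solved by the `boot` simplex backend) as bounds. Both formulations
#' yield the same optimum; the improved one is the default. With
#' `decompose = TRUE` the instance is first split into independent
#' subproblems whose optima add up.
#'
#' @param x an `hdx_instance`.
#' @param formulation `"improved"` or `"basic"`.
#' @param decompose solve independent subproblems separately.
#' @return list with `optimum`, `y` (|P| x K counts on the full partition),
#'   `partition`, and `per_subproblem` (when decomposed).
#' @export
solve_min_error <- function(x, formulation = c("improved", "basic"),
                            decompose = TRUE) {
  formulation <- match.arg(formulation)
  partition <- compute_parts(x)
  if (!decompose || nrow(x$fragments) == 0L) {
    model <- build_ilp(x, formulation)
    r <- ilp_bnb(model, "solve")
    y <- model_counts_to_partition(model, r$solutions[[1L]], partition)
    return(list(optimum = r$optimum, y = y, partition = partition,
                per_subproblem = NULL))
  }
  comps <- decompose_subproblems(x)
  total <- 0L
  y <- matrix(0L, length(partition$sizes), x$K)
  per <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    sub <- subproblem_instance(x, comps[[ci]])
    model <- build_ilp(sub, formulation)
    r <- ilp_bnb(model, "solve")
    ysub <- model_counts_to_partition(model, r$solutions[[1L]],
                                      model$partition)
    idx <- part_indices_in(partition, model$partition)
    y[idx, ] <- ysub
    total <- total + r$optimum
    per[[ci]] <- list(fragments = comps[[ci]]$fragments, optimum = r$optimum)
  }
  colnames(y) <- x$color_names
  list(optimum = as.integer(total), y = y, partition = partition,
       per_subproblem = per)
}

# map a solution of the engine (per aggregated unit) to per-part counts of
# the reference partition
model_counts_to_partition <- function(model, y, partition) {
  if (model$formulation == "improved") return(y)
  # basic: units are single covered residues of model$partition
  cov <- model$partition$covered
  m <- length(partition$sizes)
  out <- matrix(0L, m, model$K)
  for (i in seq_along(cov)) {
    p <- partition$part_of[cov[i]]
    out[p, ] <- out[p, ] + as.integer(y[i, ])
  }
  out
}

# positions of the parts of `sub` (partition of a subproblem instance)
# within the full partition: matched by leading residue
part_indices_in <- function(partition, sub_partition) {
  vapply(sub_partition$parts, function(p) partition$part_of[p[[1L]]], integer(1L))
}

#' Enumerate all optimal (or bound-satisfying) solutions
#'
#' Complete, duplicate-free enumeration of the integral solutions with
#' total error within `error_bound`, by LP-pruned branching that also
#' branches on integral variables until every count is fixed. With
#' `error_bound = "auto"` the optimum is computed first and enumeration
#' runs at that bound, so exactly the minimum-error solutions are returned.
#'
#' @param x an `hdx_instance`.
#' @param error_bound `"auto"` or a nonnegative integer; a bound below the
#'   optimum yields an empty set.
#' @param formulation `"improved"` (equivalence classes) or `"basic"`
#'   (residue-level assignments).
#' @return an `hdx_solution_set`: list with `optimum`, `bound`,
#'   `formulation`, `solutions` (canonically ordered count matrices),
#'   `expansions` (per solution; for `improved`), `n_solutions`,
#'   `n_expanded`, `partition`, and for `basic` also `assignments`.
#' @export
enumerate_optimal <- function(x, error_bound = "auto",
                              formulation = c("improved", "basic")) {
  formulation <- match.arg(formulation)
  model <- build_ilp(x, formulation)
  if (identical(error_bound, "auto")) {
    bound <- ilp_bnb(model, "solve")$optimum
  } else {
    bound <- as.numeric(error_bound)
    if (bound < 0) stop("error_bound must be nonnegative")
  }
  r <- ilp_bnb(model, "enumerate", bound = bound)
  solution_set(x, model, r$solutions, bound)
}

solution_set <- function(x, model, sols, bound) {
  partition <- model$partition
  out <- list(formulation = model$formulation, bound = bound,
              partition = partition,
              n_solutions = length(sols), solutions = sols)
  if (length(sols)) {
    errs <- vapply(sols, function(y) sum(abs(model$b - span_counts(model, y))),
                   numeric(1L))
    out$optimum <- as.integer(min(errs))
  } else out$optimum <- NA_integer_
  if (model$formulation == "improved") {
    out$expansions <- vapply(sols, function(y) count_expansions(partition, y),
                             numeric(1L))
    out$n_expanded <- sum(out$expansions)
  } else {
    cov <- partition$covered
    out$assignments <- lapply(sols, function(y)
      hdx_assignment(apply(y, 1L, which.max), cov))
    out$expansions <- rep(1, length(sols))
    out$n_expanded <- length(sols)
  }
  structure(out, class = "hdx_solution_set")
}

#' @export
print.hdx_solution_set <- function(x, ...) {
  cat("HDX solution set (", x$formulation, "-ILP level): ",
      x$n_solutions, " solution(s) at error bound ", x$bound, "\n", sep = "")
  if (!is.na(x$optimum))
    cat("  optimum ", x$optimum, ", expanded assignments ", x$n_expanded,
        "\n", sep = "")
  invisible(x)
}

#' Serialize a solution set to JSON and TSV
#'
#' @param s an `hdx_solution_set`.
#' @param json_path,tsv_path output paths (either may be `NULL`).
#' @return invisibly, the JSON-ready list.
#' @export
write_solution_set <- function(s, json_path = NULL, tsv_path = NULL) {
  doc <- list(optimum = s$optimum, formulation = s$formulation,
              bound = s$bound, n_solutions = s$n_solutions,
              n_expanded = s$n_expanded,
              solutions = lapply(seq_along(s$solutions), function(i)
                list(y = unname(apply(s$solutions[[i]], 1L, function(r) r,
                                      simplify = FALSE)),
                     expansions = s$expansions[[i]])))
  if (!is.null(json_path))
    jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(tsv_path)) {
    rows <- c("solution\tpart\tresidues\tcounts")
    for (i in seq_along(s$solutions)) {
      y <- s$solutions[[i]]
      for (p in seq_len(nrow(y))) {
        rng <- range(s$partition$parts[[p]])
        rows <- c(rows, paste(i, p, paste0(rng[1L], "-", rng[2L]),
                              paste(y[p, ], collapse = ","), sep = "\t"))
      }
    }
    writeLines(rows, tsv_path, useBytes = TRUE)
  }
  invisible(doc)
}
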