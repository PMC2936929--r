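#' Default subgradient schedule
#'
#' Held-Karp style schedule: multipliers start at the part sizes, the step
#' scalar theta starts at 2 and is halved after `halve_after` consecutive
#' iterations without improvement of the best bound; iteration caps shrink
#' with branch-and-bound depth.
#'
#' @param theta0 initial step scalar in (0, 2].
#' @param halve_after iterations without bound improvement before halving.
#' @param theta_min terminate once theta falls below this threshold.
#' @param iter_cap_root iteration cap at the root node.
#' @param window number of trailing subproblem solutions averaged for
#'   branching decisions.
#' @return a named list of schedule parameters.
#' @export
lagrangian_schedule <- function(theta0 = 2, halve_after = 30L,
                                theta_min = 1e-4, iter_cap_root = 1000L,
                                window = 10L) {
  list(theta0 = theta0, halve_after = as.integer(halve_after),
       theta_min = theta_min, iter_cap_root = as.integer(iter_cap_root),
       window = as.integer(window))
}

lag_iter_cap <- function(schedule, depth) {
  if (depth <= 0L) schedule$iter_cap_root
  else max(100L, schedule$iter_cap_root - 100L * depth)
}

#' Per-color Lagrangian subproblem
#'
#' Dualizing the linking constraints (the per-part color counts must sum to
#' the part size) with multipliers `lambda` splits the relaxed problem into
#' one interval problem per color:
#' minimize `sum_f |sum_{p in f} y_p - b_f^k| + lambda' y` over integral
#' `y` within the box `[lo, hi]`. The constraint matrix has the same
#' interval structure as the two-color LP, so the minimum-cost-flow solve
#' (with node supplies given by differenced multipliers) returns an
#' integral optimum.
#'
#' @param x an `hdx_instance`.
#' @param lambda multiplier vector of length |P|.
#' @param k color index.
#' @param lo,hi optional per-part bounds on `y^k` (defaults: 0 and |p|).
#' @param partition optional precomputed partition.
#' @return list with `y` (integer vector) and `value`.
#' @export
lagrangian_subproblem <- function(x, lambda, k, lo = NULL, hi = NULL,
                                  partition = NULL) {
  if (is.null(partition)) partition <- compute_parts(x)
  m <- length(partition$sizes)
  if (is.null(lo)) lo <- rep(0, m)
  if (is.null(hi)) hi <- as.numeric(partition$sizes)
  if (any(lo > hi)) stop("infeasible bounds: lo exceeds hi")
  if (length(lambda) != m) stop("lambda must have one entry per part")
  r <- .lag_subproblem_cpp(as.integer(partition$frag_parts[, 1L]),
                           as.integer(partition$frag_parts[, 2L]),
                           as.numeric(x$requirements[, k]),
                           as.numeric(lambda), as.numeric(lo), as.numeric(hi))
  list(y = as.integer(round(r$y)), value = r$value)
}

#' Lagrangian dual function
#'
#' `z(lambda) = sum_k v_k(lambda) - lambda' P`, where `v_k` is the value of
#' the color-k subproblem; `z(lambda)` is a lower bound on the minimum
#' total error for every multiplier vector.
#'
#' @param x an `hdx_instance`.
#' @param lambda multiplier vector of length |P|.
#' @param partition optional precomputed partition.
#' @return the dual value (numeric lower bound).
#' @export
evaluate_dual <- function(x, lambda, partition = NULL) {
  if (is.null(partition)) partition <- compute_parts(x)
  v <- sum(vapply(seq_len(x$K), function(k)
    lagrangian_subproblem(x, lambda, k, partition = partition)$value,
    numeric(1L)))
  v - sum(lambda * partition$sizes)
}

#' Subgradient optimization of the Lagrangian dual
#'
#' Held-Karp subgradient ascent: from `lambda^0 = P`, iterate
#' `lambda <- lambda + mu * (sum_k y^k - P)` with step length
#' `mu = theta * (UB - z(lambda)) / ||sum_k y^k - P||^2`, halving `theta`
#' per the schedule. Terminates when theta underruns its threshold, the
#' iteration cap is hit, or the subgradient vanishes (then the relaxed
#' solution is feasible and proven optimal).
#'
#' @param x an `hdx_instance`.
#' @param UB upper bound on the optimum; default: heuristic over all
#'   color orders.
#' @param schedule a [lagrangian_schedule()].
#' @param lambda0 starting multipliers (default: part sizes).
#' @param partition optional precomputed partition.
#' @return list with `best_bound`, `best_lambda`, `iterations`,
#'   `zero_subgradient`, and when proven optimal `y_feasible` and
#'   `feasible_error`.
#' @export
subgradient_optimize <- function(x, UB = NULL, schedule = lagrangian_schedule(),
                                 lambda0 = NULL, partition = NULL) {
  if (is.null(partition)) partition <- compute_parts(x)
  m <- length(partition$sizes)
  if (m == 0L)
    return(list(best_bound = 0, best_lambda = numeric(0), iterations = 0L,
                zero_subgradient = TRUE,
                y_feasible = matrix(0L, 0L, x$K), feasible_error = 0))
  if (is.null(UB)) UB <- heuristic_solve(x, "all")$error
  if (is.null(lambda0)) lambda0 <- as.numeric(partition$sizes)
  lo <- matrix(0, m, x$K); hi <- matrix(partition$sizes, m, x$K)
  r <- .lag_subgradient_cpp(as.numeric(partition$sizes),
                            as.integer(partition$frag_parts[, 1L]),
                            as.integer(partition$frag_parts[, 2L]),
                            matrix(as.numeric(x$requirements), nrow(x$requirements)),
                            lo, hi, as.numeric(lambda0), as.numeric(UB),
                            schedule$theta0, schedule$halve_after,
                            schedule$theta_min, lag_iter_cap(schedule, 0L),
                            Inf, schedule$window)
  r
}

#' Enumerate all optimal solutions by Lagrangian branch-and-bound
#'
#' Solver-independent alternative to [enumerate_optimal()]: lower bounds
#' come from the subgradient-optimized Lagrangian dual (per-color
#' minimum-cost flows), the initial upper bound from the heuristic.
#' Branching picks the unfixed variable whose average value over the last
#' `window` subproblem solutions has fractional part closest to 0.5 (ties:
#' lowest part, then color) and splits its domain at `<= v` / `>= v + 1`;
#' integral variables are branched the same way, so every surviving box is
#' eventually reduced to a single count matrix, which is evaluated exactly.
#' The result is the same solution set as the ILP enumeration.
#'
#' @param x an `hdx_instance`.
#' @param error_bound `"auto"` (enumerate at the optimum) or an integer.
#' @param schedule a [lagrangian_schedule()].
#' @return an `hdx_solution_set` (improved-ILP level).
#' @export
branch_and_bound_enumerate <- function(x, error_bound = "auto",
                                       schedule = lagrangian_schedule()) {
  model <- build_ilp(x, "improved")
  if (identical(error_bound, "auto")) {
    bound <- lag_bnb(x, model, schedule, mode = "solve")$optimum
  } else {
    bound <- as.numeric(error_bound)
    if (bound < 0) stop("error_bound must be nonnegative")
  }
  r <- lag_bnb(x, model, schedule, mode = "enumerate", bound = bound)
  solution_set(x, model, r$solutions, bound)
}

#' Exact minimum-error solve by Lagrangian branch-and-bound
#'
#' @param x an `hdx_instance`.
#' @param schedule a [lagrangian_schedule()].
#' @param decompose solve independent subproblems separately.
#' @return list with `optimum`, `y`, `partition` as in [solve_min_error()].
#' @export
solve_min_error_lagrangian <- function(x, schedule = lagrangian_schedule(),
                                       decompose = TRUE) {
  partition <- compute_parts(x)
  if (!decompose || nrow(x$fragments) == 0L) {
    model <- build_ilp(x, "improved")
    r <- lag_bnb(x, model, schedule, mode = "solve")
    return(list(optimum = r$optimum, y = r$solutions[[1L]],
                partition = partition, per_subproblem = NULL))
  }
  comps <- decompose_subproblems(x)
  total <- 0L
  y <- matrix(0L, length(partition$sizes), x$K)
  per <- vector("list", length(comps))
  for (ci in seq_along(comps)) {
    sub <- subproblem_instance(x, comps[[ci]])
    model <- build_ilp(sub, "improved")
    r <- lag_bnb(sub, model, schedule, mode = "solve")
    idx <- part_indices_in(partition, model$partition)
    y[idx, ] <- r$solutions[[1L]]
    total <- total + r$optimum
    per[[ci]] <- list(fragments = comps[[ci]]$fragments, optimum = r$optimum)
  }
  colnames(y) <- x$color_names
  list(optimum = as.integer(total), y = y, partition = partition,
       per_subproblem = per)
}

# Lagrangian branch-and-bound core. Nodes carry boxes [lo, hi]; bounds are
# ceil'ed before pruning (the objective is integral). Warm starts: children
# inherit the parent's best multipliers.
lag_bnb <- function(x, model, schedule, mode = c("solve", "enumerate"),
                    bound = Inf, node_limit = 1e6) {
  mode <- match.arg(mode)
  partition <- model$partition
  m <- length(partition$sizes); K <- x$K
  sizes <- as.numeric(partition$sizes)
  h <- heuristic_solve(x, "all")
  incumbent <- h$error; inc_y <- h$y
  if (m == 0L) {
    sols <- if (mode == "solve" || incumbent <= bound)
      list(matrix(integer(), 0L, K)) else list()
    return(list(optimum = as.integer(incumbent), solutions = sols))
  }
  UB <- max(incumbent, if (is.finite(bound)) bound else incumbent)
  found <- list(); seen <- new.env(hash = TRUE, parent = emptyenv())
  root <- propagate_box(sizes, matrix(0, m, K), matrix(sizes, m, K))
  if (is.null(root)) stop("instance admits no count solution")
  root$depth <- 0L
  root$lambda <- sizes
  stack <- list(root)
  nodes <- 0L
  fp <- partition$frag_parts
  breq <- matrix(as.numeric(x$requirements), nrow(x$requirements))
  while (length(stack)) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    if (nodes > node_limit) stop("branch-and-bound node limit exceeded")
    lo <- nd$lo; hi <- nd$hi
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
    prune_above <- if (mode == "solve") incumbent - 1 else bound
    sg <- .lag_subgradient_cpp(sizes, as.integer(fp[, 1L]), as.integer(fp[, 2L]),
                               breq, lo, hi, nd$lambda, UB,
                               schedule$theta0, schedule$halve_after,
                               schedule$theta_min,
                               lag_iter_cap(schedule, nd$depth),
                               prune_above, schedule$window)
    lb <- ceiling(sg$best_bound - 1e-6)
    if (mode == "solve" && lb >= incumbent) {
      if (isTRUE(sg$zero_subgradient) && sg$feasible_error < incumbent) {
        incumbent <- sg$feasible_error; inc_y <- sg$y_feasible
      }
      next
    }
    if (mode == "enumerate" && lb > bound) next
    if (mode == "solve" && isTRUE(sg$zero_subgradient)) {
      # relaxation solution is feasible: optimal within this box
      if (sg$feasible_error < incumbent) {
        incumbent <- sg$feasible_error; inc_y <- sg$y_feasible
      }
      next
    }
    sel <- lag_select_branch(sg$ybar, lo, hi)
    split <- min(max(floor(sel$value + 1e-9), lo[sel$p, sel$k]),
                 hi[sel$p, sel$k] - 1)
    left <- list(lo = lo, hi = hi); left$hi[sel$p, sel$k] <- split
    right <- list(lo = lo, hi = hi); right$lo[sel$p, sel$k] <- split + 1
    for (child in list(right, left)) {
      pb <- propagate_box(sizes, child$lo, child$hi)
      if (!is.null(pb)) {
        pb$depth <- nd$depth + 1L
        pb$lambda <- sg$best_lambda
        stack[[length(stack) + 1L]] <- pb
      }
    }
  }
  if (mode == "solve") {
    y <- matrix(as.integer(round(inc_y)), m, K)
    list(optimum = as.integer(round(incumbent)), solutions = list(y))
  } else {
    list(optimum = if (length(found))
      min(vapply(found, function(y) sum(abs(model$b - span_counts(model, y))),
                 numeric(1L))) else NA_integer_,
      solutions = canonical_sort(found))
  }
}

# window-average branching: fractional part of the averaged variable
# closest to 0.5 among unfixed variables; ties lowest part then color
lag_select_branch <- function(ybar, lo, hi) {
  un <- which(hi - lo > 1e-9, arr.ind = TRUE)
  fr <- ybar - floor(ybar)
  d <- abs(fr[un] - 0.5)
  ordx <- order(d, un[, 1L], un[, 2L])
  p <- un[ordx[1L], 1L]; k <- un[ordx[1L], 2L]
  list(p = p, k = k, value = ybar[p, k])
}
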