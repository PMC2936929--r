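# Thin wrapper around boot::simplex used for all LP relaxations of the
# integer programs. Rows are split by direction and rows with negative
# right-hand sides are negated first (the backend requires nonnegative rhs).
# Variables are implicitly nonnegative, which matches every model here.
lp_solve <- function(obj, A, dir, rhs, maximize = FALSE) {
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- ifelse(dir[neg] == "<=", ">=",
                       ifelse(dir[neg] == ">=", "<=", "=="))
  }
  le <- dir == "<="; ge <- dir == ">="; eq <- dir == "=="
  nv <- length(obj)
  res <- tryCatch(
    boot::simplex(a = obj,
                  A1 = if (any(le)) A[le, , drop = FALSE], b1 = rhs[le],
                  A2 = if (any(ge)) A[ge, , drop = FALSE], b2 = rhs[ge],
                  A3 = if (any(eq)) A[eq, , drop = FALSE], b3 = rhs[eq],
                  maxi = maximize,
                  n.iter = 50L * (nv + length(rhs)), eps = 1e-10),
    error = function(e) NULL)
  if (is.null(res)) return(list(status = "failed", value = NA_real_, x = NULL))
  if (res$solved == -1L) return(list(status = "infeasible", value = NA_real_, x = NULL))
  if (res$solved != 1L) return(list(status = "failed", value = NA_real_, x = NULL))
  list(status = "optimal", value = unname(res$value), x = unname(res$soln))
}
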