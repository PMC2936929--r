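#' Construct an HDX fragment instance
#'
#' An instance bundles the protein length, the peptic fragments as 1-based
#' inclusive residue intervals, and the per-fragment "requirement" counts
#' \eqn{b_f^k}: how many residues of fragment \eqn{f} the upstream analysis
#' placed into exchange-rate class \eqn{k}.
#'
#' @param n protein length (number of residues).
#' @param fragments two-column matrix or data frame of 1-based inclusive
#'   intervals (`start`, `end`), one row per fragment.
#' @param requirements integer matrix, one row per fragment, one column per
#'   color class.
#' @param color_names character vector of class labels; defaults to
#'   `c("slow", "medium", "fast")` truncated/extended to `K`.
#' @param residue_labels optional length-`n` character vector of one-letter
#'   residue codes.
#' @return An object of class `hdx_instance`.
#' @examples
#' inst <- hdx_instance(5, rbind(c(1, 3), c(2, 5)),
#'                      rbind(c(2, 1), c(1, 3)), color_names = c("slow", "fast"))
#' inst
#' @export
hdx_instance <- function(n, fragments, requirements,
                         color_names = NULL, residue_labels = NULL) {
  fragments <- as.matrix(fragments)
  if (length(fragments) == 0L) fragments <- matrix(integer(), 0L, 2L)
  if (ncol(fragments) != 2L) stop("`fragments` must have two columns (start, end)")
  storage.mode(fragments) <- "integer"
  colnames(fragments) <- c("start", "end")
  requirements <- as.matrix(requirements)
  if (nrow(fragments) == 0L && length(requirements) == 0L)
    requirements <- matrix(integer(), 0L, max(ncol(requirements), length(color_names), 2L))
  storage.mode(requirements) <- "integer"
  K <- ncol(requirements)
  if (is.null(color_names)) {
    color_names <- if (K == 3L) c("slow", "medium", "fast")
      else if (K == 2L) c("slow", "fast")
      else paste0("class", seq_len(K))
  }
  x <- structure(list(n = as.integer(n), K = K,
                      fragments = fragments, requirements = requirements,
                      color_names = as.character(color_names),
                      residue_labels = residue_labels),
                 class = "hdx_instance")
  validate_instance(x)
}

#' Validate an HDX instance
#'
#' Errors on structurally impossible input (reversed or out-of-range
#' intervals, negative counts, dimension mismatches). Requirement rows whose
#' sum differs from the fragment length, or single counts exceeding it, are
#' legal — measurement noise routinely produces them and the solvers absorb
#' the discrepancy as error — but trigger a warning.
#'
#' @param x an `hdx_instance`.
#' @return `x`, invisibly unchanged, after checks.
#' @export
validate_instance <- function(x) {
  stopifnot(inherits(x, "hdx_instance"))
  fr <- x$fragments
  if (x$n < 0L) stop("protein length must be nonnegative")
  if (x$K < 2L) stop("at least two color classes are required")
  if (nrow(fr) != nrow(x$requirements))
    stop("requirements must have one row per fragment")
  if (length(x$color_names) != x$K)
    stop("color_names must have one entry per class")
  if (nrow(fr)) {
    bad <- which(fr[, 1L] < 1L | fr[, 2L] < fr[, 1L] | fr[, 2L] > x$n)
    if (length(bad))
      stop("invalid fragment interval in row(s): ", paste(bad, collapse = ", "))
    if (any(x$requirements < 0L))
      stop("negative requirement count in row(s): ",
           paste(which(rowSums(x$requirements < 0L) > 0L), collapse = ", "))
    len <- fragment_lengths(x)
    off <- which(rowSums(x$requirements) != len)
    if (length(off))
      warning("requirement counts do not sum to fragment length in row(s): ",
              paste(off, collapse = ", "), call. = FALSE)
    over <- which(apply(x$requirements > len, 1L, any))
    if (length(over))
      warning("a single class count exceeds the fragment length in row(s): ",
              paste(over, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' Fragment lengths of an instance
#'
#' @param x an `hdx_instance`.
#' @return integer vector of residue counts per fragment (the vector **F**).
#' @export
fragment_lengths <- function(x) {
  if (nrow(x$fragments) == 0L) return(integer())
  unname(x$fragments[, 2L] - x$fragments[, 1L] + 1L)
}

#' @export
print.hdx_instance <- function(x, ...) {
  cat("HDX fragment instance\n")
  cat("  residues:  ", x$n, "\n", sep = "")
  cat("  fragments: ", nrow(x$fragments), "\n", sep = "")
  cat("  classes:   ", paste(x$color_names, collapse = "/"), "\n", sep = "")
  if (nrow(x$fragments)) {
    len <- fragment_lengths(x)
    cons <- sum(rowSums(x$requirements) == len)
    cat("  consistent count rows: ", cons, "/", nrow(x$fragments), "\n", sep = "")
  }
  invisible(x)
}

#' Residue-level color assignment
#'
#' Wraps a named integer vector mapping covered residue indices to color
#' indices `1..K`. Uncovered residues carry no prediction and are absent.
#'
#' @param colors integer vector of color indices.
#' @param residues integer vector of residue indices (same length).
#' @return an `hdx_assignment` (integer vector named by residue index).
#' @export
hdx_assignment <- function(colors, residues = seq_along(colors)) {
  stopifnot(length(colors) == length(residues))
  a <- as.integer(colors)
  names(a) <- as.character(as.integer(residues))
  structure(a, class = "hdx_assignment")
}

#' @export
print.hdx_assignment <- function(x, ...) {
  cat("HDX residue assignment over", length(x), "covered residues\n")
  print(table(factor(unclass(x))))
  invisible(x)
}
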