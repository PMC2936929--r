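#' Read a fragment table
#'
#' The fragment TSV dialect: a first header line
#' `# n=<int> K=<int> colors=<c1,c2,...>`, then a tab-separated column header
#' `fragment_id  start  end  count_<c1> ... count_<cK>` (an optional
#' `sequence` column is carried through), then one row per fragment. Lines
#' starting with `#` after the first are comments. Intervals are 1-based and
#' inclusive.
#'
#' Optional preprocessing for unobservable amide hydrogens (off by default;
#' the input is assumed already reduced):
#' * `drop_first_residue_per_fragment`: each fragment's first residue does
#'   not retain deuterium, so `start` is incremented; fragments of length 1
#'   are removed with a warning. Requirement counts are left unchanged.
#' * `drop_n_terminal_residue`: only the protein's N-terminal residue is
#'   removed from fragments containing it.
#'
#' @param path file path.
#' @param drop_first_residue_per_fragment logical.
#' @param drop_n_terminal_residue logical.
#' @return an `hdx_instance`.
#' @export
read_fragment_table <- function(path,
                                drop_first_residue_per_fragment = FALSE,
                                drop_n_terminal_residue = FALSE) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines) || !grepl("^#\\s*n=", lines[[1L]]))
    stop("missing header line '# n=<int> K=<int> colors=...' in ", path)
  hdr <- lines[[1L]]
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", hdr))
  K <- as.integer(sub(".*K=([0-9]+).*", "\\1", hdr))
  colors <- strsplit(sub(".*colors=([^ ]+).*", "\\1", hdr), ",")[[1L]]
  if (length(colors) != K) stop("header declares K=", K, " but ",
                                length(colors), " color names")
  body <- lines[-1L]
  body <- body[!grepl("^#", body) & nzchar(trimws(body))]
  if (!length(body))
    return(hdx_instance(n, matrix(integer(), 0L, 2L),
                        matrix(integer(), 0L, K), color_names = colors))
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (grepl("^fragment_id", body[[1L]])) {
    col_names <- fields[[1L]]
    fields <- fields[-1L]
  } else {
    col_names <- c("fragment_id", "start", "end", paste0("count_", colors))
  }
  expect_min <- 3L + K
  rows <- lapply(seq_along(fields), function(i) {
    fl <- fields[[i]]
    if (length(fl) < expect_min)
      stop("row ", i, ": expected at least ", expect_min, " tab-separated fields")
    vals <- suppressWarnings(as.integer(fl[2:(3 + K)]))
    if (anyNA(vals)) stop("row ", i, ": non-integer start/end/count field")
    vals
  })
  tab <- do.call(rbind, rows)
  fragments <- tab[, 1:2, drop = FALSE]
  requirements <- tab[, 3:(2 + K), drop = FALSE]
  if (any(fragments[, 2L] < fragments[, 1L]))
    stop("row ", which(fragments[, 2L] < fragments[, 1L])[1L],
         ": fragment end precedes start")
  if (drop_n_terminal_residue && nrow(fragments)) {
    hit <- fragments[, 1L] == 1L
    fragments[hit, 1L] <- 2L
    bad <- fragments[, 2L] < fragments[, 1L]
    if (any(bad)) {
      warning(sum(bad), " fragment(s) of length 1 removed by N-terminal trimming")
      fragments <- fragments[!bad, , drop = FALSE]
      requirements <- requirements[!bad, , drop = FALSE]
    }
  }
  if (drop_first_residue_per_fragment && nrow(fragments)) {
    short <- fragments[, 2L] == fragments[, 1L]
    if (any(short)) {
      warning(sum(short), " fragment(s) of length 1 removed by first-residue trimming")
      fragments <- fragments[!short, , drop = FALSE]
      requirements <- requirements[!short, , drop = FALSE]
    }
    fragments[, 1L] <- fragments[, 1L] + 1L
  }
  inst <- hdx_instance(n, fragments, requirements, color_names = colors)
  seq_col <- match("sequence", col_names)
  if (!is.na(seq_col)) {
    seqs <- vapply(fields, function(fl)
      if (length(fl) >= seq_col) fl[[seq_col]] else NA_character_, character(1L))
    if (drop_n_terminal_residue || drop_first_residue_per_fragment) seqs <- NULL
    inst$fragment_sequences <- seqs
  }
  inst
}

#' Write a fragment table
#'
#' Writes the canonical fragment TSV dialect read by
#' [read_fragment_table()]; `read(write(x))` reproduces `x` and a rewrite is
#' byte-identical.
#'
#' @param x an `hdx_instance`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fragment_table <- function(x, path) {
  stopifnot(inherits(x, "hdx_instance"))
  hdr <- sprintf("# n=%d K=%d colors=%s", x$n, x$K,
                 paste(x$color_names, collapse = ","))
  cols <- c("fragment_id", "start", "end", paste0("count_", x$color_names))
  has_seq <- !is.null(x$fragment_sequences)
  if (has_seq) cols <- c(cols, "sequence")
  body <- character(nrow(x$fragments))
  for (f in seq_len(nrow(x$fragments))) {
    fl <- c(f, x$fragments[f, ], x$requirements[f, ])
    line <- paste(fl, collapse = "\t")
    if (has_seq) line <- paste(line, x$fragment_sequences[[f]], sep = "\t")
    body[[f]] <- line
  }
  writeLines(c(hdr, paste(cols, collapse = "\t"), body), path, useBytes = TRUE)
  invisible(path)
}

#' Read per-residue reference rates or classes
#'
#' Tab-separated, either `residue  rate_per_hour` (rates in 1/h, later
#' discretized with [discretize_rates()]) or `residue  class` (class labels
#' or 1-based indices). `#` comments ignored; residues absent from the file
#' are treated as missing.
#'
#' @param path file path.
#' @param n protein length.
#' @param color_names class labels used to interpret a `class` column.
#' @return list with `rates` (numeric length-n, NA = missing) or `classes`
#'   (integer length-n, NA = missing), depending on the columns present.
#' @export
read_reference_table <- function(path, n, color_names = c("slow", "medium", "fast")) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty reference table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  is_rate <- "rate_per_hour" %in% header
  is_class <- "class" %in% header
  if (!is_rate && !is_class)
    stop("reference table needs a 'rate_per_hour' or 'class' column")
  fields <- fields[-1L]
  res <- vapply(fields, function(fl) as.integer(fl[[1L]]), integer(1L))
  if (any(res < 1L | res > n)) stop("residue index outside 1..n in reference table")
  if (is_rate) {
    val <- vapply(fields, function(fl) as.numeric(fl[[2L]]), numeric(1L))
    rates <- rep(NA_real_, n)
    rates[res] <- val
    list(rates = rates)
  } else {
    lab <- vapply(fields, function(fl) fl[[2L]], character(1L))
    idx <- match(lab, color_names)
    num <- suppressWarnings(as.integer(lab))
    idx[is.na(idx)] <- num[is.na(idx)]
    if (anyNA(idx)) stop("unknown class label in reference table")
    classes <- rep(NA_integer_, n)
    classes[res] <- idx
    list(classes = classes)
  }
}

#' Write a per-residue reference/prediction class table
#'
#' @param classes integer vector (NA = missing), 1-based class indices.
#' @param path output path.
#' @param color_names class labels.
#' @return `path`, invisibly.
#' @export
write_class_table <- function(classes, path, color_names = c("slow", "medium", "fast")) {
  keep <- which(!is.na(classes))
  writeLines(c("residue\tclass",
               paste(keep, color_names[classes[keep]], sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}
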