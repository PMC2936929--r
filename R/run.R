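#' Run configuration
#'
#' Bundles the choices of an end-to-end run: solver, enumeration bound,
#' consensus method, preprocessing flags, seed and output paths.
#'
#' @param input path to a fragment TSV.
#' @param solver one of `"ilp-improved"`, `"ilp-basic"`, `"flow2"`,
#'   `"heuristic"`, `"lagrange"`.
#' @param enumerate enumerate all optimal solutions (exact solvers only).
#' @param error_bound `"auto"` or an integer bound for enumeration.
#' @param consensus_method `NULL` or one of `"single"`, `"majority"`,
#'   `"mean"`.
#' @param weighting `"class"` or `"expanded"`.
#' @param reference optional path to a reference-rate TSV for comparison.
#' @param drop_first_residue_per_fragment,drop_n_terminal_residue
#'   preprocessing flags, see [read_fragment_table()].
#' @param out_prefix prefix for output files (JSON summary, solution TSV).
#' @param seed integer seed (recorded in the summary; the solvers are
#'   deterministic).
#' @param verbose print progress to stderr.
#' @return an `hdx_run_config`.
#' @export
hdx_config <- function(input,
                       solver = c("ilp-improved", "ilp-basic", "flow2",
                                  "heuristic", "lagrange"),
                       enumerate = FALSE, error_bound = "auto",
                       consensus_method = NULL, weighting = "class",
                       reference = NULL,
                       drop_first_residue_per_fragment = FALSE,
                       drop_n_terminal_residue = FALSE,
                       out_prefix = NULL, seed = 1L, verbose = FALSE) {
  solver <- match.arg(solver)
  if (!identical(error_bound, "auto") && error_bound < 0)
    stop("error_bound must be nonnegative")
  structure(list(input = input, solver = solver, enumerate = enumerate,
                 error_bound = error_bound,
                 consensus_method = consensus_method, weighting = weighting,
                 reference = reference,
                 drop_first_residue_per_fragment = drop_first_residue_per_fragment,
                 drop_n_terminal_residue = drop_n_terminal_residue,
                 out_prefix = out_prefix, seed = as.integer(seed),
                 verbose = verbose),
            class = "hdx_run_config")
}

#' Execute an end-to-end run
#'
#' Reads the instance, decomposes it into independent subproblems, solves
#' (and optionally enumerates) each with the configured solver, merges the
#' results, and applies consensus/comparison post-processing. The summary
#' mirrors the usual reporting schema: per subproblem the residue count n,
#' part count |P|, mean part size n/|P|, fragment count |F|, total error
#' epsilon, and the number of solution classes and expanded assignments.
#'
#' @param config an [hdx_config()].
#' @return an `hdx_run_result`: list with `summary` (list, JSON-ready),
#'   `y` (counts on the full partition), `partition`, `solution_sets`
#'   (per subproblem, when enumerating), `consensus`, `comparison`.
#' @export
hdx_run <- function(config) {
  stopifnot(inherits(config, "hdx_run_config"))
  say <- function(...) if (config$verbose) message(...)
  inst <- read_fragment_table(
    config$input,
    drop_first_residue_per_fragment = config$drop_first_residue_per_fragment,
    drop_n_terminal_residue = config$drop_n_terminal_residue)
  if (config$solver == "flow2" && inst$K != 2L)
    stop("solver 'flow2' requires a two-class instance (K = 2), got K = ",
         inst$K, "; use ilp-improved, lagrange or the heuristic")
  partition <- compute_parts(inst)
  comps <- decompose_subproblems(inst)
  say("instance: n=", inst$n, " fragments=", nrow(inst$fragments),
      " parts=", length(partition$sizes), " subproblems=", length(comps))
  y <- matrix(0L, length(partition$sizes), inst$K)
  sub_summaries <- list()
  solution_sets <- list()
  total_eps <- 0L
  for (ci in seq_along(comps)) {
    t0 <- proc.time()[["elapsed"]]
    sub <- subproblem_instance(inst, comps[[ci]])
    subpart <- compute_parts(sub)
    sol_set <- NULL
    res <- switch(config$solver,
      "ilp-improved" = solve_min_error(sub, "improved", decompose = FALSE),
      "ilp-basic" = solve_min_error(sub, "basic", decompose = FALSE),
      "flow2" = {
        s <- solve_two_color(sub, subpart)
        list(optimum = s$optimum, y = s$y, partition = s$partition)
      },
      "heuristic" = {
        s <- heuristic_solve(sub, "all")
        list(optimum = s$error, y = s$y, partition = s$partition)
      },
      "lagrange" = solve_min_error_lagrangian(sub, decompose = FALSE))
    if (config$enumerate && config$solver %in% c("ilp-improved", "ilp-basic",
                                                 "lagrange")) {
      sol_set <- switch(config$solver,
        "ilp-improved" = enumerate_optimal(sub, config$error_bound, "improved"),
        "ilp-basic" = enumerate_optimal(sub, config$error_bound, "basic"),
        "lagrange" = branch_and_bound_enumerate(sub, config$error_bound))
      solution_sets[[length(solution_sets) + 1L]] <- sol_set
    }
    idx <- part_indices_in(partition, if (!is.null(res$partition)) res$partition
                                      else compute_parts(sub))
    y[idx, ] <- res$y
    total_eps <- total_eps + res$optimum
    el <- proc.time()[["elapsed"]] - t0
    ncov <- length(subpart$covered)
    sub_summaries[[ci]] <- list(
      subproblem = ci, n = ncov, n_parts = length(subpart$sizes),
      mean_part_size = if (length(subpart$sizes)) ncov / length(subpart$sizes)
                       else NA,
      n_fragments = length(comps[[ci]]$fragments), epsilon = res$optimum,
      n_solutions = if (!is.null(sol_set)) sol_set$n_solutions else NA,
      n_expanded = if (!is.null(sol_set)) sol_set$n_expanded else NA)
    say("subproblem ", ci, ": epsilon=", res$optimum, " (", round(el, 2), "s)")
  }
  colnames(y) <- inst$color_names
  cons <- NULL; comparison <- NULL
  if (!is.null(config$consensus_method) && length(solution_sets) > 0L) {
    cons <- lapply(solution_sets, consensus, method = config$consensus_method,
                   weighting = config$weighting)
  }
  if (!is.null(config$reference)) {
    ref <- read_reference_table(config$reference, inst$n, inst$color_names)
    classes <- if (!is.null(ref$classes)) ref$classes
               else discretize_rates(ref$rates)
    comparison <- agreement_score(y, classes, partition)
  }
  summary <- list(input = config$input, solver = config$solver,
                  seed = config$seed, n = inst$n,
                  n_fragments = nrow(inst$fragments),
                  n_parts = length(partition$sizes),
                  n_subproblems = length(comps),
                  epsilon = total_eps,
                  subproblems = sub_summaries)
  if (!is.null(comparison)) summary$agreement_percent <- comparison$score
  if (!is.null(config$out_prefix)) {
    jsonlite::write_json(summary, paste0(config$out_prefix, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tsv <- paste0(config$out_prefix, "_solution.tsv")
    rows <- c("part\tresidues\tcounts")
    for (p in seq_len(nrow(y))) {
      rng <- range(partition$parts[[p]])
      rows <- c(rows, paste(p, paste0(rng[1L], "-", rng[2L]),
                            paste(y[p, ], collapse = ","), sep = "\t"))
    }
    writeLines(rows, tsv, useBytes = TRUE)
  }
  structure(list(summary = summary, y = y, partition = partition,
                 solution_sets = solution_sets, consensus = cons,
                 comparison = comparison, instance = inst),
            class = "hdx_run_result")
}

#' @export
print.hdx_run_result <- function(x, ...) {
  s <- x$summary
  cat("HDX run (", s$solver, "): n=", s$n, ", |F|=", s$n_fragments,
      ", |P|=", s$n_parts, ", subproblems=", s$n_subproblems,
      ", epsilon=", s$epsilon, "\n", sep = "")
  invisible(x)
}
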