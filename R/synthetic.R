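#' Specification for a synthetic digestion instance
#'
#' Emulates the shape of real overlapping-fragment inputs: one or more
#' protease "generations" each tile the protein with contiguous fragments
#' of a given mean length (overlaying generations produces the overlaps a
#' combined digest would), a planted residue coloring supplies the ground
#' truth, and requirement counts are derived from it exactly before an
#' integer noise process perturbs them. Noise is discrete count swapping —
#' a fragment loses one count in one class and gains it in another —
#' because the inputs are integer class counts; a unit swap is the
#' smallest physically meaningful corruption.
#'
#' @param n residue count.
#' @param K number of classes.
#' @param mean_length target mean fragment length per generation.
#' @param multiplicity number of digestion generations overlaid.
#' @param min_length minimum fragment length.
#' @param noise_moves number of unit count swaps applied.
#' @param class_freq planted class frequencies (default 0.4/0.3/0.3 for
#'   slow/medium/fast, renormalized to `K` entries).
#' @param planted optional explicit planted coloring (length `n`).
#' @param seed integer seed; the same spec and seed reproduce the instance.
#' @return an `hdx_synthetic_spec`.
#' @export
synthetic_spec <- function(n, K = 3L, mean_length = 8, multiplicity = 2L,
                           min_length = 2L, noise_moves = 0L,
                           class_freq = NULL, planted = NULL, seed = 1L) {
  if (n < 1L) stop("n must be positive")
  if (K < 2L) stop("K must be at least 2")
  if (noise_moves < 0L) stop("noise_moves must be nonnegative")
  if (mean_length > n) stop("mean fragment length exceeds protein length")
  if (is.null(class_freq)) {
    class_freq <- if (K == 3L) c(0.4, 0.3, 0.3) else rep(1 / K, K)
  }
  if (length(class_freq) != K) stop("class_freq must have K entries")
  structure(list(n = as.integer(n), K = as.integer(K),
                 mean_length = mean_length,
                 multiplicity = as.integer(multiplicity),
                 min_length = as.integer(min_length),
                 noise_moves = as.integer(noise_moves),
                 class_freq = class_freq / sum(class_freq),
                 planted = planted, seed = as.integer(seed)),
            class = "hdx_synthetic_spec")
}

with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv())
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Generate a synthetic instance with a planted coloring
#'
#' Fragments are drawn per generation as a random composition of the
#' protein into stretches of at least `min_length` residues whose count
#' matches the requested mean length; requirements are counted exactly
#' from the planted coloring (so the noise-free optimum is 0 and the
#' planted coloring is optimal), then `noise_moves` unit swaps are
#' applied. Each swap changes two requirement entries of one fragment by
#' one, so the planted coloring's error — and hence the optimum — is at
#' most `2 * noise_moves`.
#'
#' @param spec an [synthetic_spec()].
#' @return list with `instance` (an `hdx_instance`), `planted` (an
#'   [hdx_assignment()] over covered residues), `planted_full` (length-n
#'   integer vector), `spec`.
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "hdx_synthetic_spec"))
  with_local_seed(spec$seed, {
    n <- spec$n; K <- spec$K
    planted <- spec$planted
    if (is.null(planted)) {
      planted <- sample.int(K, n, replace = TRUE, prob = spec$class_freq)
    }
    frags <- NULL
    for (g in seq_len(spec$multiplicity)) {
      nf <- max(1L, round(n / spec$mean_length))
      frags <- rbind(frags, random_tiling(n, nf, spec$min_length))
    }
    req <- t(apply(frags, 1L, function(fr)
      tabulate(planted[fr[1L]:fr[2L]], nbins = K)))
    len <- frags[, 2L] - frags[, 1L] + 1L
    for (mv in seq_len(spec$noise_moves)) {
      f <- sample.int(nrow(frags), 1L)
      donors <- which(req[f, ] > 0L)
      from <- if (length(donors) == 1L) donors else sample(donors, 1L)
      to <- sample(seq_len(K)[-from], 1L)
      if (req[f, to] < len[f]) {
        req[f, from] <- req[f, from] - 1L
        req[f, to] <- req[f, to] + 1L
      }
    }
    inst <- suppressWarnings(hdx_instance(n, frags, req))
    part <- compute_parts(inst)
    list(instance = inst,
         planted = hdx_assignment(planted[part$covered], part$covered),
         planted_full = planted, spec = spec)
  })
}

# random composition of 1..n into nf contiguous stretches of >= min_len
random_tiling <- function(n, nf, min_len) {
  nf <- min(nf, n %/% min_len)
  if (nf < 1L) nf <- 1L
  extra <- n - nf * min_len
  bonus <- if (extra > 0 && nf > 1L) {
    cuts <- sort(sample.int(extra + nf - 1L, nf - 1L))
    diff(c(0L, cuts, extra + nf - 1L)) - 1L
  } else if (nf == 1L) extra else rep(0L, nf)
  lens <- min_len + bonus
  ends <- cumsum(lens)
  cbind(start = c(1L, head(ends, -1L) + 1L), end = ends)
}

#' Fixed benchmark battery
#'
#' Two tiers, reproducible from one seed:
#' * tier "tiny": many small instances (n <= 12, K = 3, at most 6
#'   fragments) solvable by exhaustive search, for oracle cross-checks;
#' * tier "scale": realistically sized instances (n in 74..152, 18..49
#'   fragments, K = 3) with mixed noise, matching the size range of
#'   published combined-digest experiments.
#'
#' @param seed integer seed.
#' @param n_tiny number of tiny-tier instances (>= 200 by default).
#' @param n_scale number of scale-tier instances.
#' @return list of entries: `instance`, `planted`, `tier`, `noise_moves`,
#'   `spec`.
#' @export
benchmark_suite <- function(seed, n_tiny = 200L, n_scale = 12L) {
  # derived stream seeds, folded into the 32-bit range
  substream <- function(s, i) as.integer((as.numeric(s) * 1009 + i) %% 2147483629)
  out <- vector("list", n_tiny + n_scale)
  noise_cycle <- c(0L, 1L, 2L, 3L)
  for (i in seq_len(n_tiny)) {
    n <- 6L + (i %% 7L)
    sp <- synthetic_spec(n, K = 3L,
                         mean_length = max(2.5, n / 3),
                         multiplicity = 2L, min_length = 2L,
                         noise_moves = noise_cycle[1L + (i %% 4L)],
                         seed = substream(seed, i))
    g <- generate_instance(sp)
    # the tiling construction caps fragments at 2 * ceil(n / mean); keep <= 6
    stopifnot(nrow(g$instance$fragments) <= 6L)
    out[[i]] <- list(instance = g$instance, planted = g$planted,
                     tier = "tiny", noise_moves = sp$noise_moves, spec = sp)
  }
  scale_noise <- c(0L, 2L, 4L, 8L)
  for (j in seq_len(n_scale)) {
    i <- n_tiny + j
    sp <- with_local_seed(substream(seed, 100000 + j), {
      n <- sample(74:152, 1L)
      nf_target <- sample(18:49, 1L)
      mult <- if (nf_target >= 30L) 3L else 2L
      synthetic_spec(n, K = 3L,
                     mean_length = n / (nf_target / mult),
                     multiplicity = mult, min_length = 3L,
                     noise_moves = scale_noise[1L + (j %% 4L)],
                     seed = substream(seed, 100000 + j))
    })
    g <- generate_instance(sp)
    nf <- nrow(g$instance$fragments)
    stopifnot(nf >= 18L, nf <= 49L)
    out[[i]] <- list(instance = g$instance, planted = g$planted,
                     tier = "scale", noise_moves = sp$noise_moves, spec = sp)
  }
  out
}

#' Exhaustive minimum-error search (oracle)
#'
#' Enumerates every coloring of the covered residues (K^n of them) and
#' returns the minimum total error, optionally with all optimal
#' colorings. Independent of the LP/flow/Lagrangian machinery; intended
#' as ground truth for small instances.
#'
#' @param x an `hdx_instance`.
#' @param keep_all return all optimal colorings (memory grows with their
#'   number).
#' @return list with `optimum` and, when `keep_all`, `assignments` (list
#'   of [hdx_assignment()]).
#' @export
solve_exhaustive <- function(x, keep_all = FALSE) {
  part <- compute_parts(x)
  cov <- part$covered
  pos <- match(seq_len(x$n), cov)
  Fn <- nrow(x$fragments)
  fi <- if (Fn) pos[x$fragments[, 1L]] else integer(0)
  fj <- if (Fn) pos[x$fragments[, 2L]] else integer(0)
  r <- .bf_enumerate_cpp(length(cov), x$K, as.integer(fi), as.integer(fj),
                         x$requirements, keep_all)
  out <- list(optimum = as.integer(r$optimum))
  if (keep_all) {
    out$assignments <- lapply(seq_len(nrow(r$solutions)), function(i)
      hdx_assignment(r$solutions[i, ], cov))
  }
  out
}

#' Write a ground-truth coloring table
#'
#' @param gen output of [generate_instance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(gen, path) {
  write_class_table(gen$planted_full, path,
                    color_names = gen$instance$color_names)
}
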