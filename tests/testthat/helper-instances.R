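# shared fixtures and an independent pure-R brute force used to vouch for
# the compiled oracle on the smallest cases

# random instance with planted coloring and optional count-swap noise;
# built directly here (not via the synthetic module) so generator tests
# have an independent construction to compare against
rand_instance <- function(n, K = 3, nf = NULL, noise = NULL) {
  if (is.null(nf)) nf <- sample(2:5, 1)
  fr <- t(sapply(seq_len(nf), function(j) sort(sample(seq_len(n), 2, TRUE))))
  truth <- sample(seq_len(K), n, TRUE)
  b <- t(sapply(seq_len(nf), function(f)
    tabulate(truth[fr[f, 1]:fr[f, 2]], nbins = K)))
  if (is.null(noise)) noise <- sample(0:2, 1)
  if (noise > 0) for (r in seq_len(noise)) {
    f <- sample(nf, 1)
    d <- which(b[f, ] > 0)
    from <- if (length(d) > 1) sample(d, 1) else d
    to <- sample(setdiff(seq_len(K), from), 1)
    b[f, from] <- b[f, from] - 1
    b[f, to] <- b[f, to] + 1
  }
  suppressWarnings(hdx_instance(n, fr, b))
}

# pure-R exhaustive minimum over all K^n colorings of covered residues
brute_force_r <- function(inst) {
  part <- compute_parts(inst)
  cov <- part$covered
  if (!length(cov)) return(list(optimum = 0L))
  grid <- expand.grid(rep(list(seq_len(inst$K)), length(cov)))
  errs <- apply(grid, 1, function(cols) {
    evaluate_assignment(inst, hdx_assignment(cols, cov))$total
  })
  list(optimum = min(errs),
       colorings = grid[errs == min(errs), , drop = FALSE])
}

# instance echoing the published worked example's shape: 28 residues,
# part {7,8,9} spanned by exactly fragments 1, 2, 6 and 8
worked_example_instance <- function() {
  fr <- rbind(c(1, 10), c(5, 12), c(12, 19), c(13, 22),
              c(20, 28), c(7, 9), c(23, 28), c(6, 11))
  K <- 3
  truth <- rep(1:3, length.out = 28)
  b <- t(sapply(seq_len(nrow(fr)), function(f)
    tabulate(truth[fr[f, 1]:fr[f, 2]], nbins = K)))
  suppressWarnings(hdx_instance(28, fr, b))
}
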