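make_solution_set <- function(inst, sols, expansions = rep(1, length(sols))) {
  part <- compute_parts(inst)
  opt <- if (length(sols)) {
    as.integer(min(sapply(sols, function(y) error_from_counts(inst, part, y)$total)))
  } else NA_integer_
  structure(list(formulation = "improved", bound = opt,
                 partition = part, n_solutions = length(sols),
                 solutions = sols, expansions = expansions,
                 n_expanded = sum(expansions), optimum = opt),
            class = "hdx_solution_set")
}

test_that("rates discretize with inclusive extreme boundaries", {
  expect_identical(discretize_rates(c(0.05, 0.1, 1.0, 8, 20, NA)),
                   c(1L, 1L, 2L, 3L, 3L, NA))
  expect_error(discretize_rates(-0.5), "nonnegative")
})

test_that("consensus methods follow their stated constructions", {
  inst <- suppressWarnings(hdx_instance(2, rbind(c(1, 2)), rbind(c(2, 0, 0))))
  sols <- list(matrix(c(2L, 0L, 0L), 1), matrix(c(0L, 2L, 0L), 1))
  ss <- make_solution_set(inst, sols)

  # size-1 set: every method returns that solution
  ss1 <- make_solution_set(inst, sols[1])
  for (m in c("single", "majority", "mean"))
    expect_identical(consensus(ss1, m)$y, sols[[1]])

  expect_identical(consensus(ss, "single")$y, sols[[1]])
  # largest remainder on summed counts (2,2,0) for 2 seats: (1,1,0)
  expect_identical(unname(consensus(ss, "majority")$y[1, ]), c(1L, 1L, 0L))
  # mean ordinal 1.5 per slot rounds half-to-even to color 2: (0,2,0)
  expect_identical(unname(consensus(ss, "mean")$y[1, ]), c(0L, 2L, 0L))

  # expansion weighting with a single class equals class weighting
  g <- generate_instance(synthetic_spec(8, mean_length = 4, noise_moves = 1,
                                        seed = 71))
  es <- enumerate_optimal(g$instance)
  one <- make_solution_set(g$instance, es$solutions[1], es$expansions[1])
  expect_identical(consensus(one, "majority", "class")$y,
                   consensus(one, "majority", "expanded")$y)

  expect_error(consensus(make_solution_set(inst, list())), "empty")
})

test_that("the single-solution consensus attains the optimum error", {
  set.seed(701)
  for (i in 1:8) {
    inst <- rand_instance(sample(5:9, 1))
    es <- enumerate_optimal(inst)
    cs <- consensus(es, "single")
    expect_identical(error_from_counts(inst, es$partition, cs$y)$total,
                     as.numeric(es$optimum))
  }
})

test_that("agreement scoring compares per-part multisets", {
  inst <- hdx_instance(3, rbind(c(1, 3)), rbind(c(2, 1, 0)))
  part <- compute_parts(inst)
  pred <- matrix(c(2L, 1L, 0L), 1)
  # identical counts: 100%
  expect_identical(agreement_score(pred, c(1L, 1L, 2L), part)$score, 100)
  # (2,1,0) vs (1,2,0): matched min(2,1)+min(1,2) = 2 of 3
  r <- agreement_score(pred, c(1L, 2L, 2L), part)
  expect_equal(r$score, 100 * 2 / 3)
  # missing reference excluded from numerator and denominator
  r2 <- agreement_score(pred, c(NA, NA, NA), part)
  expect_true(is.na(r2$score))
  r3 <- agreement_score(pred, c(1L, NA, 2L), part)
  expect_identical(r3$compared, 2L)
  expect_identical(r3$matched, 2L)

  # symmetry and invariance to within-part permutation of the reference
  set.seed(702)
  for (i in 1:10) {
    inst <- rand_instance(sample(5:9, 1))
    part <- compute_parts(inst)
    K <- inst$K
    ya <- t(sapply(part$sizes, function(s) tabulate(sample(K, s, TRUE), K)))
    ref <- rep(NA_integer_, inst$n)
    for (p in seq_along(part$parts))
      ref[part$parts[[p]]] <- sample(K, part$sizes[p], TRUE)
    refcounts <- t(sapply(seq_along(part$parts), function(p)
      tabulate(ref[part$parts[[p]]], K)))
    s1 <- agreement_score(ya, ref, part)$score
    ref2 <- ref
    for (p in seq_along(part$parts)) {  # permute reference within parts
      v <- ref[part$parts[[p]]]
      ref2[part$parts[[p]]] <- v[sample.int(length(v))]
    }
    expect_equal(agreement_score(ya, ref2, part)$score, s1)
    # symmetry: swap roles of prediction and reference
    pred_res <- rep(NA_integer_, inst$n)
    for (p in seq_along(part$parts))
      pred_res[part$parts[[p]]] <- rep(seq_len(K), times = ya[p, ])
    expect_equal(agreement_score(refcounts, pred_res, part)$score, s1)
  }
})

test_that("residue-level comparison marks agreement, mismatch and gaps", {
  inst <- hdx_instance(5, rbind(c(2, 4)), rbind(c(1, 1, 1)))
  es <- enumerate_optimal(inst)
  cs <- consensus(es, "single")
  cmp <- residue_comparison(cs, c(1L, 1L, NA, 3L, 2L), 5)
  expect_identical(cmp$symbol[1], "-")    # residue 1 uncovered
  expect_identical(cmp$symbol[3], "?")    # reference missing
  expect_identical(nrow(cmp), 5L)
})
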