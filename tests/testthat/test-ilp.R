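test_that("both ILP formulations solve hand-checked instances exactly", {
  i1 <- hdx_instance(3, rbind(c(1, 3)), rbind(c(1, 1, 1)))
  s1 <- solve_min_error(i1, "improved")
  expect_identical(s1$optimum, 0L)
  expect_identical(unname(s1$y[1, ]), c(1L, 1L, 1L))
  expect_identical(solve_min_error(i1, "basic")$optimum, 0L)

  # noise-free planted data is exactly satisfiable
  g <- generate_instance(synthetic_spec(10, mean_length = 4, noise_moves = 0,
                                        seed = 17))
  expect_identical(solve_min_error(g$instance)$optimum, 0L)
})

test_that("the compiled exhaustive oracle agrees with a pure-R brute force", {
  set.seed(501)
  for (i in 1:8) {
    inst <- rand_instance(sample(4:6, 1), nf = sample(2:3, 1))
    expect_identical(solve_exhaustive(inst)$optimum,
                     as.integer(brute_force_r(inst)$optimum))
  }
})

test_that("branch-and-bound optima equal the exhaustive minimum", {
  set.seed(502)
  for (i in 1:25) {
    inst <- rand_instance(sample(5:11, 1), nf = sample(2:6, 1))
    bf <- solve_exhaustive(inst)$optimum
    expect_identical(solve_min_error(inst, "improved")$optimum, bf)
  }
  # basic formulation on a smaller sample (one engine, aggregated units)
  for (i in 1:8) {
    inst <- rand_instance(sample(4:7, 1), nf = sample(2:4, 1))
    expect_identical(solve_min_error(inst, "basic")$optimum,
                     solve_exhaustive(inst)$optimum)
  }
})

test_that("enumeration is complete, duplicate-free and bound-monotone", {
  set.seed(503)
  for (i in 1:10) {
    inst <- rand_instance(sample(5:9, 1))
    es <- enumerate_optimal(inst)
    expect_gte(es$n_solutions, 1L)
    keys <- sapply(es$solutions, function(y) paste(t(y), collapse = ","))
    expect_identical(anyDuplicated(keys), 0L)
    errs <- sapply(es$solutions, function(y)
      error_from_counts(inst, es$partition, y)$total)
    expect_true(all(errs == es$optimum))
    # raising the bound never shrinks the set
    es2 <- enumerate_optimal(inst, error_bound = es$optimum + 1)
    expect_gte(es2$n_solutions, es$n_solutions)
    keys2 <- sapply(es2$solutions, function(y) paste(t(y), collapse = ","))
    expect_true(all(keys %in% keys2))
    # a bound below the optimum yields an empty set, not an error
    if (es$optimum > 0) {
      expect_identical(enumerate_optimal(inst, es$optimum - 1)$n_solutions, 0L)
    }
  }
})

test_that("basic-level solutions expand the improved-level classes exactly", {
  set.seed(504)
  for (i in 1:6) {
    inst <- rand_instance(sample(4:7, 1), nf = sample(2:4, 1))
    ei <- enumerate_optimal(inst, formulation = "improved")
    eb <- enumerate_optimal(inst, formulation = "basic")
    expect_identical(eb$optimum, ei$optimum)
    expect_identical(as.numeric(eb$n_solutions), ei$n_expanded)
    expect_lte(ei$n_solutions, eb$n_solutions)
  }
})

test_that("unique-solution instances enumerate to a single class", {
  # every residue pinned by nested fragments
  inst <- hdx_instance(3, rbind(c(1, 3), c(2, 3), c(3, 3)),
                       rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1)))
  es <- enumerate_optimal(inst)
  expect_identical(es$n_solutions, 1L)
  expect_identical(unname(es$solutions[[1]]),
                   matrix(c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3, 3, byrow = TRUE))
})

test_that("LP relaxation is integral for two colors but can drop below for three", {
  set.seed(505)
  for (i in 1:10) {
    inst <- rand_instance(sample(4:9, 1), K = 2)
    expect_equal(lp_relaxation_value(inst),
                 solve_min_error(inst)$optimum, tolerance = 1e-6)
  }
  for (i in 1:10) {
    inst <- rand_instance(sample(5:9, 1), K = 3)
    expect_lte(lp_relaxation_value(inst),
               solve_min_error(inst)$optimum + 1e-6)
  }
})

test_that("solution sets serialize to JSON and TSV", {
  set.seed(506)
  inst <- rand_instance(7)
  es <- enumerate_optimal(inst)
  jp <- file.path(tempdir(), "sols.json")
  tp <- file.path(tempdir(), "sols.tsv")
  write_solution_set(es, jp, tp)
  doc <- jsonlite::read_json(jp)
  expect_identical(doc$n_solutions, es$n_solutions)
  expect_identical(doc$optimum, as.integer(es$optimum))
  tsv <- readLines(tp)
  expect_identical(length(tsv) - 1L,
                   es$n_solutions * length(es$partition$sizes))
})
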