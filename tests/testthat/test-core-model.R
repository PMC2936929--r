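test_that("instances validate their intervals and counts", {
  inst <- hdx_instance(28, rbind(c(12, 19)), rbind(c(5, 2, 1)))
  expect_identical(unname(inst$fragments[1, ]), c(12L, 19L))
  expect_identical(unname(inst$requirements[1, ]), c(5L, 2L, 1L))
  expect_identical(fragment_lengths(inst), 8L)

  # empty fragment list is a valid (vacuous) instance
  empty <- hdx_instance(10, matrix(integer(), 0, 2), matrix(integer(), 0, 3))
  expect_s3_class(empty, "hdx_instance")
  expect_identical(nrow(empty$fragments), 0L)

  expect_error(hdx_instance(28, rbind(c(19, 12)), rbind(c(5, 2, 1))),
               "invalid fragment interval")
  expect_error(hdx_instance(10, rbind(c(1, 11)), rbind(c(5, 2, 4))),
               "invalid fragment interval")
  expect_error(hdx_instance(10, rbind(c(1, 5)), rbind(c(-1, 2, 4))),
               "negative requirement")
  # inconsistent counts warn but do not fail
  expect_warning(hdx_instance(10, rbind(c(1, 5)), rbind(c(1, 1, 1))),
                 "sum to fragment length")
  w <- capture_warnings(hdx_instance(10, rbind(c(1, 3)), rbind(c(4, 0, 0))))
  expect_true(any(grepl("exceeds the fragment length", w)))
})

test_that("parts are maximal runs with identical fragment sets", {
  inst <- hdx_instance(5, rbind(c(1, 3), c(2, 5)), rbind(c(2, 1), c(1, 3)),
                       color_names = c("s", "f"))
  part <- compute_parts(inst)
  expect_identical(part$parts, list(1L, 2:3, 4:5))
  expect_identical(unname(part$sizes), c(1L, 2L, 2L))
  expect_identical(part$A, matrix(c(1L, 0L, 1L, 1L, 0L, 1L), 2, 3))

  # the worked-example shape: residues 7-9 lie in exactly fragments 1,2,6,8
  we <- worked_example_instance()
  wp <- compute_parts(we)
  memb <- sapply(seq_len(nrow(we$fragments)), function(f)
    we$fragments[f, 1] <= 7 & we$fragments[f, 2] >= 9)
  expect_identical(unname(which(memb)), c(1L, 2L, 6L, 8L))
  pid <- wp$part_of[7]
  expect_identical(wp$parts[[pid]], 7:9)
  expect_identical(which(wp$A[, pid] == 1L), c(1L, 2L, 6L, 8L))

  # single full-length fragment: one part of size n
  one <- hdx_instance(9, rbind(c(1, 9)), rbind(c(3, 3, 3)))
  expect_identical(compute_parts(one)$sizes, 9L)
})

test_that("every part is inside or disjoint from every fragment, with consecutive ones", {
  set.seed(101)
  for (i in 1:25) {
    inst <- rand_instance(sample(5:14, 1))
    part <- compute_parts(inst)
    for (f in seq_len(nrow(inst$fragments))) {
      rng <- inst$fragments[f, 1]:inst$fragments[f, 2]
      for (p in seq_along(part$parts)) {
        inter <- length(intersect(part$parts[[p]], rng))
        expect_true(inter == 0L || inter == length(part$parts[[p]]))
      }
      ones <- which(part$A[f, ] == 1L)
      if (length(ones)) expect_identical(ones, min(ones):max(ones))
    }
    expect_identical(sort(unlist(part$parts)), part$covered)
  }
})

test_that("overlap components define independent subproblems", {
  i1 <- hdx_instance(7, rbind(c(1, 3), c(5, 7)), rbind(c(3, 0), c(0, 3)),
                     color_names = c("s", "f"))
  expect_length(decompose_subproblems(i1), 2L)

  i2 <- hdx_instance(9, rbind(c(1, 4), c(4, 6), c(8, 9)),
                     rbind(c(4, 0), c(3, 0), c(2, 0)),
                     color_names = c("s", "f"))
  comps <- decompose_subproblems(i2)
  expect_identical(lapply(comps, `[[`, "fragments"), list(c(1L, 2L), 3L))

  i3 <- hdx_instance(8, rbind(c(1, 3), c(2, 5), c(4, 8)),
                     rbind(c(3, 0), c(4, 0), c(5, 0)),
                     color_names = c("s", "f"))
  expect_length(decompose_subproblems(i3), 1L)

  # oracle: pairwise overlap graph components on random instances
  set.seed(102)
  for (i in 1:20) {
    inst <- rand_instance(sample(6:12, 1))
    fr <- inst$fragments
    nf <- nrow(fr)
    adj <- outer(seq_len(nf), seq_len(nf), Vectorize(function(a, b)
      max(fr[a, 1], fr[b, 1]) <= min(fr[a, 2], fr[b, 2])))
    lab <- seq_len(nf)
    repeat {
      new <- sapply(seq_len(nf), function(v) min(lab[adj[v, ]]))
      if (identical(new, lab)) break
      lab <- new
    }
    want <- unname(split(seq_len(nf), lab))
    got <- lapply(decompose_subproblems(inst), `[[`, "fragments")
    expect_identical(got[order(sapply(got, min))],
                     want[order(sapply(want, min))])
  }
})

test_that("assignment errors follow the absolute-deviation objective", {
  inst <- hdx_instance(28, rbind(c(12, 19)), rbind(c(5, 2, 1)))
  pi1 <- hdx_assignment(c(rep(1, 5), 2, 2, 3), 12:19)
  expect_identical(unname(evaluate_assignment(inst, pi1)$e[1, ]), c(0L, 0L, 0L))
  pi2 <- hdx_assignment(c(rep(1, 5), 2, 2, 2), 12:19)
  expect_identical(unname(evaluate_assignment(inst, pi2)$e[1, ]), c(0L, 1L, 1L))

  i3 <- hdx_instance(3, rbind(c(1, 3)), rbind(c(1, 1, 1)))
  rep3 <- evaluate_assignment(i3, hdx_assignment(c(1, 1, 1)))
  expect_identical(unname(rep3$e[1, ]), c(2L, 1L, 1L))
  expect_identical(rep3$total, 4L)

  expect_error(evaluate_assignment(i3, hdx_assignment(1, 1)),
               "missing covered residue")
})

test_that("count aggregation preserves the error and counts expansions", {
  set.seed(103)
  for (i in 1:20) {
    inst <- rand_instance(sample(5:10, 1))
    part <- compute_parts(inst)
    cols <- sample(seq_len(inst$K), length(part$covered), TRUE)
    a <- hdx_assignment(cols, part$covered)
    y <- counts_from_assignment(part, a, inst$K)
    expect_identical(as.integer(rowSums(y)), unname(part$sizes))
    expect_identical(error_from_counts(inst, part, y)$total,
                     as.numeric(evaluate_assignment(inst, a)$total))
  }

  # permuting colors within one part never changes the error
  inst <- worked_example_instance()
  part <- compute_parts(inst)
  cols <- sample(1:3, length(part$covered), TRUE)
  a <- hdx_assignment(cols, part$covered)
  p <- which(sapply(part$parts, length) >= 2)[1]
  swap <- part$parts[[p]][1:2]
  cols2 <- cols
  i1 <- match(swap[1], part$covered); i2 <- match(swap[2], part$covered)
  cols2[c(i1, i2)] <- cols2[c(i2, i1)]
  expect_identical(evaluate_assignment(inst, a)$total,
                   evaluate_assignment(inst, hdx_assignment(cols2, part$covered))$total)
})

test_that("expansion counts match brute-force enumeration of orderings", {
  part1 <- compute_parts(hdx_instance(3, rbind(c(1, 1), c(2, 2), c(3, 3)),
                                      rbind(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0))))
  expect_identical(count_expansions(part1, matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0), 3, 3)), 1)

  part2 <- compute_parts(hdx_instance(3, rbind(c(1, 3)), rbind(c(1, 1, 1))))
  expect_identical(count_expansions(part2, matrix(c(1, 1, 1), 1, 3)), 6)
  expect_length(expand_counts(part2, matrix(c(1, 1, 1), 1, 3)), 6L)

  # sizes (2, 3) with rows (1,1,0) and (2,0,1): 2 * 3 = 6, matching the
  # number of distinct colorings enumerated directly
  inst <- hdx_instance(5, rbind(c(1, 2), c(3, 5)), rbind(c(1, 1, 0), c(2, 0, 1)))
  part <- compute_parts(inst)
  y <- rbind(c(1L, 1L, 0L), c(2L, 0L, 1L))
  expect_identical(count_expansions(part, y), 6)
  expanded <- expand_counts(part, y)
  keys <- sapply(expanded, function(a) paste(unclass(a), collapse = ","))
  expect_identical(length(unique(keys)), 6L)

  expect_error(count_expansions(part, rbind(c(1L, 0L, 0L), c(2L, 0L, 1L))),
               "row sums")
})

test_that("subproblem optima add up to the whole-instance optimum", {
  set.seed(104)
  for (i in 1:10) {
    inst <- rand_instance(sample(8:13, 1), nf = sample(3:5, 1))
    whole <- solve_min_error(inst, decompose = FALSE)$optimum
    split <- solve_min_error(inst, decompose = TRUE)
    expect_identical(split$optimum, whole)
    expect_identical(sum(sapply(split$per_subproblem, `[[`, "optimum")),
                     as.integer(whole))
  }
})
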