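test_that("per-color subproblems solve their interval program exactly", {
  # zero multipliers on satisfiable single-color data: value 0, y = b
  inst <- hdx_instance(6, rbind(c(1, 3), c(4, 6)), rbind(c(2, 1, 0), c(1, 1, 1)))
  part <- compute_parts(inst)
  r <- lagrangian_subproblem(inst, rep(0, length(part$sizes)), 1, partition = part)
  expect_identical(r$value, 0)
  expect_identical(unname(part$A %*% r$y)[, 1], c(2, 1))

  # huge positive multipliers force y to zero; value = sum of requirements
  big <- rep(100, length(part$sizes))
  r2 <- lagrangian_subproblem(inst, big, 1, partition = part)
  expect_identical(r2$y, rep(0L, length(part$sizes)))
  expect_equal(r2$value, sum(inst$requirements[, 1]))

  expect_error(lagrangian_subproblem(inst, rep(0, length(part$sizes) + 1), 1,
                                     partition = part),
               "one entry per part")
  expect_error(lagrangian_subproblem(inst, big, 1, lo = c(2, 2), hi = c(1, 1),
                                     partition = part),
               "lo exceeds hi")
})

test_that("subproblem values match brute force over the bound box", {
  set.seed(601)
  for (i in 1:25) {
    inst <- rand_instance(sample(4:8, 1))
    part <- compute_parts(inst)
    m <- length(part$sizes)
    lam <- round(runif(m, -3, 3), 2)
    lo <- sapply(part$sizes, function(s) sample(0:s, 1))
    hi <- pmin(part$sizes, lo + sapply(part$sizes, function(s) sample(0:s, 1)))
    k <- sample(inst$K, 1)
    r <- lagrangian_subproblem(inst, lam, k, lo, hi, part)
    grid <- expand.grid(lapply(seq_len(m), function(p) lo[p]:hi[p]))
    vals <- apply(grid, 1, function(y)
      sum(abs(inst$requirements[, k] - as.numeric(part$A %*% y))) + sum(lam * y))
    expect_equal(r$value, min(vals), tolerance = 1e-9)
    expect_true(all(r$y >= lo & r$y <= hi))
  }
})

test_that("the dual lower-bounds the optimum for every multiplier vector", {
  set.seed(602)
  for (i in 1:15) {
    inst <- rand_instance(sample(4:9, 1))
    part <- compute_parts(inst)
    opt <- solve_exhaustive(inst)$optimum
    for (j in 1:6) {
      lam <- round(runif(length(part$sizes), -4, 4), 2)
      expect_lte(evaluate_dual(inst, lam, part), opt + 1e-9)
    }
  }
  # noise-free data: z(0) = 0 and the optimum is 0
  g <- generate_instance(synthetic_spec(10, mean_length = 4, noise_moves = 0,
                                        seed = 61))
  part <- compute_parts(g$instance)
  expect_identical(evaluate_dual(g$instance, rep(0, length(part$sizes)), part), 0)
})

test_that("subgradient ascent closes the gap to the LP relaxation", {
  set.seed(603)
  for (i in 1:10) {
    inst <- rand_instance(sample(5:10, 1))
    sg <- subgradient_optimize(inst)
    opt <- solve_min_error(inst)$optimum
    expect_lte(sg$best_bound, opt + 1e-6)
    lpv <- lp_relaxation_value(inst)
    expect_gte(sg$best_bound, lpv - 0.1)
  }
  # zero duality gap certified on noise-free data
  g <- generate_instance(synthetic_spec(12, mean_length = 4, noise_moves = 0,
                                        seed = 63))
  sg <- subgradient_optimize(g$instance)
  expect_true(sg$zero_subgradient)
  expect_equal(sg$feasible_error, 0)
})

test_that("Lagrangian branch-and-bound reproduces the ILP solution set", {
  set.seed(604)
  for (i in 1:15) {
    inst <- rand_instance(sample(5:10, 1))
    li <- branch_and_bound_enumerate(inst)
    ei <- enumerate_optimal(inst)
    expect_identical(li$optimum, ei$optimum)
    expect_identical(li$n_solutions, ei$n_solutions)
    expect_identical(li$solutions, ei$solutions)
  }
})

test_that("the subgradient trajectory is deterministic", {
  set.seed(605)
  inst <- rand_instance(9, noise = 2)
  a <- subgradient_optimize(inst)
  b <- subgradient_optimize(inst)
  expect_identical(a$best_bound, b$best_bound)
  expect_identical(a$best_lambda, b$best_lambda)
  expect_identical(a$iterations, b$iterations)
  e1 <- branch_and_bound_enumerate(inst)
  e2 <- branch_and_bound_enumerate(inst)
  expect_identical(e1$solutions, e2$solutions)
})
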