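write_test_instance <- function(noise = 1, seed = 91, n = 24) {
  g <- generate_instance(synthetic_spec(n, mean_length = 6, multiplicity = 2,
                                        noise_moves = noise, seed = seed))
  path <- file.path(tempdir(), sprintf("run_%d_%d.tsv", seed, noise))
  write_fragment_table(g$instance, path)
  list(path = path, gen = g)
}

test_that("an end-to-end run reports per-subproblem errors that add up", {
  tf <- write_test_instance(noise = 2)
  out <- file.path(tempdir(), "runout")
  cfg <- hdx_config(tf$path, solver = "ilp-improved", enumerate = TRUE,
                    out_prefix = out)
  res <- hdx_run(cfg)
  s <- res$summary
  expect_identical(sum(sapply(s$subproblems, `[[`, "epsilon")), s$epsilon)
  expect_identical(s$n_subproblems, length(s$subproblems))
  expect_true(file.exists(paste0(out, "_summary.json")))
  expect_true(file.exists(paste0(out, "_solution.tsv")))
  doc <- jsonlite::read_json(paste0(out, "_summary.json"))
  expect_identical(doc$epsilon, s$epsilon)

  # noise-free data runs to epsilon 0
  tf0 <- write_test_instance(noise = 0, seed = 92)
  res0 <- hdx_run(hdx_config(tf0$path, solver = "lagrange"))
  expect_identical(res0$summary$epsilon, 0L)
})

test_that("solver guards reject contradictory configurations", {
  tf <- write_test_instance(noise = 0, seed = 93)
  expect_error(hdx_run(hdx_config(tf$path, solver = "flow2")), "requires")
  expect_error(hdx_config(tf$path, solver = "nonsense"))
  expect_error(hdx_config(tf$path, error_bound = -1), "nonnegative")
})

test_that("identical configurations produce byte-identical outputs", {
  tf <- write_test_instance(noise = 1, seed = 94)
  o1 <- file.path(tempdir(), "det1")
  o2 <- file.path(tempdir(), "det2")
  hdx_run(hdx_config(tf$path, solver = "ilp-improved", enumerate = TRUE,
                     out_prefix = o1, seed = 3))
  hdx_run(hdx_config(tf$path, solver = "ilp-improved", enumerate = TRUE,
                     out_prefix = o2, seed = 3))
  for (suffix in c("_summary.json", "_solution.tsv")) {
    f1 <- paste0(o1, suffix); f2 <- paste0(o2, suffix)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
  }
})

test_that("solvers agree end-to-end on the same input", {
  tf <- write_test_instance(noise = 2, seed = 95)
  eps <- sapply(c("ilp-improved", "ilp-basic", "lagrange"), function(sv)
    hdx_run(hdx_config(tf$path, solver = sv))$summary$epsilon)
  expect_true(all(eps == eps[[1]]))
  heur <- hdx_run(hdx_config(tf$path, solver = "heuristic"))$summary$epsilon
  expect_gte(heur, eps[[1]])
})

test_that("comparison against a reference table is wired through", {
  tf <- write_test_instance(noise = 0, seed = 96)
  ref <- file.path(tempdir(), "ref.tsv")
  write_class_table(tf$gen$planted_full, ref,
                    color_names = tf$gen$instance$color_names)
  res <- hdx_run(hdx_config(tf$path, solver = "ilp-improved", reference = ref))
  expect_false(is.null(res$comparison))
  expect_true(res$comparison$score >= 0 && res$comparison$score <= 100)
})

test_that("the command-line front end runs the documented subcommands", {
  cli <- system.file("cli", "hdxresolve.R", package = "hdxresolve")
  env <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  out <- file.path(tempdir(), "clisim")
  r1 <- suppressWarnings(system2("Rscript", c(cli, "simulate", "--n", "20",
                                              "--seed", "4", "--noise", "1",
                                              "--out", out),
                                 stdout = TRUE, stderr = TRUE, env = env))
  expect_true(file.exists(paste0(out, "_fragments.tsv")))
  r2 <- suppressWarnings(system2("Rscript", c(cli, "solve", "--input",
                                              paste0(out, "_fragments.tsv"),
                                              "--solver", "lagrange",
                                              "--out", file.path(tempdir(), "clirun")),
                                 stdout = TRUE, stderr = TRUE, env = env))
  expect_identical(attr(r2, "status"), NULL)
  expect_true(any(grepl("epsilon=", r2)))
})
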