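test_that("recovery score is the community-count ratio", {
  expect_equal(recovery_score(10, 10), 1)
  expect_equal(recovery_score(12, 10), 1.2)
  expect_equal(recovery_score(5, 10), 0.5)
  expect_error(recovery_score(0, 10), "positive")
  expect_error(recovery_score(10, 0), "positive")
})

test_that("a single run wires the whole pipeline together", {
  p <- sfm_params(n_I = 5, n_D = 5, sigma_I = 10, sigma_D = 1, n_exp = 10)
  run <- run_single_simulation(p, seed = 1, keep = TRUE)
  expect_s3_class(run, "sfm_run")
  expect_length(run$movements, 10)
  expect_true(all(vapply(run$movements, length, integer(1)) == 30L))
  expect_equal(dim(unclass(run$graph)), c(30, 30))
  expect_equal(graph_half_weight(run$graph), 29 * 10)
  expect_equal(run$score, run$n_eval / 5)
  expect_length(unclass(run$partition), 30)
})

test_that("each movement draws a fresh population realization", {
  p <- sfm_params(n_I = 3, n_D = 2, sigma_I = 10, n_exp = 3)
  run <- run_single_simulation(p, seed = 2, keep = TRUE)
  expect_false(identical(run$populations[[1]]$locations,
                         run$populations[[2]]$locations))
  # but memberships are fixed by the parameters
  expect_identical(run$populations[[1]]$subgroup,
                   run$populations[[2]]$subgroup)
})

test_that("runs are reproducible from their seed", {
  p <- sfm_params(n_I = 4, n_D = 3, sigma_I = 5, n_exp = 5)
  a <- run_single_simulation(p, seed = 42, keep = TRUE)
  b <- run_single_simulation(p, seed = 42, keep = TRUE)
  expect_identical(a$partition, b$partition)
  expect_identical(lapply(a$movements, as.integer),
                   lapply(b$movements, as.integer))
  expect_identical(unclass(a$graph), unclass(b$graph))
})

test_that("degenerate single-agent runs are refused", {
  expect_error(
    run_single_simulation(sfm_params(1, 0, sigma_I = 1), seed = 1),
    "degenerate")
})

test_that("a two-agent path forces one community and score 1/n_I", {
  p <- sfm_params(n_I = 1, n_D = 1, sigma_I = 5, n_exp = 1)
  run <- run_single_simulation(p, seed = 3)
  expect_equal(sum(run$graph), 2)  # single unit edge
  expect_equal(run$n_eval, 1L)
  expect_equal(run$score, 1 / p$n_I)

  p2 <- sfm_params(n_I = 2, n_D = 0, sigma_I = 5, n_exp = 1)
  run2 <- run_single_simulation(p2, seed = 3)
  expect_equal(run2$n_eval, 1L)
  expect_equal(run2$score, 0.5)
})

test_that("average_score reduces to the single replicate at n_reps = 1", {
  p <- sfm_params(n_I = 3, n_D = 3, sigma_I = 50, n_exp = 5)
  res <- average_score(p, n_reps = 1, seed = 9)
  seeds <- singlefile:::derive_seeds(9, 1)
  expect_equal(res$mean_r,
               run_single_simulation(p, seed = seeds[1])$score)
  expect_true(is.na(res$sd_r))
})

test_that("sweep emits one row per grid point and is seed-reproducible", {
  sw <- sweep_scores(n_I = c(2, 3), n_D = c(1, 2), sigma_I = c(10, 100),
                     n_exp = 2, n_reps = 2, seed = 4)
  expect_s3_class(sw, "sfm_sweep")
  expect_equal(nrow(sw), 2 * 2 * 2 * 1)
  expect_named(as.data.frame(sw),
               c("n_I", "n_D", "sigma_I", "n_exp", "n_reps",
                 "mean_r", "sd_r"))
  sw2 <- sweep_scores(n_I = c(2, 3), n_D = c(1, 2), sigma_I = c(10, 100),
                      n_exp = 2, n_reps = 2, seed = 4)
  expect_identical(sw, sw2)

  one <- sweep_scores(n_I = 3, n_D = 2, sigma_I = 10, n_exp = 2,
                      n_reps = 1, seed = 4)
  expect_equal(nrow(one), 1)
})

test_that("default grid covers the reference evaluation axes", {
  g <- default_sweep_grid()
  expect_equal(prod(lengths(g)), 4000)
})

test_that("separated subgroups are recovered almost surely", {
  p <- sfm_params(n_I = 5, n_D = 5, sigma_I = 1e6, n_exp = 30)
  res <- average_score(p, n_reps = 30, seed = 123)
  expect_gte(mean(res$scores == 1), 0.99)
})
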