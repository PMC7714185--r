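test_that("merge delta matches hand-computed cases", {
  tri2 <- two_triangles()
  d <- merge_modularity_delta(tri2, c(1, 1, 1, 2, 2, 2), 1, 2)
  expect_equal(d$m, 0)
  expect_equal(d$K_p, 6)
  expect_equal(d$K_q, 6)
  expect_equal(d$M, 6)
  expect_equal(d$delta, -0.5)

  pair <- structure(matrix(c(0L, 1L, 1L, 0L), 2), class = "sfm_graph")
  d2 <- merge_modularity_delta(pair, c(1, 2), 1, 2)
  expect_equal(d2$delta, 0.5)

  expect_error(merge_modularity_delta(tri2, c(1, 1, 1, 2, 2, 2), 1, 1),
               "distinct")
  expect_error(merge_modularity_delta(tri2, c(1, 1, 1, 2, 2, 2), 1, 9),
               "present")
})

test_that("merge delta equals the direct modularity difference", {
  set.seed(14)
  for (case in 1:25) {
    n <- sample(5:20, 1)
    G <- random_weighted_graph(n)
    m <- random_partition(n, k = sample(2:5, 1))
    labs <- unique(m)
    pq <- sample(labs, 2)
    d <- merge_modularity_delta(G, m, pq[1], pq[2])
    merged <- m
    merged[merged == pq[2]] <- pq[1]
    expect_equal(d$delta, modularity_q(G, merged) - modularity_q(G, m),
                 tolerance = 1e-12)
  }
})

test_that("expected between-subgroup weight reports both normalizations", {
  e <- expected_between_weight(10, 30)
  expect_equal(e$as_printed, 3)
  expect_equal(e$enumeration, 6)  # twice the printed value

  e2 <- expected_between_weight(2, 10)
  expect_equal(e2$enumeration, 10)  # the unique pair is adjacent always
  expect_equal(e2$n_orderings, 2L)

  expect_error(expected_between_weight(1, 10), "n_I")

  # enumeration equals the closed-form adjacency probability 2/n_I
  for (nI in 3:6) {
    e <- expected_between_weight(nI, 12)
    expect_equal(e$enumeration, 2 * 12 / nI)
    expect_equal(e$n_orderings, factorial(nI))
  }
  # beyond the enumeration cap the closed form is used directly
  big <- expected_between_weight(9, 12)
  expect_equal(big$enumeration, 2 * 12 / 9)
  expect_true(is.na(big$n_orderings))
})

test_that("sufficient-condition bound and prefactor match direct substitution", {
  b <- sufficient_condition_bound(
    sfm_params(n_I = 10, n_D = 5, sigma_I = 10, n_exp = 30))
  expect_equal(b$M, 1770)
  expect_equal(b$bound, 22500 / 3540)
  expect_equal(b$prefactor, 2.5 * 5 / 5.9)
  expect_true(b$holds_printed)
  expect_true(b$holds_enumeration)

  b0 <- sufficient_condition_bound(
    sfm_params(n_I = 3, n_D = 0, sigma_I = 10, n_exp = 10))
  expect_equal(b0$bound, 0)
  expect_equal(b0$prefactor, 0)
})

test_that("empirical between weight sums across the true boundary", {
  # hand-built 4-node graph, subgroups {1,2} and {3,4}, one crossing edge
  A <- matrix(0L, 4, 4)
  A[1, 2] <- A[2, 1] <- 3L
  A[3, 4] <- A[4, 3] <- 2L
  A[2, 3] <- A[3, 2] <- 1L
  pop <- fake_population(matrix(0, 4, 2), subgroup = c(1L, 1L, 2L, 2L),
                         n_I = 2)
  e <- empirical_between_weight(structure(A, class = "sfm_graph"), pop, 1, 2)
  expect_equal(e$m, 1)
  expect_equal(e$K_p, 3 + 4)   # strengths 3 and 3+1
  expect_equal(e$K_q, 3 + 2)   # strengths 2+1 and 2

  nox <- A; nox[2, 3] <- nox[3, 2] <- 0L
  expect_equal(
    empirical_between_weight(structure(nox, class = "sfm_graph"),
                             pop, 1, 2)$m, 0)
  expect_error(empirical_between_weight(A, pop, 1, 1), "distinct")
  expect_error(empirical_between_weight(A, pop, 1, 5), "subgroup")
})

test_that("simulated between weight matches the block-ordering expectation", {
  # separated regime, n_I = 2: the unique subgroup pair is adjacent in
  # every movement, so m = n_exp deterministically (up to the vanishing
  # block-mixing probability)
  p <- sfm_params(n_I = 2, n_D = 3, sigma_I = 1e6, n_exp = 10)
  set.seed(31)
  ms <- replicate(300, {
    run <- run_single_simulation(p, keep = TRUE)
    empirical_between_weight(run$graph, run$populations[[1]], 1, 2)$m
  })
  expected <- expected_between_weight(2, 10)$enumeration
  expect_equal(mean(ms), expected, tolerance = 0.01)
})

test_that("true partition resists every single merge when the weight condition holds", {
  p <- sfm_params(n_I = 4, n_D = 3, sigma_I = 1e6, n_exp = 10)
  set.seed(17)
  for (case in 1:10) {
    run <- run_single_simulation(p, keep = TRUE)
    sub <- run$populations[[1]]$subgroup
    q_true <- modularity_q(run$graph, sub)
    M <- graph_half_weight(run$graph)
    for (pq in utils::combn(p$n_I, 2, simplify = FALSE)) {
      e <- empirical_between_weight(run$graph, run$populations[[1]],
                                    pq[1], pq[2])
      merged <- sub
      merged[merged == pq[2]] <- pq[1]
      if (e$m < e$K_p * e$K_q / (2 * M))
        expect_gt(q_true, modularity_q(run$graph, merged))
    }
  }
})
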