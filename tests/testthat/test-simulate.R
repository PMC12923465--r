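test_that("trajectories are reproducible and well formed", {
  net <- random_network(5, seed = 1)
  t1 <- glauber_chain(net, sweeps = 200, seed = 7)
  t2 <- glauber_chain(net, sweeps = 200, seed = 7)
  expect_identical(t1$n, t2$n)
  expect_identical(t1$final_state, t2$final_state)
  expect_length(t1$n, 200 - t1$burn_in)
  expect_identical(t1$burn_in, 20L)
  t3 <- glauber_chain(net, sweeps = 50, seed = 7, burn_in = 0,
                      record_states = TRUE)
  expect_identical(dim(t3$states), c(50L, 5L))
  expect_true(all(t3$states %in% 0:1))
  expect_identical(rowSums(t3$states), as.double(t3$n))
  expect_error(glauber_chain(net, sweeps = 10, burn_in = 10), "burn_in")
})

test_that("one Glauber sweep preserves the Boltzmann distribution", {
  # brute-force transition operator averaged over all visit orders, N <= 4
  for (seed in c(6, 16)) {
    net <- random_network(3, seed = seed, w_max = 1.5, m_max = 1.5)
    op <- glauber_sweep_operator(net)
    p <- microstate_distribution(net)$probabilities
    expect_equal(as.vector(p %*% op), p, tolerance = 1e-10)
    # rows of the operator are proper distributions
    expect_equal(rowSums(op), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("long chains reproduce the exact macrostate distribution", {
  net <- random_network(5, seed = 8, w_max = 1, m_max = 1)
  tr <- glauber_chain(net, sweeps = 2e4, seed = 9)
  occ <- macrostate_occupancy(tr)
  exact <- macrostate_distribution(net)
  expect_lt(0.5 * sum(abs(occ - exact)), 0.03)
})

test_that("high beta concentrates the chain on the energy minimum", {
  net <- random_network(4, seed = 12, w_max = 1, m_max = 1)
  cold <- ising_network(net$thresholds, net$weights, beta = 100)
  dist <- microstate_distribution(cold)
  argmin <- which.min(dist$energies) - 1L
  tr <- glauber_chain(cold, sweeps = 4000, seed = 13, burn_in = 1000,
                      init = index_to_microstate(argmin, 4),
                      record_states = TRUE)
  idx <- apply(tr$states, 1, microstate_index)
  expect_gt(mean(idx == argmin), 0.95)
})

test_that("exact sampling matches enumeration marginals", {
  fair <- ising_network(c(0, 0), matrix(0, 2, 2))
  s <- sample_exact(fair, 1e5, seed = 3)
  expect_equal(unname(colMeans(s$values)), c(0.5, 0.5), tolerance = 0.01)

  net <- random_network(5, seed = 77, w_max = 1.2)
  draws <- sample_exact(net, 2e4, seed = 78)
  emp <- tabulate(rowSums(draws$values) + 1L, nbins = 6) / 2e4
  exact <- unname(macrostate_distribution(net))
  mc_se <- sqrt(exact * (1 - exact) / 2e4)
  expect_true(all(abs(emp - exact) < 3 * mc_se + 1e-9))

  empty <- sample_exact(net, 0)
  expect_identical(empty$person_count, 0L)
  expect_identical(empty$labels, net$labels)

  # the simulate() method is the same sampler
  expect_identical(simulate(net, nsim = 50, seed = 5)$values,
                   sample_exact(net, 50, seed = 5)$values)
})

test_that("exact sampler and Glauber chain agree on the n-distribution", {
  net <- random_network(4, seed = 21)
  exact_draws <- sample_exact(net, 2e4, seed = 22)
  tr <- glauber_chain(net, sweeps = 2e4, seed = 23)
  p1 <- tabulate(rowSums(exact_draws$values) + 1L, nbins = 5) / 2e4
  p2 <- unname(macrostate_occupancy(tr))
  expect_lt(0.5 * sum(abs(p1 - p2)), 0.04)
})

test_that("synthetic group generation is seeded and truthful", {
  base <- random_network(4, seed = 41, m_max = 0.5)
  g1 <- synthetic_group_data(base, threshold_shift = -1, n_per_group = 300,
                             seed = 5)
  g2 <- synthetic_group_data(base, threshold_shift = -1, n_per_group = 300,
                             seed = 5)
  expect_identical(g1$group_a$values, g2$group_a$values)
  expect_identical(g1$group_b$values, g2$group_b$values)
  expect_equal(g1$network_b$thresholds, base$thresholds - 1)
  # a negative shift lowers activation: check against enumeration expectations
  expect_lt(expected_active(g1$network_b), expected_active(g1$network_a))
  expect_lt(mean(rowSums(g1$group_b$values)),
            mean(rowSums(g1$group_a$values)))
  # identical parameters give exchangeable groups
  same <- synthetic_group_data(base, n_per_group = 2000, seed = 6)
  expect_equal(mean(rowSums(same$group_a$values)),
               mean(rowSums(same$group_b$values)),
               tolerance = 0.1)
})

test_that("trajectory TSV export records per-sweep counts", {
  net <- random_network(3, seed = 2)
  tr <- glauber_chain(net, sweeps = 30, seed = 2, burn_in = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(tr, f)
  tab <- utils::read.delim(f)
  expect_identical(names(tab), c("sweep", "n"))
  expect_identical(tab$n, tr$n)
  expect_identical(tab$sweep, 11:30)
})
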