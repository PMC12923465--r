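test_that("macrostate distribution groups the Boltzmann law by n", {
  flat <- ising_network(c(0, 0), matrix(0, 2, 2))
  expect_equal(unname(macrostate_distribution(flat)), c(0.25, 0.5, 0.25))

  for (seed in c(4, 40, 400)) {
    net <- random_network(sample(3:6, 1), seed = seed, w_max = 2, m_max = 2)
    p <- macrostate_distribution(net)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(unname(p), group_microstates(net), tolerance = 1e-14)
  }
})

test_that("independent nodes follow the Poisson-binomial closed form", {
  for (seed in 1:5) {
    n <- 3 + (seed %% 5)
    net <- withr::with_seed(seed, ising_network(
      stats::runif(n, -2, 2), matrix(0, n, n), beta = stats::runif(1, 0.5, 2)
    ))
    marg <- stats::plogis(net$beta * net$thresholds)
    expect_equal(unname(macrostate_distribution(net)), poisbinom_pmf(marg),
                 tolerance = 1e-13)
  }
})

test_that("the potential is the negative log of the macrostate law", {
  flat <- potential_landscape(ising_network(c(0, 0), matrix(0, 2, 2)))
  expect_equal(flat$potential, c(log(4), log(2), log(4)))
  expect_equal(flat$count, c(1, 2, 1))
  expect_equal(flat$n, 0:2)

  w <- matrix(c(0, log(2), log(2), 0), 2)
  land <- potential_landscape(ising_network(c(0, 0), w))
  expect_equal(land$potential, c(log(5), log(2.5), log(2.5)))

  net <- random_network(6, seed = 77)
  land <- potential_landscape(net)
  expect_equal(land$probability, exp(-land$potential))
  # ordering of U reverses the ordering of P_SS
  expect_identical(order(land$potential), rev(order(land$probability)))
  # extreme parameters stay finite through log-space evaluation
  hot <- potential_landscape(scale_parameters(net, 40, 40))
  expect_true(all(is.finite(hot$potential)))
})

test_that("increasing all thresholds increases the expected active count", {
  for (seed in c(3, 33)) {
    net <- random_network(5, seed = seed)
    shifted <- ising_network(net$thresholds + 0.5, net$weights,
                             beta = net$beta)
    expect_gt(expected_active(shifted), expected_active(net))
  }
})

test_that("local minima detection handles edges and plateaus", {
  expect_identical(locate_local_minima(c(1, 2, 1.5, 2.5, 0.5)), c(0L, 2L, 4L))
  expect_identical(locate_local_minima(c(1, 2, 3, 4)), 0L)   # increasing
  expect_identical(locate_local_minima(c(2, 2, 2)), c(0L, 2L)) # plateau
  expect_identical(locate_local_minima(c(3, 1, 1, 3, 0)), c(1L, 2L, 4L))
  expect_identical(locate_local_minima(c(1, 2, 1.5, 2.5, 0.5), c(1, 3)), 2L)
  expect_error(locate_local_minima(c(1, 2), c(2, 1)), "window")
  expect_error(locate_local_minima(c(1, 2), c(0, 5)), "window")
  # non-finite sentinel values are never minima
  expect_identical(locate_local_minima(c(Inf, 1, 2)), 1L)
})

test_that("barrier height scans the interior between two minima", {
  u <- c(1, 2, 1.5, 2.5, 0.5)
  expect_equal(barrier_height(u, 0, 4), 1.5)
  expect_equal(barrier_height(u, 4, 0), 2.0)
  expect_equal(barrier_height(u, 0, 2), 1.0)
  # symmetric double well: equal barriers iff equal depths
  v <- c(0.5, 2, 1, 2, 0.5)
  expect_equal(barrier_height(v, 0, 4), barrier_height(v, 4, 0))
  expect_error(barrier_height(u, 0, 1), "not a local minimum")
  expect_error(barrier_height(u, 3, 4), "not a local minimum")
  expect_warning(b <- barrier_height(c(2, 1, 1, 3), 1, 2)[[1]],
                 "adjacent")
  expect_equal(b, 0)
  # single-minimum landscape: no second minimum to connect to
  expect_error(barrier_height(c(1, 2, 3, 4), 0, 3), "undefined")
})

test_that("landscape TSV export has the fixed column layout", {
  net <- random_network(4, seed = 50)
  land <- potential_landscape(net)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_landscape_tsv(land, f)
  lines <- readLines(f)
  expect_identical(lines[1], "n\tcount\tprobability\tpotential")
  expect_length(lines, n_nodes(net) + 2)
  tab <- utils::read.delim(f)
  expect_equal(tab$n, 0:4)
  expect_equal(tab$count, choose(4, 0:4))
  expect_equal(tab$probability, unname(macrostate_distribution(net)),
               tolerance = 1e-11)
})

test_that("permuting node labels leaves the landscape unchanged", {
  net <- random_network(6, seed = 60)
  perm <- withr::with_seed(1, sample(6))
  l1 <- potential_landscape(net)
  l2 <- potential_landscape(permute_nodes(net, perm))
  expect_equal(l1$probability, l2$probability)
  expect_equal(l1$potential, l2$potential)
})
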