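make_groups <- function(shift = 0, n = 250, seed = 100) {
  base <- random_network(3, seed = 55, w_max = 0.6, m_max = 0.6)
  synthetic_group_data(base, threshold_shift = shift, n_per_group = n,
                       seed = seed)
}

test_that("bootstrap results are reproducible and coherent", {
  g <- make_groups()
  r1 <- bootstrap_stability(g$group_a, cutoff = 2, B = 120, seed = 31)
  r2 <- bootstrap_stability(g$group_a, cutoff = 2, B = 120, seed = 31)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(c(r1$ci_low, r1$ci_high), c(r2$ci_low, r2$ci_high))
  expect_identical(r1$p_value, r2$p_value)
  expect_equal(r1$estimate, stability_difference(g$group_a, 2))
  expect_lte(r1$ci_low, r1$ci_high)
  expect_false(r1$invalid)
  if (!r1$degenerate) {
    expect_gte(r1$estimate, r1$ci_low)
    expect_lte(r1$estimate, r1$ci_high)
    expect_true(r1$p_value >= 0 && r1$p_value <= 1)
  }
  expect_error(bootstrap_stability(g$group_a, 2, B = 50), "at least 100")
})

test_that("a constant statistic yields a degenerate bootstrap", {
  x <- matrix(rep(c(1L, 0L, 1L), each = 60), nrow = 60)
  colnames(x) <- c("a", "b", "c")
  r <- suppressWarnings(bootstrap_stability(x, cutoff = 2, B = 100, seed = 1))
  expect_equal(r$standard_error, 0)
  expect_identical(c(r$ci_low, r$ci_high), c(r$estimate, r$estimate))
  expect_true(r$degenerate)
  expect_true(is.na(r$p_value))
})

test_that("BCa machinery matches the boot package on shared replicates", {
  skip_if_not_installed("boot")
  x <- withr::with_seed(17, stats::rexp(40))
  bt <- withr::with_seed(18, boot::boot(x, function(d, i) mean(d[i]),
                                        R = 999))
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  influence <- isingscape:::.jack_influence(jack)
  for (conf in c(0.9, 0.95)) {
    ref <- boot::boot.ci(bt, conf = conf, type = "bca")$bca[4:5]
    mine <- isingscape:::.bca_ci(as.vector(bt$t), bt$t0, influence, conf)$ci
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("the inverted p-value is monotone consistent with the intervals", {
  t <- withr::with_seed(3, stats::rnorm(800, mean = 0.4, sd = 0.6))
  t0 <- 0.35
  influence <- withr::with_seed(4, stats::rnorm(50))
  p <- isingscape:::.bca_pvalue(t, t0, influence, null_value = 0)
  for (alpha in c(0.01, 0.05, 0.1, 0.25, 0.5)) {
    ci <- isingscape:::.bca_ci(t, t0, influence, 1 - alpha)$ci
    excluded <- 0 < ci[1] || 0 > ci[2]
    expect_identical(p <= alpha, excluded)
  }
})

test_that("comparing a group against itself is null by construction", {
  g <- make_groups()
  cmp <- compare_groups(g$group_a, g$group_a, cutoff = 2, B = 100, seed = 9,
                        per_group_bootstrap = FALSE)
  expect_equal(cmp$between$estimate, 0)
  u <- lapply(c("a", "b"), function(thr)
    lapply(c("a", "b"), function(w) cmp$swap_landscapes[[thr]][[w]]$potential))
  expect_equal(u[[1]][[1]], u[[1]][[2]])
  expect_equal(u[[1]][[1]], u[[2]][[1]])
  expect_equal(u[[1]][[1]], u[[2]][[2]])
})

test_that("swap-grid diagonals equal the pure per-group landscapes", {
  g <- make_groups(shift = -0.8)
  cmp <- compare_groups(g$group_a, g$group_b, cutoff = 2, B = 100, seed = 11,
                        per_group_bootstrap = FALSE)
  expect_equal(cmp$swap_landscapes$a$a$potential, cmp$landscape_a$potential)
  expect_equal(cmp$swap_landscapes$b$b$potential, cmp$landscape_b$potential)
})

test_that("threshold-only group differences vary across swap rows, not columns", {
  g <- make_groups(shift = -1.2, n = 500, seed = 77)
  cmp <- compare_groups(g$group_a, g$group_b, cutoff = 2, B = 100, seed = 12,
                        per_group_bootstrap = FALSE)
  sw <- cmp$swap_landscapes
  col_effect <- max(abs(sw$a$a$potential - sw$a$b$potential),
                    abs(sw$b$a$potential - sw$b$b$potential))
  row_effect <- max(abs(sw$a$a$potential - sw$b$a$potential),
                    abs(sw$a$b$potential - sw$b$b$potential))
  expect_gt(row_effect, col_effect)
})

test_that("group equalization subsamples deterministically", {
  g <- make_groups()
  bigger <- rbind(g$group_b$values, g$group_b$values)
  c1 <- compare_groups(g$group_a$values, bigger, cutoff = 2, B = 100,
                       seed = 21, equalize = TRUE,
                       per_group_bootstrap = FALSE)
  c2 <- compare_groups(g$group_a$values, bigger, cutoff = 2, B = 100,
                       seed = 21, equalize = TRUE,
                       per_group_bootstrap = FALSE)
  expect_identical(c1$group_sizes, c(a = 250L, b = 250L))
  expect_identical(c1$between$estimate, c2$between$estimate)
  expect_identical(c1$between$replicates, c2$between$replicates)
  expect_error(
    compare_groups(g$group_a$values[, c(2, 1, 3)], g$group_b, cutoff = 2,
                   B = 100), "labels")
})

test_that("the permutation test recovers known mean-count differences", {
  g <- make_groups()
  same <- permutation_mean_difference(g$group_a, g$group_a, B = 200, seed = 3)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$p_value, 1)

  gap <- make_groups(shift = -1.5, n = 600, seed = 44)
  true_gap <- expected_active(gap$network_a) - expected_active(gap$network_b)
  perm <- permutation_mean_difference(gap$group_a, gap$group_b, B = 2000,
                                      seed = 4)
  expect_equal(perm$mean_difference, true_gap, tolerance = 0.25)
  expect_lt(perm$p_value, 0.01)
  p2 <- permutation_mean_difference(gap$group_a, gap$group_b, B = 2000,
                                    seed = 4)
  expect_identical(perm$p_value, p2$p_value)
})
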