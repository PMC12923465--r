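# Uncertainty for stability metrics: BCa bootstrap, stratified two-group
# contrast, parameter-swap landscapes, and the permutation test on symptom
# counts.

# Quantiles of bootstrap replicates with normal-order-statistic
# interpolation (the convention of the classical bootstrap literature), so
# adjusted BCa levels land between order statistics smoothly.
.norm_inter <- function(t, alpha) {
  t <- sort(t)
  r <- length(t)
  rk <- (r + 1) * alpha
  k <- trunc(rk)
  out <- numeric(length(alpha))
  for (i in seq_along(alpha)) {
    if (k[i] == 0) {
      out[i] <- t[1]
    } else if (k[i] >= r) {
      out[i] <- t[r]
    } else if (k[i] == rk[i]) {
      out[i] <- t[k[i]]
    } else {
      t1 <- t[k[i]]
      t2 <- t[k[i] + 1]
      num <- stats::qnorm(alpha[i]) - stats::qnorm(k[i] / (r + 1))
      den <- stats::qnorm((k[i] + 1) / (r + 1)) - stats::qnorm(k[i] / (r + 1))
      out[i] <- t1 + num / den * (t2 - t1)
    }
  }
  out
}

# Leave-one-out jackknife influence values: L_i = (n - 1) * (mean - u_i).
.jack_influence <- function(u) {
  (length(u) - 1) * (mean(u) - u)
}

# BCa interval endpoints. z0 from the fraction of replicates below the point
# estimate, acceleration from jackknife influence values. Returns the
# endpoints plus a degeneracy flag (z0 undefined when all replicates fall on
# one side of the estimate).
.bca_ci <- function(t, t0, influence, conf) {
  r <- length(t)
  prop <- sum(t < t0) / r
  if (prop == 0 || prop == 1) {
    return(list(ci = .norm_inter(t, c((1 - conf) / 2, (1 + conf) / 2)),
                degenerate = TRUE, z0 = NA_real_, a = NA_real_))
  }
  z0 <- stats::qnorm(prop)
  denom <- sum(influence^2)^1.5
  a <- if (denom == 0) 0 else sum(influence^3) / (6 * denom)
  zal <- stats::qnorm(c((1 - conf) / 2, (1 + conf) / 2))
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  list(ci = .norm_inter(t, adj), degenerate = FALSE, z0 = z0, a = a)
}

# p-value by interval inversion: the smallest alpha on a grid of step `step`
# at which the (1 - alpha) BCa interval excludes `null_value`. Monotone
# consistent with the intervals by construction. Returns 1 when even the
# narrowest searched interval contains the null.
.bca_pvalue <- function(t, t0, influence, null_value, step = 0.001) {
  prop <- sum(t < t0) / length(t)
  if (prop == 0 || prop == 1) return(NA_real_)
  z0 <- stats::qnorm(prop)
  denom <- sum(influence^2)^1.5
  a <- if (denom == 0) 0 else sum(influence^3) / (6 * denom)
  alphas <- seq(step, 1 - step, by = step)
  z_lo <- stats::qnorm(alphas / 2)
  z_hi <- stats::qnorm(1 - alphas / 2)
  lo <- .norm_inter(t, stats::pnorm(z0 + (z0 + z_lo) / (1 - a * (z0 + z_lo))))
  hi <- .norm_inter(t, stats::pnorm(z0 + (z0 + z_hi) / (1 - a * (z0 + z_hi))))
  excluded <- null_value < lo | null_value > hi
  if (any(excluded)) alphas[which(excluded)[1]] else 1
}

# Fast stability-difference statistic used in all resampling loops; `a` and
# `gn` are the precomputed state matrix and its row sums. NA marks a failed
# replicate (separation / non-convergence).
.stat_stability_difference <- function(x, cutoff, ridge, a, gn) {
  fit <- tryCatch(.fit_nodewise(x, ridge = ridge, on_separation = "fail"),
                  error = function(e) list(ok = FALSE))
  if (!isTRUE(fit$ok)) return(NA_real_)
  u <- .potential_from_params(fit$m, fit$w, 1, a, gn)
  res <- tryCatch(.phase_stability_core(u, cutoff),
                  error = function(e) NULL)
  if (is.null(res)) return(NA_real_)
  res$stability_difference
}

.new_bootstrap_result <- function(statistic, t0, t, b, n_failed, ci, p_value,
                                  conf, null_value, seed, degenerate) {
  structure(
    list(statistic = statistic, estimate = t0, B = b,
         standard_error = stats::sd(t), ci_low = ci[1], ci_high = ci[2],
         conf = conf, p_value = p_value, null_value = null_value,
         n_failed_replicates = n_failed,
         invalid = n_failed / b > 0.05, degenerate = degenerate,
         seed = seed, replicates = t),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap of %s (B = %d, %d failed replicate(s))\n",
              x$statistic, x$B, x$n_failed_replicates))
  cat(sprintf("  estimate %.*g, SE %.*g\n", digits, x$estimate, digits,
              x$standard_error))
  cat(sprintf("  %g%% BCa CI [%.*g, %.*g]\n", 100 * x$conf, digits, x$ci_low,
              digits, x$ci_high))
  if (is.na(x$p_value)) {
    cat("  p-value: degenerate (replicate distribution uninformative)\n")
  } else {
    cat(sprintf("  p = %.3g (vs null %g, by CI inversion)\n", x$p_value,
                x$null_value))
  }
  if (x$invalid)
    cat("  WARNING: >5% failed replicates; result flagged invalid\n")
  invisible(x)
}

#' BCa bootstrap of the stability difference
#'
#' Resamples persons with replacement from the dataset; every replicate
#' re-estimates the Ising network by nodewise logistic regression and
#' recomputes the stability difference at the given cutoff. The standard
#' error is the replicate standard deviation; the confidence interval uses
#' the bias-corrected and accelerated (BCa) method, appropriate because the
#' replicate distribution of the stability difference is often skewed (bias
#' correction from the fraction of replicates below the point estimate,
#' acceleration from a leave-one-person-out jackknife). The p-value inverts
#' the interval: the smallest `alpha` on a grid of step 0.001 at which the
#' `(1 - alpha)` interval excludes `null_value`.
#'
#' Replicates in which estimation fails (e.g. perfect separation in a
#' resample) are dropped and counted; a result with more than 5% failures is
#' flagged invalid. Results are reproducible bit-for-bit given `seed`.
#'
#' @param data A [binary_dataset()] or 0/1 matrix of persons by nodes.
#' @param cutoff Integer clinical cutoff in `1..N`.
#' @param B Number of bootstrap replicates (at least 100; default 1000).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param null_value Null value for the p-value inversion (default 0).
#' @param conf Confidence level of the reported interval (default 0.95).
#' @param ridge L2 penalty passed to the nodewise fits (default 0).
#' @return An object of class `bootstrap_result`.
#' @seealso [compare_groups()], [stability_difference()]
#' @export
bootstrap_stability <- function(data, cutoff, B = 1000, seed = NULL,
                                null_value = 0, conf = 0.95, ridge = 0) {
  if (!.is_count(B) || B < 100)
    .stopf("`B` must be an integer of at least 100")
  x <- .as_binary_matrix(data)
  nn <- ncol(x)
  if (!.is_count(cutoff) || cutoff < 1 || cutoff > nn)
    .stopf("`cutoff` must be an integer in 1..%d", nn)
  a <- .state_matrix(nn, 0:(2^nn - 1))
  gn <- rowSums(a)
  t0 <- .stat_stability_difference(x, cutoff, ridge, a, gn)
  if (is.na(t0))
    .stopf("estimation failed on the full dataset; consider a ridge penalty")
  np <- nrow(x)
  t <- .with_seed(seed, vapply(seq_len(B), function(b) {
    idx <- sample.int(np, np, replace = TRUE)
    .stat_stability_difference(x[idx, , drop = FALSE], cutoff, ridge, a, gn)
  }, numeric(1)))
  n_failed <- sum(is.na(t))
  t <- t[!is.na(t)]
  if (!length(t)) .stopf("all bootstrap replicates failed")
  jack <- vapply(seq_len(np), function(i) {
    .stat_stability_difference(x[-i, , drop = FALSE], cutoff, ridge, a, gn)
  }, numeric(1))
  influence <- .jack_influence(jack[!is.na(jack)])
  if (all(t == t0)) {
    return(.new_bootstrap_result("stability_difference", t0, t, B, n_failed,
                                 c(t0, t0), NA_real_, conf, null_value, seed,
                                 degenerate = TRUE))
  }
  ci <- .bca_ci(t, t0, influence, conf)
  p <- if (ci$degenerate) NA_real_
       else .bca_pvalue(t, t0, influence, null_value)
  .new_bootstrap_result("stability_difference", t0, t, B, n_failed, ci$ci, p,
                        conf, null_value, seed, degenerate = ci$degenerate)
}

#' Compare the stability landscapes of two groups
#'
#' Estimates a network, landscape, and phase-stability metrics per group,
#' bootstraps each group's stability difference, and tests the between-group
#' contrast (group A's stability difference minus group B's) by stratified
#' bootstrap: every replicate resamples persons independently within each
#' group, re-estimates both networks, and recomputes the contrast; BCa
#' intervals use a pooled leave-one-person-out jackknife. To keep estimation
#' power comparable, `equalize = TRUE` subsamples the larger group without
#' replacement down to the smaller group's size (seeded) before any
#' estimation.
#'
#' The returned 2 x 2 parameter-swap grid pairs thresholds from either group
#' with weights from either group and computes the landscape of each
#' combination; comparing rows against columns shows whether group
#' differences are driven by thresholds or by connectivity. Its diagonal
#' cells equal the pure per-group landscapes.
#'
#' @param data_a,data_b [binary_dataset()]s or 0/1 matrices with identical
#'   node labels.
#' @param cutoff Integer clinical cutoff in `1..N`.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Optional integer seed; subsampling, per-group bootstraps, and
#'   the between-group bootstrap use deterministically split sub-seeds.
#' @param equalize Subsample the larger group to the smaller size first.
#' @param conf Confidence level (default 0.95).
#' @param ridge L2 penalty for all nodewise fits (default 0).
#' @param per_group_bootstrap Also bootstrap each group's own stability
#'   difference (default `TRUE`; disable for speed when only the contrast is
#'   of interest).
#' @return An object of class `group_comparison`: per-group `landscape_*`,
#'   `metrics_*`, `bootstrap_*`; `between` (a `bootstrap_result` for the
#'   contrast); `swap_landscapes` (nested list:
#'   `swap_landscapes[[thresholds_from]][[weights_from]]`); `group_sizes`,
#'   `equalized`, `cutoff`, `seed`.
#' @export
compare_groups <- function(data_a, data_b, cutoff, B = 1000, seed = NULL,
                           equalize = FALSE, conf = 0.95, ridge = 0,
                           per_group_bootstrap = TRUE) {
  xa <- .as_binary_matrix(data_a)
  xb <- .as_binary_matrix(data_b)
  if (!identical(colnames(xa), colnames(xb)))
    .stopf("node labels of the two groups do not match")
  if (!.is_count(B) || B < 100)
    .stopf("`B` must be an integer of at least 100")
  nn <- ncol(xa)
  if (!.is_count(cutoff) || cutoff < 1 || cutoff > nn)
    .stopf("`cutoff` must be an integer in 1..%d", nn)
  seeds <- .split_seeds(seed, 4)
  sizes_in <- c(a = nrow(xa), b = nrow(xb))
  if (equalize && nrow(xa) != nrow(xb)) {
    target <- min(sizes_in)
    .with_seed(seeds[[1]], {
      if (nrow(xa) > target)
        xa <- xa[sample.int(nrow(xa), target), , drop = FALSE]
      if (nrow(xb) > target)
        xb <- xb[sample.int(nrow(xb), target), , drop = FALSE]
    })
  }
  net_a <- estimate_ising(xa, ridge = ridge)
  net_b <- estimate_ising(xb, ridge = ridge)
  land_a <- potential_landscape(net_a)
  land_b <- potential_landscape(net_b)
  met_a <- phase_stability(land_a, cutoff)
  met_b <- phase_stability(land_b, cutoff)
  boot_a <- boot_b <- NULL
  if (per_group_bootstrap) {
    boot_a <- bootstrap_stability(xa, cutoff, B = B, seed = seeds[[2]],
                                  conf = conf, ridge = ridge)
    boot_b <- bootstrap_stability(xb, cutoff, B = B, seed = seeds[[3]],
                                  conf = conf, ridge = ridge)
  }
  a <- .state_matrix(nn, 0:(2^nn - 1))
  gn <- rowSums(a)
  na_p <- nrow(xa)
  nb_p <- nrow(xb)
  d0 <- met_a$stability_difference - met_b$stability_difference
  t <- .with_seed(seeds[[4]], vapply(seq_len(B), function(b) {
    ta <- .stat_stability_difference(
      xa[sample.int(na_p, na_p, replace = TRUE), , drop = FALSE],
      cutoff, ridge, a, gn)
    tb <- .stat_stability_difference(
      xb[sample.int(nb_p, nb_p, replace = TRUE), , drop = FALSE],
      cutoff, ridge, a, gn)
    ta - tb
  }, numeric(1)))
  n_failed <- sum(is.na(t))
  t <- t[!is.na(t)]
  if (!length(t)) .stopf("all between-group bootstrap replicates failed")
  sd_a_full <- met_a$stability_difference
  sd_b_full <- met_b$stability_difference
  jack <- c(
    vapply(seq_len(na_p), function(i) {
      .stat_stability_difference(xa[-i, , drop = FALSE], cutoff, ridge,
                                 a, gn) - sd_b_full
    }, numeric(1)),
    vapply(seq_len(nb_p), function(i) {
      sd_a_full - .stat_stability_difference(xb[-i, , drop = FALSE], cutoff,
                                             ridge, a, gn)
    }, numeric(1))
  )
  influence <- .jack_influence(jack[!is.na(jack)])
  between <- if (all(t == d0)) {
    .new_bootstrap_result("between_group_stability_difference", d0, t, B,
                          n_failed, c(d0, d0), NA_real_, conf, 0, seeds[[4]],
                          degenerate = TRUE)
  } else {
    ci <- .bca_ci(t, d0, influence, conf)
    p <- if (ci$degenerate) NA_real_ else .bca_pvalue(t, d0, influence, 0)
    .new_bootstrap_result("between_group_stability_difference", d0, t, B,
                          n_failed, ci$ci, p, conf, 0, seeds[[4]],
                          degenerate = ci$degenerate)
  }
  swap <- lapply(list(a = net_a, b = net_b), function(thr_src) {
    lapply(list(a = net_a, b = net_b), function(w_src) {
      potential_landscape(ising_network(
        thr_src$thresholds, w_src$weights, labels = thr_src$labels, beta = 1
      ))
    })
  })
  structure(
    list(landscape_a = land_a, landscape_b = land_b,
         metrics_a = met_a, metrics_b = met_b,
         bootstrap_a = boot_a, bootstrap_b = boot_b, between = between,
         swap_landscapes = swap, cutoff = as.integer(cutoff),
         group_sizes = c(a = na_p, b = nb_p), input_sizes = sizes_in,
         equalized = equalize, seed = seed, subsample_seed = seeds[[1]]),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, digits = 4, ...) {
  cat(sprintf("Group comparison at cutoff %d (groups of %d and %d persons",
              x$cutoff, x$group_sizes["a"], x$group_sizes["b"]))
  cat(if (x$equalized) ", equalized by subsampling)\n" else ")\n")
  cat(sprintf("  stability difference A: %.*g   B: %.*g\n", digits,
              x$metrics_a$stability_difference, digits,
              x$metrics_b$stability_difference))
  cat("Between-group contrast (A - B):\n")
  print(x$between, digits = digits)
  invisible(x)
}

#' Permutation test on mean symptom counts
#'
#' Two-sided permutation test of the difference in mean number of active
#' symptoms per person between two groups. Group sizes are first equalized
#' by seeded random subsampling of the larger group; the null distribution is
#' built by permuting group labels `B` times, and
#' `p = (1 + #(|T_perm| >= |T_obs|)) / (B + 1)`.
#'
#' @param data_a,data_b [binary_dataset()]s or 0/1 matrices.
#' @param B Number of permutations (default 10000).
#' @param seed Optional integer seed (split into subsampling and permutation
#'   sub-seeds).
#' @return An object of class `permutation_test`: list with
#'   `mean_difference` (group A minus group B), `p_value`, `B`,
#'   `group_sizes`, `seed`.
#' @export
permutation_mean_difference <- function(data_a, data_b, B = 10000,
                                        seed = NULL) {
  if (!.is_count(B) || B < 1) .stopf("`B` must be a positive integer")
  xa <- .as_binary_matrix(data_a)
  xb <- .as_binary_matrix(data_b)
  if (nrow(xa) < 1 || nrow(xb) < 1) .stopf("both groups must be nonempty")
  seeds <- .split_seeds(seed, 2)
  target <- min(nrow(xa), nrow(xb))
  .with_seed(seeds[[1]], {
    if (nrow(xa) > target)
      xa <- xa[sample.int(nrow(xa), target), , drop = FALSE]
    if (nrow(xb) > target)
      xb <- xb[sample.int(nrow(xb), target), , drop = FALSE]
  })
  counts <- c(rowSums(xa), rowSums(xb))
  n_a <- nrow(xa)
  n_tot <- length(counts)
  t_obs <- mean(counts[seq_len(n_a)]) - mean(counts[-seq_len(n_a)])
  t_perm <- .with_seed(seeds[[2]], vapply(seq_len(B), function(b) {
    idx <- sample.int(n_tot, n_a)
    mean(counts[idx]) - mean(counts[-idx])
  }, numeric(1)))
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (B + 1)
  structure(
    list(mean_difference = t_obs, p_value = p, B = B,
         group_sizes = c(a = nrow(xa), b = nrow(xb)), seed = seed),
    class = "permutation_test"
  )
}

#' @export
print.permutation_test <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Permutation test on symptom counts (B = %d, groups of %d and %d)\n",
    x$B, x$group_sizes["a"], x$group_sizes["b"]))
  cat(sprintf("  mean difference (A - B): %.*g, two-sided p = %.3g\n",
              digits, x$mean_difference, x$p_value))
  invisible(x)
}
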