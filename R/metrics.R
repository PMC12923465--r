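# Cutoff-anchored phase-stability metrics.

# Core arithmetic on a raw potential vector u over n = 0..N; cutoff c is the
# smallest active-symptom count belonging to the disorder phase. Indices in
# the result are n values (0-based); reference indices are NA when the
# corresponding stability is 0 by the edge rule.
.phase_stability_core <- function(u, cutoff) {
  n <- length(u) - 1L
  left_min <- locate_local_minima(u, c(0L, cutoff - 1L))
  if (!length(left_min)) .stopf("no finite local minimum in the healthy portion")
  i_star <- min(left_min)
  if (i_star == cutoff - 1L) {
    healthy <- 0
    ref_h <- NA_integer_
  } else {
    seg <- u[(i_star + 2):cutoff] # n = i*+1 .. c-1
    healthy <- max(seg) - u[i_star + 1]
    ref_h <- i_star + 1L + (which.max(seg) - 1L) # leftmost argmax
  }
  right_min <- locate_local_minima(u, c(cutoff, n))
  if (!length(right_min)) .stopf("no finite local minimum in the disorder portion")
  j_star <- max(right_min)
  if (j_star == cutoff) {
    disorder <- 0
    ref_d <- NA_integer_
  } else {
    seg <- u[(cutoff + 1):j_star] # n = c .. j*-1
    disorder <- max(seg) - u[j_star + 1]
    ref_d <- cutoff + (max(which(seg == max(seg))) - 1L) # rightmost argmax
  }
  list(healthy_stability = healthy, disorder_stability = disorder,
       stability_difference = healthy - disorder,
       healthy_minimum_index = i_star, disorder_minimum_index = j_star,
       reference_maximum_indices = c(healthy = ref_h, disorder = ref_d))
}

#' Phase-stability metrics of a landscape
#'
#' Splits the landscape at a clinical cutoff `c` (the smallest number of
#' active symptoms that belongs to the disorder phase, e.g. 5 of 9 depression
#' symptoms, or 8 of 11 pandemic-anxiety symptoms) and quantifies the
#' stability of each phase:
#'
#' * healthy-phase stability: within the left portion `n = 0..c-1`, the
#'   difference between the maximum potential strictly to the right of the
#'   leftmost local minimum and the potential at that minimum (0 when the
#'   minimum sits at the portion's right edge);
#' * disorder-phase stability: mirror-symmetric on the right portion
#'   `n = c..N`, using the rightmost local minimum and the maximum strictly
#'   to its left (0 when the minimum sits at the portion's left edge).
#'
#' Maxima are scanned strictly within each portion (never across the cutoff)
#' and may fall on the portion edge adjacent to the cutoff. The stability
#' difference is healthy minus disorder stability: positive values mean the
#' healthy phase is the more stable one. Both metrics are differences of `U`
#' values, so they are invariant to the additive normalization of the
#' potential.
#'
#' @param landscape An [potential_landscape()] result, or a bare numeric
#'   potential vector over `n = 0..N`.
#' @param cutoff Integer in `1..N`.
#' @return An object of class `stability_metrics`: list with `cutoff`,
#'   `healthy_stability`, `disorder_stability`, `stability_difference`,
#'   `healthy_minimum_index`, `disorder_minimum_index`, and
#'   `reference_maximum_indices` (all indices are `n` values).
#' @examples
#' phase_stability(c(1, 2, 1.5, 2.5, 0.5), cutoff = 3)
#' @export
phase_stability <- function(landscape, cutoff) {
  u <- if (inherits(landscape, "ising_landscape")) landscape$potential
       else as.numeric(landscape)
  n <- length(u) - 1L
  if (!.is_count(cutoff) || cutoff < 1 || cutoff > n)
    .stopf("`cutoff` must be an integer in 1..%d", n)
  out <- .phase_stability_core(u, as.integer(cutoff))
  out <- c(list(cutoff = as.integer(cutoff)), out)
  if (inherits(landscape, "ising_landscape"))
    out$network_fingerprint <- landscape$network_fingerprint
  structure(out, class = "stability_metrics")
}

#' @export
print.stability_metrics <- function(x, digits = 4, ...) {
  cat(sprintf("Phase stability at cutoff %d (disorder phase: n >= %d)\n",
              x$cutoff, x$cutoff))
  cat(sprintf("  healthy phase:  %.*g (minimum at n = %d)\n", digits,
              x$healthy_stability, x$healthy_minimum_index))
  cat(sprintf("  disorder phase: %.*g (minimum at n = %d)\n", digits,
              x$disorder_stability, x$disorder_minimum_index))
  cat(sprintf("  stability difference (healthy - disorder): %.*g\n", digits,
              x$stability_difference))
  invisible(x)
}

#' Serialize stability metrics as a JSON record
#'
#' @param metrics A `stability_metrics` object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_metrics_json <- function(metrics, path = NULL) {
  stopifnot(inherits(metrics, "stability_metrics"))
  rec <- list(
    cutoff = metrics$cutoff,
    healthy_stability = metrics$healthy_stability,
    disorder_stability = metrics$disorder_stability,
    stability_difference = metrics$stability_difference,
    indices = list(
      healthy_minimum = metrics$healthy_minimum_index,
      disorder_minimum = metrics$disorder_minimum_index,
      reference_maxima = as.list(metrics$reference_maximum_indices)
    )
  )
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Stability difference of a network, landscape, or dataset
#'
#' Convenience composition ending in the scalar statistic that the bootstrap
#' machinery resamples: for a dataset, estimate the network by nodewise
#' logistic regression, compute its landscape, and return healthy minus
#' disorder phase stability at the given cutoff.
#'
#' @param x An `ising_network`, `ising_landscape`, `binary_dataset`, or a
#'   binary matrix/data frame of persons by nodes.
#' @param cutoff Integer clinical cutoff in `1..N`.
#' @param ... Passed on to [estimate_ising()] for data inputs (e.g. `ridge`).
#' @return The scalar stability difference.
#' @examples
#' net <- ising_network(c(0, 0), matrix(0, 2, 2))
#' stability_difference(net, cutoff = 1)
#' @export
stability_difference <- function(x, cutoff, ...) {
  UseMethod("stability_difference")
}

#' @export
stability_difference.ising_landscape <- function(x, cutoff, ...) {
  phase_stability(x, cutoff)$stability_difference
}

#' @export
stability_difference.ising_network <- function(x, cutoff, ...) {
  phase_stability(potential_landscape(x), cutoff)$stability_difference
}

#' @export
stability_difference.binary_dataset <- function(x, cutoff, ...) {
  stability_difference(estimate_ising(x, ...), cutoff)
}

#' @export
stability_difference.matrix <- function(x, cutoff, ...) {
  stability_difference(estimate_ising(x, ...), cutoff)
}

#' @export
stability_difference.data.frame <- function(x, cutoff, ...) {
  stability_difference(estimate_ising(as.matrix(x), ...), cutoff)
}
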