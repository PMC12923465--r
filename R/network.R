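#' Construct an Ising network
#'
#' An Ising network over `N` binary nodes (0 = inactive/absent, 1 =
#' active/present) is fully described by a threshold vector `m`, a symmetric
#' zero-diagonal weight matrix `W`, and an inverse temperature `beta`. The
#' threshold of a node is its intrinsic activation tendency; an edge weight
#' `w[i, j] > 0` makes joint activation of nodes `i` and `j` more likely than
#' any other joint configuration of that pair; `beta` scales the overall
#' randomness of the system (larger `beta`, less stochastic behaviour).
#'
#' The 0/1 node coding standard in psychological networks is used throughout;
#' no -1/+1 spin convention is offered. Self-loops (`w[i, i] != 0`) are
#' rejected. Weight matrices that are asymmetric within `symmetrize_tol` are
#' symmetrized by averaging with a warning; larger asymmetries are an error.
#'
#' @param thresholds Numeric vector of node thresholds `m` (length `N >= 1`).
#' @param weights Numeric `N x N` weight matrix `W`, symmetric with zero
#'   diagonal.
#' @param labels Optional character vector of `N` unique node names; defaults
#'   to the dimnames of `weights`, the names of `thresholds`, or `V1..VN`.
#' @param beta Positive inverse temperature (default 1).
#' @param metadata Free-form provenance list stored with the network.
#' @param symmetrize_tol Maximum tolerated asymmetry `max |W - t(W)|` before
#'   the matrix is rejected (default 1e-8).
#' @return An object of class `ising_network` with fields `labels`,
#'   `thresholds`, `weights`, `beta`, `metadata`.
#' @examples
#' net <- ising_network(c(-1, -1, 0), rbind(
#'   c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)
#' ))
#' hamiltonian(net, c(1, 1, 0))
#' @seealso [potential_landscape()], [estimate_ising()], [scale_parameters()]
#' @export
ising_network <- function(thresholds, weights, labels = NULL, beta = 1,
                          metadata = list(), symmetrize_tol = 1e-8) {
  if (!is.numeric(thresholds) || length(thresholds) < 1L)
    .stopf("`thresholds` must be a numeric vector of length >= 1")
  if (!all(is.finite(thresholds)))
    .stopf("`thresholds` contains non-finite values")
  n <- length(thresholds)
  weights <- as.matrix(weights)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n)
    .stopf("`weights` must be a numeric %d x %d matrix", n, n)
  if (!all(is.finite(weights)))
    .stopf("`weights` contains non-finite values")
  if (any(diag(weights) != 0))
    .stopf("`weights` has nonzero diagonal entries (self-loops are not allowed)")
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetrize_tol)
    .stopf("`weights` is asymmetric beyond tolerance (max |w_ij - w_ji| = %g)",
           asym)
  if (asym > 0) {
    .warnf("weights symmetrized by averaging (max asymmetry %g)", asym)
    weights <- (weights + t(weights)) / 2
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    .stopf("`beta` must be a single positive finite number")
  if (is.null(labels)) {
    labels <- colnames(weights)
    if (is.null(labels)) labels <- names(thresholds)
    if (is.null(labels)) labels <- paste0("V", seq_len(n))
  }
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels) || any(is.na(labels)))
    .stopf("`labels` must be %d unique non-missing node names", n)
  thresholds <- as.numeric(thresholds)
  names(thresholds) <- labels
  dimnames(weights) <- list(labels, labels)
  structure(
    list(labels = labels, thresholds = thresholds, weights = weights,
         beta = as.numeric(beta), metadata = metadata),
    class = "ising_network"
  )
}

#' Number of nodes of an Ising network
#' @param network An `ising_network`.
#' @return Integer node count `N`.
#' @export
n_nodes <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  length(network$thresholds)
}

#' Rescale threshold and connectivity parameters
#'
#' Returns a new network with `m' = threshold_multiplier * m` and
#' `W' = connectivity_multiplier * W`; `beta` and labels are unchanged and the
#' input network is not modified. Multiplier grids over, e.g., 0.8/1/1.2 are
#' the standard way to explore how global strengthening or weakening of
#' thresholds and connectivity reshapes the stability landscape.
#'
#' @param network An `ising_network`.
#' @param threshold_multiplier Finite scalar applied to all thresholds.
#' @param connectivity_multiplier Finite scalar applied to all weights.
#' @return A new `ising_network`.
#' @examples
#' net <- ising_network(c(-1, -1), matrix(c(0, 0.5, 0.5, 0), 2))
#' scale_parameters(net, 0.8, 1.2)
#' @export
scale_parameters <- function(network, threshold_multiplier = 1,
                             connectivity_multiplier = 1) {
  stopifnot(inherits(network, "ising_network"))
  for (mult in c(threshold_multiplier, connectivity_multiplier))
    if (!is.numeric(mult) || length(mult) != 1L || !is.finite(mult))
      .stopf("multipliers must be single finite numbers")
  ising_network(
    thresholds = network$thresholds * threshold_multiplier,
    weights = network$weights * connectivity_multiplier,
    labels = network$labels, beta = network$beta,
    metadata = c(network$metadata,
                 list(threshold_multiplier = threshold_multiplier,
                      connectivity_multiplier = connectivity_multiplier))
  )
}

#' Relabel the nodes of a network by a permutation
#'
#' Applies the same permutation to labels, thresholds, and both dimensions of
#' the weight matrix. All distributional quantities (microstate probabilities
#' up to relabeling, the macrostate distribution, and the landscape) are
#' invariant under this operation.
#'
#' @param network An `ising_network`.
#' @param perm Integer permutation of `1:N`: node `i` of the result is node
#'   `perm[i]` of the input.
#' @return A new `ising_network`.
#' @export
permute_nodes <- function(network, perm) {
  stopifnot(inherits(network, "ising_network"))
  n <- n_nodes(network)
  if (length(perm) != n || !setequal(perm, seq_len(n)))
    .stopf("`perm` must be a permutation of 1:%d", n)
  ising_network(network$thresholds[perm], network$weights[perm, perm],
                labels = network$labels[perm], beta = network$beta,
                metadata = network$metadata)
}

#' @export
print.ising_network <- function(x, ...) {
  n <- n_nodes(x)
  cat(sprintf("Ising network: %d nodes, beta = %g\n", n, x$beta))
  cat("Thresholds:\n")
  print(round(x$thresholds, 3))
  nedges <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Edges: %d of %d nonzero\n", nedges, n * (n - 1) / 2))
  if (!is.null(x$metadata$method))
    cat(sprintf("Estimated by: %s\n", x$metadata$method))
  invisible(x)
}

#' @export
summary.ising_network <- function(object, ...) {
  w <- object$weights[upper.tri(object$weights)]
  out <- list(
    n_nodes = n_nodes(object), beta = object$beta,
    threshold_range = range(object$thresholds),
    mean_threshold = mean(object$thresholds),
    n_edges = sum(w != 0), mean_weight = mean(w),
    weight_range = if (length(w)) range(w) else c(NA_real_, NA_real_),
    fingerprint = .network_fingerprint(object)
  )
  class(out) <- "summary.ising_network"
  out
}

#' @export
print.summary.ising_network <- function(x, ...) {
  cat(sprintf("Ising network: %d nodes, beta = %g, fingerprint %s\n",
              x$n_nodes, x$beta, x$fingerprint))
  cat(sprintf("Thresholds: mean %.3f, range [%.3f, %.3f]\n",
              x$mean_threshold, x$threshold_range[1], x$threshold_range[2]))
  cat(sprintf("Weights: %d nonzero edges, mean %.3f, range [%.3f, %.3f]\n",
              x$n_edges, x$mean_weight, x$weight_range[1], x$weight_range[2]))
  invisible(x)
}

#' @export
coef.ising_network <- function(object, ...) {
  list(thresholds = object$thresholds, weights = object$weights,
       beta = object$beta)
}
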