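# Monte-Carlo machinery: Glauber dynamics, exact sampling from the enumerated
# Boltzmann distribution, and synthetic group-data generation.

#' Glauber-dynamics trajectory of an Ising network
#'
#' Runs single-site heat-bath dynamics: in every sweep, the nodes are visited
#' in a fresh random order and each is resampled from its full conditional
#' ([conditional_activation_probability()]). The stationary distribution of
#' this chain is the exact Boltzmann distribution, so the long-run occupancy
#' of the number of active nodes converges to the analytic macrostate
#' distribution -- the chain is the simulation fallback (and test oracle)
#' for networks beyond the enumeration guard.
#'
#' @param network An [ising_network()].
#' @param sweeps Number of full sweeps (each sweep updates every node once).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @param burn_in Sweeps discarded before recording (default 10% of
#'   `sweeps`).
#' @param init Optional initial activation vector (default: uniform random).
#' @param record_states If `TRUE`, keep the full microstate at every recorded
#'   sweep, not just the number of active nodes.
#' @return An object of class `chain_trajectory`: list with `n` (number of
#'   active nodes at every post-burn-in sweep), optional `states` matrix,
#'   `final_state`, `sweeps`, `burn_in`, `seed`, `n_nodes`, and
#'   `network_fingerprint`.
#' @examples
#' net <- ising_network(c(0, 0), matrix(0, 2, 2))
#' tr <- glauber_chain(net, sweeps = 100, seed = 1)
#' table(tr$n)
#' @export
glauber_chain <- function(network, sweeps, seed = NULL,
                          burn_in = floor(0.1 * sweeps), init = NULL,
                          record_states = FALSE) {
  stopifnot(inherits(network, "ising_network"))
  n <- n_nodes(network)
  if (!.is_count(sweeps) || sweeps < 1)
    .stopf("`sweeps` must be a positive integer")
  if (!.is_count(burn_in) || burn_in >= sweeps)
    .stopf("`burn_in` must be a nonnegative integer below `sweeps`")
  if (!is.null(init)) init <- .check_state(init, n)
  res <- .with_seed(seed, {
    if (is.null(init)) init <- stats::rbinom(n, 1L, 0.5)
    glauber_chain_cpp(network$thresholds, network$weights, network$beta,
                      as.integer(sweeps), as.integer(burn_in),
                      as.integer(init), record_states)
  })
  structure(
    list(n = res$n,
         states = if (record_states) res$states else NULL,
         final_state = res$final, sweeps = as.integer(sweeps),
         burn_in = as.integer(burn_in), seed = seed, n_nodes = n,
         network_fingerprint = .network_fingerprint(network)),
    class = "chain_trajectory"
  )
}

#' @export
print.chain_trajectory <- function(x, ...) {
  cat(sprintf(
    "Glauber trajectory: %d sweeps (%d burn-in discarded), %d nodes\n",
    x$sweeps, x$burn_in, x$n_nodes))
  cat("Occupancy of n:\n")
  print(round(macrostate_occupancy(x), 4))
  invisible(x)
}

#' Empirical macrostate occupancy of a trajectory
#'
#' @param trajectory A [glauber_chain()] result.
#' @return Named proportion vector over `n = 0..N`, comparable directly with
#'   [macrostate_distribution()].
#' @export
macrostate_occupancy <- function(trajectory) {
  stopifnot(inherits(trajectory, "chain_trajectory"))
  tab <- tabulate(trajectory$n + 1L, nbins = trajectory$n_nodes + 1L)
  p <- tab / length(trajectory$n)
  names(p) <- 0:trajectory$n_nodes
  p
}

#' Export a trajectory as TSV of per-sweep active-node counts
#'
#' @param trajectory A [glauber_chain()] result.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "chain_trajectory"))
  writeLines(c("sweep\tn",
               sprintf("%d\t%d",
                       seq_along(trajectory$n) + trajectory$burn_in,
                       trajectory$n)),
             path)
  invisible(path)
}

#' Exact i.i.d. samples from an Ising network
#'
#' Draws independent microstates from the enumerated Boltzmann distribution
#' (a categorical draw over all `2^N` states), so sample marginals converge
#' to the exact enumeration marginals. Only available within the enumeration
#' guard (`N <= 25`).
#'
#' @param network An [ising_network()].
#' @param n_samples Number of persons to draw (0 gives an empty dataset with
#'   a valid header).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return A [binary_dataset()] of `n_samples` rows.
#' @examples
#' net <- ising_network(c(0, 0), matrix(0, 2, 2))
#' colMeans(sample_exact(net, 1000, seed = 1)$values)
#' @export
sample_exact <- function(network, n_samples, seed = NULL) {
  stopifnot(inherits(network, "ising_network"))
  if (!.is_count(n_samples)) .stopf("`n_samples` must be a nonnegative integer")
  n <- n_nodes(network)
  dist <- microstate_distribution(network)
  idx <- .with_seed(seed, sample.int(2^n, n_samples, replace = TRUE,
                                     prob = dist$probabilities)) - 1
  binary_dataset(.state_matrix(n, idx), labels = network$labels)
}

#' @export
#' @rdname sample_exact
#' @param object An `ising_network` (for the `simulate` method).
#' @param nsim Number of persons to draw.
#' @param ... Unused.
simulate.ising_network <- function(object, nsim = 1, seed = NULL, ...) {
  sample_exact(object, nsim, seed = seed)
}

#' Generate synthetic two-group datasets with known ground truth
#'
#' Group A is sampled exactly from the base network; group B from the network
#' with thresholds `m + threshold_shift` and weights
#' `W * weight_multiplier`. The generating networks are returned alongside
#' the data, so recovery and group-comparison procedures can be checked
#' against the known truth.
#'
#' @param base_network An [ising_network()].
#' @param threshold_shift Scalar or length-`N` shift added to the thresholds
#'   of group B's network (default 0).
#' @param weight_multiplier Scalar multiplier of group B's weights
#'   (default 1).
#' @param n_per_group Persons per group.
#' @param seed Optional integer seed; group draws use deterministically split
#'   sub-seeds.
#' @return An object of class `synthetic_groups`: list with `group_a`,
#'   `group_b` ([binary_dataset()]s), `network_a`, `network_b`,
#'   `threshold_shift`, `weight_multiplier`, `n_per_group`, `seed`.
#' @export
synthetic_group_data <- function(base_network, threshold_shift = 0,
                                 weight_multiplier = 1, n_per_group,
                                 seed = NULL) {
  stopifnot(inherits(base_network, "ising_network"))
  n <- n_nodes(base_network)
  if (!length(threshold_shift) %in% c(1L, n) ||
      !all(is.finite(threshold_shift)))
    .stopf("`threshold_shift` must be a finite scalar or length-%d vector", n)
  network_b <- ising_network(
    base_network$thresholds + threshold_shift,
    base_network$weights * weight_multiplier,
    labels = base_network$labels, beta = base_network$beta
  )
  seeds <- .split_seeds(seed, 2)
  structure(
    list(group_a = sample_exact(base_network, n_per_group, seeds[[1]]),
         group_b = sample_exact(network_b, n_per_group, seeds[[2]]),
         network_a = base_network, network_b = network_b,
         threshold_shift = threshold_shift,
         weight_multiplier = weight_multiplier,
         n_per_group = n_per_group, seed = seed),
    class = "synthetic_groups"
  )
}

#' A synthetic nine-node depression-style network
#'
#' A fixed, synthetic Ising network over the nine DSM-style depression
#' symptom domains, constructed (not estimated from any data) to exhibit the
#' qualitative landscape shape typical of empirical depression networks: a
#' stable healthy phase at `n = 0` and a shallow high-symptom region beyond
#' the clinical cutoff of 5 active symptoms. It serves as the package's
#' worked-example and demonstration input.
#'
#' @return An [ising_network()] with 9 nodes and `beta = 1`.
#' @examples
#' land <- potential_landscape(synthetic_mdd_network())
#' phase_stability(land, cutoff = 5)
#' @export
synthetic_mdd_network <- function() {
  labels <- c("mood", "anhedonia", "appetite", "sleep", "psychomotor",
              "fatigue", "guilt", "concentration", "suicidality")
  m <- c(-1.9, -2.1, -2.5, -2.0, -2.9, -1.8, -2.7, -2.2, -3.5)
  w <- matrix(0.57, 9, 9)
  # stronger mood/anhedonia/fatigue core, weaker edges to suicidality
  core <- c(1, 2, 6)
  w[core, core] <- 0.93
  w[9, ] <- w[, 9] <- 0.33
  diag(w) <- 0
  ising_network(m, w, labels = labels, beta = 1,
                metadata = list(source = "synthetic demonstration network"))
}
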