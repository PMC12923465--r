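# Exact Ising-model mathematics: energies, conditional probabilities, the
# enumerated microstate distribution, and macrostate combinatorics.

# Exact enumeration is refused above this many nodes (2^25 microstates).
.ENUM_GUARD <- 25L

# Chunk size for enumeration, so the 2^N x N state matrix is never fully held.
.ENUM_CHUNK <- 65536L

.check_enum_guard <- function(n) {
  if (n > .ENUM_GUARD)
    .stopf(paste0(
      "enumeration infeasible: N = %d exceeds the exact-enumeration guard ",
      "(N = %d, 2^%d microstates); use glauber_chain() to approximate the ",
      "macrostate distribution by simulation"), n, .ENUM_GUARD, .ENUM_GUARD)
}

# Microstates for 0-based indices `idx`: row k is the binary activation vector
# of index idx[k], node j stored in bit j-1 (node 1 = least-significant bit).
.state_matrix <- function(n, idx) {
  a <- matrix(0L, length(idx), n)
  for (j in seq_len(n)) a[, j] <- as.integer((idx %/% 2^(j - 1)) %% 2)
  a
}

#' Canonical microstate indexing
#'
#' Microstates are ordered by interpreting the activation vector as an N-bit
#' integer with node 1 in the least-significant bit, giving 0-based indices
#' `0 .. 2^N - 1`. This fixes the ordering of
#' [microstate_distribution()] and of all serialized output.
#'
#' @param state Binary activation vector (entries exactly 0 or 1).
#' @return `microstate_index()`: the 0-based canonical index.
#' @examples
#' microstate_index(c(1, 0, 1)) # 5
#' index_to_microstate(5, 3)    # c(1, 0, 1)
#' @export
microstate_index <- function(state) {
  state <- .check_state(state, length(state))
  sum(state * 2^(seq_along(state) - 1))
}

#' @rdname microstate_index
#' @param index 0-based canonical index.
#' @param n_nodes Number of nodes `N`.
#' @return `index_to_microstate()`: the binary activation vector.
#' @export
index_to_microstate <- function(index, n_nodes) {
  if (!.is_count(index) || index >= 2^n_nodes)
    .stopf("`index` must be an integer in 0 .. 2^%d - 1", n_nodes)
  as.integer(.state_matrix(n_nodes, index))
}

.check_state <- function(state, n) {
  if (length(state) != n)
    .stopf("`state` has length %d but the network has %d nodes",
           length(state), n)
  if (!is.numeric(state) || !all(state %in% c(0, 1)))
    .stopf("`state` entries must be exactly 0 or 1")
  as.numeric(state)
}

# Energies of a batch of states (rows of `a`), by the quadratic form
# -a'Wa/2 - a'm, valid for symmetric zero-diagonal W.
.energies <- function(network, a) {
  -0.5 * rowSums((a %*% network$weights) * a) -
    as.vector(a %*% network$thresholds)
}

#' Hamiltonian energy of a microstate
#'
#' The energy of an activation vector `a` is
#' `H(a) = -sum_{i<j} w_ij a_i a_j - sum_i m_i a_i`, equivalently
#' `-a'Wa/2 - a'm` for symmetric zero-diagonal `W`. Lower energy means higher
#' probability under the Boltzmann distribution.
#'
#' @param network An [ising_network()].
#' @param state Binary activation vector of length `N`.
#' @return The scalar energy `H(a)`; the empty (all-zero) state has energy 0.
#' @examples
#' net <- ising_network(c(-1, -1, 0), rbind(
#'   c(0, 1, 0), c(1, 0, 0), c(0, 0, 0)
#' ))
#' hamiltonian(net, c(1, 1, 0)) # -1*1 - (-1 - 1) = 1
#' @export
hamiltonian <- function(network, state) {
  stopifnot(inherits(network, "ising_network"))
  state <- .check_state(state, n_nodes(network))
  .energies(network, matrix(state, nrow = 1L))
}

#' Conditional activation probability of one node
#'
#' The probability that node `i` is active given the activation states of all
#' other nodes: `P(a_i = 1 | a_-i) = logistic(beta * (m_i + sum_{j != i}
#' w_ij a_j))`. This full conditional is independent of the current value of
#' `a_i` itself; it is both the estimation target of nodewise logistic
#' regression and the update rule of Glauber dynamics.
#'
#' @param network An [ising_network()].
#' @param state Binary activation vector of length `N` (the value at
#'   `node_index` is ignored).
#' @param node_index Node position in `1..N`.
#' @return The conditional probability in (0, 1).
#' @examples
#' net <- ising_network(c(1, 0), matrix(c(0, 1, 1, 0), 2))
#' conditional_activation_probability(net, c(0, 1), 1) # plogis(2)
#' @export
conditional_activation_probability <- function(network, state, node_index) {
  stopifnot(inherits(network, "ising_network"))
  n <- n_nodes(network)
  state <- .check_state(state, n)
  if (!.is_count(node_index) || node_index < 1 || node_index > n)
    .stopf("`node_index` must be in 1..%d", n)
  field <- network$thresholds[[node_index]] +
    sum(network$weights[node_index, ] * state) # w_ii = 0, so a_i drops out
  stats::plogis(network$beta * field)
}

#' Exact Boltzmann distribution over all microstates
#'
#' Enumerates all `2^N` activation vectors and returns their probabilities
#' `P(a) = exp(-beta H(a)) / Z`, normalized with log-sum-exp so extreme
#' parameters cannot overflow. States are ordered by the canonical index
#' ([microstate_index()]).
#'
#' @param network An [ising_network()] with `N` at most 25.
#' @return An object of class `microstate_distribution`: a list with
#'   `probabilities` and `energies` (length `2^N`), `log_probabilities`,
#'   `log_z`, `beta`, and `n_nodes`.
#' @examples
#' net <- ising_network(c(0, 0), matrix(c(0, log(2), log(2), 0), 2))
#' microstate_distribution(net)$probabilities # 0.2 0.2 0.2 0.4
#' @export
microstate_distribution <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  n <- n_nodes(network)
  .check_enum_guard(n)
  total <- 2^n
  energies <- numeric(total)
  for (lo in seq(0, total - 1, by = .ENUM_CHUNK)) {
    idx <- lo:min(lo + .ENUM_CHUNK - 1, total - 1)
    energies[idx + 1] <- .energies(network, .state_matrix(n, idx))
  }
  logw <- -network$beta * energies
  log_z <- .logsumexp(logw)
  logp <- logw - log_z
  structure(
    list(probabilities = exp(logp), energies = energies,
         log_probabilities = logp, log_z = log_z, beta = network$beta,
         n_nodes = n),
    class = "microstate_distribution"
  )
}

#' @export
print.microstate_distribution <- function(x, ...) {
  cat(sprintf(
    "Exact Boltzmann distribution: %d nodes, %d microstates, beta = %g\n",
    x$n_nodes, length(x$probabilities), x$beta))
  cat(sprintf("log Z = %.6g; most probable microstate index %d (P = %.4g)\n",
              x$log_z, which.max(x$probabilities) - 1L,
              max(x$probabilities)))
  invisible(x)
}

#' Number of microstates with a given number of active nodes
#'
#' The macrostate `n` (number of active nodes) aggregates `C(N, n)` distinct
#' microstates; e.g. a 5-node network has `C(5, 2) = 10` microstates with two
#' active nodes.
#'
#' @param n_nodes Total number of nodes `N`.
#' @param n_active Number of active nodes, in `0..N`.
#' @return The binomial coefficient `C(N, n)` as a numeric count.
#' @examples
#' count_microstates(5, 2) # 10
#' @export
count_microstates <- function(n_nodes, n_active) {
  if (!.is_count(n_nodes) || n_nodes < 1)
    .stopf("`n_nodes` must be a positive integer")
  if (!.is_count(n_active) || n_active > n_nodes)
    .stopf("`n_active` must be an integer in 0..%d", n_nodes)
  choose(n_nodes, n_active)
}
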