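# Shared fixtures and independent oracles. Everything here is deliberately
# naive (direct enumeration, convolution, brute-force transition operators)
# so it cannot share a code path with the implementation it checks.

# Seeded random network with |w| <= w_max, |m| <= m_max.
random_network <- function(n, seed, w_max = 1, m_max = 1, beta = 1) {
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    w[upper.tri(w)] <- stats::runif(n * (n - 1) / 2, -w_max, w_max)
    w <- w + t(w)
    ising_network(stats::runif(n, -m_max, m_max), w, beta = beta)
  })
}

# Poisson-binomial pmf over 0..n by direct convolution of Bernoulli(p_i).
poisbinom_pmf <- function(p) {
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

# Macrostate distribution by direct grouping of the enumerated microstate
# distribution, counting active nodes per canonical index bit pattern.
group_microstates <- function(net) {
  dist <- microstate_distribution(net)
  n <- n_nodes(net)
  active <- vapply(0:(2^n - 1), function(i) {
    sum(as.integer(intToBits(i))[1:n])
  }, integer(1))
  as.vector(tapply(dist$probabilities, factor(active, levels = 0:n), sum))
}

# All states of an N-node system as a (2^N x N) matrix in canonical order.
all_states <- function(n) {
  t(vapply(0:(2^n - 1), function(i) as.integer(intToBits(i))[1:n],
           integer(n)))
}

# Exact one-sweep Glauber transition matrix averaged over all node visit
# orders (brute force; N <= 4). Row s, column t: P(next = t | current = s).
glauber_sweep_operator <- function(net) {
  n <- n_nodes(net)
  states <- all_states(n)
  ns <- 2^n
  site_op <- function(i) {
    # transition matrix of a single heat-bath update of node i
    op <- matrix(0, ns, ns)
    for (s in seq_len(ns)) {
      a <- states[s, ]
      p1 <- conditional_activation_probability(net, a, i)
      a1 <- a; a1[i] <- 1
      a0 <- a; a0[i] <- 0
      op[s, microstate_index(a1) + 1] <- op[s, microstate_index(a1) + 1] + p1
      op[s, microstate_index(a0) + 1] <- op[s, microstate_index(a0) + 1] +
        (1 - p1)
    }
    op
  }
  ops <- lapply(seq_len(n), site_op)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (rest in perms(v[-k])) out <- c(out, list(c(v[k], rest)))
    out
  }
  total <- matrix(0, ns, ns)
  all_orders <- perms(seq_len(n))
  for (ord in all_orders) {
    op <- diag(ns)
    for (i in ord) op <- op %*% ops[[i]]
    total <- total + op
  }
  total / length(all_orders)
}

# Expected number of active nodes under the exact macrostate distribution.
expected_active <- function(net) {
  p <- macrostate_distribution(net)
  sum(as.numeric(names(p)) * p)
}
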