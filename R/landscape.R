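# Macrostate aggregation: the steady-state distribution of the number of
# active nodes and its generalized potential ("stability landscape").

# Log of the unnormalized Boltzmann mass per macrostate n = 0..N, plus log Z,
# accumulated in chunks so the full 2^N state matrix is never materialized.
.macro_logmass <- function(network) {
  n <- n_nodes(network)
  .check_enum_guard(n)
  total <- 2^n
  lse_n <- rep(-Inf, n + 1)
  for (lo in seq(0, total - 1, by = .ENUM_CHUNK)) {
    idx <- lo:min(lo + .ENUM_CHUNK - 1, total - 1)
    a <- .state_matrix(n, idx)
    lw <- -network$beta * .energies(network, a)
    gn <- rowSums(a)
    for (g in unique(gn)) {
      lse_n[g + 1] <- .lse2(lse_n[g + 1], .logsumexp(lw[gn == g]))
    }
  }
  list(log_mass = lse_n, log_z = .logsumexp(lse_n))
}

# Fast unvalidated path used inside bootstrap loops: potential U(n) from raw
# parameters given a precomputed state matrix `a` and its row sums `gn`.
.potential_from_params <- function(m, w, beta, a, gn) {
  lw <- -beta * (-0.5 * rowSums((a %*% w) * a) - as.vector(a %*% m))
  mx <- max(lw)
  s <- rowsum(exp(lw - mx), gn) # rows ordered by n = 0..N
  as.vector(log(sum(s)) - log(s))
}

#' Steady-state distribution of the number of active nodes
#'
#' Aggregates the exact Boltzmann distribution over microstates into the
#' macrostate `n = sum(a)` (number of active nodes):
#' `P_SS(n) = sum over all microstates with n active nodes of P(a)`. This is
#' computed analytically by enumeration, without simulation.
#'
#' @param network An [ising_network()] with `N` at most 25.
#' @return Named probability vector over `n = 0..N`, summing to 1.
#' @examples
#' net <- ising_network(c(0, 0), matrix(0, 2, 2))
#' macrostate_distribution(net) # 0.25 0.50 0.25
#' @export
macrostate_distribution <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  mm <- .macro_logmass(network)
  p <- exp(mm$log_mass - mm$log_z)
  names(p) <- 0:(length(p) - 1)
  p
}

#' Compute the stability landscape of an Ising network
#'
#' The generalized potential over the number of active nodes is
#' `U(n) = -log P_SS(n)`. Lower potential marks more stable states; local
#' minima of `U` are the stable phases of the system (e.g. a healthy phase at
#' low symptom counts and a disorder phase at high counts). `U` is defined
#' only up to an additive constant: this function reports it for the
#' normalized `P_SS`, and all phase-stability metrics depend only on
#' differences of `U`. The computation stays in log space throughout, so
#' small probabilities cannot underflow to infinite potentials.
#'
#' @param network An [ising_network()] with `N` at most 25.
#' @return An object of class `ising_landscape`: list with `n` (0..N),
#'   `count` (microstates per `n`), `probability` (`P_SS(n)`), `potential`
#'   (`U(n)`), `beta`, `labels`, `network_fingerprint`, and the generating
#'   `network`.
#' @examples
#' net <- ising_network(c(0, 0), matrix(0, 2, 2))
#' potential_landscape(net)$potential # log(4), log(2), log(4)
#' @seealso [phase_stability()], [locate_local_minima()], [barrier_height()]
#' @export
potential_landscape <- function(network) {
  stopifnot(inherits(network, "ising_network"))
  n <- n_nodes(network)
  mm <- .macro_logmass(network)
  logp <- mm$log_mass - mm$log_z
  structure(
    list(n = 0:n, count = choose(n, 0:n), probability = exp(logp),
         potential = -logp, beta = network$beta, labels = network$labels,
         network_fingerprint = .network_fingerprint(network),
         network = network),
    class = "ising_landscape"
  )
}

#' @export
print.ising_landscape <- function(x, digits = 4, ...) {
  cat(sprintf("Stability landscape over n = 0..%d active nodes (beta = %g)\n",
              max(x$n), x$beta))
  print(data.frame(n = x$n, count = x$count,
                   probability = signif(x$probability, digits),
                   potential = signif(x$potential, digits)),
        row.names = FALSE)
  mins <- locate_local_minima(x)
  cat("Local minima at n =", paste(mins, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.ising_landscape <- function(x, ...) {
  data.frame(n = x$n, count = x$count, probability = x$probability,
             potential = x$potential)
}

#' @export
plot.ising_landscape <- function(x, cutoff = NULL, ...,
                                 xlab = "number of active nodes n",
                                 ylab = "potential U(n)", type = "b",
                                 pch = 19) {
  graphics::plot(x$n, x$potential, type = type, pch = pch,
                 xlab = xlab, ylab = ylab, ...)
  if (!is.null(cutoff))
    graphics::abline(v = cutoff - 0.5, lty = 2)
  invisible(x)
}

#' Locate local minima of a potential vector
#'
#' Scans a discrete potential over `n = 0..N` for indices whose value is
#' less than or equal to both neighbours, one-sided at the window edges.
#' Runs of equal values (plateaus) that qualify as minima contribute their
#' leftmost and rightmost indices as candidates. Non-finite potential values
#' (the sentinel for zero-probability macrostates) are never minima.
#'
#' @param potential Numeric potential vector indexed by `n = 0..N`, or an
#'   `ising_landscape`.
#' @param window Integer pair `c(lo, hi)` of `n` values delimiting the scan
#'   (default: the full range).
#' @return Sorted integer vector of `n` values (0-based) of the minima.
#' @examples
#' locate_local_minima(c(1, 2, 1.5, 2.5, 0.5)) # 0 2 4
#' @export
locate_local_minima <- function(potential, window = NULL) {
  u <- if (inherits(potential, "ising_landscape")) potential$potential
       else as.numeric(potential)
  len <- length(u)
  if (len < 1L) .stopf("`potential` is empty")
  if (is.null(window)) window <- c(0L, len - 1L)
  if (length(window) != 2L || !all(window == round(window)) ||
      window[1] > window[2] || window[1] < 0 || window[2] > len - 1)
    .stopf("`window` must be a nonempty integer range within 0..%d", len - 1)
  window <- as.integer(window)
  lo <- window[1]
  v <- u[(window[1]:window[2]) + 1]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k_n <- length(r$values)
  out <- integer(0)
  for (k in seq_len(k_n)) {
    val <- r$values[k]
    if (!is.finite(val)) next
    left_ok <- k == 1L || val <= r$values[k - 1L]
    right_ok <- k == k_n || val <= r$values[k + 1L]
    if (left_ok && right_ok) out <- c(out, unique(c(starts[k], ends[k])))
  }
  sort(out) + lo - 1L
}

#' Barrier height between two local minima
#'
#' The classical relative-stability measure on a landscape: the highest
#' potential value strictly between two local minima, minus the potential of
#' the starting minimum. It is undefined when the landscape has only one
#' stable state, which is why the cutoff-anchored metrics of
#' [phase_stability()] are preferred; it is retained for comparability.
#'
#' @param landscape An `ising_landscape` or numeric potential vector.
#' @param from_minimum,to_minimum `n` values (0-based) of two distinct local
#'   minima of the potential.
#' @return Nonnegative barrier height; 0 with a warning when the minima are
#'   adjacent and there is no interior point.
#' @examples
#' barrier_height(c(1, 2, 1.5, 2.5, 0.5), 0, 4) # 1.5
#' @export
barrier_height <- function(landscape, from_minimum, to_minimum) {
  u <- if (inherits(landscape, "ising_landscape")) landscape$potential
       else as.numeric(landscape)
  mins <- locate_local_minima(u)
  for (idx in c(from_minimum, to_minimum)) {
    if (!(idx %in% mins))
      .stopf(paste0("n = %d is not a local minimum of the potential ",
                    "(minima: %s); barrier height is undefined"),
             idx, paste(mins, collapse = ", "))
  }
  if (from_minimum == to_minimum)
    .stopf("`from_minimum` and `to_minimum` must differ")
  lo <- min(from_minimum, to_minimum)
  hi <- max(from_minimum, to_minimum)
  if (hi - lo < 2L) {
    .warnf("adjacent minima with no interior point; barrier height 0")
    return(0)
  }
  max(u[(lo + 2):hi]) - u[from_minimum + 1]
}

#' Export a landscape as TSV
#'
#' Writes the landscape table with header columns `n`, `count`,
#' `probability`, `potential`, each numeric value formatted with 12
#' significant digits so exports are stable and diffable.
#'
#' @param landscape An `ising_landscape`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_landscape_tsv <- function(landscape, path) {
  stopifnot(inherits(landscape, "ising_landscape"))
  lines <- c(
    "n\tcount\tprobability\tpotential",
    sprintf("%d\t%s\t%s\t%s", landscape$n,
            sprintf("%.12g", landscape$count),
            sprintf("%.12g", landscape$probability),
            sprintf("%.12g", landscape$potential))
  )
  writeLines(lines, path)
  invisible(path)
}
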