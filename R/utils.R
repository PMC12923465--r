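# Internal numerical and bookkeeping helpers.

# log(sum(exp(x))) without overflow; -Inf for empty input.
.logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Elementwise log(exp(a) + exp(b)) for running accumulators.
.lse2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(-abs(a - b)))
  both_inf <- !is.finite(m)
  out[both_inf] <- m[both_inf]
  out
}

.is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == round(x)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under a temporary seed, restoring the caller's RNG state.
# With seed = NULL the global stream is used (and advanced), as in simulate().
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!.is_count(seed)) .stopf("`seed` must be a single non-negative integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic seed splitting: one user-facing seed feeds a seeded stream from
# which independent component seeds (subsampling, bootstrap, permutation, ...)
# are drawn. NULL propagates NULL (use the ambient RNG).
.split_seeds <- function(seed, n) {
  if (is.null(seed)) return(vector("list", n))
  as.list(.with_seed(seed, sample.int(2147483646L, n)))
}

# Order-sensitive polynomial rolling hash of the network parameters; all
# arithmetic stays below 2^53 so the hash is exact in doubles.
.network_fingerprint <- function(network) {
  txt <- paste(
    sprintf("%.17g", c(network$thresholds, network$weights, network$beta)),
    collapse = "|"
  )
  bytes <- utf8ToInt(txt)
  h <- 0
  p <- 2147483647 # 2^31 - 1
  for (b in bytes) h <- (h * 131 + b) %% p
  sprintf("%08x", as.integer(h))
}
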