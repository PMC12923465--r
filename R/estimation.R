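# From raw person-by-symptom data to Ising network parameters:
# binarization and nodewise logistic-regression (pseudo-likelihood) fitting.

# Threshold magnitude used when a node's column is constant and its logistic
# intercept would diverge; keeps every landscape finite.
.CLAMP_M <- 10

#' Construct a binary dataset
#'
#' A persons-by-nodes matrix with entries exactly 0/1 and unique node labels.
#' Rows containing missing values are dropped with a message (the count is
#' kept in the `n_dropped_rows` field).
#'
#' @param values Numeric matrix or data frame of 0/1 entries.
#' @param labels Optional node names (default: column names, or `V1..VN`).
#' @return An object of class `binary_dataset` with fields `values`
#'   (integer matrix), `labels`, `person_count`, `n_dropped_rows`.
#' @export
binary_dataset <- function(values, labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("`values` must be numeric")
  if (is.null(labels)) labels <- colnames(values)
  if (is.null(labels)) labels <- paste0("V", seq_len(ncol(values)))
  labels <- as.character(labels)
  if (length(labels) != ncol(values) || anyDuplicated(labels))
    .stopf("`labels` must be %d unique node names", ncol(values))
  incomplete <- !stats::complete.cases(values)
  n_dropped <- sum(incomplete)
  if (n_dropped > 0) {
    message(sprintf("dropped %d row(s) with missing cells", n_dropped))
    values <- values[!incomplete, , drop = FALSE]
  }
  if (!all(values %in% c(0, 1)))
    .stopf("`values` entries must be exactly 0 or 1 (use binarize() first)")
  storage.mode(values) <- "integer"
  colnames(values) <- labels
  structure(
    list(values = values, labels = labels, person_count = nrow(values),
         n_dropped_rows = n_dropped),
    class = "binary_dataset"
  )
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf("Binary dataset: %d persons x %d nodes\n",
              x$person_count, length(x$labels)))
  cat("Activation rates:\n")
  print(round(colMeans(x$values), 3))
  invisible(x)
}

#' @export
as.matrix.binary_dataset <- function(x, ...) x$values

# Coerce any accepted data input to a plain 0/1 matrix with labels.
.as_binary_matrix <- function(data) {
  if (inherits(data, "binary_dataset")) return(data$values)
  binary_dataset(data)$values
}

#' Binarize ordinal symptom scores
#'
#' Recodes an ordinal persons-by-nodes matrix to symptom presence/absence:
#' entries greater than or equal to the threshold become 1, all others 0.
#' The default threshold 1 codes "no symptom presence at all" against "some
#' symptom presence" on scales starting at 0.
#'
#' @param values Numeric matrix or data frame of ordinal scores.
#' @param threshold Scalar cut: values `>= threshold` become 1 (default 1).
#' @return A [binary_dataset()]. Columns whose binarized values are all equal
#'   are degenerate for network estimation; they trigger a warning and are
#'   listed in the `degenerate_columns` field.
#' @examples
#' binarize(rbind(c(0, 3), c(1, 0)))$values
#' @export
binarize <- function(values, threshold = 1) {
  values <- as.matrix(values)
  if (!is.numeric(values)) .stopf("`values` must be numeric")
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    .stopf("`threshold` must be a single finite number")
  out <- binary_dataset((values >= threshold) * 1L, labels = colnames(values))
  const <- apply(out$values, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    .warnf("degenerate column(s) after binarization (all values equal): %s",
           paste(out$labels[const], collapse = ", "))
    out$degenerate_columns <- out$labels[const]
  }
  out
}

# Shared nodewise-logistic core. Returns thresholds m, symmetrized weights W,
# indices of clamped (constant) columns, and a divergence flag. With
# on_separation = "fail" the caller (bootstrap machinery) treats divergence
# as a failed replicate instead of an error.
.fit_nodewise <- function(x, ridge = 0, row_weights = NULL,
                          on_separation = c("error", "fail")) {
  on_separation <- match.arg(on_separation)
  n <- ncol(x)
  if (is.null(row_weights)) row_weights <- rep(1, nrow(x))
  m <- numeric(n)
  b <- matrix(0, n, n)
  const <- apply(x, 2, function(v) all(v == v[1]))
  active <- which(!const)
  for (i in which(const)) m[i] <- if (x[1, i] == 1) .CLAMP_M else -.CLAMP_M
  for (i in active) {
    pred <- setdiff(active, i)
    xp <- cbind(1, x[, pred, drop = FALSE])
    fit <- irls_logistic_cpp(xp, as.numeric(x[, i]), as.numeric(row_weights),
                             ridge)
    if (fit$diverged || !fit$converged) {
      if (on_separation == "fail")
        return(list(ok = FALSE, diverged = TRUE))
      .stopf(paste0(
        "perfect separation (or non-convergence) in the logistic regression ",
        "for node %d without a penalty; refit with a small ridge penalty, ",
        "e.g. ridge = 1e-4"), i)
    }
    cf <- as.numeric(fit$coef)
    m[i] <- cf[1]
    b[i, pred] <- cf[-1]
  }
  w <- (b + t(b)) / 2
  diag(w) <- 0
  list(ok = TRUE, m = m, w = w, clamped = which(const), diverged = FALSE)
}

#' Estimate an Ising network by nodewise logistic regression
#'
#' For each node `i`, fits a logistic regression of `a_i` on all other nodes;
#' the intercept is the threshold `m_i` and the weight `w_ij` is the average
#' of the coefficient of `j` in regression `i` and the coefficient of `i` in
#' regression `j` (symmetrization by averaging, the common choice for
#' unregularized pseudo-likelihood). `beta` is fixed at 1. The fit is
#' deterministic given the data and penalty, and invariant to row order.
#'
#' Perfect separation without a penalty is an error instructing a nonzero
#' `ridge`; constant columns have their threshold clamped to +/-10 with the
#' corresponding weights zeroed (warning), which keeps landscapes finite.
#' The regularization actually used is recorded in the output metadata.
#'
#' @param data A [binary_dataset()], 0/1 matrix, or data frame.
#' @param ridge Nonnegative L2 penalty on the slope coefficients (default 0,
#'   i.e. unregularized; `1e-4` is a reasonable fallback under separation).
#' @param row_weights Optional nonnegative case weights, e.g. exact microstate
#'   probabilities for a saturated pseudo-likelihood fit.
#' @return An [ising_network()] with estimation details in `metadata`.
#' @examples
#' x <- cbind(a = rbinom(200, 1, 0.5), b = rbinom(200, 1, 0.5))
#' estimate_ising(x)
#' @export
estimate_ising <- function(data, ridge = 0, row_weights = NULL) {
  x <- .as_binary_matrix(data)
  if (!is.numeric(ridge) || length(ridge) != 1L || !is.finite(ridge) ||
      ridge < 0)
    .stopf("`ridge` must be a single nonnegative number")
  if (ncol(x) < 2) .stopf("network estimation needs at least 2 nodes")
  if (nrow(unique(x)) < 2)
    .stopf("`data` must contain at least 2 distinct rows")
  if (!is.null(row_weights)) {
    if (length(row_weights) != nrow(x) || any(row_weights < 0) ||
        !all(is.finite(row_weights)))
      .stopf("`row_weights` must be %d nonnegative finite numbers", nrow(x))
  }
  fit <- .fit_nodewise(x, ridge = ridge, row_weights = row_weights,
                       on_separation = "error")
  labels <- colnames(x)
  if (length(fit$clamped))
    .warnf("constant column(s) %s: threshold clamped to +/-%g, weights zeroed",
           paste(labels[fit$clamped], collapse = ", "), .CLAMP_M)
  ising_network(
    thresholds = fit$m, weights = fit$w, labels = labels, beta = 1,
    metadata = list(method = "nodewise_logistic", ridge = ridge,
                    symmetrization = "average",
                    n_persons = nrow(x),
                    clamped_nodes = labels[fit$clamped],
                    weighted = !is.null(row_weights))
  )
}
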