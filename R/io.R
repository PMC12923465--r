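# File formats: JSON networks (canonical), CSV network pairs and person-level
# data (interoperability), TSV landscapes.

#' Read and write Ising networks
#'
#' The canonical on-disk format is a JSON document with keys `labels` (array
#' of strings), `thresholds` (array of reals), `weights` (row-major array of
#' arrays), optional `beta` (default 1), and an optional free-form `metadata`
#' object. Numbers are serialized with 17 significant digits, so
#' `read_network(write_network(x))` reproduces `x` exactly. All
#' [ising_network()] invariants are enforced on read, with errors naming the
#' offending field.
#'
#' @param network An [ising_network()].
#' @param path File path.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an `ising_network`.
#' @examples
#' f <- tempfile(fileext = ".json")
#' net <- ising_network(c(0, 0), matrix(0, 2, 2))
#' write_network(net, f)
#' read_network(f)
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "ising_network"))
  doc <- list(
    labels = network$labels,
    thresholds = unname(network$thresholds),
    weights = unname(network$weights),
    beta = network$beta,
    metadata = network$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) .stopf("network file not found: %s", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    .stopf("cannot parse %s as JSON: %s", path,
                           conditionMessage(e)))
  for (field in c("labels", "thresholds", "weights"))
    if (is.null(doc[[field]]))
      .stopf("network file %s: missing required field `%s`", path, field)
  n <- length(doc$labels)
  if (length(doc$thresholds) != n)
    .stopf("network file %s: field `thresholds` has length %d, expected %d",
           path, length(doc$thresholds), n)
  w <- doc$weights
  if (!is.matrix(w) || nrow(w) != n || ncol(w) != n)
    .stopf("network file %s: field `weights` is not a %d x %d matrix",
           path, n, n)
  beta <- if (is.null(doc$beta)) 1 else doc$beta
  metadata <- if (is.null(doc$metadata)) list() else as.list(doc$metadata)
  tryCatch(
    ising_network(doc$thresholds, w, labels = doc$labels, beta = beta,
                  metadata = metadata),
    error = function(e)
      .stopf("network file %s: %s", path, conditionMessage(e))
  )
}

#' Read an Ising network from a CSV pair
#'
#' Spreadsheet-friendly secondary dialect: a weights CSV (header row of node
#' labels, one row per node) plus a thresholds CSV with columns `label` and
#' `threshold`. `beta` is not representable in this dialect and defaults
#' to 1.
#'
#' @param weights_path CSV file with the square weight matrix.
#' @param thresholds_path CSV file with columns `label`, `threshold`.
#' @param beta Inverse temperature (default 1).
#' @return An [ising_network()].
#' @export
read_network_csv <- function(weights_path, thresholds_path, beta = 1) {
  for (p in c(weights_path, thresholds_path))
    if (!file.exists(p)) .stopf("file not found: %s", p)
  w <- as.matrix(utils::read.csv(weights_path, check.names = FALSE))
  th <- utils::read.csv(thresholds_path, check.names = FALSE)
  if (!all(c("label", "threshold") %in% names(th)))
    .stopf("thresholds file %s must have columns `label` and `threshold`",
           thresholds_path)
  labels <- colnames(w)
  if (nrow(w) != ncol(w))
    .stopf("weights file %s: matrix is %d x %d, expected square",
           weights_path, nrow(w), ncol(w))
  if (!setequal(th$label, labels))
    .stopf("labels in %s and %s do not match", weights_path, thresholds_path)
  m <- th$threshold[match(labels, th$label)]
  tryCatch(
    ising_network(m, w, labels = labels, beta = beta),
    error = function(e)
      .stopf("network CSV pair %s + %s: %s", weights_path, thresholds_path,
             conditionMessage(e))
  )
}

#' Read and write person-by-node CSV data
#'
#' RFC-4180-style CSV with a header row of node labels and one row per
#' person; cells are integers (binary or ordinal scores to be passed through
#' [binarize()]). Rows with missing cells are dropped with a message.
#'
#' @param path CSV file path.
#' @return `read_binary_data()` returns an integer matrix with column names;
#'   `write_binary_data()` returns `path` invisibly.
#' @export
read_binary_data <- function(path) {
  if (!file.exists(path)) .stopf("data file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!ncol(df)) .stopf("data file %s has no columns", path)
  if (!all(vapply(df, is.numeric, logical(1))))
    .stopf("data file %s contains non-numeric cells", path)
  x <- as.matrix(df)
  incomplete <- !stats::complete.cases(x)
  if (any(incomplete)) {
    message(sprintf("dropped %d row(s) with missing cells", sum(incomplete)))
    x <- x[!incomplete, , drop = FALSE]
  }
  x
}

#' @rdname read_binary_data
#' @param data A [binary_dataset()] or numeric matrix.
#' @export
write_binary_data <- function(data, path) {
  x <- if (inherits(data, "binary_dataset")) data$values else as.matrix(data)
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
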