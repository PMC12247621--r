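#' Edge index bijection
#'
#' The canonical ordering of the n(n-1)/2 unique edges of an n-node
#' undirected network: strict upper triangle in row-major order, i.e.
#' (1,2), (1,3), ..., (1,n), (2,3), ... All matrix/vector conversions in the
#' package share this bijection.
#'
#' @param n_nodes number of nodes.
#' @return a tibble with columns `edge` (1-based position), `i`, `j`
#'   (1-based node indices, i < j).
#' @export
edge_index <- function(n_nodes) {
  stopifnot(n_nodes >= 2)
  i <- rep(seq_len(n_nodes - 1L), times = (n_nodes - 1L):1L)
  j <- unlist(lapply(seq_len(n_nodes - 1L), function(k) (k + 1L):n_nodes))
  tibble::tibble(edge = seq_along(i), i = i, j = j)
}

#' Pearson functional connectivity from node time series
#'
#' @param ts node x timepoint matrix (>= 2 timepoints, no missing values).
#' @return symmetric unit-diagonal correlation matrix.
#' @export
pearson_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 2) stop("need at least 2 timepoints")
  if (anyNA(ts)) stop("time series contain missing values")
  v <- apply(ts, 1L, stats::var)
  if (any(v == 0)) {
    stop("zero-variance time series at node(s): ",
         paste(which(v == 0), collapse = ", "))
  }
  fc <- cor(t(ts))
  diag(fc) <- 1
  fc
}

#' Concatenate runs in time
#'
#' Joins several node x timepoint matrices for the same subject (e.g. the
#' two runs of a scan day) along the time axis before [pearson_fc()]; FC is
#' then averaged across days with [average_fc()].
#'
#' @param ts_list list of node x timepoint matrices with equal node counts.
#' @return a single node x timepoint matrix.
#' @export
concatenate_runs <- function(ts_list) {
  if (is.matrix(ts_list)) ts_list <- list(ts_list)
  stopifnot(length(ts_list) >= 1)
  nodes <- vapply(ts_list, nrow, integer(1))
  if (length(unique(nodes)) != 1L) {
    stop("runs have mismatched node counts: ",
         paste(unique(nodes), collapse = ", "))
  }
  do.call(cbind, ts_list)
}

#' Average FC matrices across runs
#'
#' Elementwise arithmetic mean, with the diagonal reset to exactly 1.
#'
#' @param fcs a list of FC matrices for one subject (identical dimensions).
#' @return a single FC matrix.
#' @export
average_fc <- function(fcs) {
  if (is.matrix(fcs)) fcs <- list(fcs)
  stopifnot(length(fcs) >= 1)
  dims <- vapply(fcs, dim, integer(2))
  if (any(dims != dims[, 1])) stop("FC matrices have mismatched shapes")
  out <- Reduce(`+`, fcs) / length(fcs)
  diag(out) <- 1
  out
}

#' Fisher-z average of FC matrices
#'
#' Alternative run-averaging convention: atanh-transform, average, tanh back.
#' Off-diagonal values at exactly +/-1 are clamped to +/-(1 - 1e-7) first.
#'
#' @inheritParams average_fc
#' @return a single FC matrix.
#' @export
average_fc_fisher <- function(fcs) {
  if (is.matrix(fcs)) fcs <- list(fcs)
  zs <- lapply(fcs, function(m) {
    m <- pmin(pmax(m, -1 + 1e-7), 1 - 1e-7)
    atanh(m)
  })
  out <- tanh(Reduce(`+`, zs) / length(zs))
  diag(out) <- 1
  out
}

#' Vectorize an FC matrix to its canonical edge vector
#'
#' @param fc symmetric matrix.
#' @return numeric vector of length n(n-1)/2 in [edge_index()] order.
#' @export
vectorize_fc <- function(fc) {
  fc <- as.matrix(fc)
  stopifnot(nrow(fc) == ncol(fc))
  # lower triangle of the transpose, column-major = row-major upper triangle
  tfc <- t(fc)
  tfc[lower.tri(tfc)]
}

#' Rebuild the symmetric matrix from an edge vector
#'
#' Inverse of [vectorize_fc()]; the diagonal is set to 1.
#'
#' @param ev edge vector of length n(n-1)/2.
#' @param diag_value value placed on the diagonal (1 for FC matrices, 0 for
#'   correlation/similarity matrices).
#' @return an n x n symmetric matrix.
#' @export
devectorize_fc <- function(ev, diag_value = 1) {
  m <- length(ev)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop("edge vector length ", m, " is not n(n-1)/2 for any integer n; ",
         "nearest valid n is ", round(n))
  }
  n <- as.integer(round(n))
  out <- matrix(0, n, n)
  tout <- t(out)
  tout[lower.tri(tout)] <- ev
  out <- t(tout)
  out <- out + t(out)
  diag(out) <- diag_value
  out
}

#' Stack subject FC matrices into a subjects x edges matrix
#'
#' Rows follow the order of `fcs` (which must match the behavior-table
#' subject order for downstream correlation).
#'
#' @param fcs named list of FC matrices.
#' @return subjects x edges numeric matrix with subject ids as rownames.
#' @export
stack_edges <- function(fcs) {
  stopifnot(length(fcs) >= 1)
  out <- t(vapply(fcs, vectorize_fc,
                  numeric(nrow(fcs[[1]]) * (nrow(fcs[[1]]) - 1L) / 2L)))
  rownames(out) <- names(fcs)
  out
}

#' Read a node x time or square matrix from delimited text
#'
#' @param path file path (whitespace- or tab-delimited, no header).
#' @return a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

#' Read a parcellation label table
#'
#' Expects columns `node_id`, `name`, `hemisphere`, `system`, `subsystem`.
#' 1-based `node_id` columns are shifted to the package's 0-based convention
#' with a message.
#'
#' @param path TSV path.
#' @return a tibble.
#' @export
read_parcellation <- function(path) {
  p <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE))
  need <- c("node_id", "name", "hemisphere", "system", "subsystem")
  missing <- setdiff(need, names(p))
  if (length(missing)) {
    stop("parcellation file lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (min(p$node_id) == 1L) {
    message("parcellation node_id is 1-based; shifting to 0-based")
    p$node_id <- p$node_id - 1L
  }
  if (!identical(sort(p$node_id), seq_len(nrow(p)) - 1L)) {
    stop("parcellation node_id must be contiguous from 0")
  }
  p
}
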