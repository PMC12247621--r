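#' Row-profile similarity transform of a correlation matrix
#'
#' Entry (i, j) is the Pearson correlation between the correlation profiles
#' of nodes i and j (rows of the input), computed after deleting positions i
#' and j from both rows (self-pair masking: a node's undefined self-entry
#' and the shared pair entry never contribute). The diagonal is 0 by
#' convention. This removes the negative-weight problem for modularity
#' maximization: nodes with similar edge-behavior correlation patterns get
#' high positive similarity regardless of the sign of those correlations.
#'
#' @param corr square symmetric matrix with zero diagonal (a devectorized
#'   per-measure edge-behavior correlation matrix).
#' @return a symmetric similarity matrix with zero diagonal.
#' @export
correlation_to_similarity <- function(corr) {
  corr <- as.matrix(corr)
  n <- nrow(corr)
  stopifnot(n == ncol(corr), n >= 4)
  sim <- matrix(0, n, n)
  warned <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      keep <- setdiff(seq_len(n), c(i, j))
      xi <- corr[i, keep]
      xj <- corr[j, keep]
      if (sd(xi) == 0 || sd(xj) == 0) {
        warned <- TRUE
        next # similarity stays 0
      }
      sim[i, j] <- sim[j, i] <- cor(xi, xj)
    }
  }
  if (warned) warning("constant row(s) after masking: similarity recorded as 0")
  sim
}

#' Similarity layers from an edge-behavior correlation matrix
#'
#' Devectorizes each measure's edgewise correlations to node x node form
#' (zero diagonal) and applies [correlation_to_similarity()].
#'
#' @param ebc a measures x edges `edge_behavior` matrix.
#' @return a named list of node x node similarity matrices, one per measure.
#' @export
similarity_layers <- function(ebc) {
  stopifnot(inherits(ebc, "edge_behavior") || is.matrix(ebc))
  layers <- lapply(seq_len(nrow(ebc)), function(k) {
    correlation_to_similarity(devectorize_fc(ebc[k, ], diag_value = 0))
  })
  names(layers) <- rownames(ebc)
  layers
}

#' Assemble the supra-modularity matrix
#'
#' Flattens L node x node similarity layers into an (nL) x (nL) matrix:
#' diagonal block r is \eqn{W_r - \gamma P} with the uniform null
#' \eqn{P = \mathbf{1} - I} (so \eqn{\gamma} acts as a similarity threshold),
#' and every off-diagonal block is \eqn{\omega I} (all-to-all categorical
#' coupling: a node is linked to its own copy in every other layer).
#' Node-layer unit u = (r - 1) n + i holds node i in layer r.
#'
#' @param layers list of node x node similarity matrices (equal sizes).
#' @param gamma resolution parameter (>= 0).
#' @param omega interlayer coupling (>= 0).
#' @return an (nL) x (nL) matrix of class `supra_matrix` with attributes
#'   `n_nodes`, `n_layers`, `layer_names`, `gamma`, `omega`.
#' @export
build_supra <- function(layers, gamma, omega) {
  stopifnot(length(layers) >= 1, gamma >= 0, omega >= 0,
            is.finite(gamma), is.finite(omega))
  ns <- vapply(layers, nrow, integer(1))
  if (length(unique(ns)) != 1L) stop("layers have mismatched node counts")
  n <- ns[1]
  L <- length(layers)
  P <- matrix(1, n, n) - diag(n)
  supra <- matrix(0, n * L, n * L)
  for (r in seq_len(L)) {
    rows <- (r - 1L) * n + seq_len(n)
    supra[rows, rows] <- layers[[r]] - gamma * P
    if (omega > 0) {
      for (s in seq_len(L)) {
        if (s == r) next
        cols <- (s - 1L) * n + seq_len(n)
        supra[rows, cols] <- diag(omega, n)
      }
    }
  }
  structure(supra, class = c("supra_matrix", class(supra)),
            n_nodes = n, n_layers = L,
            layer_names = names(layers) %||% paste0("layer_", seq_len(L)),
            gamma = gamma, omega = omega)
}

#' Multilayer modularity of a partition
#'
#' The exact sum of supra-matrix entries over ordered same-community
#' node-layer pairs (self-pairs excluded): within-layer terms
#' \eqn{W_{ijr} - \gamma P_{ijr}} plus \eqn{\omega} for every coupled pair
#' of copies sharing a community.
#'
#' @param supra a [build_supra()] matrix (or any symmetric matrix).
#' @param labels community labels: an n x L matrix or a length-nL vector in
#'   unit order.
#' @return the modularity value Q.
#' @export
evaluate_q <- function(supra, labels) {
  lab <- as.integer(as.vector(labels))
  if (length(lab) != nrow(supra)) {
    stop("labels length ", length(lab), " does not match supra size ",
         nrow(supra))
  }
  evaluate_q_cpp(unclass(supra), lab)
}

#' Maximize multilayer modularity with a generalized Louvain heuristic
#'
#' Greedy node-move phase (moves accepted when the modularity gain exceeds
#' `tol`, sweep order randomized from the current RNG state, ties broken
#' toward the lowest community id) alternating with community aggregation
#' until no move improves Q. Always returns a partition; the all-singletons
#' and one-community partitions are valid outputs.
#'
#' @param supra a [build_supra()] matrix.
#' @param seed integer seed; when `NULL` the current RNG state is used.
#' @param tol minimum accepted modularity gain.
#' @param rand_moves choose uniformly among strictly improving moves (the
#'   stochastic move rule that gives restarts their diversity); `FALSE`
#'   selects the best move with lowest-community-id tie-breaking.
#' @param init_labels optional starting partition (length-nL vector); the
#'   default starts from all singletons.
#' @return an object of class `ml_partition`: list with `labels` (n x L
#'   integer matrix, contiguous ids in order of first appearance), `q`,
#'   `gamma`, `omega`.
#' @export
multilayer_louvain <- function(supra, seed = NULL, tol = 1e-10,
                               rand_moves = TRUE, init_labels = NULL) {
  stopifnot(inherits(supra, "supra_matrix") || is.matrix(supra))
  if (!is.null(seed)) set.seed(seed)
  n <- attr(supra, "n_nodes") %||% nrow(supra)
  L <- attr(supra, "n_layers") %||% 1L
  groups <- if (L > 1) rep(seq_len(L) - 1L, each = n) else integer(0)
  res <- louvain_cpp(unclass(supra), tol, rand_moves,
                     as.integer(init_labels %||% integer(0)),
                     as.integer(groups))
  labels <- matrix(res$labels, nrow = n, ncol = L)
  colnames(labels) <- attr(supra, "layer_names")
  structure(list(labels = labels, q = res$q,
                 gamma = attr(supra, "gamma"), omega = attr(supra, "omega")),
            class = "ml_partition")
}

#' @export
print.ml_partition <- function(x, ...) {
  cat("<ml_partition>", nrow(x$labels), "nodes x", ncol(x$labels),
      "layers,", length(unique(as.vector(x$labels))), "communities, Q =",
      format(x$q, digits = 6), "\n")
  invisible(x)
}

#' Repeated Louvain restarts
#'
#' Runs [multilayer_louvain()] `n_restarts` times with restart seeds derived
#' deterministically as `seed + restart_index`. The first restart starts
#' from all singletons; later restarts start from a random coarse partition
#' (2-8 communities, each node's copies initialized identically across
#' layers), which widens the set of local optima the sweep can reach
#' without scrambling the cross-layer correspondence of communities.
#'
#' @inheritParams multilayer_louvain
#' @param n_restarts number of restarts.
#' @param seed master seed.
#' @return a list of `ml_partition` objects.
#' @export
run_restarts <- function(supra, n_restarts = 100L, seed = 1L) {
  stopifnot(n_restarts >= 1)
  n <- attr(supra, "n_nodes") %||% nrow(supra)
  L <- attr(supra, "n_layers") %||% 1L
  lapply(seq_len(n_restarts), function(r) {
    set.seed(seed + r)
    init <- if (r == 1L) {
      NULL
    } else {
      k <- sample(2:min(8L, n), 1L)
      rep(sample.int(k, n, replace = TRUE), L)
    }
    multilayer_louvain(supra, seed = NULL, init_labels = init)
  })
}

#' Consensus partition over Louvain restarts
#'
#' Builds the co-assignment frequency (agreement) matrix over node-layer
#' units, zeroes entries below the null threshold — the expected
#' co-assignment frequency when every partition's label vector is
#' independently permuted, which given the community sizes is exactly
#' \eqn{\tau = P^{-1}\sum_p \sum_c n_c^{(p)}(n_c^{(p)}-1)/(N(N-1))} —
#' reclusters the thresholded agreement matrix with the same Louvain
#' engine (the null threshold playing the role of the uniform-null
#' resolution; coupling is irrelevant at this stage), and iterates until
#' the agreement matrix is binary.
#'
#' @param partitions list of `ml_partition` objects on the same grid (or a
#'   single one, returned unchanged).
#' @param seed integer seed for the reclustering runs.
#' @param n_recluster Louvain runs per reclustering round (capped at the
#'   number of input partitions).
#' @param max_rounds iteration cap before aborting.
#' @return an object of class `ml_consensus` (also `ml_partition`): `labels`,
#'   `q` (`NA`; consensus has no single supra matrix), `agreement` (the
#'   initial co-assignment matrix), `threshold`, `n_input`.
#' @export
consensus_partition <- function(partitions, seed = 1L,
                                n_recluster = 12L, max_rounds = 50L) {
  if (inherits(partitions, "ml_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1)
  dims <- dim(partitions[[1]]$labels)
  lab_mat <- vapply(partitions, function(p) as.vector(p$labels),
                    integer(prod(dims)))
  lab_mat <- matrix(as.integer(lab_mat), nrow = prod(dims))
  A0 <- agreement_cpp(lab_mat)

  if (length(partitions) == 1L || all(A0 %in% c(0, 1))) {
    labels <- components_from_agreement(A0, dims)
    return(new_consensus(labels, A0, NA_real_, length(partitions),
                         partitions[[1]]))
  }

  set.seed(seed)
  cur <- lab_mat
  A <- A0
  tau <- NA_real_
  for (round in seq_len(max_rounds)) {
    if (all(A %in% c(0, 1))) {
      labels <- components_from_agreement(A, dims)
      return(new_consensus(labels, A0, tau, length(partitions),
                           partitions[[1]]))
    }
    tau <- permuted_agreement_expectation(cur)
    D <- ifelse(A >= tau, A, 0)
    diag(D) <- 0
    B <- D - tau * (1 - diag(nrow(D)))
    k_runs <- min(as.integer(n_recluster), ncol(cur))
    reruns <- vapply(seq_len(k_runs), function(r) {
      louvain_cpp(B, 1e-10)$labels
    }, integer(nrow(cur)))
    cur <- matrix(as.integer(reruns), nrow = nrow(cur))
    A <- agreement_cpp(cur)
  }
  ent <- agreement_entropy(A)
  stop("consensus did not converge after ", max_rounds,
       " rounds (agreement entropy ", format(ent, digits = 4), ")")
}

new_consensus <- function(labels, agreement, threshold, n_input, proto) {
  lab <- matrix(labels, nrow = nrow(proto$labels), ncol = ncol(proto$labels))
  colnames(lab) <- colnames(proto$labels)
  structure(list(labels = lab, q = NA_real_,
                 gamma = proto$gamma, omega = proto$omega,
                 agreement = agreement, threshold = threshold,
                 n_input = n_input),
            class = c("ml_consensus", "ml_partition"))
}

# expected off-diagonal co-assignment frequency under independent label
# permutation of every partition: depends only on the community sizes
permuted_agreement_expectation <- function(lab_mat) {
  N <- nrow(lab_mat)
  mean(apply(lab_mat, 2L, function(lab) {
    sizes <- tabulate(match(lab, unique(lab)))
    sum(sizes * (sizes - 1)) / (N * (N - 1))
  }))
}

# connected components of the binary agreement matrix = consensus labels
components_from_agreement <- function(A, dims) {
  n <- nrow(A)
  labels <- integer(n)
  next_id <- 0L
  for (u in seq_len(n)) {
    if (labels[u] > 0L) next
    next_id <- next_id + 1L
    queue <- u
    labels[u] <- next_id
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      nb <- which(A[v, ] >= 1 - 1e-9 & labels == 0L)
      labels[nb] <- next_id
      queue <- c(queue, nb)
    }
  }
  labels
}

agreement_entropy <- function(A) {
  a <- A[upper.tri(A)]
  a <- pmin(pmax(a, 1e-12), 1 - 1e-12)
  mean(-a * log2(a) - (1 - a) * log2(1 - a))
}

# relabel to contiguous ids in order of first appearance
canonical_labels <- function(labels) {
  match(labels, unique(labels))
}
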