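#' Default resolution and coupling grids
#'
#' Nine logarithmically spaced couplings \eqn{\omega = 10^{-4}, 10^{-3.5},
#' \ldots, 1} (half-decade steps) and nineteen linearly spaced resolutions
#' \eqn{\gamma = 0, 0.05, \ldots, 0.9}.
#'
#' @return a list with `gammas` (length 19) and `omegas` (length 9).
#' @export
default_grids <- function() {
  list(gammas = default_gamma_grid(), omegas = default_omega_grid())
}

#' @rdname default_grids
#' @export
default_gamma_grid <- function() seq(0, 0.9, by = 0.05)

#' @rdname default_grids
#' @export
default_omega_grid <- function() 10^seq(-4, 0, by = 0.5)

#' Sweep the (gamma, omega) grid
#'
#' For every grid point: `n_restarts` Louvain runs with deterministic
#' per-point seeds, a consensus partition, and layerwise flexibility for
#' each restart and for the consensus. Per-point seeds derive from the
#' master seed as `seed + 1009 * point_index`; restart seeds add the restart
#' index, so the whole sweep is reproducible from (`layers`, grids, `seed`).
#'
#' @param layers list of node x node similarity matrices.
#' @param gammas,omegas strictly increasing parameter values.
#' @param n_restarts Louvain restarts per point.
#' @param seed master seed.
#' @param flex_mode flexibility counting mode, see [compute_flexibility()].
#' @return an object of class `grid_result`: list with `points` (tibble of
#'   `point`, `gamma`, `omega`), `runs` (per point: list with `restarts`,
#'   `consensus`, `flex_restarts`, `flex_consensus`), `n_restarts`, `seed`.
#' @export
run_grid <- function(layers, gammas = default_gamma_grid(),
                     omegas = default_omega_grid(),
                     n_restarts = 100L, seed = 1L,
                     flex_mode = c("pairwise", "ordered")) {
  flex_mode <- match.arg(flex_mode)
  stopifnot(n_restarts >= 1, !is.unsorted(gammas, strictly = TRUE),
            !is.unsorted(omegas, strictly = TRUE))
  points <- tidyr::crossing(gamma = gammas, omega = omegas)
  points <- dplyr::arrange(points, .data$gamma, .data$omega)
  points$point <- seq_len(nrow(points))
  runs <- purrr::pmap(points, function(gamma, omega, point) {
    supra <- build_supra(layers, gamma = gamma, omega = omega)
    point_seed <- seed + 1009L * point
    restarts <- run_restarts(supra, n_restarts = n_restarts,
                             seed = point_seed)
    consensus <- consensus_partition(restarts, seed = point_seed + 500L)
    list(
      restarts = restarts,
      consensus = consensus,
      flex_restarts = lapply(restarts, compute_flexibility, mode = flex_mode),
      flex_consensus = compute_flexibility(consensus, mode = flex_mode))
  })
  structure(list(points = points[, c("point", "gamma", "omega")],
                 runs = runs, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), flex_mode = flex_mode,
                 layer_names = names(layers)),
            class = "grid_result")
}

#' @export
print.grid_result <- function(x, ...) {
  cat("<grid_result>", nrow(x$points), "grid points x", x$n_restarts,
      "restarts;", length(unique(x$points$gamma)), "gammas x",
      length(unique(x$points$omega)), "omegas\n")
  invisible(x)
}

#' PCA on consensus flexibility across parameter space
#'
#' Builds the grid-point x (node . layer) matrix of layerwise consensus
#' flexibilities, mean-centers the columns (no scaling: flexibilities share
#' the [0, 1] scale) and decomposes by SVD. The sign of each component is
#' fixed so its largest-magnitude loading is positive. Node-level loadings
#' (averaged over layers) support projection back to the parcellation.
#'
#' @param gr a [run_grid()] result.
#' @param scale. standardize columns before the decomposition.
#' @return an object of class `flex_pca`: `scores` (grid points x PCs, with
#'   `gamma`/`omega`), `loadings` (node-layer x PCs), `node_loadings`,
#'   `variance_explained`, `prcomp`.
#' @export
pca_on_flexibility <- function(gr, scale. = FALSE) {
  stopifnot(inherits(gr, "grid_result"), nrow(gr$points) >= 2)
  X <- t(vapply(gr$runs, function(run) as.vector(run$flex_consensus$layerwise),
                numeric(length(gr$runs[[1]]$flex_consensus$layerwise))))
  if (all(apply(X, 2L, sd) == 0)) {
    stop("flexibility is constant across the grid: no variance to decompose")
  }
  keep <- apply(X, 2L, sd) > 0 | !scale.
  pc <- prcomp(X[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_len(ncol(pc$rotation))) {
    top <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[top, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  n <- nrow(gr$runs[[1]]$flex_consensus$layerwise)
  L <- ncol(gr$runs[[1]]$flex_consensus$layerwise)
  loadings <- matrix(0, n * L, ncol(pc$rotation))
  loadings[keep, ] <- pc$rotation
  node_loadings <- vapply(seq_len(ncol(loadings)), function(k) {
    rowMeans(matrix(loadings[, k], n, L))
  }, numeric(n))
  scores <- dplyr::bind_cols(gr$points, tibble::as_tibble(pc$x))
  structure(list(scores = scores, loadings = loadings,
                 node_loadings = node_loadings,
                 variance_explained = ve, prcomp = pc),
            class = "flex_pca")
}

#' @export
print.flex_pca <- function(x, ...) {
  cat("<flex_pca>", nrow(x$scores), "grid points;",
      "PC1 variance =", format(x$variance_explained[1], digits = 3), "\n")
  invisible(x)
}

#' Variability in flexibility across restarts
#'
#' Per grid point: the standard deviation of each node-layer flexibility
#' across the restart partitions, averaged over node-layer units. The
#' maximizing grid point is attached as attribute `argmax`.
#'
#' @param gr a [run_grid()] result with `n_restarts >= 2`.
#' @return a tibble `gamma`, `omega`, `variability`, with attribute `argmax`.
#' @export
variability_in_flexibility <- function(gr) {
  stopifnot(inherits(gr, "grid_result"), gr$n_restarts >= 2)
  v <- vapply(gr$runs, function(run) {
    F <- vapply(run$flex_restarts, function(f) as.vector(f$layerwise),
                numeric(length(run$flex_consensus$layerwise)))
    mean(apply(F, 1L, pop_sd))
  }, numeric(1))
  out <- dplyr::mutate(gr$points, variability = v)[, c("gamma", "omega",
                                                       "variability")]
  attr(out, "argmax") <- out[which.max(out$variability), ]
  out
}

# population SD (divisor n), matching the SD of a {0,1} balanced unit = 0.5
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Adjusted Rand index
#'
#' Chance-corrected pair-counting agreement of two partitions, from the
#' contingency table:
#' \deqn{ARI = \frac{\sum_{ij} \binom{n_{ij}}{2} - E}{M - E}}
#' with \eqn{E} the product of marginal pair counts over \eqn{\binom{n}{2}}
#' and \eqn{M} the mean of the marginal pair counts. Defined as 1 when the
#' denominator vanishes and the partitions are identical (e.g. both all
#' singletons), and 0 when the denominator vanishes otherwise.
#'
#' @param a,b label vectors of equal length.
#' @return the ARI (a scalar <= 1).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) {
    stop("partitions have different lengths: ", length(a), " vs ", length(b))
  }
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n <- length(a)
  E <- ai * bj / choose(n, 2)
  M <- (ai + bj) / 2
  if (abs(M - E) < .Machine$double.eps * 4) {
    return(if (all(canonical_labels(a) == canonical_labels(b))) 1 else 0)
  }
  (nij - E) / (M - E)
}

# mean layer-averaged ARI between two n x L label matrices
layer_ari <- function(la, lb) {
  mean(vapply(seq_len(ncol(la)), function(r) {
    adjusted_rand_index(la[, r], lb[, r])
  }, numeric(1)))
}

#' Partition-landscape degeneracy
#'
#' Per grid point: (a) the ARI between every unordered pair of restart
#' partitions, computed layer-by-layer then averaged across layers and
#' pairs; (b) the ARI of each restart to the consensus, averaged likewise.
#' High values mean the algorithm keeps finding the same communities.
#'
#' @param gr a [run_grid()] result.
#' @return a tibble `gamma`, `omega`, `mean_pairwise_ari`,
#'   `mean_consensus_ari`.
#' @export
partition_landscape <- function(gr) {
  stopifnot(inherits(gr, "grid_result"))
  res <- purrr::map(gr$runs, function(run) {
    labs <- lapply(run$restarts, `[[`, "labels")
    R <- length(labs)
    pair_ari <- if (R >= 2) {
      pairs <- utils::combn(R, 2)
      mean(vapply(seq_len(ncol(pairs)), function(p) {
        layer_ari(labs[[pairs[1, p]]], labs[[pairs[2, p]]])
      }, numeric(1)))
    } else {
      NA_real_
    }
    cons_ari <- mean(vapply(labs, layer_ari, numeric(1),
                            lb = run$consensus$labels))
    c(pair = pair_ari, cons = cons_ari)
  })
  dplyr::mutate(gr$points[, c("gamma", "omega")],
                mean_pairwise_ari = vapply(res, `[[`, numeric(1), "pair"),
                mean_consensus_ari = vapply(res, `[[`, numeric(1), "cons"))
}

#' Seed-based similarity across the grid
#'
#' Either compares every point's consensus to the consensus at a chosen seed
#' grid point, or to a static reference node labeling (replicated across all
#' layers) such as canonical system assignments. ARI is computed layer by
#' layer and averaged. The maximizing point is attached as attribute
#' `argmax`.
#'
#' @param gr a [run_grid()] result.
#' @param seed_point numeric `c(gamma, omega)` of a grid point.
#' @param reference_labels a length-n node label vector (used when
#'   `seed_point` is `NULL`).
#' @return a tibble `gamma`, `omega`, `ari`, with attribute `argmax`.
#' @export
seed_similarity <- function(gr, seed_point = NULL, reference_labels = NULL) {
  stopifnot(inherits(gr, "grid_result"))
  if (is.null(seed_point) == is.null(reference_labels)) {
    stop("supply exactly one of seed_point or reference_labels")
  }
  if (!is.null(seed_point)) {
    hit <- which(abs(gr$points$gamma - seed_point[1]) < 1e-9 &
                   abs(gr$points$omega - seed_point[2]) < 1e-9)
    if (!length(hit)) {
      stop("seed point (", seed_point[1], ", ", seed_point[2],
           ") is not on the grid")
    }
    ref <- gr$runs[[hit]]$consensus$labels
  } else {
    n <- nrow(gr$runs[[1]]$consensus$labels)
    L <- ncol(gr$runs[[1]]$consensus$labels)
    stopifnot(length(reference_labels) == n)
    ref <- matrix(canonical_labels(reference_labels), n, L)
  }
  ari <- vapply(gr$runs, function(run) layer_ari(run$consensus$labels, ref),
                numeric(1))
  out <- dplyr::mutate(gr$points[, c("gamma", "omega")], ari = ari)
  attr(out, "argmax") <- out[which.max(out$ari), ]
  out
}

#' Select analysis points from the parameter-space maps
#'
#' Emits the grid points whose |PC1| and |PC2| scores are maximal together
#' with the variability-in-flexibility argmax, as a machine-readable tibble.
#'
#' @param pca a [pca_on_flexibility()] result.
#' @param variability a [variability_in_flexibility()] result.
#' @return a tibble `criterion`, `gamma`, `omega`, `value`.
#' @export
select_analysis_points <- function(pca, variability) {
  stopifnot(inherits(pca, "flex_pca"))
  pick <- function(col) {
    i <- which.max(abs(pca$scores[[col]]))
    tibble::tibble(criterion = paste0("max_abs_", col),
                   gamma = pca$scores$gamma[i],
                   omega = pca$scores$omega[i],
                   value = pca$scores[[col]][i])
  }
  am <- attr(variability, "argmax")
  dplyr::bind_rows(
    pick("PC1"),
    if ("PC2" %in% names(pca$scores)) pick("PC2"),
    tibble::tibble(criterion = "max_variability", gamma = am$gamma,
                   omega = am$omega, value = am$variability))
}
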