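#' Tidy an edge-behavior correlation matrix
#'
#' @param x an `edge_behavior` matrix.
#' @param ... unused.
#' @return a tibble `measure`, `edge`, `i`, `j`, `rho`.
#' @export
tidy.edge_behavior <- function(x, ...) {
  n_edges <- ncol(x)
  n <- as.integer(round((1 + sqrt(1 + 8 * n_edges)) / 2))
  idx <- edge_index(n)
  tibble::tibble(
    measure = rep(rownames(x), each = n_edges),
    edge = rep(idx$edge, nrow(x)),
    i = rep(idx$i, nrow(x)),
    j = rep(idx$j, nrow(x)),
    rho = as.vector(t(x)))
}

#' Tidy a permutation-test result
#'
#' @param x an `edge_perm_test`.
#' @param ... unused.
#' @return a tibble `measure`, `edge`, `rho`, `p`, `significant`.
#' @export
tidy.edge_perm_test <- function(x, ...) {
  tibble::tibble(
    measure = rep(rownames(x$p), each = ncol(x$p)),
    edge = rep(seq_len(ncol(x$p)), nrow(x$p)),
    rho = as.vector(t(x$rho)),
    p = as.vector(t(x$p)),
    significant = as.vector(t(x$significant)))
}

#' @rdname tidy.edge_perm_test
#' @export
glance.edge_perm_test <- function(x, ...) {
  tibble::tibble(
    n_tests = length(x$p),
    n_significant = sum(x$significant),
    p_crit = if (length(x$p_crit) == 1) x$p_crit else NA_real_,
    n_perm = x$n_perm,
    q = x$q,
    fdr_scope = x$fdr_scope)
}

#' Tidy a multilayer partition
#'
#' @param x an `ml_partition` (or `ml_consensus`).
#' @param ... unused.
#' @return a tibble `layer`, `node`, `community`.
#' @export
tidy.ml_partition <- function(x, ...) {
  lab <- x$labels
  tibble::tibble(
    layer = rep(colnames(lab) %||% as.character(seq_len(ncol(lab))),
                each = nrow(lab)),
    node = rep(seq_len(nrow(lab)) - 1L, ncol(lab)),
    community = as.vector(lab))
}

#' @rdname tidy.ml_partition
#' @export
glance.ml_partition <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$labels),
    n_layers = ncol(x$labels),
    n_communities = length(unique(as.vector(x$labels))),
    q = x$q,
    gamma = x$gamma %||% NA_real_,
    omega = x$omega %||% NA_real_)
}

#' Tidy a flexibility profile
#'
#' @param x a `flexibility_profile`.
#' @param ... unused.
#' @return a tibble `node`, `layer`, `flexibility`, `overall`.
#' @export
tidy.flexibility_profile <- function(x, ...) {
  lw <- x$layerwise
  tibble::tibble(
    node = rep(seq_len(nrow(lw)) - 1L, ncol(lw)),
    layer = rep(colnames(lw) %||% as.character(seq_len(ncol(lw))),
                each = nrow(lw)),
    flexibility = as.vector(lw),
    overall = rep(x$overall, ncol(lw)))
}

#' @rdname tidy.flexibility_profile
#' @export
glance.flexibility_profile <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$overall),
    n_layers = ncol(x$layerwise),
    mean_flexibility = mean(x$overall),
    median_flexibility = median(x$overall),
    mode = x$mode)
}

#' Tidy a flexibility PCA
#'
#' @param x a `flex_pca`.
#' @param ... unused.
#' @return the per-grid-point score tibble (long over components).
#' @export
tidy.flex_pca <- function(x, ...) {
  tidyr::pivot_longer(x$scores, dplyr::starts_with("PC"),
                      names_to = "component", values_to = "score")
}

#' @rdname tidy.flex_pca
#' @export
glance.flex_pca <- function(x, ...) {
  tibble::tibble(
    component = paste0("PC", seq_along(x$variance_explained)),
    variance_explained = x$variance_explained)
}

#' Tidy a layer-switch analysis
#'
#' @param x a `layer_switch`.
#' @param ... unused.
#' @return a tibble `layer_a`, `layer_b`, `proportion`, `p`, `p_bh` over
#'   unordered layer pairs.
#' @export
tidy.layer_switch <- function(x, ...) {
  L <- ncol(x$proportions)
  nm <- colnames(x$proportions) %||% as.character(seq_len(L))
  idx <- which(upper.tri(x$proportions), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(
    layer_a = nm[idx[, 1]],
    layer_b = nm[idx[, 2]],
    proportion = x$proportions[idx],
    p = x$p[idx],
    p_bh = x$p_bh[idx])
}

#' Tidy system-level flexibility statistics
#'
#' @param x a `system_flex_stats`.
#' @param ... unused.
#' @return the pairwise comparison tibble.
#' @export
tidy.system_flex_stats <- function(x, ...) x$pairwise

#' @rdname tidy.system_flex_stats
#' @export
glance.system_flex_stats <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$kruskal$statistic),
    df = unname(x$kruskal$parameter),
    p_value = x$kruskal$p.value,
    n_systems = nrow(x$medians),
    n_perm = x$n_perm)
}
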