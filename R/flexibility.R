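#' Node flexibility of a multilayer partition
#'
#' Layerwise flexibility of node i in layer r is the fraction of other
#' layers whose community label disagrees:
#' \eqn{f_{ir} = \#\{s \ne r : \sigma_{ir} \ne \sigma_{is}\} / (L - 1)}.
#' Overall flexibility is \eqn{f_i = a_i / t} with \eqn{a_i} the number of
#' unordered layer pairs on which the labels differ and
#' \eqn{t = L(L-1)/2} the number of pairs; it equals the mean of the
#' layerwise values exactly. With all-to-all coupling the layers are
#' unordered, so the pairwise count is the default; `mode = "ordered"`
#' counts changes between consecutive layers (\eqn{t = L - 1}) for
#' sequence-like layer sets.
#'
#' @param partition an `ml_partition` or a node x layer label matrix.
#' @param mode `"pairwise"` (default) or `"ordered"`.
#' @return an object of class `flexibility_profile`: list with `layerwise`
#'   (node x layer), `overall` (length n), `a` (change counts), `t`, `mode`.
#' @export
compute_flexibility <- function(partition, mode = c("pairwise", "ordered")) {
  mode <- match.arg(mode)
  labels <- if (inherits(partition, "ml_partition")) {
    partition$labels
  } else {
    as.matrix(partition)
  }
  L <- ncol(labels)
  if (L < 2) stop("flexibility is undefined for a single layer")
  n <- nrow(labels)
  layerwise <- vapply(seq_len(L), function(r) {
    rowSums(labels[, -r, drop = FALSE] != labels[, r]) / (L - 1)
  }, numeric(n))
  layerwise <- matrix(layerwise, nrow = n, ncol = L) # n = 1 drops to vector
  dimnames(layerwise) <- dimnames(labels)
  if (mode == "pairwise") {
    t_total <- L * (L - 1) / 2
    pairs <- utils::combn(L, 2)
    a <- integer(n)
    for (p in seq_len(ncol(pairs))) {
      a <- a + (labels[, pairs[1, p]] != labels[, pairs[2, p]])
    }
    overall <- rowMeans(layerwise) # = a / t, exactly, by the identity
  } else {
    t_total <- L - 1
    a <- rowSums(labels[, -1L, drop = FALSE] != labels[, -L, drop = FALSE])
    overall <- a / t_total
  }
  structure(list(layerwise = layerwise, overall = overall,
                 a = as.integer(a), t = t_total, mode = mode),
            class = "flexibility_profile")
}

#' @export
print.flexibility_profile <- function(x, ...) {
  cat("<flexibility_profile>", length(x$overall), "nodes x",
      ncol(x$layerwise), "layers (", x$mode, "); mean =",
      format(mean(x$overall), digits = 3), "\n")
  invisible(x)
}

#' System-level flexibility statistics
#'
#' Kruskal-Wallis rank-sum test (with tie correction) of overall node
#' flexibility across systems, plus one-sided pairwise permutation tests of
#' "system A more flexible than system B" using the difference in group
#' medians as the statistic: node flexibilities are shuffled across all
#' system labels jointly per permutation, and
#' \eqn{p = (1 + \#\{\Delta_{perm} \ge \Delta_{obs}\}) / (n_{perm} + 1)}.
#'
#' @param flex a [compute_flexibility()] result.
#' @param parcellation parcellation tibble (`node_id` 0-based).
#' @param n_perm permutations for the pairwise tests.
#' @param seed integer seed.
#' @param level grouping column, `"system"` or `"subsystem"`.
#' @return an object of class `system_flex_stats`: `medians` tibble,
#'   `kruskal` (htest), `pairwise` tibble (`system_a`, `system_b`,
#'   `median_diff`, `p`), `excluded` (systems with < 2 nodes), `n_perm`.
#' @export
system_flexibility_tests <- function(flex, parcellation, n_perm = 10000L,
                                     seed = 1L, level = "system") {
  stopifnot(inherits(flex, "flexibility_profile"),
            level %in% names(parcellation))
  f <- flex$overall
  groups <- parcellation[[level]][order(parcellation$node_id)]
  if (anyNA(groups)) stop("unlabeled node(s) in the parcellation")
  stopifnot(length(groups) == length(f))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding system(s) with < 2 nodes: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    f <- f[keep]
    groups <- groups[keep]
  }
  if (length(unique(groups)) < 2) {
    stop("fewer than 2 systems remain after exclusions")
  }
  groups <- factor(groups)
  kw <- kruskal.test(f, groups)
  medians <- tibble::tibble(
    !!level := levels(groups),
    n_nodes = as.integer(table(groups)),
    median_flexibility = as.numeric(tapply(f, groups, median)))

  set.seed(seed)
  lv <- levels(groups)
  pairs <- utils::combn(length(lv), 2)
  obs_med <- tapply(f, groups, median)
  # directional statistics for both orientations of every pair
  perm_ge <- matrix(0L, length(lv), length(lv))
  for (t in seq_len(n_perm)) {
    fp <- sample(f)
    pm <- tapply(fp, groups, median)
    d <- outer(pm, pm, `-`)
    perm_ge <- perm_ge + (d >= outer(obs_med, obs_med, `-`) - 1e-12)
  }
  p_mat <- (1 + perm_ge) / (n_perm + 1)
  pairwise <- tidyr::crossing(system_a = lv, system_b = lv)
  pairwise <- dplyr::filter(pairwise, .data$system_a != .data$system_b)
  pairwise <- dplyr::mutate(
    pairwise,
    median_diff = obs_med[.data$system_a] - obs_med[.data$system_b],
    p = p_mat[cbind(match(.data$system_a, lv), match(.data$system_b, lv))],
    p_bh = p.adjust(.data$p, method = "BH"))
  structure(list(medians = medians, kruskal = kw, pairwise = pairwise,
                 excluded = small, n_perm = as.integer(n_perm),
                 level = level),
            class = "system_flex_stats")
}

#' @export
print.system_flex_stats <- function(x, ...) {
  cat("<system_flex_stats> Kruskal-Wallis H =",
      format(unname(x$kruskal$statistic), digits = 4),
      ", df =", x$kruskal$parameter,
      ", p =", format(x$kruskal$p.value, digits = 3), "\n")
  print(x$medians)
  invisible(x)
}

#' Layer-pair community-switching analysis
#'
#' Observed proportions: for each unordered layer pair (r, s), the fraction
#' of nodes whose community label differs between the two layers, computed
#' per partition and averaged across partitions. Null: per permutation each
#' node's label vector is shuffled across layers independently (per
#' partition), proportions recomputed and averaged, and
#' \eqn{p(r,s) = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\}) / (n_{perm}+1)}.
#'
#' @param partitions an `ml_partition` or list of them (e.g. all restarts).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return an object of class `layer_switch`: `proportions` (L x L,
#'   symmetric, zero diagonal), `p` (L x L), `p_bh`, `n_perm`, `n_partitions`.
#' @export
layer_switch_analysis <- function(partitions, n_perm = 1000L, seed = 1L) {
  if (inherits(partitions, "ml_partition")) partitions <- list(partitions)
  stopifnot(length(partitions) >= 1)
  labs <- lapply(partitions, function(p) {
    m <- if (inherits(p, "ml_partition")) p$labels else as.matrix(p)
    matrix(as.integer(m), nrow = nrow(m))
  })
  L <- ncol(labs[[1]])
  if (L < 2) stop("need at least 2 layers")
  n <- nrow(labs[[1]])
  prop <- matrix(0, L, L)
  for (lab in labs) {
    for (r in seq_len(L - 1)) {
      for (s in (r + 1):L) {
        d <- mean(lab[, r] != lab[, s])
        prop[r, s] <- prop[r, s] + d
        prop[s, r] <- prop[s, r] + d
      }
    }
  }
  prop <- prop / length(labs)
  first <- partitions[[1]]
  layer_names <- colnames(if (inherits(first, "ml_partition")) first$labels
                          else as.matrix(first))
  if (!is.null(layer_names)) dimnames(prop) <- list(layer_names, layer_names)

  set.seed(seed)
  counts <- layer_switch_null_cpp(labs, prop, as.integer(n_perm))
  p <- (1 + counts) / (n_perm + 1)
  diag(p) <- NA_real_
  dimnames(p) <- dimnames(prop)
  ut <- upper.tri(p)
  p_bh <- p
  p_bh[ut] <- p.adjust(p[ut], method = "BH")
  p_bh[lower.tri(p_bh)] <- t(p_bh)[lower.tri(p_bh)]
  structure(list(proportions = prop, p = p, p_bh = p_bh,
                 n_perm = as.integer(n_perm),
                 n_partitions = length(labs)),
            class = "layer_switch")
}

#' @export
print.layer_switch <- function(x, ...) {
  cat("<layer_switch>", ncol(x$proportions), "layers,", x$n_partitions,
      "partition(s),", x$n_perm, "permutations\n")
  cat("  mean switch proportion per layer:\n")
  print(round(rowMeans(x$proportions) * ncol(x$proportions) /
                (ncol(x$proportions) - 1), 3))
  invisible(x)
}

#' Leave-one-layer-out flexibility robustness
#'
#' Recomputes overall flexibility after excluding each layer in turn
#' (denominator rescaled to the remaining layers) and reports the Spearman
#' correlation with the original per-node flexibility. An undefined
#' correlation (constant profile) is reported as `NA` with a warning.
#'
#' @param partition an `ml_partition` or node x layer label matrix (>= 3
#'   layers).
#' @param mode flexibility counting mode.
#' @return a tibble `excluded_layer`, `rho`, `p`.
#' @export
leave_one_layer_out <- function(partition, mode = c("pairwise", "ordered")) {
  mode <- match.arg(mode)
  labels <- if (inherits(partition, "ml_partition")) {
    partition$labels
  } else {
    as.matrix(partition)
  }
  L <- ncol(labels)
  if (L < 3) stop("leave-one-layer-out needs at least 3 layers")
  orig <- compute_flexibility(labels, mode = mode)$overall
  undefined <- integer(0)
  out <- purrr::map_dfr(seq_len(L), function(r) {
    red <- compute_flexibility(labels[, -r, drop = FALSE],
                               mode = mode)$overall
    if (sd(orig) == 0 || sd(red) == 0) {
      undefined <<- c(undefined, r)
      return(tibble::tibble(excluded_layer = colnames(labels)[r] %||%
                              as.character(r),
                            rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(cor.test(orig, red, method = "spearman"))
    tibble::tibble(excluded_layer = colnames(labels)[r] %||% as.character(r),
                   rho = unname(ct$estimate), p = ct$p.value)
  })
  if (length(undefined)) {
    warning("constant flexibility profile: correlation undefined for ",
            "excluded layer(s) ", paste(undefined, collapse = ", "))
  }
  out
}

#' System versus global layer-switching patterns
#'
#' Computes the layer-pair switching proportions both globally and
#' restricted to each system's nodes, then correlates (Pearson) each
#' system's upper-triangle proportion vector with the global one, and all
#' systems with each other. Constant vectors yield `NA` with a warning.
#'
#' @param partitions an `ml_partition` or list of them.
#' @param parcellation parcellation tibble.
#' @param level grouping column, `"system"` or `"subsystem"`.
#' @return an object of class `system_layer_pattern`: `global` tibble
#'   (`system`, `r`, `p`), `system_matrix` (system x system correlation of
#'   switch vectors), `vectors` (systems x layer-pairs).
#' @export
system_pattern_correlation <- function(partitions, parcellation,
                                       level = "system") {
  if (inherits(partitions, "ml_partition")) partitions <- list(partitions)
  labs <- lapply(partitions, function(p) {
    if (inherits(p, "ml_partition")) p$labels else as.matrix(p)
  })
  L <- ncol(labs[[1]])
  if (L < 3) stop("need at least 3 layers (>= 3 layer pairs)")
  groups <- parcellation[[level]][order(parcellation$node_id)]
  stopifnot(length(groups) == nrow(labs[[1]]))

  # upper-triangle order must be consistent; build explicitly
  pair_idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  pair_idx <- pair_idx[order(pair_idx[, 1], pair_idx[, 2]), , drop = FALSE]
  vec_for <- function(node_idx) {
    agg <- Reduce(`+`, lapply(labs, function(lab) {
      sub <- lab[node_idx, , drop = FALSE]
      apply(pair_idx, 1L, function(rs) mean(sub[, rs[1]] != sub[, rs[2]]))
    })) / length(labs)
    agg
  }
  global <- vec_for(seq_along(groups))
  systems <- sort(unique(groups))
  vectors <- t(vapply(systems, function(g) vec_for(which(groups == g)),
                      numeric(nrow(pair_idx))))
  rownames(vectors) <- systems

  cor_or_na <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      warning("constant switch vector: correlation undefined")
      return(c(r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x, y)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  gl <- t(vapply(systems, function(g) cor_or_na(vectors[g, ], global),
                 numeric(2)))
  global_tbl <- tibble::tibble(system = systems, r = gl[, 1], p = gl[, 2])
  names(global_tbl)[1] <- level
  sys_mat <- suppressWarnings(cor(t(vectors)))
  structure(list(global = global_tbl, system_matrix = sys_mat,
                 vectors = vectors, global_vector = global, level = level),
            class = "system_layer_pattern")
}
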