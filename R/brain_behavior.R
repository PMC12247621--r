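#' Spearman correlation of every edge with every behavioral measure
#'
#' For each measure k and edge e, computes the Spearman rank correlation
#' (average ranks for ties) of the measure's scores with the edge's weights
#' across subjects. Constant columns (undefined correlation) are recorded as
#' 0 with a warning.
#'
#' @param edges subjects x edges matrix (rows in behavior-table order).
#' @param behavior behavior tibble with `subject_id` plus measure columns.
#' @return a measures x edges matrix of class `edge_behavior` with measure
#'   names as rownames.
#' @export
spearman_edge_behavior <- function(edges, behavior) {
  scores <- behavior_scores(behavior)
  if (nrow(scores) != nrow(edges)) {
    stop("behavior table (", nrow(scores), " subjects) does not match the ",
         "edge matrix (", nrow(edges), " rows)")
  }
  re <- rank_columns(edges)
  rb <- rank_columns(scores)
  const_e <- attr(re, "constant")
  const_b <- attr(rb, "constant")
  if (any(const_e) || any(const_b)) {
    warning(sum(const_e), " constant edge(s) and ", sum(const_b),
            " constant measure(s): correlations undefined, recorded as 0")
  }
  # measures x edges; Pearson on average ranks = Spearman (cor's own
  # zero-sd warning is superseded by the message above)
  rho <- suppressWarnings(cor(rb, re))
  rho[const_b, ] <- 0
  rho[, const_e] <- 0
  rownames(rho) <- colnames(scores)
  class(rho) <- c("edge_behavior", class(rho))
  rho
}

behavior_scores <- function(behavior) {
  stopifnot(is.data.frame(behavior))
  num <- vapply(behavior, is.numeric, logical(1))
  num["subject_id"] <- FALSE
  m <- as.matrix(behavior[, num, drop = FALSE])
  if (anyNA(m)) stop("behavior table contains missing scores")
  m
}

# columnwise average ranks; flags constant columns
rank_columns <- function(m) {
  out <- apply(m, 2L, rank)
  const <- apply(m, 2L, function(x) length(unique(x)) == 1L)
  attr(out, "constant") <- const
  out
}

#' Subject-shuffling permutation test for edge-behavior correlations
#'
#' Shuffles the rows of the behavior table `n_perm` times (the same shuffle
#' applied to all measures jointly, preserving inter-measure correlation),
#' recomputes all Spearman correlations, and assigns each (measure, edge)
#' cell the two-sided exceedance p-value
#' \deqn{p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\}) / (n_{perm} + 1).}
#' Significance is then assessed by Benjamini-Hochberg FDR, by default
#' pooled across all measure x edge tests.
#'
#' @inheritParams spearman_edge_behavior
#' @param n_perm number of permutations (>= 100).
#' @param q FDR level.
#' @param seed integer seed for the shuffles.
#' @param fdr_scope `"pooled"` (one correction over all measures x edges) or
#'   `"per-measure"`.
#' @return an object of class `edge_perm_test`: list with `rho`, `p`
#'   (measures x edges), `significant` (logical mask), `p_crit` (realized
#'   adjusted criterion), `n_perm`, `q`, `fdr_scope`.
#' @export
edge_permutation_test <- function(edges, behavior, n_perm = 1000L,
                                  q = 0.05, seed = 1L,
                                  fdr_scope = c("pooled", "per-measure")) {
  fdr_scope <- match.arg(fdr_scope)
  if (n_perm < 100L) {
    stop("n_perm must be >= 100 (p-value resolution too coarse below that)")
  }
  scores <- behavior_scores(behavior)
  n_sub <- nrow(scores)
  stopifnot(n_sub == nrow(edges))

  re_r <- rank_columns(edges)
  rb_r <- rank_columns(scores)
  re <- scale(re_r)
  rb <- scale(rb_r)
  re[, attr(re_r, "constant")] <- 0
  rb[, attr(rb_r, "constant")] <- 0
  denom <- n_sub - 1
  rho_obs <- crossprod(rb, re) / denom # measures x edges
  abs_obs <- abs(rho_obs)

  set.seed(seed)
  exceed <- matrix(0L, nrow(rho_obs), ncol(rho_obs))
  for (t in seq_len(n_perm)) {
    idx <- sample.int(n_sub)
    rho_p <- crossprod(rb[idx, , drop = FALSE], re) / denom
    exceed <- exceed + (abs(rho_p) >= abs_obs - 1e-12)
  }
  p <- (1 + exceed) / (n_perm + 1)
  dimnames(p) <- dimnames(rho_obs) <- list(colnames(scores), NULL)

  if (fdr_scope == "pooled") {
    fdr <- bh_fdr(as.vector(p), q)
    significant <- matrix(fdr$significant, nrow(p), ncol(p))
    p_crit <- fdr$p_crit
  } else {
    significant <- matrix(FALSE, nrow(p), ncol(p))
    p_crit <- numeric(nrow(p))
    for (k in seq_len(nrow(p))) {
      fdr <- bh_fdr(p[k, ], q)
      significant[k, ] <- fdr$significant
      p_crit[k] <- fdr$p_crit
    }
    names(p_crit) <- rownames(p)
  }
  dimnames(significant) <- dimnames(p)
  structure(
    list(rho = rho_obs, p = p, significant = significant, p_crit = p_crit,
         n_perm = as.integer(n_perm), q = q, fdr_scope = fdr_scope),
    class = "edge_perm_test")
}

#' @export
print.edge_perm_test <- function(x, ...) {
  cat("<edge_perm_test>", nrow(x$p), "measures x", ncol(x$p), "edges,",
      x$n_perm, "permutations\n")
  cat("  significant cells:", sum(x$significant), "of", length(x$p),
      " (q =", x$q, ",", x$fdr_scope, "FDR, p_crit =",
      format(x$p_crit, digits = 3), ")\n")
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR
#'
#' Standard step-up: rejects the k* smallest p-values where
#' k* = max\{k : p_(k) <= k q / m\}. The realized criterion is p_(k*) (the
#' largest rejected p-value), `NA` when nothing is rejected.
#'
#' @param p vector of p-values in (0, 1].
#' @param q FDR level.
#' @return list with `significant` (logical), `p_crit` (realized criterion).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (!length(p)) {
    warning("empty p-value collection; criterion undefined")
    return(list(significant = logical(0), p_crit = NA_real_))
  }
  stopifnot(all(p > 0), all(p <= 1))
  significant <- p.adjust(p, method = "BH") <= q
  p_crit <- if (any(significant)) max(p[significant]) else NA_real_
  list(significant = significant, p_crit = p_crit)
}

#' Summarize significant edges per subsystem and measure
#'
#' An edge belongs to a subsystem when either endpoint carries that label
#' (so an edge can count toward two subsystems). For every
#' (subsystem, measure) pair, reports the number of edges, the number
#' significant, and log10 of the significant proportion (`NA` when no edge
#' is significant).
#'
#' @param perm an [edge_permutation_test()] result.
#' @param parcellation parcellation tibble (`node_id` 0-based, `subsystem`).
#' @param level grouping column: `"subsystem"` (default) or `"system"`.
#' @return a tibble: `subsystem`, `measure`, `n_edges`, `n_significant`,
#'   `proportion`, `log10_proportion`.
#' @export
system_summary <- function(perm, parcellation, level = "subsystem") {
  stopifnot(inherits(perm, "edge_perm_test"), level %in% names(parcellation))
  n_edges <- ncol(perm$p)
  n <- nrow(parcellation)
  if (n * (n - 1L) / 2L != n_edges) {
    stop("parcellation (", n, " nodes) does not match the edge count ",
         n_edges)
  }
  labels <- parcellation[[level]][order(parcellation$node_id)]
  if (anyNA(labels)) {
    stop("unlabeled node(s): ",
         paste(parcellation$node_id[is.na(labels)], collapse = ", "))
  }
  idx <- edge_index(n)
  long <- dplyr::bind_rows(
    tibble::tibble(edge = idx$edge, group = labels[idx$i]),
    tibble::tibble(edge = idx$edge, group = labels[idx$j]))
  long <- dplyr::distinct(long) # both endpoints in the same group counts once

  sig_long <- tibble::as_tibble(t(perm$significant))
  names(sig_long) <- rownames(perm$p)
  sig_long$edge <- seq_len(n_edges)
  sig_long <- tidyr::pivot_longer(sig_long, -dplyr::all_of("edge"),
                                  names_to = "measure",
                                  values_to = "significant")
  out <- dplyr::inner_join(long, sig_long, by = "edge",
                           relationship = "many-to-many")
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$group, .data$measure),
    n_edges = dplyr::n(),
    n_significant = sum(.data$significant),
    .groups = "drop")
  out <- dplyr::mutate(
    out,
    proportion = .data$n_significant / .data$n_edges,
    log10_proportion = ifelse(.data$n_significant > 0,
                              log10(.data$proportion), NA_real_))
  names(out)[1] <- level
  dplyr::arrange(out, .data[[level]], .data$measure)
}
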