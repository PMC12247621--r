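# shared fixtures, built once per test run

fixture_env <- new.env(parent = emptyenv())

# default-condition synthetic dataset plus its similarity layers (the
# heaviest shared input), memoized by seed
planted_layers <- function(seed = 3L, n_subjects = 200L) {
  key <- paste0("ds", seed, "_", n_subjects)
  if (is.null(fixture_env[[key]])) {
    cfg <- synth_config(n_subjects = n_subjects, seed = seed)
    ds <- generate_dataset(cfg)
    eb <- spearman_edge_behavior(stack_edges(ds$fc), ds$behavior)
    fixture_env[[key]] <- list(config = cfg, dataset = ds, ebc = eb,
                               layers = similarity_layers(eb))
  }
  fixture_env[[key]]
}

# a small random symmetric zero-diagonal similarity matrix
random_layer <- function(n) {
  m <- matrix(runif(n * n, -1, 1), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# independent pair-counting ARI oracle: agreement over all C(n,2) element
# pairs, chance-corrected (no contingency table)
ari_pair_counting <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n_pairs <- choose(n, 2)
  n11 <- sum(same_a & same_b)
  e <- sum(same_a) * sum(same_b) / n_pairs
  m <- (sum(same_a) + sum(same_b)) / 2
  if (abs(m - e) < 1e-12) {
    return(if (all(same_a == same_b)) 1 else 0)
  }
  (n11 - e) / (m - e)
}

# hand-rolled BH step-up oracle
bh_step_up <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= q * seq_len(m) / m)
  reject <- logical(m)
  if (length(k)) reject[o[seq_len(max(k))]] <- TRUE
  reject
}
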