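test_that("default grids match the analysis design", {
  g <- default_grids()
  expect_length(g$omegas, 9L)
  expect_length(g$gammas, 19L)
  expect_equal(g$omegas[1], 1e-4)
  expect_equal(g$omegas[9], 1)
  expect_equal(g$gammas[1], 0)
  expect_equal(g$gammas[19], 0.9)
  expect_equal(diff(g$gammas), rep(0.05, 18))
  expect_equal(diff(log10(g$omegas)), rep(0.5, 8))
})

small_grid <- function(seed = 21, n_restarts = 4) {
  set.seed(seed)
  layers <- list(random_layer(8), random_layer(8))
  run_grid(layers, gammas = c(0.1, 0.4), omegas = c(0.01, 0.5),
           n_restarts = n_restarts, seed = seed)
}

test_that("run_grid covers the grid deterministically", {
  gr <- small_grid()
  expect_equal(nrow(gr$points), 4L)
  gr2 <- small_grid()
  expect_identical(
    lapply(gr$runs, function(r) r$consensus$labels),
    lapply(gr2$runs, function(r) r$consensus$labels))
  expect_identical(
    lapply(gr$runs, function(r) lapply(r$restarts, `[[`, "labels")),
    lapply(gr2$runs, function(r) lapply(r$restarts, `[[`, "labels")))
})

test_that("a single restart makes the consensus that restart", {
  gr <- small_grid(seed = 22, n_restarts = 1)
  for (run in gr$runs) {
    expect_equal(
      multiflex:::canonical_labels(as.vector(run$consensus$labels)),
      multiflex:::canonical_labels(as.vector(run$restarts[[1]]$labels)))
  }
})

test_that("PCA on flexibility behaves like an SVD of centered data", {
  gr <- small_grid(seed = 23)
  pc <- pca_on_flexibility(gr)
  expect_true(all(diff(pc$variance_explained) <= 1e-12))
  expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  expect_equal(sum(pc$variance_explained), 1)
  # reconstruction with all components reproduces the centered matrix
  X <- t(vapply(gr$runs,
                function(r) as.vector(r$flex_consensus$layerwise),
                numeric(16)))
  Xc <- scale(X, scale = FALSE)
  rec <- pc$prcomp$x %*% t(pc$prcomp$rotation)
  expect_equal(rec, Xc, tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: the largest-|loading| entry of each PC is positive
  for (k in seq_len(ncol(pc$prcomp$rotation))) {
    expect_gt(pc$prcomp$rotation[which.max(abs(pc$prcomp$rotation[, k])), k],
              0)
  }
})

test_that("rank-1 flexibility variation loads entirely on PC1", {
  gr <- small_grid(seed = 24)
  # overwrite flexibilities with a rank-1 pattern across grid points
  v <- runif(16)
  for (k in 1:4) {
    gr$runs[[k]]$flex_consensus$layerwise <- matrix(k * v, 8, 2)
  }
  pc <- pca_on_flexibility(gr)
  expect_equal(pc$variance_explained[1], 1)
  # duplicated grid points get identical scores
  gr$runs[[2]] <- gr$runs[[1]]
  pc2 <- pca_on_flexibility(gr)
  expect_equal(pc2$scores$PC1[1], pc2$scores$PC1[2])
  # constant matrix is rejected
  for (k in 1:4) gr$runs[[k]]$flex_consensus$layerwise <- matrix(0.5, 8, 2)
  expect_error(pca_on_flexibility(gr), "constant")
})

test_that("variability in flexibility is zero for unanimous restarts", {
  gr <- small_grid(seed = 25)
  for (k in 1:4) {
    gr$runs[[k]]$flex_restarts <-
      rep(gr$runs[[k]]$flex_restarts[1], 4)
  }
  v <- variability_in_flexibility(gr)
  expect_equal(v$variability, rep(0, 4))
})

test_that("variability averages population SDs of node-layer units", {
  gr <- small_grid(seed = 26)
  # alternate one unit between 0 and 1 across 4 restarts: population SD 0.5
  for (k in 1:4) {
    for (r in 1:4) {
      lw <- matrix(0, 8, 2)
      lw[1, 1] <- (r - 1) %% 2
      gr$runs[[k]]$flex_restarts[[r]]$layerwise <- lw
    }
  }
  v <- variability_in_flexibility(gr)
  expect_equal(v$variability, rep(0.5 / 16, 4))
  am <- attr(v, "argmax")
  expect_equal(am$variability, max(v$variability))
})

test_that("adjusted_rand_index matches its pair-counting definition", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
  # all singletons vs all singletons: degenerate but identical
  expect_equal(adjusted_rand_index(1:5, 5:1), 1)
})

test_that("landscape maps are 1 for unanimous restarts, ~0 for random", {
  gr <- small_grid(seed = 27)
  for (k in 1:4) {
    gr$runs[[k]]$restarts <- rep(gr$runs[[k]]$restarts[1], 4)
    gr$runs[[k]]$consensus$labels <- gr$runs[[k]]$restarts[[1]]$labels
  }
  land <- partition_landscape(gr)
  expect_equal(land$mean_pairwise_ari, rep(1, 4))
  expect_equal(land$mean_consensus_ari, rep(1, 4))

  # independent uniform labelings have chance-corrected similarity near 0
  set.seed(28)
  aris <- replicate(50, {
    adjusted_rand_index(sample(1:4, 500, replace = TRUE),
                        sample(1:4, 500, replace = TRUE))
  })
  expect_lt(max(abs(aris)), 0.05)
})

test_that("mean pairwise ARI over two unanimous groups matches enumeration", {
  # 6 restarts in two unanimous groups of 3: mean over C(6,2) pairs is
  # (3 + 3 + 9 * ari_between) / 15, computed here by brute force over pairs
  a <- rep(1:2, each = 5)
  b <- rep(1:2, times = 5)
  labs <- c(rep(list(matrix(a, ncol = 1)), 3), rep(list(matrix(b, ncol = 1)), 3))
  pairs <- combn(6, 2)
  manual <- mean(vapply(seq_len(ncol(pairs)), function(p) {
    adjusted_rand_index(labs[[pairs[1, p]]], labs[[pairs[2, p]]])
  }, numeric(1)))
  ari_between <- adjusted_rand_index(a, b)
  expect_equal(manual, (3 + 3 + 9 * ari_between) / 15)
})

test_that("seed similarity is 1 at the seed and for matching references", {
  gr <- small_grid(seed = 29)
  ss <- seed_similarity(gr, seed_point = c(0.1, 0.5))
  at_seed <- ss$gamma == 0.1 & ss$omega == 0.5
  expect_equal(ss$ari[at_seed], 1)
  expect_error(seed_similarity(gr, seed_point = c(0.15, 0.5)), "grid")
  expect_error(seed_similarity(gr), "exactly one")

  # a reference equal to every layer of one point's consensus scores 1 there
  ref <- gr$runs[[1]]$consensus$labels[, 1]
  gr$runs[[1]]$consensus$labels <- matrix(ref, 8, 2)
  ss2 <- seed_similarity(gr, reference_labels = ref)
  expect_equal(ss2$ari[1], 1)
  am <- attr(ss2, "argmax")
  expect_equal(am$ari, max(ss2$ari))
})

test_that("analysis points are selected from the PCA and variability maps", {
  gr <- small_grid(seed = 30)
  pc <- pca_on_flexibility(gr)
  v <- variability_in_flexibility(gr)
  sel <- select_analysis_points(pc, v)
  expect_true(all(c("max_abs_PC1", "max_variability") %in% sel$criterion))
  i <- which.max(abs(pc$scores$PC1))
  expect_equal(sel$gamma[sel$criterion == "max_abs_PC1"],
               pc$scores$gamma[i])
})
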