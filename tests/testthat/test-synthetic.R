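test_that("behavior scores match the configured T-score scale and correlation", {
  # independent measures: empirical correlations near zero
  cfg <- synth_config(n_subjects = 10000, n_measures = 4, n_nodes = 12,
                      n_flexible = 0, measure_correlation = diag(4),
                      seed = 7)
  b <- generate_behavior(cfg)
  scores <- as.matrix(b[, -1])
  expect_equal(dim(scores), c(10000L, 4L))
  rho <- cor(scores, method = "spearman")
  expect_lt(max(abs(rho[upper.tri(rho)])), 0.05)
  expect_true(all(abs(colMeans(scores) - 50) < 3 * 10 / sqrt(10000)))
  expect_true(all(apply(scores, 2, sd) > 6 & apply(scores, 2, sd) < 14))

  # a single strong correlation survives the rank transform per the
  # bivariate-normal mapping rho_s = (6/pi) asin(rho/2) = 0.891
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  cfg2 <- synth_config(n_subjects = 5000, n_measures = 2, n_nodes = 12,
                       n_flexible = 0, measure_correlation = R, seed = 5)
  b2 <- generate_behavior(cfg2)
  rs <- cor(b2[[2]], b2[[3]], method = "spearman")
  expect_gt(rs, 0.82)
  expect_lt(rs, 0.95)

  # the default study conditions give the 92 x 7 score table
  b3 <- generate_behavior(synth_config(seed = 1))
  expect_equal(dim(b3), c(92L, 8L)) # subject_id + 7 measures
  expect_equal(sum(vapply(b3, is.numeric, logical(1))), 7L)
})

test_that("a non-PSD measure correlation is rejected naming the eigenvalue", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(
    synth_config(n_measures = 3, measure_correlation = R, seed = 1),
    "eigenvalue")
})

test_that("planted partitions have the promised structure", {
  # no flexible nodes: every layer identical
  cfg <- synth_config(n_flexible = 0, seed = 1)
  tr <- generate_planted_partitions(cfg)
  expect_equal(length(tr$flexible), 0L)
  expect_true(all(tr$partitions == tr$partitions[, 1]))

  # 3 non-empty communities per layer by construction
  expect_true(all(apply(tr$partitions, 2,
                        function(x) length(unique(x))) == 3L))

  # cycle pattern with as many communities as layers: a flexible node gets a
  # distinct label in every one of the 7 layers -> 21 of 21 pairs differ
  cfg2 <- synth_config(n_nodes = 21, n_communities = 7, n_flexible = 1,
                       flexible_pattern = "cycle", seed = 1)
  tr2 <- generate_planted_partitions(cfg2)
  f <- tr2$flexible[1]
  labs <- tr2$partitions[f, ]
  pairs <- combn(7, 2)
  n_diff <- sum(labs[pairs[1, ]] != labs[pairs[2, ]])
  expect_equal(length(unique(labs)), 7L)
  expect_equal(n_diff, 21L)

  # flexible nodes differ between at least one layer pair; stable never
  cfg3 <- synth_config(seed = 2)
  tr3 <- generate_planted_partitions(cfg3)
  per_node_changes <- apply(tr3$partitions, 1,
                            function(x) length(unique(x)) > 1)
  expect_true(all(per_node_changes[tr3$flexible]))
  expect_false(any(per_node_changes[-tr3$flexible]))

  expect_error(synth_config(n_nodes = 4, n_communities = 9, n_flexible = 0,
                            seed = 1),
               "communities")
})

test_that("generated FC matrices are symmetric, unit-diagonal and planted", {
  cfg <- synth_config(n_subjects = 5, seed = 9)
  ds <- generate_dataset(cfg)
  for (fc in ds$fc) {
    expect_equal(fc, t(fc))
    expect_equal(unname(diag(fc)), rep(1, nrow(fc)))
    expect_true(all(fc >= -1 & fc <= 1))
  }
  # one subject still works
  cfg1 <- synth_config(n_subjects = 1, seed = 9)
  ds1 <- generate_dataset(cfg1)
  expect_length(ds1$fc, 1L)
  expect_equal(ds1$fc[[1]], t(ds1$fc[[1]]))
})

test_that("null generator (beta = 0) yields null edge-behavior correlations", {
  cfg <- synth_config(n_subjects = 92, effect_size = 0, seed = 12)
  ds <- generate_dataset(cfg)
  eb <- spearman_edge_behavior(stack_edges(ds$fc), ds$behavior)
  # at n = 92 the null |rho| 99th percentile stays below 0.3
  expect_lt(quantile(abs(eb), 0.99), 0.3)
})

test_that("planted effect separates within- from between-block edges", {
  # Monte-Carlo check of the edge model: matching-measure Spearman rho is
  # much larger for edges inside the measure's planted blocks
  cfg <- synth_config(n_subjects = 500, noise_sd = 0.05, effect_size = 1.5,
                      seed = 11)
  ds <- generate_dataset(cfg)
  eb <- spearman_edge_behavior(stack_edges(ds$fc), ds$behavior)
  idx <- edge_index(cfg$n_nodes)
  for (k in c(1, 4)) {
    lab <- ds$truth_partitions[, k]
    within <- lab[idx$i] == lab[idx$j]
    expect_gt(mean(eb[k, within]) - mean(eb[k, !within]), 0.3)
  }
})

test_that("identical configs give bit-identical datasets", {
  cfg <- synth_config(n_subjects = 8, seed = 33)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$behavior, d2$behavior)
  expect_identical(d1$fc, d2$fc)
  expect_identical(d1$truth_partitions, d2$truth_partitions)
})

test_that("excessive clipping triggers a warning naming the fraction", {
  cfg <- synth_config(n_subjects = 20, effect_size = 12,
                      within_block_baseline = 0.9, noise_sd = 0.5, seed = 2)
  expect_warning(generate_dataset(cfg), "clipped")
})

test_that("datasets round-trip through the on-disk format", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_subjects = 3, n_nodes = 10, n_flexible = 2, seed = 4)
  ds <- generate_dataset(cfg)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "behavior.csv")))
  expect_true(file.exists(file.path(dir, "sub-001_fc.tsv")))
  fc <- read_matrix_tsv(file.path(dir, "sub-001_fc.tsv"))
  expect_equal(unname(fc), unname(ds$fc[[1]]), tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$flexible_nodes, ds$truth_flexible)
  p <- read_parcellation(file.path(dir, "parcellation.tsv"))
  expect_equal(nrow(p), 10L)
})

test_that("simulated time series reproduce a target FC", {
  cfg <- synth_config(n_subjects = 1, n_nodes = 12, n_flexible = 3, seed = 5)
  ds <- generate_dataset(cfg)
  ts <- simulate_timeseries(ds$fc[[1]], n_timepoints = 4000, seed = 1)
  fc_hat <- pearson_fc(ts)
  expect_lt(max(abs(fc_hat - ds$fc[[1]])), 0.12)
})
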