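test_that("flexibility counts disagreeing layer pairs", {
  # constant labels -> 0; all-distinct labels -> 1
  lab0 <- matrix(2, 5, 7)
  fx0 <- compute_flexibility(lab0)
  expect_equal(fx0$overall, rep(0, 5))
  lab1 <- matrix(rep(1:7, each = 5), 5, 7)
  fx1 <- compute_flexibility(lab1)
  expect_equal(fx1$overall, rep(1, 5))

  # 3 layers (1,1,2): pairs {1,3} and {2,3} differ of 3 -> 2/3
  lab <- matrix(c(1, 1, 2), 1, 3)
  fx <- compute_flexibility(lab)
  expect_equal(fx$overall, 2 / 3)
  expect_equal(as.vector(fx$layerwise), c(1 / 2, 1 / 2, 1))
  expect_equal(fx$t, 3)
  expect_equal(fx$a, 2)

  expect_error(compute_flexibility(matrix(1, 4, 1)), "single layer")
})

test_that("overall flexibility equals the mean of layerwise exactly", {
  set.seed(31)
  for (i in 1:20) {
    L <- sample(2:8, 1)
    lab <- matrix(sample(1:4, 12 * L, replace = TRUE), 12, L)
    fx <- compute_flexibility(lab)
    expect_equal(fx$overall, rowMeans(fx$layerwise))
    expect_true(all(fx$overall >= 0 & fx$overall <= 1))
    expect_true(all(fx$layerwise >= 0 & fx$layerwise <= 1))
    # relabeling within each layer changes nothing
    lab2 <- apply(lab, 2, function(x) 5 - x)
    expect_equal(compute_flexibility(lab2)$overall, fx$overall)
  }
})

test_that("ordered mode counts consecutive changes over L - 1", {
  lab <- matrix(c(1, 1, 2, 2), 1, 4)
  fx <- compute_flexibility(lab, mode = "ordered")
  expect_equal(fx$a, 1)
  expect_equal(fx$t, 3)
  expect_equal(fx$overall, 1 / 3)
})

test_that("layer-switch proportions are consistent with flexibility counts", {
  set.seed(32)
  lab <- matrix(sample(1:3, 30 * 5, replace = TRUE), 30, 5)
  part <- structure(list(labels = lab, q = NA_real_, gamma = NA, omega = NA),
                    class = "ml_partition")
  sw <- layer_switch_analysis(part, n_perm = 100, seed = 1)
  fx <- compute_flexibility(lab)
  # sum over unordered pairs of n * proportion equals sum of change counts
  ut <- upper.tri(sw$proportions)
  expect_equal(sum(sw$proportions[ut]) * 30, sum(fx$a))
  expect_equal(diag(sw$proportions), rep(0, 5), ignore_attr = TRUE)
})

test_that("layer-switch examples count switching nodes", {
  lab_all_same <- matrix(1, 4, 3)
  sw0 <- layer_switch_analysis(
    structure(list(labels = lab_all_same, q = NA, gamma = NA, omega = NA),
              class = "ml_partition"), n_perm = 100, seed = 1)
  expect_true(all(sw0$proportions == 0))

  # 3 nodes, 2 layers, exactly one switches -> 1/3
  lab <- cbind(c(1, 1, 2), c(1, 2, 2))
  sw1 <- layer_switch_analysis(
    structure(list(labels = lab, q = NA, gamma = NA, omega = NA),
              class = "ml_partition"), n_perm = 100, seed = 1)
  expect_equal(sw1$proportions[1, 2], 1 / 3)
})

test_that("exchangeable labels give calibrated layer-switch p-values", {
  # labels drawn iid across layers are exactly exchangeable under the null
  set.seed(33)
  rates <- replicate(6, {
    parts <- lapply(1:3, function(i) {
      structure(list(labels = matrix(sample(1:3, 40 * 4, replace = TRUE),
                                     40, 4),
                     q = NA, gamma = NA, omega = NA),
                class = "ml_partition")
    })
    sw <- layer_switch_analysis(parts, n_perm = 200, seed = i <- sample.int(1e6, 1))
    mean(sw$p[upper.tri(sw$p)] < 0.05)
  })
  expect_lt(mean(rates), 0.15)
})

test_that("system flexibility tests recover the rank statistic", {
  # two groups of 3 with complete separation:
  # H = 12/(N(N+1)) * sum n_i (Rbar_i - Rbar)^2 = 3.857...
  flex <- structure(list(
    layerwise = matrix(0, 6, 2), overall = c(1, 2, 3, 10, 11, 12) / 12,
    a = rep(0, 6), t = 1, mode = "pairwise"),
    class = "flexibility_profile")
  parc <- tibble::tibble(node_id = 0:5, name = letters[1:6],
                         hemisphere = "L",
                         system = rep(c("A", "B"), each = 3),
                         subsystem = rep(c("A", "B"), each = 3))
  st <- system_flexibility_tests(flex, parc, n_perm = 200, seed = 1)
  expect_equal(unname(st$kruskal$statistic),
               12 / (6 * 7) * (3 * (2 - 3.5)^2 + 3 * (5 - 3.5)^2))
  # B has uniformly higher flexibility: directional p small for B > A
  pw <- st$pairwise
  p_ba <- pw$p[pw$system_a == "B" & pw$system_b == "A"]
  p_ab <- pw$p[pw$system_a == "A" & pw$system_b == "B"]
  expect_lt(p_ba, 0.1)
  expect_gt(p_ab, 0.9)
})

test_that("degenerate system groupings are handled", {
  flex <- structure(list(layerwise = matrix(0, 3, 2),
                         overall = c(0.1, 0.2, 0.3),
                         a = rep(0, 3), t = 1, mode = "pairwise"),
                    class = "flexibility_profile")
  parc <- tibble::tibble(node_id = 0:2, name = letters[1:3],
                         hemisphere = "L",
                         system = c("A", "A", "B"),
                         subsystem = c("A", "A", "B"))
  # B has < 2 nodes: excluded with a warning, then only one group remains
  expect_warning(expect_error(
    system_flexibility_tests(flex, parc, n_perm = 100, seed = 1),
    "fewer than 2"), "excluding")
})

test_that("pairwise system tests are calibrated under a shared null", {
  set.seed(34)
  n_sim <- 60
  hits <- 0; total <- 0
  parc <- tibble::tibble(node_id = 0:29, name = as.character(0:29),
                         hemisphere = "L",
                         system = rep(c("A", "B", "C"), each = 10),
                         subsystem = rep(c("A", "B", "C"), each = 10))
  for (i in seq_len(n_sim)) {
    flex <- structure(list(layerwise = matrix(0, 30, 2),
                           overall = runif(30),
                           a = rep(0, 30), t = 1, mode = "pairwise"),
                      class = "flexibility_profile")
    st <- system_flexibility_tests(flex, parc, n_perm = 200, seed = i)
    hits <- hits + sum(st$pairwise$p < 0.05)
    total <- total + nrow(st$pairwise)
  }
  expect_gt(hits / total, 0.01)
  expect_lt(hits / total, 0.11)
})

test_that("leave-one-layer-out flexibility is robust and well-defined", {
  # excluding a duplicated layer preserves the ranking exactly
  set.seed(35)
  base <- matrix(sample(1:3, 40 * 6, replace = TRUE), 40, 6)
  lab <- cbind(base, base[, 6]) # layer 7 duplicates layer 6
  loo <- leave_one_layer_out(lab)
  expect_equal(nrow(loo), 7L)
  fx_full <- compute_flexibility(lab)$overall
  fx_drop <- compute_flexibility(lab[, -7])$overall
  if (sd(fx_full) > 0 && !any(duplicated(fx_full))) {
    expect_equal(loo$rho[7], 1)
  }
  expect_gt(min(loo$rho), 0.7) # most layer pairs are shared

  # all-zero flexibility: correlation undefined, reported missing
  expect_warning(loo0 <- leave_one_layer_out(matrix(1, 5, 4)), "constant")
  expect_true(all(is.na(loo0$rho)))
  expect_error(leave_one_layer_out(matrix(1, 5, 2)), "3 layers")
})

test_that("system switching patterns correlate as constructed", {
  set.seed(36)
  lab <- matrix(sample(1:3, 30 * 4, replace = TRUE), 30, 4)
  parc_all <- tibble::tibble(node_id = 0:29, name = as.character(0:29),
                             hemisphere = "L", system = "All",
                             subsystem = "All")
  part <- structure(list(labels = lab, q = NA, gamma = NA, omega = NA),
                    class = "ml_partition")
  sp <- system_pattern_correlation(part, parc_all)
  # a system containing every node reproduces the global pattern exactly
  expect_equal(sp$global$r[1], 1)

  # two systems with identical switch vectors correlate at 1
  lab2 <- rbind(lab[1:15, ], lab[1:15, ])
  parc2 <- tibble::tibble(node_id = 0:29, name = as.character(0:29),
                          hemisphere = "L",
                          system = rep(c("A", "B"), each = 15),
                          subsystem = rep(c("A", "B"), each = 15))
  part2 <- structure(list(labels = lab2, q = NA, gamma = NA, omega = NA),
                     class = "ml_partition")
  sp2 <- system_pattern_correlation(part2, parc2)
  expect_equal(unname(sp2$system_matrix["A", "B"]), 1)

  # proportional vectors give r = 1 (3-layer toy)
  expect_equal(unname(cor(c(0.2, 0.4, 0.6), c(0.1, 0.2, 0.3))), 1)
})

test_that("the planted distinct layer dominates switching and flexibility", {
  fx <- planted_layers(seed = 3)
  ds <- fx$dataset
  supra <- build_supra(fx$layers, gamma = 0.45, omega = 0.01)
  parts <- run_restarts(supra, 12, seed = 7)
  sw <- layer_switch_analysis(parts, n_perm = 200, seed = 2)
  L <- ncol(sw$proportions)
  rowmean <- rowSums(sw$proportions) / (L - 1)
  # layer 1 is the planted distinct layer
  expect_equal(unname(which.max(rowmean)), 1L)
  # and its pairwise p-values are the smallest on average
  p_distinct <- mean(sw$p[1, -1])
  p_rest <- mean(sw$p[-1, -1][upper.tri(matrix(0, L - 1, L - 1))])
  expect_lte(p_distinct, p_rest)
})
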