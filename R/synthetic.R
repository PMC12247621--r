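#' Default inter-measure correlation structure
#'
#' Seven behavioral measures split into a positively inter-correlated
#' "support" block of three (friendship, emotional support, instrumental
#' support) and a "distress" block of four (hostility, rejection, loneliness,
#' stress), with the two blocks negatively correlated — the sign structure
#' typically observed among perceived social-support and social-distress
#' scales. Default magnitudes are deliberately modest: because a measure's
#' edgewise correlation pattern inherits every correlated measure's planted
#' structure, strong inter-measure correlations would make the per-layer
#' planted partitions unidentifiable from the data (see the methods
#' vignette).
#'
#' @param within_support correlation among the three support measures.
#' @param within_distress correlation among the four distress measures.
#' @param between cross-block correlation (negative).
#' @return a 7 x 7 correlation matrix with measure names as dimnames.
#' @export
default_measure_correlation <- function(within_support = 0.15,
                                        within_distress = 0.15,
                                        between = -0.075) {
  measures <- c("friendship", "emotional_support", "instrumental_support",
                "hostility", "rejection", "loneliness", "stress")
  block <- c(1, 1, 1, 2, 2, 2, 2)
  R <- matrix(between, 7, 7, dimnames = list(measures, measures))
  R[block == 1, block == 1] <- within_support
  R[block == 2, block == 2] <- within_distress
  diag(R) <- 1
  R
}

#' Synthetic study configuration
#'
#' Bundles every knob of the synthetic-data generator: sample size, node and
#' layer counts, the inter-measure correlation matrix, the planted per-layer
#' community layout, the set of ground-truth flexible nodes, and the edge
#' model parameters. Defaults emulate the study conditions the pipeline is
#' designed for: 92 subjects, 7 T-scored behavioral measures (mean 50, SD 10),
#' and a 60-node network with 3 planted communities, 12 flexible nodes and
#' one deliberately distinct layer.
#'
#' @param n_subjects number of subjects.
#' @param n_nodes number of network nodes.
#' @param n_measures number of behavioral measures (= layers).
#' @param n_communities number of planted base communities.
#' @param n_flexible number of nodes whose planted community differs across
#'   layers.
#' @param measure_correlation inter-measure correlation matrix
#'   (`n_measures` x `n_measures`, symmetric PSD, unit diagonal).
#' @param measure_mean,measure_sd T-score scale of the generated measures.
#' @param effect_size dimensionless total slope \eqn{\beta} of an edge weight
#'   on the standardized scores: an edge co-communal with a measure's planted
#'   partition in every layer has slope `effect_size` on the layer-averaged
#'   standardized score (per-layer slope `effect_size / n_measures`).
#' @param within_block_baseline,between_block_baseline baseline FC level for
#'   edges co-communal in all layers / in no layer (interpolated linearly in
#'   the co-membership fraction in between).
#' @param noise_sd SD of the Gaussian edge noise.
#' @param flexible_pattern `"distinct-layer"`: flexible nodes keep their home
#'   community in every layer except `distinct_layer`, where they all move to
#'   the next community — so that layer's correlation pattern is deliberately
#'   different from all others; `"cycle"`: flexible node labels advance by
#'   one community per layer (with `n_communities >= n_measures` every layer
#'   gets a distinct label).
#' @param distinct_layer index of the deliberately distinct layer.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_subjects = 92L,
                         n_nodes = 60L,
                         n_measures = 7L,
                         n_communities = 3L,
                         n_flexible = 12L,
                         measure_correlation = NULL,
                         measure_mean = 50,
                         measure_sd = 10,
                         effect_size = 1,
                         within_block_baseline = 0.35,
                         between_block_baseline = 0.05,
                         noise_sd = 0.1,
                         flexible_pattern = c("distinct-layer", "cycle"),
                         distinct_layer = 1L,
                         seed = 1L) {
  flexible_pattern <- match.arg(flexible_pattern)
  if (is.null(measure_correlation)) {
    measure_correlation <- if (n_measures == 7L) {
      default_measure_correlation()
    } else {
      diag(n_measures)
    }
  }
  if (n_communities > n_nodes) {
    stop("more planted communities (", n_communities,
         ") than nodes (", n_nodes, ")")
  }
  stopifnot(n_subjects >= 1, n_nodes >= 2, n_measures >= 2,
            n_communities >= 2, n_flexible >= 0,
            n_flexible < n_nodes, effect_size >= 0, noise_sd > 0)
  if (!isTRUE(all.equal(measure_correlation, t(measure_correlation))) ||
      nrow(measure_correlation) != n_measures) {
    stop("measure_correlation must be a symmetric ", n_measures, " x ",
         n_measures, " matrix")
  }
  ev <- eigen(measure_correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("measure_correlation is not positive semi-definite: ",
         "smallest eigenvalue is ", format(min(ev), digits = 4))
  }
  if (any(abs(diag(measure_correlation) - 1) > 1e-12)) {
    stop("measure_correlation must have unit diagonal")
  }
  if (is.null(rownames(measure_correlation))) {
    nm <- paste0("measure_", seq_len(n_measures))
    dimnames(measure_correlation) <- list(nm, nm)
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_nodes = as.integer(n_nodes),
         n_measures = as.integer(n_measures),
         n_communities = as.integer(n_communities),
         n_flexible = as.integer(n_flexible),
         measure_correlation = measure_correlation,
         measure_names = rownames(measure_correlation),
         measure_mean = measure_mean,
         measure_sd = measure_sd,
         effect_size = effect_size,
         within_block_baseline = within_block_baseline,
         between_block_baseline = between_block_baseline,
         noise_sd = noise_sd,
         flexible_pattern = flexible_pattern,
         distinct_layer = as.integer(distinct_layer),
         seed = as.integer(seed)),
    class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>", x$n_subjects, "subjects,", x$n_nodes, "nodes,",
      x$n_measures, "measures/layers,", x$n_communities, "communities,",
      x$n_flexible, "flexible nodes\n")
  cat("  effect_size =", x$effect_size, " noise_sd =", x$noise_sd,
      " pattern =", x$flexible_pattern, " seed =", x$seed, "\n")
  invisible(x)
}

#' Generate correlated behavioral scores
#'
#' Draws multivariate-normal scores with the configured inter-measure
#' correlation and affinely maps them to the T-score scale (population mean
#' 50, SD 10 by default). All downstream stages are Spearman-based, hence
#' invariant to this monotone choice of marginal.
#'
#' @param config a [synth_config()].
#' @return a tibble with `subject_id` and one column per measure.
#' @export
generate_behavior <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  z <- MASS::mvrnorm(config$n_subjects, mu = rep(0, config$n_measures),
                     Sigma = config$measure_correlation)
  z <- matrix(z, nrow = config$n_subjects)
  scores <- config$measure_mean + config$measure_sd * z
  colnames(scores) <- config$measure_names
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("sub-%03d", seq_len(config$n_subjects))),
    tibble::as_tibble(scores))
}

#' Generate planted per-layer partitions and flexible nodes
#'
#' Non-flexible nodes keep one "home" community in every layer. Flexible
#' nodes (spread evenly across the node range) change community according to
#' `flexible_pattern`: with `"distinct-layer"` they all move to the next
#' community in the distinct layer and stay home elsewhere, so the distinct
#' layer disagrees with every other layer on all flexible nodes while other
#' layer pairs agree everywhere; with `"cycle"` each flexible node's label
#' advances by one community per layer.
#'
#' @param config a [synth_config()].
#' @return a list with `partitions` (node x layer integer matrix of community
#'   labels) and `flexible` (integer vector of flexible node indices, 1-based).
#' @export
generate_planted_partitions <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n <- config$n_nodes
  K <- config$n_communities
  L <- config$n_measures
  home <- rep(seq_len(K), each = ceiling(n / K), length.out = n)
  flexible <- if (config$n_flexible > 0) {
    unique(round(seq(1, n, length.out = config$n_flexible)))
  } else {
    integer(0)
  }
  shift <- function(h, by) ((h - 1L + by) %% K) + 1L
  part <- matrix(rep(home, L), nrow = n, ncol = L)
  if (length(flexible)) {
    if (config$flexible_pattern == "cycle") {
      for (r in seq_len(L)) {
        part[flexible, r] <- shift(home[flexible], r - 1L)
      }
    } else {
      part[flexible, config$distinct_layer] <- shift(home[flexible], 1L)
    }
  }
  colnames(part) <- config$measure_names
  list(partitions = part, flexible = flexible)
}

#' Generate per-subject functional connectivity with planted structure
#'
#' Edge model: for subject \eqn{s},
#' \deqn{w_{ij}(s) = \mathrm{clip}\big(b_{ij} + (\beta/L)\sum_k m_{ijk}\, z_k(s)
#'   + \varepsilon_{ij}(s)\big)}
#' where \eqn{m_{ijk} = 1} if nodes i, j share a community in layer k's
#' planted partition (else 0), \eqn{z_k} is the subject's standardized score
#' on measure k, \eqn{b_{ij}} interpolates between the between- and
#' within-block baselines according to the fraction of layers in which the
#' edge is co-communal, and clipping is hard clipping to \eqn{[-1, 1]}.
#' The fraction of clipped edge values is attached as attribute `clipped`
#' and a warning names it when it exceeds 5%.
#'
#' @param config a [synth_config()].
#' @param behavior the behavior table generated from the same config.
#' @param truth planted partitions as returned by
#'   [generate_planted_partitions()]; regenerated from `config` when `NULL`.
#' @return a named list of symmetric unit-diagonal FC matrices, one per
#'   subject, with attribute `clipped` (fraction of edge values clipped).
#' @export
generate_fc <- function(config, behavior, truth = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(truth)) truth <- generate_planted_partitions(config)
  part <- truth$partitions
  n <- config$n_nodes
  L <- config$n_measures
  scores <- as.matrix(behavior[, config$measure_names, drop = FALSE])
  z <- scale(scores) # standardized per measure across subjects
  z[!is.finite(z)] <- 0 # single subject or constant measure: no effect
  n_sub <- nrow(scores)
  n_edge <- n * (n - 1L) / 2L
  idx <- edge_index(n)

  # per-layer co-membership of each edge: n_edge x L
  m <- vapply(seq_len(L), function(r) {
    lab <- part[, r]
    as.numeric(lab[idx$i] == lab[idx$j])
  }, numeric(n_edge))
  co_frac <- rowSums(m) / L
  base <- config$between_block_baseline +
    (config$within_block_baseline - config$between_block_baseline) * co_frac

  set.seed(config$seed + 1L)
  slope <- config$effect_size / L
  # subjects x edges: baseline + planted effect + noise
  effect <- z %*% t(m) * slope
  eps <- matrix(rnorm(n_sub * n_edge, sd = config$noise_sd), n_sub, n_edge)
  w <- sweep(effect + eps, 2L, base, `+`)
  clipped <- mean(w > 1 | w < -1)
  w[w > 1] <- 1
  w[w < -1] <- -1
  if (clipped > 0.05) {
    warning(sprintf("%.1f%% of edge values clipped at +/-1; reduce effect_size, baselines or noise_sd",
                    100 * clipped))
  }
  fcs <- lapply(seq_len(n_sub), function(s) devectorize_fc(w[s, ]))
  names(fcs) <- behavior$subject_id
  attr(fcs, "clipped") <- clipped
  fcs
}

#' Synthetic parcellation labels
#'
#' Assigns each node a hemisphere and a system/subsystem label. Systems
#' follow the planted home communities (`System1`, `System2`, ...), each
#' split into two subsystems (`...A`, `...B`), so system-level statistics
#' align with the planted structure.
#'
#' @param config a [synth_config()].
#' @param truth planted partitions (regenerated when `NULL`).
#' @return a tibble: `node_id` (0-based), `name`, `hemisphere`, `system`,
#'   `subsystem`.
#' @export
synth_parcellation <- function(config, truth = NULL) {
  if (is.null(truth)) truth <- generate_planted_partitions(config)
  n <- config$n_nodes
  # home community layout, independent of the flexible-node reassignments
  home <- rep(seq_len(config$n_communities),
              each = ceiling(n / config$n_communities), length.out = n)
  sys <- paste0("System", home)
  sub <- paste0(sys, rep_len(c("A", "B"), n))
  tibble::tibble(
    node_id = seq_len(n) - 1L,
    name = sprintf("node_%03d", seq_len(n) - 1L),
    hemisphere = rep_len(c("L", "R"), n),
    system = sys,
    subsystem = sub)
}

`%||%` <- function(a, b) if (length(a)) a else b

#' Canonical whole-brain parcellation scaffold
#'
#' A label table of the size used for whole-brain analyses: 400 cortical
#' parcels plus 41 subcortical parcels per hemisphere (482 nodes in total).
#' Names and system assignments are synthetic stand-ins cycling through the
#' canonical functional-system vocabulary; only the structure (node count,
#' columns, contiguous 0-based ids) mirrors the real atlas.
#'
#' @param n_cortical number of cortical parcels.
#' @param n_subcortical_per_hemisphere subcortical parcels per hemisphere.
#' @return a tibble with columns `node_id`, `name`, `hemisphere`, `system`,
#'   `subsystem`.
#' @export
parcellation_template <- function(n_cortical = 400L,
                                  n_subcortical_per_hemisphere = 41L) {
  systems <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic",
               "Cont", "Default", "TempPar")
  n_ctx <- as.integer(n_cortical)
  n_sub <- 2L * as.integer(n_subcortical_per_hemisphere)
  ctx_sys <- rep_len(systems, n_ctx)
  ctx <- tibble::tibble(
    node_id = seq_len(n_ctx) - 1L,
    name = sprintf("ctx_%s_%03d", rep_len(c("lh", "rh"), n_ctx), seq_len(n_ctx)),
    hemisphere = rep_len(c("L", "R"), n_ctx),
    system = ctx_sys,
    subsystem = paste0(ctx_sys, rep_len(c("A", "B"), n_ctx)))
  sub_sys <- rep_len(c("Thalamus", "Striatum", "Hippocampus", "Amygdala"),
                     n_sub)
  sub <- tibble::tibble(
    node_id = n_ctx + seq_len(n_sub) - 1L,
    name = sprintf("subctx_%s_%03d", rep_len(c("lh", "rh"), n_sub),
                   seq_len(n_sub)),
    hemisphere = rep_len(c("L", "R"), n_sub),
    system = "Subcortex",
    subsystem = sub_sys)
  dplyr::bind_rows(ctx, sub)
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_behavior()], [generate_planted_partitions()] and
#' [generate_fc()] under one configuration and bundles the results with the
#' synthetic parcellation and the ground truth.
#'
#' @param config a [synth_config()].
#' @return an object of class `synth_dataset`: a list with `behavior`, `fc`,
#'   `truth_partitions`, `truth_flexible`, `parcellation`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  behavior <- generate_behavior(config)
  truth <- generate_planted_partitions(config)
  fc <- generate_fc(config, behavior, truth)
  structure(
    list(behavior = behavior,
         fc = fc,
         truth_partitions = truth$partitions,
         truth_flexible = truth$flexible,
         parcellation = synth_parcellation(config, truth),
         config = config),
    class = "synth_dataset")
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat("<synth_dataset>", length(x$fc), "subjects x", x$config$n_nodes,
      "nodes,", x$config$n_measures, "layers;",
      length(x$truth_flexible), "flexible nodes; clipped fraction",
      format(attr(x$fc, "clipped"), digits = 3), "\n")
  invisible(x)
}

#' Draw node time series consistent with a target FC matrix
#'
#' Helper for exercising the connectivity module: samples Gaussian time
#' series whose population correlation equals `fc` (after projection to the
#' nearest positive-definite matrix when needed).
#'
#' @param fc target correlation matrix.
#' @param n_timepoints number of samples.
#' @param seed integer seed.
#' @return a node x time matrix.
#' @export
simulate_timeseries <- function(fc, n_timepoints = 200L, seed = 1L) {
  stopifnot(nrow(fc) == ncol(fc))
  set.seed(seed)
  ev <- eigen(fc, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-6)
  sigma <- ev$vectors %*% (vals * t(ev$vectors))
  d <- sqrt(diag(sigma))
  sigma <- sigma / tcrossprod(d)
  t(MASS::mvrnorm(n_timepoints, mu = rep(0, nrow(fc)), Sigma = sigma))
}

#' Write a synthetic dataset to disk
#'
#' Writes the behavior table (CSV), one FC matrix per subject
#' (`sub-<id>_fc.tsv`), the ground truth (JSON) and the parcellation (TSV)
#' into `dir`.
#'
#' @param dataset a `synth_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(dataset$behavior, file.path(dir, "behavior.csv"),
            row.names = FALSE)
  for (id in names(dataset$fc)) {
    utils::write.table(dataset$fc[[id]],
                       file.path(dir, paste0(id, "_fc.tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  truth <- list(
    partitions = setNames(
      lapply(seq_len(ncol(dataset$truth_partitions)),
             function(r) unname(dataset$truth_partitions[, r])),
      colnames(dataset$truth_partitions)),
    flexible_nodes = dataset$truth_flexible)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE)
  utils::write.table(dataset$parcellation, file.path(dir, "parcellation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
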