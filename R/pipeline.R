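#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), checks keys, fills defaults
#' (analysis grids, 100 restarts, 1000 edgewise / 10000 system-pairwise
#' permutations, q = 0.05, pairwise flexibility mode) and rejects unknown
#' keys (suggesting the nearest valid one), a missing seed, and contradictory
#' values.
#'
#' @param config path to a YAML file or a named list.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config) %||% list()
  }
  stopifnot(is.list(config))
  defaults <- list(
    synthetic = TRUE,
    data_dir = NULL,
    out_dir = NULL,
    seed = NULL,
    n_subjects = 92L, n_nodes = 60L, n_measures = 7L,
    n_communities = 3L, n_flexible = 12L,
    effect_size = 1, noise_sd = 0.1,
    gammas = default_gamma_grid(),
    omegas = default_omega_grid(),
    n_restarts = 100L,
    n_perm_edges = 1000L,
    n_perm_systems = 10000L,
    n_perm_layers = 1000L,
    q = 0.05,
    flex_mode = "pairwise")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    nearest <- vapply(unknown, function(k) {
      names(defaults)[which.min(utils::adist(k, names(defaults)))]
    }, character(1))
    stop("unknown config key(s): ",
         paste0(unknown, " (did you mean '", nearest, "'?)",
                collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$seed)) stop("config must set a seed")
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (!cfg$synthetic && is.null(cfg$data_dir)) {
    stop("non-synthetic runs must set data_dir")
  }
  if (!is.null(cfg$data_dir) && !dir.exists(cfg$data_dir)) {
    stop("data_dir does not exist: ", cfg$data_dir)
  }
  stopifnot(cfg$n_restarts >= 1, cfg$n_perm_edges >= 100, cfg$q > 0,
            cfg$q < 1, cfg$flex_mode %in% c("pairwise", "ordered"))
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates: simulate (or ingest) -> stack edges -> edgewise Spearman
#' correlation -> permutation test + FDR -> similarity layers -> parameter
#' grid -> flexibility -> layer-switch analyses -> report. Each stage writes
#' its outputs under `out_dir` and is skipped when they already exist
#' (delete a file to recompute from that stage on). A manifest with the
#' config snapshot and md5 checksums of every output is written last.
#'
#' @param config a [validate_config()] result (or something coercible).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    behavior = file.path(out, "behavior.csv"),
    parcellation = file.path(out, "parcellation.tsv"),
    edges = file.path(out, "edges.tsv"),
    rho = file.path(out, "edge_behavior_rho.tsv"),
    perm = file.path(out, "edge_perm_pvalues.tsv"),
    sig = file.path(out, "edge_perm_significant.tsv"),
    summary = file.path(out, "system_summary.csv"),
    partitions = file.path(out, "partitions.csv"),
    flexibility = file.path(out, "flexibility.csv"),
    landscape = file.path(out, "landscape.csv"),
    switches = file.path(out, "layer_switch.csv"),
    report = file.path(out, "report.json"),
    manifest = file.path(out, "manifest.json"))

  # stage: simulate / ingest ------------------------------------------------
  if (!file.exists(paths$behavior) || !file.exists(paths$edges)) {
    if (isTRUE(cfg$synthetic)) {
      sc <- synth_config(n_subjects = cfg$n_subjects, n_nodes = cfg$n_nodes,
                         n_measures = cfg$n_measures,
                         n_communities = cfg$n_communities,
                         n_flexible = cfg$n_flexible,
                         effect_size = cfg$effect_size,
                         noise_sd = cfg$noise_sd, seed = cfg$seed)
      ds <- generate_dataset(sc)
      behavior <- ds$behavior
      edges <- stack_edges(ds$fc)
      parcellation <- ds$parcellation
    } else {
      behavior <- tibble::as_tibble(read.csv(file.path(cfg$data_dir,
                                                       "behavior.csv")))
      parcellation <- read_parcellation(file.path(cfg$data_dir,
                                                  "parcellation.tsv"))
      fc_files <- file.path(cfg$data_dir,
                            paste0(behavior$subject_id, "_fc.tsv"))
      fcs <- lapply(fc_files, read_matrix_tsv)
      names(fcs) <- behavior$subject_id
      edges <- stack_edges(fcs)
    }
    write.csv(behavior, paths$behavior, row.names = FALSE)
    utils::write.table(edges, paths$edges, sep = "\t",
                       row.names = FALSE, col.names = FALSE)
    utils::write.table(parcellation, paths$parcellation, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    behavior <- tibble::as_tibble(read.csv(paths$behavior))
    parcellation <- read_parcellation(paths$parcellation)
    edges <- as.matrix(utils::read.table(paths$edges, sep = "\t"))
  }

  # stage: correlate + permutation test -------------------------------------
  if (!file.exists(paths$perm)) {
    perm <- edge_permutation_test(edges, behavior, n_perm = cfg$n_perm_edges,
                                  q = cfg$q, seed = cfg$seed + 11L)
    utils::write.table(perm$rho, paths$rho, sep = "\t", row.names = TRUE,
                       col.names = FALSE)
    utils::write.table(perm$p, paths$perm, sep = "\t", row.names = TRUE,
                       col.names = FALSE)
    utils::write.table(perm$significant * 1L, paths$sig, sep = "\t",
                       row.names = TRUE, col.names = FALSE)
    write.csv(system_summary(perm, parcellation), paths$summary,
              row.names = FALSE)
  } else {
    perm <- NULL
  }
  rho <- as.matrix(utils::read.table(paths$rho, sep = "\t", row.names = 1))
  class(rho) <- c("edge_behavior", class(rho))

  # stage: similarity + grid + flexibility ----------------------------------
  if (!file.exists(paths$partitions) || !file.exists(paths$flexibility)) {
    layers <- similarity_layers(rho)
    gr <- run_grid(layers, gammas = cfg$gammas, omegas = cfg$omegas,
                   n_restarts = cfg$n_restarts, seed = cfg$seed + 23L,
                   flex_mode = cfg$flex_mode)
    write.csv(grid_partitions_long(gr), paths$partitions, row.names = FALSE)
    write.csv(grid_flexibility_long(gr), paths$flexibility,
              row.names = FALSE)
    land <- partition_landscape(gr)
    vab <- variability_in_flexibility(gr)
    land$variability <- vab$variability
    write.csv(land, paths$landscape, row.names = FALSE)
  } else {
    gr <- NULL
    land <- tibble::as_tibble(read.csv(paths$landscape))
  }

  # stage: layer switching at the most stable interior point ----------------
  if (!file.exists(paths$switches)) {
    if (is.null(gr)) {
      stop("partitions stage outputs missing but landscape present; ",
           "delete ", paths$landscape, " to recompute")
    }
    best <- interior_point(gr, land)
    ls <- layer_switch_analysis(gr$runs[[best$point]]$restarts,
                                n_perm = cfg$n_perm_layers,
                                seed = cfg$seed + 31L)
    sw <- tibble::as_tibble(as.data.frame(as.table(ls$proportions)))
    names(sw) <- c("layer_a", "layer_b", "proportion")
    sw$p <- as.vector(ls$p)
    write.csv(sw, paths$switches, row.names = FALSE)
  }

  # stage: report ------------------------------------------------------------
  if (!file.exists(paths$report)) {
    report <- list(
      n_subjects = nrow(behavior),
      n_nodes = nrow(parcellation),
      n_edges = ncol(edges),
      n_measures = nrow(rho),
      n_grid_points = length(cfg$gammas) * length(cfg$omegas),
      seed = cfg$seed)
    if (!is.null(perm)) {
      report$n_significant_edges <- sum(perm$significant)
      report$p_crit <- perm$p_crit
    }
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA)
  }

  manifest <- list(
    config = unclass(cfg),
    outputs = as.list(tools::md5sum(unlist(paths[names(paths) !=
                                                   "manifest"]))),
    created = format(Sys.time(), tz = "UTC"),
    package_version = as.character(utils::packageVersion("multiflex")))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE)
  invisible(manifest)
}

# pick the interior grid point with the highest consensus reproducibility
interior_point <- function(gr, land) {
  pts <- gr$points
  gs <- sort(unique(pts$gamma))
  os <- sort(unique(pts$omega))
  interior <- rep(TRUE, nrow(pts))
  if (length(gs) > 2) interior <- interior & !pts$gamma %in% range(gs)
  if (length(os) > 2) interior <- interior & !pts$omega %in% range(os)
  cand <- which(interior)
  if (!length(cand)) cand <- seq_len(nrow(pts))
  best <- cand[which.max(land$mean_consensus_ari[cand])]
  pts[best, ]
}

#' Long-format partition table for a grid result
#'
#' @param gr a [run_grid()] result.
#' @return a tibble `gamma`, `omega`, `restart` (`"consensus"` for the
#'   consensus partition), `layer`, `node`, `community`.
#' @export
grid_partitions_long <- function(gr) {
  stopifnot(inherits(gr, "grid_result"))
  one <- function(labels, gamma, omega, restart) {
    tibble::tibble(
      gamma = gamma, omega = omega, restart = restart,
      layer = rep(colnames(labels) %||% as.character(seq_len(ncol(labels))),
                  each = nrow(labels)),
      node = rep(seq_len(nrow(labels)) - 1L, ncol(labels)),
      community = as.vector(labels))
  }
  purrr::map_dfr(seq_len(nrow(gr$points)), function(k) {
    run <- gr$runs[[k]]
    g <- gr$points$gamma[k]
    o <- gr$points$omega[k]
    dplyr::bind_rows(
      purrr::imap_dfr(run$restarts,
                      function(p, r) one(p$labels, g, o, as.character(r))),
      one(run$consensus$labels, g, o, "consensus"))
  })
}

#' Long-format consensus flexibility table for a grid result
#'
#' @param gr a [run_grid()] result.
#' @return a tibble `gamma`, `omega`, `node`, `layer`, `flexibility`,
#'   `overall`.
#' @export
grid_flexibility_long <- function(gr) {
  stopifnot(inherits(gr, "grid_result"))
  purrr::map_dfr(seq_len(nrow(gr$points)), function(k) {
    fx <- gr$runs[[k]]$flex_consensus
    lw <- fx$layerwise
    tibble::tibble(
      gamma = gr$points$gamma[k], omega = gr$points$omega[k],
      node = rep(seq_len(nrow(lw)) - 1L, ncol(lw)),
      layer = rep(colnames(lw) %||% as.character(seq_len(ncol(lw))),
                  each = nrow(lw)),
      flexibility = as.vector(lw),
      overall = rep(fx$overall, ncol(lw)))
  })
}
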