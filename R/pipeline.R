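#' Configure an end-to-end bioregionalization run
#'
#' Exactly one of `occurrences` (a path or data.frame of raw records) or
#' `world` (a [world_config()] for a synthetic run) must be supplied.
#'
#' @param occurrences raw occurrence table path or data.frame, or `NULL`.
#' @param world a [world_config()], or `NULL`.
#' @param synonyms optional [synonym_table()] (synthetic runs use the table
#'   emitted by the corruption stage automatically).
#' @param overrides optional manual reassignment table (`cell_id`,
#'   `cluster`).
#' @param grid a [grid_spec()].
#' @param min_species cell-richness filter for clustering (default 7).
#' @param linkage clustering linkage (default `"average"`).
#' @param k number of primary clusters (default 20); set to `NULL` to pick
#'   the best silhouette K from `k_range`.
#' @param k_range candidate K values scanned for diagnostics.
#' @param cut_dissimilarity secondary cut (default 0.935).
#' @param layout a [layout_params()] (its seed is overridden by the master
#'   seed substream).
#' @param min_cells independent-province threshold (default 2).
#' @param seed master seed for all stochastic stages.
#' @param out_dir optional directory; when set, all stage exports are
#'   written there.
#' @return object of class `run_config`.
#' @export
run_config <- function(occurrences = NULL, world = NULL, synonyms = NULL,
                       overrides = NULL, grid = grid_spec(),
                       min_species = 7, linkage = "average", k = 20,
                       k_range = NULL, cut_dissimilarity = 0.935,
                       layout = layout_params(), min_cells = 2, seed = 1,
                       out_dir = NULL) {
  if (is.null(occurrences) == is.null(world))
    stop("supply exactly one of `occurrences` or `world`")
  if (min_species < 1) stop("min_species must be >= 1")
  if (cut_dissimilarity < 0 || cut_dissimilarity > 1)
    stop("cut_dissimilarity must lie in [0, 1]")
  structure(list(occurrences = occurrences, world = world,
                 synonyms = synonyms, overrides = overrides, grid = grid,
                 min_species = min_species, linkage = linkage, k = k,
                 k_range = k_range, cut_dissimilarity = cut_dissimilarity,
                 layout = layout, min_cells = min_cells,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(paste0("[bioregionize] ", fmt), ...))
}

#' Run the full bioregionalization pipeline
#'
#' Executes clean -> grid -> rarefy -> primary clustering -> pooling ->
#' secondary grouping -> network consensus -> outlier reassignment ->
#' scheme delineation, and returns all stage artifacts plus a manifest with
#' per-stage record counts. Re-running with the same config (and seed) is
#' byte-identical, including layout coordinates.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage log messages (default TRUE).
#' @return object of class `bioregionalization`: list with `cleaned`,
#'   `incidence` (species/genus/filtered), `rarefaction`, `tree`,
#'   `diagnostics`, `partition`, `pools`, `grouping`, `network`, `layout`,
#'   `consensus`, `reassignment`, `scheme`, `truth` (synthetic runs only)
#'   and `manifest`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  truth <- NULL
  synonyms <- config$synonyms

  if (!is.null(config$world)) {
    cfg <- config$world
    cfg$seed <- derive_seed(seed, "world")
    log_stage(quiet, "simulating synthetic world (seed %d)", cfg$seed)
    world <- generate_world(cfg)
    truth <- world$truth
    corr <- corrupt_records(world$records, cfg$noise,
                            seed = derive_seed(seed, "noise"))
    raw <- corr$raw
    synonyms <- if (is.null(synonyms)) corr$synonyms else synonyms
    corruption_log <- corr$log
  } else {
    raw <- if (is.character(config$occurrences))
      read_occurrences(config$occurrences) else config$occurrences
    corruption_log <- NULL
  }

  log_stage(quiet, "cleaning %d raw records", nrow(raw))
  cleaned <- clean_records(raw, synonyms)
  n_kept <- sum(cleaned$records$n_dup)
  stopifnot(n_kept + nrow(cleaned$log) == nrow(raw))

  inc_sp <- build_incidence(cleaned$records, config$grid, "species")
  inc_gen <- build_incidence(cleaned$records, config$grid, "genus")
  inc <- filter_cells(inc_sp, config$min_species)
  log_stage(quiet, "%d occupied cells, %d retained (richness >= %d)",
            nrow(inc_sp), nrow(inc), config$min_species)
  if (nrow(inc) < 2)
    stop("fewer than 2 cells pass the richness filter; nothing to cluster")

  curves <- rarefaction_by_stratum(cleaned$records, "zones")

  d <- jaccard_distance(inc)
  tree <- agglomerate(d, config$linkage)
  k_range <- config$k_range %||%
    (2:min(max(config$k %||% 10, 10), nrow(inc) - 1))
  diagnostics <- select_k(tree, d, inc, k_range)
  k <- config$k %||%
    diagnostics$k[which.max(diagnostics$silhouette)]
  k <- min(k, nrow(inc))
  partition <- cut_k(tree, k)
  pools <- pool_clusters(partition, inc)
  grouping <- secondary_grouping(pools, config$linkage,
                                 config$cut_dissimilarity)
  log_stage(quiet, "K = %d primary clusters -> %d groupings", k,
            length(unique(grouping$groupings)))

  network <- build_bipartite(pools)
  lp <- config$layout
  lp$seed <- derive_seed(seed, "layout")
  coords <- layout_force(network, lp)
  consensus <- consensus_communities(network, grouping$groupings)

  adjacency <- cell_adjacency(rownames(inc), config$grid)
  reassignment <- reassign_outliers(partition, inc, adjacency,
                                    min_cells = config$min_cells,
                                    overrides = config$overrides)
  scheme <- build_scheme(grouping$groupings, reassignment$labels,
                         inc_sp, inc_gen, adjacency,
                         min_cells = config$min_cells,
                         consensus = consensus)

  manifest <- list(
    package_version = as.character(utils::packageVersion("bioregionize")),
    seed = seed,
    counts = list(raw = nrow(raw),
                  kept = n_kept,
                  rejected = nrow(cleaned$log),
                  cells_occupied = nrow(inc_sp),
                  cells_clustered = nrow(inc),
                  species = ncol(inc_sp),
                  genera = ncol(inc_gen),
                  clusters = partition$k,
                  groupings = length(unique(grouping$groupings)),
                  bioregions = length(scheme$bioregions),
                  bioprovinces = length(scheme$bioprovinces),
                  reassigned_cells = nrow(reassignment$audit)),
    parameters = list(min_species = config$min_species,
                      linkage = config$linkage, k = k,
                      cut_dissimilarity = config$cut_dissimilarity,
                      min_cells = config$min_cells))

  result <- structure(
    list(cleaned = cleaned, corruption_log = corruption_log,
         incidence = list(species = inc_sp, genus = inc_gen, filtered = inc),
         rarefaction = curves, dist = d, tree = tree,
         diagnostics = diagnostics, partition = partition, pools = pools,
         grouping = grouping, network = network, layout = coords,
         consensus = consensus, reassignment = reassignment,
         scheme = scheme, truth = truth, manifest = manifest),
    class = "bioregionalization")

  if (!is.null(config$out_dir)) export_run(result, config$out_dir)
  result
}

#' Write all pipeline exports to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
export_run <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cleaned(result$cleaned, file.path(dir, "cleaned.csv"),
                file.path(dir, "rejections.csv"))
  utils::write.csv(
    data.frame(cell_id = rownames(result$incidence$species),
               result$incidence$species, check.names = FALSE),
    file.path(dir, "incidence_species.csv"), row.names = FALSE)
  export_grid_geojson(result$incidence$species,
                      file.path(dir, "grid_richness.geojson"))
  export_rarefaction_csv(result$rarefaction,
                         file.path(dir, "rarefaction.csv"))
  export_dendrogram(result$tree, file.path(dir, "dendrogram.nwk"),
                    file.path(dir, "dendrogram_merges.csv"))
  utils::write.csv(
    data.frame(cell_id = names(result$reassignment$labels),
               cluster = unname(result$reassignment$labels)),
    file.path(dir, "partition.csv"), row.names = FALSE)
  export_network(result$network, file.path(dir, "network.graphml"),
                 file.path(dir, "network_edges.csv"))
  utils::write.csv(result$layout, file.path(dir, "layout.csv"),
                   row.names = FALSE)
  export_scheme(result$scheme, file.path(dir, "scheme.json"),
                file.path(dir, "scheme.csv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.bioregionalization <- function(x, ...) {
  m <- x$manifest
  cat("Bioregionalization run\n")
  cat(sprintf("  records: %d raw -> %d kept (%d rejected)\n",
              m$counts$raw, m$counts$kept, m$counts$rejected))
  cat(sprintf("  cells: %d occupied, %d clustered (richness >= %d)\n",
              m$counts$cells_occupied, m$counts$cells_clustered,
              m$parameters$min_species))
  cat(sprintf("  clustering: K = %d -> %d groupings (cut %.3f)\n",
              m$counts$clusters, m$counts$groupings,
              m$parameters$cut_dissimilarity))
  cat(sprintf("  scheme: %d bioregions / %d bioprovinces\n",
              m$counts$bioregions, m$counts$bioprovinces))
  print(x$scheme)
  invisible(x)
}

#' @export
summary.bioregionalization <- function(object, ...) {
  print(object)
  cat("\nK-selection diagnostics:\n")
  print(object$diagnostics, row.names = FALSE)
  invisible(object)
}
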