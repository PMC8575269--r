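#' Queen adjacency between grid cells
#'
#' Two cells are adjacent if they share an edge or a corner; columns wrap
#' across the antimeridian, rows do not wrap over the poles.
#'
#' @param cell_ids character vector of `"r<row>c<col>"` identifiers.
#' @param grid a [grid_spec()].
#' @return named list mapping each cell id to the character vector of its
#'   neighbours within `cell_ids` (symmetric, no self-edges).
#' @export
cell_adjacency <- function(cell_ids, grid = grid_spec()) {
  rc <- cell_id_to_rc(cell_ids)
  idx <- stats::setNames(seq_along(cell_ids), cell_ids)
  out <- stats::setNames(vector("list", length(cell_ids)), cell_ids)
  for (i in seq_along(cell_ids)) {
    nbr <- character(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- rc$row[i] + dr
      if (r < 1 || r > grid$n_rows) next
      cc <- ((rc$col[i] + dc - 1) %% grid$n_cols) + 1
      id <- paste0("r", r, "c", cc)
      if (!is.na(idx[id])) nbr <- c(nbr, id)
    }
    out[[i]] <- nbr
  }
  out
}

connected_components <- function(cells, adjacency) {
  comp <- stats::setNames(rep(NA_integer_, length(cells)), cells)
  cid <- 0L
  for (seed_cell in cells) {
    if (!is.na(comp[seed_cell])) next
    cid <- cid + 1L
    queue <- seed_cell
    comp[seed_cell] <- cid
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      nbr <- intersect(adjacency[[cur]], cells)
      new <- nbr[is.na(comp[nbr])]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  comp
}

#' Spatial contiguity of a cell set
#'
#' Fraction of the cells lying in the largest connected component under
#' queen adjacency; 1 means fully contiguous.
#'
#' @param cells character vector of cell ids (>= 1).
#' @param adjacency adjacency list from [cell_adjacency()] covering the
#'   cells.
#' @return score in (0, 1\].
#' @export
contiguity_score <- function(cells, adjacency) {
  if (length(cells) == 0) stop("empty cell set")
  comp <- connected_components(cells, adjacency)
  max(table(comp)) / length(cells)
}

#' Check the non-nesting criterion of a scheme
#'
#' Bioregions and bioprovinces must partition their members: no cell in two
#' bioprovinces and no bioprovince in two bioregions.
#'
#' @param scheme a [build_scheme()] result (or any list with `bioprovinces`
#'   each holding `cells`, and `bioregions` each holding `provinces`).
#' @return list with `ok` (logical) and `violations` (character vector of
#'   offending cells/provinces).
#' @export
check_nesting <- function(scheme) {
  cells <- unlist(lapply(scheme$bioprovinces, `[[`, "cells"))
  provs <- unlist(lapply(scheme$bioregions, `[[`, "provinces"))
  dup <- c(unique(cells[duplicated(cells)]), unique(provs[duplicated(provs)]))
  list(ok = length(dup) == 0, violations = dup)
}

province_centroid <- function(cells, grid = grid_spec()) {
  ctr <- cell_centroid(cells, grid)
  c(lat = mean(ctr$lat), lon = mean(ctr$lon))
}

#' Reassign spatial outlier cells between clusters
#'
#' Clusters whose cells are not fully contiguous have their
#' minority-component cells reassigned, one component at a time, to the
#' geographically nearest cluster: candidates are clusters with a cell
#' queen-adjacent to the outlier cell (all clusters, by centroid proximity,
#' if none is adjacent); among candidates the one sharing maximal Jaccard
#' similarity with the cell's species set wins, ties broken by smaller
#' great-circle centroid distance. The procedure iterates to a fixed point,
#' so a scattered cluster is progressively absorbed by its cohesive
#' neighbours — the remedy for clusters linked only by widespread or
#' disjunct (e.g. antitropical) species. Every move is logged; a manual
#' override table takes precedence.
#'
#' @param partition a `partition` over cells (from [cut_k()]).
#' @param incidence the filtered incidence matrix (for cell species sets).
#' @param adjacency adjacency list from [cell_adjacency()].
#' @param min_cells clusters smaller than this are also treated as
#'   reassignable fragments when they have an adjacent neighbour cluster
#'   (default 2).
#' @param overrides optional data.frame `cell_id`, `cluster` applied first
#'   and never re-reassigned.
#' @param max_iter safety cap on reassignment sweeps.
#' @return list with `labels` (revised named cluster vector), `audit`
#'   (data.frame of moves: cell, from, to, reason, similarity, distance_km).
#' @export
reassign_outliers <- function(partition, incidence, adjacency,
                              min_cells = 2, overrides = NULL,
                              max_iter = 25) {
  grid <- attr(incidence, "grid") %||% grid_spec()
  lab <- partition$labels[rownames(incidence)]
  audit <- data.frame(cell = character(), from = character(),
                      to = character(), reason = character(),
                      similarity = numeric(), distance_km = numeric(),
                      stringsAsFactors = FALSE)
  pinned <- character(0)
  if (!is.null(overrides) && nrow(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      cell <- overrides$cell_id[i]
      audit <- rbind(audit, data.frame(
        cell = cell, from = as.character(lab[cell]),
        to = as.character(overrides$cluster[i]), reason = "override",
        similarity = NA_real_, distance_km = NA_real_))
      lab[cell] <- overrides$cluster[i]
    }
    pinned <- overrides$cell_id
  }
  cell_species <- lapply(seq_len(nrow(incidence)),
                         function(i) which(incidence[i, ] > 0))
  names(cell_species) <- rownames(incidence)

  for (iter in seq_len(max_iter)) {
    moved <- FALSE
    for (cl in sort(unique(lab))) {
      cells <- names(lab)[lab == cl]
      comp <- connected_components(cells, adjacency)
      tab <- table(comp)
      fragmented <- length(tab) > 1
      tiny <- length(cells) < min_cells
      if (!fragmented && !tiny) next
      main_comp <- names(tab)[which.max(tab)]
      outliers <- if (fragmented) cells[comp != main_comp] else cells
      outliers <- setdiff(outliers, pinned)
      for (cell in outliers) {
        cand <- setdiff(unique(lab[intersect(adjacency[[cell]],
                                             names(lab))]), cl)
        reason <- "adjacent"
        if (length(cand) == 0) {
          if (tiny && !fragmented) next   # remote singleton: leave in place
          cand <- setdiff(unique(lab), cl)
          reason <- "nearest_centroid"
        }
        if (length(cand) == 0) next
        here <- cell_centroid(cell, grid)
        sim <- vapply(cand, function(k2) {
          pool <- unique(unlist(cell_species[names(lab)[lab == k2]]))
          length(intersect(cell_species[[cell]], pool)) /
            length(union(cell_species[[cell]], pool))
        }, numeric(1))
        dist_km <- vapply(cand, function(k2) {
          ctr <- province_centroid(names(lab)[lab == k2], grid)
          great_circle_km(here$lat, here$lon, ctr["lat"], ctr["lon"])
        }, numeric(1))
        ord <- order(-sim, dist_km)
        best <- cand[ord[1]]
        tie <- sum(sim == sim[ord[1]]) > 1
        audit <- rbind(audit, data.frame(
          cell = cell, from = as.character(cl), to = as.character(best),
          reason = if (tie) paste0(reason, "_tie") else reason,
          similarity = sim[ord[1]], distance_km = dist_km[ord[1]]))
        lab[cell] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  list(labels = lab, audit = audit)
}

#' Biodiversity indices from raw unit counts
#'
#' The index arithmetic used for every biogeographical unit: species/genus
#' ratio `S/G` rounded half-up to 2 decimals (a diversification-rate proxy)
#' and percentage endemism `100 E/S` rounded half-up to 1 decimal. Exposed
#' so published unit tables (S, G, E counts) can be recomputed directly.
#'
#' @param S species richness (>= 1).
#' @param G genus richness.
#' @param E endemic species count.
#' @return list of class `province_indices` with `S`, `G`, `E`, `ratio`,
#'   `endemism_pct`.
#' @examples
#' province_indices(117, 50, 88)   # ratio 2.34, endemism 75.2%
#' @export
province_indices <- function(S, G, E) {
  if (S < 1) stop("empty province")
  structure(list(S = S, G = G, E = E,
                 ratio = round_half_up(S / G, 2),
                 endemism_pct = round_half_up(100 * E / S, 1)),
            class = "province_indices")
}

#' Biogeographical indices of a unit
#'
#' Species richness S, genus richness G, the species/genus ratio S/G (a
#' proxy for the within-area diversification rate, rounded half-up to 2
#' decimals), the endemic species count E (species occurring in no cell
#' outside the unit, dataset-wide denominator) and percentage endemism
#' 100 E/S (half-up to 1 decimal). Genus-level (sp./spp.) records count
#' toward G only.
#'
#' @param cells character vector of the unit's cell ids.
#' @param species_incidence species-level incidence matrix covering the
#'   whole dataset.
#' @param genus_incidence genus-level incidence matrix covering the whole
#'   dataset.
#' @return list of class `province_indices` with `S`, `G`, `E`, `ratio`,
#'   `endemism_pct`.
#' @export
compute_indices <- function(cells, species_incidence, genus_incidence) {
  cells_s <- intersect(cells, rownames(species_incidence))
  if (length(cells_s) == 0) stop("empty province")
  inside <- colSums(species_incidence[cells_s, , drop = FALSE]) > 0
  S <- sum(inside)
  outside_cells <- setdiff(rownames(species_incidence), cells_s)
  outside <- colSums(species_incidence[outside_cells, , drop = FALSE]) > 0
  E <- sum(inside & !outside)
  cells_g <- intersect(cells, rownames(genus_incidence))
  G <- sum(colSums(genus_incidence[cells_g, , drop = FALSE]) > 0)
  province_indices(S, G, E)
}

#' @export
print.province_indices <- function(x, ...) {
  cat(sprintf("S = %d (G = %d) [ratio %.2f], endemics %d (%.1f%%)\n",
              x$S, x$G, x$ratio, x$E, x$endemism_pct))
  invisible(x)
}

#' Assemble the bioregion/bioprovince scheme
#'
#' Bioprovinces are the (outlier-corrected) primary clusters; bioregions are
#' the secondary groupings of those clusters. Clusters below `min_cells`
#' cells with no queen-adjacent neighbour cluster are emitted as independent
#' provinces (small remote units such as oceanic islands) rather than merged
#' into a bioregion. Emits the three-criteria report: non-nesting,
#' per-province contiguity, and (when a consensus report is supplied)
#' network support.
#'
#' @param groupings named vector cluster id -> grouping label (from
#'   [secondary_grouping()]).
#' @param labels named vector cell id -> cluster id (e.g.
#'   `reassign_outliers()$labels`).
#' @param species_incidence,genus_incidence dataset-wide incidence matrices.
#' @param adjacency adjacency list from [cell_adjacency()].
#' @param min_cells independent-province size threshold (default 2).
#' @param consensus optional [consensus_communities()] report.
#' @return object of class `bioscheme`: list with `bioregions` (label ->
#'   list(provinces, indices)), `bioprovinces` (label -> list(clusters,
#'   cells, indices, contiguity)), `independent` (province labels),
#'   `criteria` (nesting ok, min contiguity, network ARI).
#' @export
build_scheme <- function(groupings, labels, species_incidence,
                         genus_incidence, adjacency, min_cells = 2,
                         consensus = NULL) {
  if (!all(names(labels) %in% rownames(genus_incidence) |
           names(labels) %in% rownames(species_incidence)))
    stop("cells in the partition are missing from the incidence matrices")
  clusters <- sort(unique(labels))
  bioprovinces <- list()
  independent <- character(0)
  for (cl in clusters) {
    cells <- names(labels)[labels == cl]
    nbr_cells <- setdiff(unlist(adjacency[cells]), cells)
    has_neighbour <- any(nbr_cells %in% names(labels))
    is_independent <- length(cells) < min_cells && !has_neighbour
    key <- as.character(cl)
    bioprovinces[[key]] <- list(
      clusters = key, cells = cells,
      grouping = unname(groupings[key]),
      indices = compute_indices(cells, species_incidence, genus_incidence),
      contiguity = contiguity_score(cells, adjacency),
      independent = is_independent)
    if (is_independent) independent <- c(independent, key)
  }
  region_labels <- sort(unique(unname(
    groupings[setdiff(names(bioprovinces), independent)])))
  bioregions <- list()
  for (g in region_labels) {
    provs <- setdiff(names(bioprovinces)[vapply(bioprovinces, function(b)
      identical(b$grouping, g), logical(1))], independent)
    cells <- unlist(lapply(bioprovinces[provs], `[[`, "cells"))
    bioregions[[g]] <- list(
      provinces = provs,
      indices = compute_indices(cells, species_incidence, genus_incidence))
  }
  scheme <- structure(list(bioregions = bioregions,
                           bioprovinces = bioprovinces,
                           independent = independent),
                      class = "bioscheme")
  nest <- check_nesting(scheme)
  scheme$criteria <- list(
    nesting_ok = nest$ok,
    min_contiguity = min(vapply(bioprovinces, `[[`, 0, "contiguity")),
    network_ari = if (!is.null(consensus)) consensus$ari else NA_real_)
  scheme
}

#' @export
print.bioscheme <- function(x, ...) {
  cat(sprintf("<bioscheme: %d bioregions, %d bioprovinces%s>\n",
              length(x$bioregions), length(x$bioprovinces),
              if (length(x$independent))
                paste0(", ", length(x$independent), " independent")
              else ""))
  for (g in names(x$bioregions)) {
    cat(sprintf("  Bioregion %s (provinces: %s): ", g,
                paste(x$bioregions[[g]]$provinces, collapse = ", ")))
    print(x$bioregions[[g]]$indices)
  }
  if (length(x$independent))
    cat("  Independent provinces:", paste(x$independent, collapse = ", "),
        "\n")
  cat(sprintf(
    "  criteria: nesting %s, min contiguity %.2f, network ARI %s\n",
    x$criteria$nesting_ok, x$criteria$min_contiguity,
    if (is.na(x$criteria$network_ari)) "n/a" else
      sprintf("%.2f", x$criteria$network_ari)))
  invisible(x)
}

#' Export a scheme as nested JSON and a flat CSV
#'
#' The CSV mirrors the published index-table layout: one row per unit with
#' S, G, ratio, E, endemism percentage and latitude range.
#'
#' @param scheme a [build_scheme()] result.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @param grid a [grid_spec()].
#' @return invisibly, the paths written.
#' @export
export_scheme <- function(scheme, json_path = NULL, csv_path = NULL,
                          grid = grid_spec()) {
  if (!is.null(json_path)) {
    nested <- lapply(scheme$bioregions, function(r) {
      provs <- lapply(scheme$bioprovinces[r$provinces], function(p)
        list(clusters = p$clusters, cells = p$cells,
             indices = unclass(p$indices)))
      list(provinces = provs, indices = unclass(r$indices))
    })
    jsonlite::write_json(list(bioregions = nested,
                              independent = scheme$independent),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    unit_row <- function(name, kind, cells, idc) {
      b <- cell_bounds(cell_id_to_rc(cells)$row, cell_id_to_rc(cells)$col,
                       grid)
      data.frame(unit = name, kind = kind, S = idc$S, G = idc$G,
                 ratio = idc$ratio, E = idc$E,
                 endemism_pct = idc$endemism_pct,
                 lat_min = min(b$lat_min), lat_max = max(b$lat_max))
    }
    rows <- c(
      lapply(names(scheme$bioregions), function(g) {
        cells <- unlist(lapply(
          scheme$bioprovinces[scheme$bioregions[[g]]$provinces], `[[`,
          "cells"))
        unit_row(g, "bioregion", cells, scheme$bioregions[[g]]$indices)
      }),
      lapply(names(scheme$bioprovinces), function(p)
        unit_row(p, if (p %in% scheme$independent) "independent" else
          "bioprovince", scheme$bioprovinces[[p]]$cells,
          scheme$bioprovinces[[p]]$indices)))
    utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  }
  invisible(c(json_path, csv_path))
}
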