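#' Build the bipartite cluster-species network
#'
#' One node per cluster (sized by its species count) and one per distinct
#' species (sized by the number of clusters it occurs in); an edge of weight
#' 1 links a cluster to each species in its pool. Node ordering is
#' deterministic: clusters by id, then species alphabetically.
#'
#' @param pools list from [pool_clusters()].
#' @return object of class `bipartite_network`: list with `nodes`
#'   (data.frame `id`, `type` in cluster/species, `size`) and `edges`
#'   (data.frame `cluster`, `species`, `weight`).
#' @export
build_bipartite <- function(pools) {
  if (length(pools) == 0) stop("need at least one pool")
  ids <- vapply(pools, function(p) as.character(p$id), "")
  edges <- do.call(rbind, lapply(pools, function(p)
    if (length(p$species)) data.frame(cluster = as.character(p$id),
                                      species = p$species, weight = 1,
                                      stringsAsFactors = FALSE)))
  species <- sort(unique(edges$species))
  sp_deg <- as.integer(table(edges$species)[species])
  nodes <- rbind(
    data.frame(id = ids, type = "cluster",
               size = vapply(pools, `[[`, 0L, "n_species"),
               stringsAsFactors = FALSE),
    data.frame(id = species, type = "species", size = sp_deg,
               stringsAsFactors = FALSE))
  structure(list(nodes = nodes, edges = edges), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network: %d clusters, %d species, %d edges>\n",
              sum(x$nodes$type == "cluster"),
              sum(x$nodes$type == "species"), nrow(x$edges)))
  invisible(x)
}

#' Force-directed layout parameters
#'
#' Defaults follow the ForceAtlas2 settings used for occurrence-network
#' visualization: scaling 10, gravity 1, edge weight influence 1, tolerance
#' 0.1, Barnes-Hut approximation theta 1.2.
#'
#' @param scaling repulsion scaling constant (> 0).
#' @param gravity central gravity strength.
#' @param edge_weight_influence exponent applied to edge weights in the
#'   attraction term.
#' @param tolerance mean-displacement convergence tolerance (layout stops
#'   early once mean per-iteration displacement falls below it).
#' @param approximation Barnes-Hut opening angle theta (>= 0); pairwise
#'   repulsion is computed exactly for networks below `bh_min_nodes` nodes.
#' @param bh_min_nodes node count above which the Barnes-Hut grid
#'   approximation is used.
#' @param iterations maximum iterations.
#' @param seed integer seed for the initial positions.
#' @return object of class `layout_params`.
#' @export
layout_params <- function(scaling = 10, gravity = 1,
                          edge_weight_influence = 1, tolerance = 0.1,
                          approximation = 1.2, bh_min_nodes = 2000,
                          iterations = 300, seed = 1) {
  if (scaling <= 0) stop("scaling must be positive")
  if (approximation < 0) stop("approximation (theta) must be >= 0")
  structure(list(scaling = scaling, gravity = gravity,
                 edge_weight_influence = edge_weight_influence,
                 tolerance = tolerance, approximation = approximation,
                 bh_min_nodes = bh_min_nodes,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "layout_params")
}

#' Force-directed layout of a network
#'
#' ForceAtlas2-style iteration: linear attraction along edges scaled by
#' `weight^edge_weight_influence`, degree-weighted pairwise repulsion scaled
#' by `scaling`, central gravity proportional to degree + 1, and an
#' annealed adaptive step so late iterations shrink monotonically; stops
#' when the mean displacement drops below `tolerance`. Coordinates are
#' deterministic given the seed. A single node is placed at the origin (the
#' gravity fixed point). For networks with at least `bh_min_nodes` nodes,
#' repulsion is approximated on a coarse grid (Barnes-Hut style, cell size
#' governed by theta); below that it is exact.
#'
#' @param network a [build_bipartite()] result (or any list with `nodes$id`
#'   and `edges` naming node ids).
#' @param params a [layout_params()].
#' @return data.frame `id`, `x`, `y`, plus attribute `displacement` (mean
#'   displacement per iteration, for convergence diagnostics).
#' @export
layout_force <- function(network, params = layout_params()) {
  nodes <- network$nodes
  n <- nrow(nodes)
  if (n == 0) stop("empty network")
  if (n == 1)
    return(structure(data.frame(id = nodes$id, x = 0, y = 0),
                     displacement = numeric(0)))
  e_from <- match(network$edges$cluster %||% network$edges$from, nodes$id)
  e_to <- match(network$edges$species %||% network$edges$to, nodes$id)
  w <- (network$edges$weight)^params$edge_weight_influence
  deg <- tabulate(c(e_from, e_to), nbins = n)
  mass <- deg + 1

  pos <- with_stage_seed(params$seed, "layout-init",
                         matrix(stats::runif(2 * n, -1, 1) * sqrt(n), n, 2))
  disp_trace <- numeric(0)
  speed <- 1
  for (it in seq_len(params$iterations)) {
    # repulsion: k_r * mass_i * mass_j / d  (exact pairwise below the
    # Barnes-Hut threshold; grid-aggregated above it)
    if (n < params$bh_min_nodes) {
      dx <- outer(pos[, 1], pos[, 1], "-")
      dy <- outer(pos[, 2], pos[, 2], "-")
      d2 <- dx^2 + dy^2
      d2[d2 < 1e-8] <- 1e-8
      f <- params$scaling * outer(mass, mass) / d2
      diag(f) <- 0
      fx <- rowSums(f * dx)
      fy <- rowSums(f * dy)
    } else {
      cell <- max(params$approximation, 0.1) * sqrt(n) / 4
      gx <- round(pos[, 1] / cell)
      gy <- round(pos[, 2] / cell)
      key <- paste(gx, gy)
      agg_m <- tapply(mass, key, sum)
      agg_x <- tapply(pos[, 1] * mass, key, sum) / agg_m
      agg_y <- tapply(pos[, 2] * mass, key, sum) / agg_m
      dx <- outer(pos[, 1], agg_x, "-")
      dy <- outer(pos[, 2], agg_y, "-")
      d2 <- dx^2 + dy^2
      d2[d2 < 1e-8] <- 1e-8
      f <- params$scaling * outer(mass, as.numeric(agg_m)) / d2
      fx <- rowSums(f * dx)
      fy <- rowSums(f * dy)
    }
    # gravity toward origin
    fx <- fx - params$gravity * mass * pos[, 1]
    fy <- fy - params$gravity * mass * pos[, 2]
    # linear attraction along edges
    ax <- (pos[e_to, 1] - pos[e_from, 1]) * w
    ay <- (pos[e_to, 2] - pos[e_from, 2]) * w
    fx <- fx + tabulate_add(e_from, ax, n) - tabulate_add(e_to, ax, n)
    fy <- fy + tabulate_add(e_from, ay, n) - tabulate_add(e_to, ay, n)
    # annealed step: speed decays so displacement shrinks monotonically in
    # the convergence tail
    speed <- 1 / (1 + it * 0.05)
    step_x <- speed * fx / mass
    step_y <- speed * fy / mass
    lim <- 2 * sqrt(n)
    norm <- sqrt(step_x^2 + step_y^2)
    too_big <- norm > lim
    step_x[too_big] <- step_x[too_big] * lim / norm[too_big]
    step_y[too_big] <- step_y[too_big] * lim / norm[too_big]
    pos[, 1] <- pos[, 1] + step_x
    pos[, 2] <- pos[, 2] + step_y
    disp <- mean(sqrt(step_x^2 + step_y^2))
    disp_trace <- c(disp_trace, disp)
    if (disp < params$tolerance) break
  }
  structure(data.frame(id = nodes$id, x = pos[, 1], y = pos[, 2],
                       stringsAsFactors = FALSE),
            displacement = disp_trace)
}

tabulate_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- tapply(val, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Community-consensus check of cluster groupings
#'
#' Projects the bipartite network onto its cluster nodes (edge weight =
#' Jaccard similarity of shared species), detects communities by greedy
#' modularity maximization ([igraph::cluster_fast_greedy()]), and reports
#' the adjusted Rand index between those communities and a reference
#' grouping — a quantitative stand-in for the visual check that cluster and
#' network analyses reveal the same structure. Clusters whose strongest
#' projected edge leads to a different reference grouping than their own are
#' flagged equivocal.
#'
#' @param network a [build_bipartite()] result with >= 2 cluster nodes.
#' @param reference_grouping named vector (cluster id -> grouping label),
#'   e.g. `secondary_grouping()$groupings`.
#' @return object of class `consensus_report`: list with `graph` (projected
#'   igraph), `communities` (named membership vector), `ari`, `modularity`,
#'   `equivocal` (character vector of flagged cluster ids).
#' @export
consensus_communities <- function(network, reference_grouping) {
  cl_ids <- network$nodes$id[network$nodes$type == "cluster"]
  if (length(cl_ids) < 2)
    return(structure(list(graph = NULL, communities = NULL, ari = NA_real_,
                          modularity = NA_real_, equivocal = character(0),
                          flag = "single cluster node; ARI undefined"),
                     class = "consensus_report"))
  sp_sets <- split(network$edges$species, network$edges$cluster)[cl_ids]
  k <- length(cl_ids)
  wmat <- matrix(0, k, k, dimnames = list(cl_ids, cl_ids))
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    inter <- length(intersect(sp_sets[[i]], sp_sets[[j]]))
    uni <- length(union(sp_sets[[i]], sp_sets[[j]]))
    wmat[i, j] <- wmat[j, i] <- if (uni > 0) inter / uni else 0
  }
  g <- igraph::graph_from_adjacency_matrix(wmat, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight)
  membership <- igraph::membership(comm)
  ref <- reference_grouping[cl_ids]
  a <- ari(as.integer(membership), as.character(ref))
  equivocal <- character(0)
  for (i in seq_len(k)) {
    if (all(wmat[i, -i] == 0)) next
    best <- cl_ids[-i][which.max(wmat[i, -i])]
    if (!identical(unname(ref[best]), unname(ref[i])))
      equivocal <- c(equivocal, cl_ids[i])
  }
  structure(list(graph = g, communities = membership, ari = a,
                 modularity = igraph::modularity(comm),
                 equivocal = equivocal, flag = NULL),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat("<consensus_report:", x$flag, ">\n")
  } else {
    cat(sprintf(
      "<consensus_report: %d communities, modularity %.3f, ARI %.3f%s>\n",
      length(unique(x$communities)), x$modularity, x$ari,
      if (length(x$equivocal))
        paste0("; equivocal: ", paste(x$equivocal, collapse = ", "))
      else ""))
  }
  invisible(x)
}

#' Export a bipartite network
#'
#' @param network a [build_bipartite()] result.
#' @param graphml_path,edges_csv_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
export_network <- function(network, graphml_path = NULL,
                           edges_csv_path = NULL) {
  if (!is.null(graphml_path)) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("cluster", "species", "weight")],
      directed = FALSE, vertices = network$nodes)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(edges_csv_path))
    utils::write.csv(network$edges, edges_csv_path, row.names = FALSE)
  invisible(c(graphml_path, edges_csv_path))
}
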