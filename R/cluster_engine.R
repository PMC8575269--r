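#' Pairwise Jaccard dissimilarity between incidence rows
#'
#' `d(A, B) = 1 - |A intersect B| / |A union B|` on the taxon sets of each
#' pair of rows.
#'
#' @param incidence binary matrix (rows = sites/cells, columns = taxa) with
#'   at least 2 rows and no empty rows.
#' @return symmetric dissimilarity matrix with zero diagonal, entries in
#'   \[0, 1\], dimnames from the row names.
#' @export
jaccard_distance <- function(incidence) {
  m <- (incidence > 0) * 1L
  if (nrow(m) < 2) stop("need at least 2 rows")
  if (any(rowSums(m) == 0))
    stop("empty rows (richness 0) are not allowed; filter cells first")
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

lw_update <- function(linkage, d_ik, d_jk, d_ij, n_i, n_j, n_k) {
  switch(linkage,
    average  = (n_i * d_ik + n_j * d_jk) / (n_i + n_j),
    complete = pmax(d_ik, d_jk),
    single   = pmin(d_ik, d_jk),
    ward     = sqrt(((n_i + n_k) * d_ik^2 + (n_j + n_k) * d_jk^2 -
                       n_k * d_ij^2) / (n_i + n_j + n_k)))
}

#' Agglomerative hierarchical clustering with deterministic tie-breaking
#'
#' Standard Lance-Williams agglomeration of a dissimilarity matrix. Ties in
#' the minimal merge distance are broken by the lexicographically smallest
#' pair of cluster indices (a cluster is indexed by the smallest original
#' leaf it contains), so results are identical across platforms. `"ward"`
#' follows the Ward.D2 convention (squared-dissimilarity update, heights on
#' the original scale).
#'
#' @param dist symmetric dissimilarity matrix (zero diagonal).
#' @param linkage `"average"` (UPGMA, default), `"complete"`, `"single"` or
#'   `"ward"`.
#' @return object of class `agglom`: list with `merge` (hclust-style
#'   (n-1) x 2 matrix, negative entries = leaves), `height`, `labels`,
#'   `order` (leaf ordering), `linkage`.
#' @export
agglomerate <- function(dist, linkage = c("average", "complete", "single",
                                          "ward")) {
  linkage <- match.arg(linkage)
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-12)))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(dist)
  if (n < 2) stop("need at least 2 items")
  labels <- rownames(dist) %||% as.character(seq_len(n))
  d <- as.matrix(dist)
  active <- seq_len(n)             # columns of d still in play
  leader <- seq_len(n)             # smallest original leaf per active cluster
  node <- -seq_len(n)              # hclust-style node id per active cluster
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(active)
    dd <- d[active, active, drop = FALSE]
    dd[!upper.tri(dd)] <- Inf
    h <- min(dd)
    cand <- which(dd == h, arr.ind = TRUE)
    # order candidate pairs by (leader_i, leader_j), both ascending
    li <- pmin(leader[cand[, 1]], leader[cand[, 2]])
    lj <- pmax(leader[cand[, 1]], leader[cand[, 2]])
    pick <- order(li, lj)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (leader[i] > leader[j]) { tmp <- i; i <- j; j <- tmp }
    ai <- active[i]; aj <- active[j]
    merge[step, ] <- c(node[i], node[j])
    height[step] <- h
    others <- setdiff(seq_len(k), c(i, j))
    if (length(others)) {
      ao <- active[others]
      d[ai, ao] <- d[ao, ai] <- lw_update(linkage, d[ai, ao], d[aj, ao],
                                          d[ai, aj], size[i], size[j],
                                          size[others])
    }
    size[i] <- size[i] + size[j]
    node[i] <- step
    leader[i] <- min(leader[i], leader[j])
    active <- active[-j]; leader <- leader[-j]; node <- node[-j]
    size <- size[-j]
  }
  order <- dendro_order(merge, n)
  structure(list(merge = merge, height = height, labels = labels,
                 order = order, linkage = linkage),
            class = "agglom")
}

# leaf order by left-to-right traversal of the merge tree
dendro_order <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1L)
}

#' @export
print.agglom <- function(x, ...) {
  cat(sprintf("<agglom: %d leaves, %s linkage, merge heights %.3g..%.3g>\n",
              length(x$labels), x$linkage, min(x$height), max(x$height)))
  invisible(x)
}

#' Convert to a stats::hclust object
#'
#' @param x an [agglomerate()] result.
#' @param ... unused.
#' @return an `hclust` object (usable with [stats::cutree()], plotting,
#'   [ape::as.phylo()]).
#' @export
as.hclust.agglom <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels,
                 method = x$linkage, call = match.call(),
                 dist.method = "user"),
            class = "hclust")
}

#' Cut a dendrogram into K clusters
#'
#' Removes the `K - 1` highest merges; cluster labels `1..K` are assigned by
#' order of first appearance along the dendrogram leaf ordering.
#'
#' @param tree an [agglomerate()] result.
#' @param k number of clusters, `1 <= k <= n`.
#' @return object of class `partition`: list with `labels` (named integer
#'   vector item -> cluster), `k`.
#' @export
cut_k <- function(tree, k) {
  n <- length(tree$labels)
  if (k < 1 || k > n) stop("k must lie in [1, n]")
  membership_from_merges(tree, n_merges = n - k)
}

#' Cut a dendrogram at a dissimilarity height
#'
#' Clusters are the connected components after removing all merges at height
#' strictly greater than the threshold (a merge exactly at the cut is kept).
#'
#' @param tree an [agglomerate()] result.
#' @param dissimilarity cut height in \[0, 1\] (or any height scale).
#' @return a `partition` (see [cut_k()]).
#' @export
cut_height <- function(tree, dissimilarity) {
  membership_from_merges(tree, n_merges = sum(tree$height <= dissimilarity))
}

membership_from_merges <- function(tree, n_merges) {
  n <- length(tree$labels)
  comp <- seq_len(n)
  node_comp <- integer(nrow(tree$merge))
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  for (s in seq_len(n_merges)) {
    a <- tree$merge[s, 1]; b <- tree$merge[s, 2]
    ra <- find(if (a < 0) -a else node_comp[a])
    rb <- find(if (b < 0) -b else node_comp[b])
    comp[rb] <- ra
    node_comp[s] <- ra
  }
  if (n_merges < nrow(tree$merge)) {
    for (s in seq(n_merges + 1, nrow(tree$merge))) {
      a <- tree$merge[s, 1]
      node_comp[s] <- find(if (a < 0) -a else node_comp[a])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # relabel by first appearance in dendrogram leaf order
  first_seen <- unique(roots[tree$order])
  labels <- match(roots, first_seen)
  names(labels) <- tree$labels
  structure(list(labels = labels, k = length(first_seen)),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition: %d items in %d clusters>\n",
              length(x$labels), x$k))
  invisible(x)
}

#' Total within-cluster sum of squares
#'
#' Centroids are the per-cluster mean incidence vectors; WSS is the sum of
#' squared Euclidean distances of rows to their cluster centroid, the
#' quantity scanned over K by the elbow method.
#'
#' @param partition a `partition` over the rows of `incidence`.
#' @param incidence numeric matrix whose rows are the clustered items.
#' @return scalar WSS (>= 0).
#' @export
wss <- function(partition, incidence) {
  lab <- if (!is.null(rownames(incidence)))
    partition$labels[rownames(incidence)] else partition$labels
  total <- 0
  for (cl in unique(lab)) {
    rows <- incidence[lab == cl, , drop = FALSE]
    ctr <- colMeans(rows)
    total <- total + sum(sweep(rows, 2, ctr)^2)
  }
  total
}

#' Average silhouette width
#'
#' Per item, `s(i) = (b - a) / max(a, b)` where `a` is the mean
#' dissimilarity to the item's own cluster (excluding itself) and `b` the
#' smallest mean dissimilarity to any other cluster; members of singleton
#' clusters contribute 0.
#'
#' @param partition a `partition` with `k >= 2`.
#' @param dist symmetric dissimilarity matrix over the same items.
#' @return average silhouette width in \[-1, 1\].
#' @export
silhouette_width <- function(partition, dist) {
  if (partition$k < 2) stop("silhouette requires at least 2 clusters")
  lab <- if (!is.null(rownames(dist)) &&
             all(rownames(dist) %in% names(partition$labels)))
    partition$labels[rownames(dist)] else partition$labels
  n <- nrow(dist)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(lab == lab[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(dist[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
      mean(dist[i, lab == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Diagnostics table for choosing the number of clusters
#'
#' For each K in `k_range`, cuts the tree, computes WSS and the average
#' silhouette width, and flags the elbow (the K maximizing the second
#' difference of WSS) and local silhouette maxima. The choice of K is left
#' to the caller.
#'
#' @param tree an [agglomerate()] result.
#' @param dist the dissimilarity matrix the tree was built from.
#' @param incidence the incidence matrix (for WSS).
#' @param k_range integer vector of candidate K (subset of `2..n-1`).
#' @return data.frame with columns `k`, `wss`, `silhouette`, `elbow`,
#'   `silhouette_local_max`.
#' @export
select_k <- function(tree, dist, incidence, k_range = 2:10) {
  n <- length(tree$labels)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1))
    stop("k_range must lie within [2, n-1]")
  rows <- lapply(k_range, function(k) {
    p <- cut_k(tree, k)
    data.frame(k = k, wss = wss(p, incidence),
               silhouette = silhouette_width(p, dist))
  })
  tab <- do.call(rbind, rows)
  m <- nrow(tab)
  d2 <- rep(NA_real_, m)
  if (m >= 3)
    d2[2:(m - 1)] <- diff(tab$wss, differences = 2)
  tab$elbow <- !is.na(d2) & d2 == max(d2, na.rm = TRUE)
  sil <- tab$silhouette
  loc <- rep(FALSE, m)
  for (i in seq_len(m)) {
    left <- if (i > 1) sil[i] >= sil[i - 1] else TRUE
    right <- if (i < m) sil[i] >= sil[i + 1] else TRUE
    loc[i] <- left && right
  }
  tab$silhouette_local_max <- loc
  tab
}

#' Pool member cells and species unions per cluster
#'
#' @param partition a `partition` over the rows of `incidence`.
#' @param incidence binary incidence matrix.
#' @return list of `cluster_pool` objects ordered by cluster label, each
#'   with `id`, `cells`, `species` (union over member cells) and
#'   `n_species`.
#' @export
pool_clusters <- function(partition, incidence) {
  lab <- partition$labels[rownames(incidence)]
  lapply(sort(unique(lab)), function(cl) {
    cells <- rownames(incidence)[lab == cl]
    sp <- colnames(incidence)[colSums(incidence[lab == cl, , drop = FALSE]) > 0]
    structure(list(id = cl, cells = cells, species = sp,
                   n_species = length(sp)),
              class = "cluster_pool")
  })
}

#' Secondary grouping of cluster pools
#'
#' Computes Jaccard dissimilarities between the pooled species sets of the
#' primary clusters, agglomerates them, and cuts at a fixed dissimilarity —
#' the second stage of the two-stage scheme that condenses many clusters
#' into a few groupings. Groupings are labelled `A`, `B`, `C`, ... in
#' dendrogram leaf order.
#'
#' @param pools list from [pool_clusters()] (>= 2 pools).
#' @param linkage linkage for the secondary tree (default `"average"`).
#' @param cut_dissimilarity dissimilarity cut (default 0.935, i.e. a Jaccard
#'   similarity cut-off of 0.065).
#' @return list with `groupings` (named character vector cluster id ->
#'   grouping letter), `tree` (the secondary `agglom`), `dist` (pool
#'   dissimilarities).
#' @export
secondary_grouping <- function(pools, linkage = "average",
                               cut_dissimilarity = 0.935) {
  if (length(pools) < 2) stop("need at least 2 pools")
  ids <- vapply(pools, function(p) as.character(p$id), "")
  all_sp <- sort(unique(unlist(lapply(pools, `[[`, "species"))))
  m <- matrix(0L, length(pools), length(all_sp),
              dimnames = list(ids, all_sp))
  for (i in seq_along(pools)) m[i, pools[[i]]$species] <- 1L
  d <- jaccard_distance(m)
  tree <- agglomerate(d, linkage)
  part <- cut_height(tree, cut_dissimilarity)
  letters_ext <- c(LETTERS, paste0("A", LETTERS))
  groupings <- letters_ext[part$labels]
  names(groupings) <- names(part$labels)
  list(groupings = groupings, tree = tree, dist = d)
}

#' Export a dendrogram
#'
#' Writes the merge table as CSV and/or the tree in Newick format with merge
#' heights converted to branch lengths (via [ape::write.tree()]).
#'
#' @param tree an [agglomerate()] result.
#' @param newick_path,merge_csv_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
export_dendrogram <- function(tree, newick_path = NULL,
                              merge_csv_path = NULL) {
  if (!is.null(newick_path)) {
    phy <- ape::as.phylo(stats::as.hclust(tree))
    ape::write.tree(phy, file = newick_path)
  }
  if (!is.null(merge_csv_path)) {
    utils::write.csv(data.frame(left = tree$merge[, 1],
                                right = tree$merge[, 2],
                                height = tree$height),
                     merge_csv_path, row.names = FALSE)
  }
  invisible(c(newick_path, merge_csv_path))
}
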