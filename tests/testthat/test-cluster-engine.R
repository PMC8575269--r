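test_that("Jaccard dissimilarities are exact on row species sets", {
  inc <- incidence_from_sets(list(p = c("a", "b", "c"),
                                  q = c("b", "c", "d"),
                                  r = c("x", "y")))
  d <- jaccard_distance(inc)
  expect_equal(d["p", "q"], 0.5)              # |int| 2 / |union| 4
  expect_equal(d["p", "r"], 1)                # disjoint
  expect_equal(diag(d), c(p = 0, q = 0, r = 0))
  same <- incidence_from_sets(list(u = c("a", "b"), v = c("a", "b")))
  expect_equal(jaccard_distance(same)["u", "v"], 0)
  expect_error(jaccard_distance(inc[1, , drop = FALSE]), "2 rows")
  empty_row <- rbind(inc, z = 0)
  expect_error(jaccard_distance(empty_row), "empty rows")
})

test_that("Jaccard distances agree with vegan's binary implementation", {
  skip_if_not_installed("vegan")
  set.seed(41)
  m <- matrix(rbinom(20 * 12, 1, 0.4), 20, 12)
  m[rowSums(m) == 0, 1] <- 1
  expect_equal(unname(jaccard_distance(m)),
               unname(as.matrix(vegan::vegdist(m, "jaccard", binary = TRUE))),
               tolerance = 1e-12)
})

test_that("small agglomerations follow the Lance-Williams updates", {
  d2 <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  t2 <- agglomerate(d2)
  expect_equal(t2$height, 0.3)
  d3 <- matrix(c(0, 0.1, 0.9,
                 0.1, 0, 0.9,
                 0.9, 0.9, 0), 3, 3)
  t3 <- agglomerate(d3, "average")
  expect_equal(t3$height, c(0.1, 0.9))
  expect_equal(t3$merge[1, ], c(-1L, -2L))
  expect_error(agglomerate(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("agglomeration matches the brute-force rescanning oracle", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(3:6, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2)
    d <- d + t(d)
    for (link in c("average", "complete", "single")) {
      expect_equal(agglomerate(d, link)$height, bf_agglomerate(d, link),
                   tolerance = 1e-12)
    }
    X <- matrix(rnorm(n * 2), n, 2)
    expect_equal(agglomerate(as.matrix(dist(X)), "ward")$height,
                 bf_ward_heights(X), tolerance = 1e-9)
  }
})

test_that("heights agree with hclust on tie-free instances", {
  set.seed(43)
  d <- matrix(0, 12, 12)
  d[upper.tri(d)] <- runif(66)
  d <- d + t(d)
  for (pair in list(c("average", "average"), c("complete", "complete"),
                    c("single", "single"), c("ward", "ward.D2"))) {
    expect_equal(sort(agglomerate(d, pair[1])$height),
                 sort(hclust(as.dist(d), pair[2])$height),
                 tolerance = 1e-12)
  }
})

test_that("average-linkage dendrograms are monotone", {
  set.seed(44)
  for (rep in 1:10) {
    d <- matrix(0, 10, 10)
    d[upper.tri(d)] <- runif(45)
    d <- d + t(d)
    expect_true(all(diff(agglomerate(d, "average")$height) > -1e-12))
  }
})

test_that("ties are broken by the smallest leaf-index pair", {
  # all distances equal: merges must proceed (1,2), then (1,3), (1,4)
  d <- matrix(0.5, 4, 4); diag(d) <- 0
  tr <- agglomerate(d, "single")
  expect_equal(tr$merge[1, ], c(-1L, -2L))
  expect_equal(tr$merge[2, ], c(1L, -3L))
  expect_equal(tr$merge[3, ], c(2L, -4L))
})

test_that("cutting into K clusters matches cutree up to relabeling", {
  set.seed(45)
  d <- matrix(0, 15, 15)
  d[upper.tri(d)] <- runif(105)
  d <- d + t(d)
  tr <- agglomerate(d, "average")
  h <- stats::as.hclust(tr)
  for (k in c(1, 4, 8, 15)) {
    own <- cut_k(tr, k)
    expect_equal(own$k, k)
    expect_equal(ari(own$labels, cutree(h, k)), 1)
    expect_equal(sort(unique(own$labels)), seq_len(k))  # labels 1..K
  }
  expect_error(cut_k(tr, 0), "k must lie")
  expect_error(cut_k(tr, 16), "k must lie")
})

test_that("a planted block structure is recovered exactly at K = 3", {
  blocks <- rep(1:3, each = 4)
  d <- matrix(0.9, 12, 12)
  d[outer(blocks, blocks, "==")] <- 0.05
  diag(d) <- 0
  part <- cut_k(agglomerate(d), 3)
  expect_equal(ari(part$labels, blocks), 1)
})

test_that("height cuts keep merges at or below the threshold", {
  d3 <- matrix(c(0, 0.9, 0.95,
                 0.9, 0, 0.95,
                 0.95, 0.95, 0), 3, 3)
  tr <- agglomerate(d3, "average")
  expect_equal(cut_height(tr, 0.935)$k, 2)    # pools linked at 0.9 join
  expect_equal(cut_height(tr, 1)$k, 1)
  expect_equal(cut_height(tr, 0)$k, 3)
  # cut exactly at the max merge height keeps one cluster; below the min
  # merge height, all singletons
  expect_equal(cut_height(tr, max(tr$height))$k, 1)
  expect_equal(cut_height(tr, min(tr$height) - 1e-9)$k, 3)
})

test_that("within-cluster sum of squares matches direct arithmetic", {
  inc <- rbind(a = c(1, 0, 0), b = c(1, 0, 0),
               c = c(0, 1, 1), d = c(0, 1, 0))
  p2 <- structure(list(labels = c(a = 1, b = 1, c = 2, d = 2), k = 2),
                  class = "partition")
  # pair (a,b) identical -> 0; pair (c,d) centroid (0,1,.5) -> 2 * .25 = .5
  expect_equal(wss(p2, inc), 0.5)
  p4 <- structure(list(labels = c(a = 1, b = 2, c = 3, d = 4), k = 4),
                  class = "partition")
  expect_equal(wss(p4, inc), 0)
  same <- rbind(x = c(1, 1), y = c(1, 1), z = c(1, 1))
  p1 <- structure(list(labels = c(x = 1, y = 1, z = 1), k = 1),
                  class = "partition")
  expect_equal(wss(p1, same), 0)
})

test_that("silhouette widths follow the per-point formula", {
  d <- matrix(0.9, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  diag(d) <- 0
  p <- structure(list(labels = c(1, 1, 2, 2), k = 2), class = "partition")
  expect_equal(silhouette_width(p, d), 8 / 9)
  # all points equidistant: a = b, silhouette 0
  deq <- matrix(0.5, 4, 4); diag(deq) <- 0
  expect_equal(silhouette_width(p, deq), 0)
  expect_error(silhouette_width(structure(list(labels = rep(1, 4), k = 1),
                                          class = "partition"), d),
               "at least 2")
})

test_that("silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(46)
  d <- matrix(0, 10, 10)
  d[upper.tri(d)] <- runif(45)
  d <- d + t(d)
  lab <- sample(1:3, 10, replace = TRUE)
  lab[1:3] <- 1:3   # ensure all clusters non-empty
  p <- structure(list(labels = lab, k = 3), class = "partition")
  ref <- mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  expect_equal(silhouette_width(p, d), ref, tolerance = 1e-12)
})

test_that("K-selection diagnostics flag the planted K", {
  set.seed(47)
  blocks <- rep(1:3, each = 5)
  inc <- matrix(0L, 15, 30)
  for (i in 1:15)
    inc[i, ((blocks[i] - 1) * 10 + 1):(blocks[i] * 10)] <-
      rbinom(10, 1, 0.9)
  inc[rowSums(inc) == 0, 1] <- 1L
  rownames(inc) <- paste0("c", 1:15)
  d <- jaccard_distance(inc)
  tr <- agglomerate(d)
  tab <- select_k(tr, d, inc, 2:6)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$k[which.max(tab$silhouette)], 3)
  expect_true(all(diff(tab$wss) < 1e-9))      # WSS nonincreasing in K
  expect_true(tab$silhouette_local_max[tab$k == 3])
  expect_error(select_k(tr, d, inc, 1:3), "k_range")
})

test_that("cluster pools union member-cell species", {
  inc <- incidence_from_sets(list(c1 = c("a", "b"), c2 = c("b", "c"),
                                  c3 = "z"))
  p <- structure(list(labels = c(c1 = 1, c2 = 1, c3 = 2), k = 2),
                 class = "partition")
  pools <- pool_clusters(p, inc)
  expect_equal(pools[[1]]$species, c("a", "b", "c"))
  expect_equal(pools[[1]]$n_species, 3)
  expect_equal(pools[[2]]$cells, "c3")
  expect_equal(pools[[2]]$species, "z")
})

test_that("secondary grouping cuts pool dissimilarities at 0.935", {
  mk <- function(id, sp) structure(list(id = id, cells = character(0),
                                        species = sp,
                                        n_species = length(sp)),
                                   class = "cluster_pool")
  disjoint <- list(mk(1, c("a", "b")), mk(2, c("c", "d")), mk(3, "e"))
  g1 <- secondary_grouping(disjoint)
  expect_equal(length(unique(g1$groupings)), 3)
  # 50% shared species: d = 2/3 < 0.935 -> grouped together
  half <- list(mk(1, c("a", "b", "c", "d")), mk(2, c("c", "d", "e", "f")))
  g2 <- secondary_grouping(half)
  expect_equal(length(unique(g2$groupings)), 1)
  expect_error(secondary_grouping(half[1]), "at least 2")
})

test_that("dendrograms export to Newick and a merge table", {
  d <- matrix(c(0, 0.2, 0.8, 0.2, 0, 0.8, 0.8, 0.8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- agglomerate(d)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_dendrogram(tr, nwk, csv)
  phy <- ape::read.tree(nwk)
  expect_setequal(phy$tip.label, c("x", "y", "z"))
  tab <- read.csv(csv)
  expect_equal(tab$height, tr$height)
})
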