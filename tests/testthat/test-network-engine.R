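mk_pool <- function(id, sp) structure(list(id = id, cells = character(0),
                                           species = sp,
                                           n_species = length(sp)),
                                      class = "cluster_pool")

test_that("bipartite construction gives the stated degrees and counts", {
  pools <- list(mk_pool(1, c("a", "b", "s")), mk_pool(2, c("c", "s")))
  net <- build_bipartite(pools)
  sp_nodes <- net$nodes[net$nodes$type == "species", ]
  expect_equal(sp_nodes$size[sp_nodes$id == "s"], 2L)   # shared species
  expect_equal(sp_nodes$size[sp_nodes$id == "a"], 1L)
  expect_equal(nrow(net$edges), 3 + 2)
  # degree-sum identity: cluster sizes = species degrees = edge count
  cl_nodes <- net$nodes[net$nodes$type == "cluster", ]
  expect_equal(sum(cl_nodes$size), nrow(net$edges))
  expect_equal(sum(sp_nodes$size), nrow(net$edges))
})

test_that("endemic species have degree 1 under perfect pooling", {
  w <- generate_world(small_world_config(seed = 51))
  inc <- filter_cells(build_incidence(w$records), 7)
  truth_lab <- w$truth$cells$province[match(rownames(inc),
                                            w$truth$cells$cell_id)]
  p <- structure(list(labels = stats::setNames(truth_lab, rownames(inc)),
                      k = length(unique(truth_lab))), class = "partition")
  net <- build_bipartite(pool_clusters(p, inc))
  sp_nodes <- net$nodes[net$nodes$type == "species", ]
  endemics <- w$truth$species$species[w$truth$species$endemic]
  expect_true(all(sp_nodes$size[sp_nodes$id %in% endemics] == 1))
})

test_that("the force layout is deterministic and centers single nodes", {
  pools <- list(mk_pool(1, letters[1:5]), mk_pool(2, letters[4:8]))
  net <- build_bipartite(pools)
  par <- layout_params(iterations = 80, seed = 3)
  l1 <- layout_force(net, par)
  l2 <- layout_force(net, par)
  expect_identical(l1, l2)
  l3 <- layout_force(net, layout_params(iterations = 80, seed = 4))
  expect_false(identical(l1$x, l3$x))
  single <- list(nodes = data.frame(id = "only", type = "cluster", size = 1),
                 edges = data.frame(cluster = character(),
                                    species = character(),
                                    weight = numeric()))
  expect_equal(layout_force(single)[, c("x", "y")],
               data.frame(x = 0, y = 0))
  expect_error(layout_force(list(nodes = data.frame(), edges = NULL)),
               "empty")
})

test_that("planted blocks separate in layout space across seeds", {
  # each block's clusters share a 6-species core; one species bridges the
  # two blocks
  sets <- c(lapply(1:4, function(i)
    mk_pool(i, c(paste0("coreA", 1:6), paste0("u", i, "_", 1:4)))),
    lapply(5:8, function(i)
      mk_pool(i, c(paste0("coreB", 1:6), paste0("u", i, "_", 1:4)))))
  sets[[1]]$species <- c(sets[[1]]$species, "bridge")
  sets[[5]]$species <- c(sets[[5]]$species, "bridge")
  net <- build_bipartite(sets)
  ok <- vapply(1:10, function(s) {
    xy <- layout_force(net, layout_params(iterations = 150, seed = s))
    cl <- xy[match(as.character(1:8), xy$id), ]
    within <- mean(c(dist(cl[1:4, c("x", "y")]), dist(cl[5:8, c("x", "y")])))
    between <- mean(as.matrix(dist(cl[, c("x", "y")]))[1:4, 5:8])
    within < between
  }, logical(1))
  expect_true(mean(ok) >= 0.8)
})

test_that("layout displacement is nonincreasing over the final iterations", {
  pools <- lapply(1:6, function(i) mk_pool(i, paste0("s", i, 1:6)))
  net <- build_bipartite(pools)
  xy <- layout_force(net, layout_params(iterations = 200, tolerance = 0,
                                        seed = 9))
  trace <- attr(xy, "displacement")
  tail_part <- trace[seq(ceiling(0.9 * length(trace)), length(trace))]
  expect_true(all(diff(tail_part) <= 1e-8))
})

test_that("network communities agree with the reference grouping", {
  pools <- c(lapply(1:3, function(i) mk_pool(i, c(paste0("x", 1:6, "_", i),
                                                  "shared_x"))),
             lapply(4:6, function(i) mk_pool(i, c(paste0("y", 1:6, "_", i),
                                                  "shared_y"))))
  net <- build_bipartite(pools)
  ref <- stats::setNames(rep(c("A", "B"), each = 3), 1:6)
  rep1 <- consensus_communities(net, ref)
  expect_equal(rep1$ari, 1)
  expect_length(rep1$equivocal, 0)
  # ARI is invariant under relabeling of the reference
  ref2 <- stats::setNames(rep(c("Q", "Z"), each = 3), 1:6)
  expect_equal(consensus_communities(net, ref2)$ari, 1)
  # modularity of the detected communities beats the trivial partition
  expect_gt(rep1$modularity,
            igraph::modularity(rep1$graph, rep(1, 6)) - 1e-12)
})

test_that("a cluster pulled toward the wrong grouping is flagged equivocal", {
  pools <- list(mk_pool(1, c("a1", "a2", "a3")),
                mk_pool(2, c("a1", "a2", "a4")),
                mk_pool(3, c("b1", "b2", "a1")))
  net <- build_bipartite(pools)
  ref <- stats::setNames(c("A", "A", "B"), 1:3)
  rep1 <- consensus_communities(net, ref)
  expect_true("3" %in% rep1$equivocal)
  single <- build_bipartite(list(mk_pool(1, "a")))
  flagged <- consensus_communities(single, stats::setNames("A", 1))
  expect_true(is.na(flagged$ari))
})

test_that("networks export to GraphML and an edge list", {
  net <- build_bipartite(list(mk_pool(1, c("a", "b")), mk_pool(2, "b")))
  gml <- withr::local_tempfile(fileext = ".graphml")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_network(net, gml, csv)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(nrow(read.csv(csv)), nrow(net$edges))
})
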