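test_that("queen adjacency includes diagonals and wraps the antimeridian", {
  cells <- c("r10c1", "r10c2", "r11c2", "r10c72", "r20c40")
  adj <- cell_adjacency(cells)
  expect_true("r11c2" %in% adj[["r10c1"]])          # corner contact
  expect_true("r10c1" %in% adj[["r10c72"]])         # antimeridian wrap
  expect_length(adj[["r20c40"]], 0)
  # symmetry, no self-edges
  for (a in cells) for (b in adj[[a]]) {
    expect_true(a %in% adj[[b]])
    expect_false(a %in% adj[[a]])
  }
})

test_that("contiguity is the largest-component fraction", {
  adj <- cell_adjacency(c("r5c5", "r6c6", "r5c8"))
  expect_equal(contiguity_score("r5c5", adj), 1)
  expect_equal(contiguity_score(c("r5c5", "r6c6"), adj), 1)  # diagonal
  expect_equal(contiguity_score(c("r5c5", "r5c8"),
                                cell_adjacency(c("r5c5", "r5c8"))), 0.5)
  expect_error(contiguity_score(character(0), adj), "empty")
})

test_that("nesting violations are detected", {
  ok_scheme <- list(
    bioprovinces = list(p1 = list(cells = c("r1c1", "r1c2")),
                        p2 = list(cells = "r5c5")),
    bioregions = list(A = list(provinces = "p1"),
                      B = list(provinces = "p2")))
  expect_true(check_nesting(ok_scheme)$ok)
  bad <- ok_scheme
  bad$bioprovinces$p2$cells <- c("r5c5", "r1c1")
  v <- check_nesting(bad)
  expect_false(v$ok)
  expect_equal(v$violations, "r1c1")
})

test_that("outlier cells move to the most similar adjacent cluster", {
  # cluster 1 is fragmented: r1c1-r1c2 plus a distant cell r1c6 that sits
  # next to cluster 2 (r1c7, r2c7) and shares 90% of its species with it
  sets <- list(r1c1 = c("a", "b"), r1c2 = c("a", "c"),
               r1c6 = c("p", "q", "r", "s", "t", "u", "v", "w", "x", "a"),
               r1c7 = c("p", "q", "r", "s", "t", "u", "v", "w", "x", "y"),
               r2c7 = c("p", "q", "s"))
  inc <- incidence_from_sets(sets)
  lab <- c(r1c1 = 1, r1c2 = 1, r1c6 = 1, r1c7 = 2, r2c7 = 2)
  p <- structure(list(labels = lab, k = 2), class = "partition")
  adj <- cell_adjacency(names(sets))
  out <- reassign_outliers(p, inc, adj)
  expect_equal(unname(out$labels["r1c6"]), 2)
  expect_equal(out$audit$cell, "r1c6")
  expect_equal(out$audit$from, "1")
  expect_gt(out$audit$similarity, 0.8)
  # every surviving cluster is contiguous afterwards
  for (cl in unique(out$labels))
    expect_equal(contiguity_score(names(out$labels)[out$labels == cl], adj),
                 1)
})

test_that("similarity ties are settled by centroid distance and logged", {
  sets <- list(r10c10 = c("a", "b"),                    # outlier fragment
               r10c11 = c("a", "b"), r10c12 = "zz",     # cluster 2 (near)
               r10c9 = c("a", "b"), r10c8 = "qq",       # cluster 3 (same sim)
               r20c40 = c("k1", "k2"), r20c41 = c("k1", "k3"))
  inc <- incidence_from_sets(sets)
  lab <- c(r10c10 = 1, r10c11 = 2, r10c12 = 2, r10c9 = 3, r10c8 = 3,
           r20c40 = 1, r20c41 = 1)
  p <- structure(list(labels = lab, k = 3), class = "partition")
  adj <- cell_adjacency(names(sets))
  out <- reassign_outliers(p, inc, adj)
  move <- out$audit[out$audit$cell == "r10c10", ]
  expect_true(grepl("tie", move$reason[1]))
  expect_true(move$to[1] %in% c("2", "3"))
  # manual overrides win and are never re-reassigned
  ov <- data.frame(cell_id = "r10c10", cluster = 3)
  out2 <- reassign_outliers(p, inc, adj, overrides = ov)
  expect_equal(unname(out2$labels["r10c10"]), 3)
  expect_equal(out2$audit$reason[1], "override")
})

test_that("antitropical disjunct cells return to their geographic province", {
  # two hemispheres share one widespread species; the clustering lumped the
  # two disjunct cells into one cluster spanning both
  north <- list(r30c10 = c("n1", "n2", "disjunct"),
                r30c11 = c("n1", "n3"), r31c10 = c("n2", "n3"))
  south <- list(r6c10 = c("s1", "s2", "disjunct"),
                r6c11 = c("s1", "s3"), r5c10 = c("s2", "s3"))
  inc <- incidence_from_sets(c(north, south))
  lab <- c(r30c10 = 9, r30c11 = 1, r31c10 = 1,
           r6c10 = 9, r6c11 = 2, r5c10 = 2)
  p <- structure(list(labels = lab, k = 3), class = "partition")
  adj <- cell_adjacency(names(lab))
  out <- reassign_outliers(p, inc, adj)
  expect_equal(unname(out$labels["r30c10"]), 1)   # stays in the north
  expect_equal(unname(out$labels["r6c10"]), 2)    # stays in the south
})

test_that("indices reproduce the published worked examples", {
  i1 <- province_indices(117, 50, 88)
  expect_equal(i1$ratio, 2.34)
  expect_equal(i1$endemism_pct, 75.2)
  i2 <- province_indices(126, 52, 82)
  expect_equal(i2$ratio, 2.42)
  expect_equal(i2$endemism_pct, 65.1)
  all_unique <- province_indices(10, 5, 10)
  expect_equal(all_unique$endemism_pct, 100)
  expect_error(province_indices(0, 0, 0), "empty")
})

test_that("computed indices match a set-based brute-force oracle", {
  set.seed(61)
  w <- generate_world(small_world_config(seed = 61))
  rec <- w$records
  sp_inc <- build_incidence(rec, level = "species")
  gen_inc <- build_incidence(rec, level = "genus")
  truth <- w$truth$cells
  for (p in unique(truth$province)) {
    cells <- intersect(truth$cell_id[truth$province == p],
                       rownames(sp_inc))
    idx <- compute_indices(cells, sp_inc, gen_inc)
    # brute force over the raw records
    a <- assign_cell(rec$latitude, rec$longitude)
    inside <- a$cell_id %in% cells
    sp_in <- unique(paste(rec$genus, rec$species)[inside])
    sp_out <- unique(paste(rec$genus, rec$species)[!inside])
    expect_equal(idx$S, length(sp_in))
    expect_equal(idx$G, length(unique(rec$genus[inside])))
    expect_equal(idx$E, length(setdiff(sp_in, sp_out)))
    expect_equal(idx$ratio, round_half_up(idx$S / idx$G, 2))
    expect_true(idx$E <= idx$S && idx$ratio >= 1)
  }
})

test_that("schemes assemble groupings, provinces and independents", {
  sets <- list(r1c1 = letters[1:8], r1c2 = letters[2:9],      # cluster 1
               r3c1 = letters[11:18], r3c2 = letters[12:19],  # cluster 2
               r20c40 = c("iso1", "iso2", "a"))               # remote single
  inc <- incidence_from_sets(sets)
  lab <- c(r1c1 = 1, r1c2 = 1, r3c1 = 2, r3c2 = 2, r20c40 = 3)
  groupings <- stats::setNames(c("A", "A", "B"), 1:3)
  adj <- cell_adjacency(names(sets))
  scheme <- build_scheme(groupings, lab, inc, inc, adj)
  expect_equal(names(scheme$bioregions), "A")
  expect_equal(sort(scheme$bioregions$A$provinces), c("1", "2"))
  expect_equal(scheme$independent, "3")
  expect_true(scheme$criteria$nesting_ok)
  expect_equal(scheme$criteria$min_contiguity, 1)
  # cell conservation across bioprovinces
  expect_setequal(unlist(lapply(scheme$bioprovinces, `[[`, "cells")),
                  names(lab))
  # endemic counts sum to at most the species total
  e_sum <- sum(vapply(scheme$bioprovinces, function(b) b$indices$E, 0))
  expect_lte(e_sum, ncol(inc))
  single <- build_scheme(stats::setNames("A", 1),
                         c(r1c1 = 1, r1c2 = 1),
                         incidence_from_sets(sets[1:2]),
                         incidence_from_sets(sets[1:2]),
                         cell_adjacency(c("r1c1", "r1c2")))
  expect_length(single$bioregions, 1)
  expect_length(single$bioprovinces, 1)
})

test_that("schemes export to nested JSON and a flat table", {
  sets <- list(r1c1 = letters[1:8], r1c2 = letters[2:9],
               r3c1 = letters[11:18], r3c2 = letters[12:19])
  inc <- incidence_from_sets(sets)
  lab <- c(r1c1 = 1, r1c2 = 1, r3c1 = 2, r3c2 = 2)
  scheme <- build_scheme(stats::setNames(c("A", "B"), 1:2), lab, inc, inc,
                         cell_adjacency(names(sets)))
  js <- withr::local_tempfile(fileext = ".json")
  csv <- withr::local_tempfile(fileext = ".csv")
  export_scheme(scheme, js, csv)
  nested <- jsonlite::read_json(js)
  expect_setequal(names(nested$bioregions), c("A", "B"))
  tab <- read.csv(csv)
  expect_true(all(c("unit", "S", "G", "ratio", "E", "endemism_pct")
                  %in% names(tab)))
  expect_equal(sort(unique(tab$kind)), c("bioprovince", "bioregion"))
})
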