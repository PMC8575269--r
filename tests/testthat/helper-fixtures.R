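# Shared fixtures and independent oracles, built in code at test time.

# A small, fast synthetic world for unit tests (3 provinces, ~900 records).
small_world_config <- function(seed = 1, ...) {
  world_config(n_provinces = 3, cells_per_province = 6,
               species_per_province = 30, occurrences_per_cell = 50,
               genus_pool_size = 20, seed = seed, ...)
}

# Incidence matrix from a list of per-cell species vectors.
incidence_from_sets <- function(sets) {
  taxa <- sort(unique(unlist(sets)))
  m <- matrix(0L, length(sets), length(taxa),
              dimnames = list(names(sets), taxa))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- 1L
  structure(m, level = "species", grid = grid_spec(),
            class = c("incidence", "matrix"))
}

# Brute-force agglomerator: rescans all member pairs of the ORIGINAL
# distance matrix at every step (average/complete/single), with the same
# smallest-leaf-pair tie-break as the implementation under test.
bf_agglomerate <- function(d, linkage) {
  n <- nrow(d)
  cl <- as.list(seq_len(n))
  heights <- numeric(0)
  cluster_dist <- function(a, b) {
    vals <- d[a, b, drop = FALSE]
    switch(linkage, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(cl) > 1) {
    best <- NULL
    for (i in seq_len(length(cl) - 1)) for (j in seq(i + 1, length(cl))) {
      dd <- cluster_dist(cl[[i]], cl[[j]])
      key <- c(dd, min(cl[[i]], cl[[j]]), max(min(cl[[i]]), min(cl[[j]])))
      if (is.null(best) || dd < best$key[1] - 1e-15 ||
          (abs(dd - best$key[1]) <= 1e-15 &&
           (key[2] < best$key[2] ||
            (key[2] == best$key[2] && key[3] < best$key[3])))) {
        best <- list(key = key, i = i, j = j)
      }
    }
    heights <- c(heights, best$key[1])
    cl[[best$i]] <- c(cl[[best$i]], cl[[best$j]])
    cl[[best$j]] <- NULL
  }
  heights
}

# Brute-force Ward agglomeration in coordinate space: greedy minimum
# within-cluster sum-of-squares increase; heights on the Ward.D2 scale.
bf_ward_heights <- function(X) {
  cl <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  while (length(cl) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(cl) - 1)) for (j in seq(i + 1, length(cl))) {
      A <- X[cl[[i]], , drop = FALSE]
      B <- X[cl[[j]], , drop = FALSE]
      cost <- nrow(A) * nrow(B) / (nrow(A) + nrow(B)) *
        sum((colMeans(A) - colMeans(B))^2)
      if (cost < best[1]) best <- c(cost, i, j)
    }
    heights <- c(heights, sqrt(2 * best[1]))
    cl[[best[2]]] <- c(cl[[best[2]]], cl[[best[3]]])
    cl[[best[3]]] <- NULL
  }
  heights
}

# Monte-Carlo rarefaction oracle: mean and standard error of observed
# richness over `reps` random subsamples of size n.
mc_rarefy <- function(abundances, n, reps = 10000) {
  pool <- rep(seq_along(abundances), abundances)
  s <- replicate(reps, length(unique(sample(pool, n))))
  c(mean = mean(s), se = stats::sd(s) / sqrt(reps))
}

# Printed biodiversity index table used as a worked example: per-unit
# species (S), genus (G) and endemic (E) counts with the published
# species/genus ratio and endemism percentage.
published_unit_table <- function() {
  read.csv(text = "unit,S,G,E,ratio,endemism_pct
A,117,50,88,2.34,75.2
A1,60,41,26,1.46,43.3
A2,72,31,46,2.32,63.9
B,126,52,82,2.42,65.1
B1,43,24,9,1.79,20.9
B2,101,43,50,2.35,49.5
B3,20,15,2,1.33,10.0
C,74,42,40,1.76,54.1
C1,67,37,33,1.81,49.3
C2,12,10,4,1.20,33.3
D,78,47,34,1.66,43.6
D1,33,25,12,1.32,36.4
D2,55,37,18,1.49,32.7
E,85,51,45,1.67,52.9
E1,28,21,5,1.33,17.9
E2,28,22,5,1.27,17.9
E3,55,38,17,1.45,30.9
E4,19,13,3,1.46,15.8
Galapagos,10,9,2,1.11,20.0
Hawaii,11,9,2,1.22,18.2
AmsterdamStPaul,7,7,2,NA,28.6", stringsAsFactors = FALSE)
}

# Build species- and genus-level incidence matrices realizing given unit
# counts: one unit cell holding S species in G genera (E of them found
# nowhere else) plus an outside cell holding the S - E non-endemics and one
# extra species.
incidence_for_counts <- function(S, G, E) {
  genus <- sprintf("Gen%02d", ((seq_len(S) - 1) %% G) + 1)
  species <- sprintf("%s sp%03d", genus, seq_len(S))
  outside_sp <- c(species[seq_len(S - E) + E], "Zzz outside")
  sp_inc <- incidence_from_sets(list(unit = species, out = outside_sp))
  gen_inc <- incidence_from_sets(list(unit = unique(genus),
                                      out = unique(c(genus[seq_len(S - E) + E],
                                                     "Zzz"))))
  list(species = sp_inc, genus = gen_inc)
}
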