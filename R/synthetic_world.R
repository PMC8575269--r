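#' Configure a synthetic occurrence world
#'
#' Describes a world of rectangular marine provinces planted on the analysis
#' grid, each with its own species pool, from which georeferenced occurrence
#' records are simulated. Defaults emulate the statistical structure of a
#' global benthic occurrence compilation: ~400 species in ~100 genera,
#' ~15,000 occurrences, province-structured pools with endemics plus a small
#' pairwise-shared component.
#'
#' Pool composition per province (`S = species_per_province`): `round(ef*S)`
#' flagged endemic species, `round(o[p,q]*S)` species shared with each other
#' province `q` (created once per unordered pair), and the remainder filled
#' with province-restricted (but unflagged) species so that each pool has
#' exactly `S` species. `endemic_fraction + sum(overlap row) <= 1` is
#' required.
#'
#' @param n_provinces number of provinces (default 5).
#' @param cells_per_province grid cells per province (default 10, laid out as
#'   rectangular blocks of up to 5 columns).
#' @param species_per_province pool size per province (default 80).
#' @param endemic_fraction fraction of each pool planted as flagged endemics
#'   (default 0.5).
#' @param overlap_matrix symmetric matrix of pairwise shared-species
#'   fractions (diagonal ignored); default 0.04 off-diagonal, i.e. < 5%
#'   cross-province sharing.
#' @param genus_pool_size number of genera species are assigned to
#'   (default 100).
#' @param occurrences_per_cell mean occurrence count per cell; cell totals
#'   are negative-binomial with dispersion `dispersion` (default mean 300,
#'   size 5 — 5 provinces x 10 cells x 300 gives ~15,000 records).
#' @param dispersion negative-binomial size parameter of cell totals.
#' @param detection_prob per-occurrence detection (thinning) probability.
#' @param noise a [noise_config()].
#' @param seed master integer seed; independent per-stage substreams are
#'   derived from it.
#' @return object of class `world_config`.
#' @export
world_config <- function(n_provinces = 5,
                         cells_per_province = 10,
                         species_per_province = 80,
                         endemic_fraction = 0.5,
                         overlap_matrix = NULL,
                         genus_pool_size = 100,
                         occurrences_per_cell = 300,
                         dispersion = 5,
                         detection_prob = 1,
                         noise = noise_config(),
                         seed = 1) {
  if (n_provinces < 1 || cells_per_province < 1 || species_per_province < 1 ||
      genus_pool_size < 1 || occurrences_per_cell <= 0)
    stop("all counts must be positive")
  if (endemic_fraction < 0 || endemic_fraction > 1)
    stop("endemic_fraction must lie in [0, 1]")
  if (detection_prob < 0 || detection_prob > 1)
    stop("detection_prob must lie in [0, 1]")
  if (is.null(overlap_matrix)) {
    overlap_matrix <- matrix(0.04, n_provinces, n_provinces)
    diag(overlap_matrix) <- 0
  }
  if (!isTRUE(all.equal(overlap_matrix, t(overlap_matrix))))
    stop("overlap_matrix must be symmetric")
  diag(overlap_matrix) <- 0
  shared_tot <- rowSums(overlap_matrix)
  if (any(endemic_fraction + shared_tot > 1 + 1e-9))
    stop("endemic_fraction + total shared fraction must be <= 1 per province")
  structure(list(n_provinces = n_provinces,
                 cells_per_province = cells_per_province,
                 species_per_province = species_per_province,
                 endemic_fraction = endemic_fraction,
                 overlap_matrix = overlap_matrix,
                 genus_pool_size = genus_pool_size,
                 occurrences_per_cell = occurrences_per_cell,
                 dispersion = dispersion,
                 detection_prob = detection_prob,
                 noise = noise,
                 seed = as.integer(seed)),
            class = "world_config")
}

#' Configure record-level noise
#'
#' Rates of the raw-data defects the cleaning stage must handle:
#' open-nomenclature qualifiers, genus-only (`sp.`) records, single-character
#' misspellings (each paired with a synonym-table entry), and out-of-range
#' coordinates.
#'
#' @param qualifier_rate proportion rewritten with `aff.`/`cf.`/`indet.`.
#' @param sp_rate proportion rewritten as `"Genus sp."`.
#' @param misspelling_rate proportion given a one-character typo.
#' @param bad_coord_rate proportion given `|lat| > 90` or `|lon| > 180`.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(qualifier_rate = 0, sp_rate = 0,
                         misspelling_rate = 0, bad_coord_rate = 0) {
  rates <- c(qualifier_rate, sp_rate, misspelling_rate, bad_coord_rate)
  if (any(rates < 0 | rates > 1) || sum(rates) > 1)
    stop("noise rates must lie in [0, 1] and sum to at most 1")
  structure(list(qualifier_rate = qualifier_rate, sp_rate = sp_rate,
                 misspelling_rate = misspelling_rate,
                 bad_coord_rate = bad_coord_rate),
            class = "noise_config")
}

# Rectangular block placement: provinces are stacked in distinct latitude
# bands (stride = block height + 1 empty row) with staggered longitudes, so
# blocks are internally contiguous under queen adjacency and separated from
# one another by at least one empty cell.
province_blocks <- function(cfg, grid = grid_spec()) {
  ncols_b <- min(cfg$cells_per_province, 5L)
  nrows_b <- ceiling(cfg$cells_per_province / ncols_b)
  v_stride <- nrows_b + 1L
  if (2L + cfg$n_provinces * v_stride > grid$n_rows)
    stop("too many provinces to stack in distinct latitude bands at this ",
         "grid resolution")
  lapply(seq_len(cfg$n_provinces), function(p) {
    row0 <- 2L + (p - 1L) * v_stride
    col0 <- 1L + ((p - 1L) * (ncols_b + 4L)) %% (grid$n_cols - ncols_b)
    k <- seq_len(cfg$cells_per_province) - 1L
    row <- row0 + k %/% ncols_b
    col <- col0 + k %% ncols_b
    data.frame(row = row, col = col, cell_id = paste0("r", row, "c", col))
  })
}

make_species_names <- function(n_species, genus_pool_size, master_seed) {
  with_stage_seed(master_seed, "taxonomy", {
    genera <- sprintf("Genus%03d", seq_len(genus_pool_size))
    genus_of <- sample(genera, n_species, replace = TRUE)
    data.frame(genus = genus_of,
               epithet = sprintf("species%04d", seq_len(n_species)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic occurrence world
#'
#' Builds the province geography, plants species pools (endemics, pairwise
#' shared species, province-restricted filler), assigns each species a
#' per-province occupancy probability drawn from Beta(2, 2) and a geometric
#' abundance propensity, draws negative-binomial occurrence totals per cell,
#' allocates them multinomially over the species present, places each
#' occurrence at uniform-random coordinates inside its cell, and thins by
#' `detection_prob`. Deterministic given `cfg$seed` (independent named
#' substreams per stage).
#'
#' @param cfg a [world_config()].
#' @return list with `records` (clean occurrence data.frame in the
#'   [clean_records()] output schema) and `truth` (ground truth: `cells` =
#'   cell_id/province, `species` = species/genus/province-of-origin/endemic
#'   flag, `pools` = per-province species lists, `n_records` = emitted
#'   record count).
#' @export
generate_world <- function(cfg) {
  stopifnot(inherits(cfg, "world_config"))
  grid <- grid_spec()
  blocks <- province_blocks(cfg, grid)
  P <- cfg$n_provinces
  S <- cfg$species_per_province

  n_end <- round(cfg$endemic_fraction * S)
  n_shared <- matrix(0L, P, P)
  n_shared[upper.tri(n_shared)] <-
    round(cfg$overlap_matrix[upper.tri(cfg$overlap_matrix)] * S)
  n_shared <- n_shared + t(n_shared)

  # species ledger: provinces of occurrence, province of origin, endemic flag
  sp_provs <- list()    # list of integer vectors (provinces of occurrence)
  sp_origin <- integer()
  sp_endemic <- logical()
  add_species <- function(provs, origin, endemic) {
    sp_provs[[length(sp_provs) + 1L]] <<- provs
    sp_origin[length(sp_origin) + 1L] <<- origin
    sp_endemic[length(sp_endemic) + 1L] <<- endemic
  }
  for (p in seq_len(P)) {
    for (i in seq_len(n_end)) add_species(p, p, TRUE)
  }
  if (P > 1) {
    for (p in seq_len(P - 1)) for (q in seq((p + 1), P)) {
      if (n_shared[p, q] > 0)
        for (i in seq_len(n_shared[p, q])) add_species(c(p, q), p, FALSE)
    }
  }
  for (p in seq_len(P)) {
    n_fill <- S - n_end - sum(n_shared[p, ])
    if (n_fill < 0) stop("pool composition exceeds species_per_province")
    for (i in seq_len(n_fill)) add_species(p, p, FALSE)
  }
  n_species <- length(sp_provs)
  names_df <- make_species_names(n_species, cfg$genus_pool_size, cfg$seed)

  pools <- lapply(seq_len(P), function(p)
    which(vapply(sp_provs, function(v) p %in% v, logical(1))))

  # per (species, province) occupancy probability and abundance propensity
  occ_prob <- with_stage_seed(cfg$seed, "occupancy", {
    lapply(seq_len(P), function(p) {
      pr <- stats::rbeta(length(pools[[p]]), 2, 2)
      names(pr) <- pools[[p]]
      pr
    })
  })
  abund_w <- with_stage_seed(cfg$seed, "abundance", {
    lapply(seq_len(P), function(p) {
      w <- stats::rgeom(length(pools[[p]]), prob = 0.25) + 1
      names(w) <- pools[[p]]
      w
    })
  })

  recs <- with_stage_seed(cfg$seed, "placement", {
    out <- vector("list", P)
    for (p in seq_len(P)) {
      blk <- blocks[[p]]
      cell_rows <- vector("list", nrow(blk))
      for (ci in seq_len(nrow(blk))) {
        present <- pools[[p]][stats::runif(length(pools[[p]])) <
                                occ_prob[[p]]]
        if (length(present) == 0) next
        total <- stats::rnbinom(1, size = cfg$dispersion,
                                mu = cfg$occurrences_per_cell)
        # guarantee every present species is recorded at least once so the
        # planted occupancy is exactly realized when detection_prob = 1
        counts <- rep(1L, length(present))
        extra <- max(0L, total - length(present))
        if (extra > 0) {
          w <- abund_w[[p]][as.character(present)]
          counts <- counts +
            as.integer(stats::rmultinom(1, extra, prob = w / sum(w)))
        }
        b <- cell_bounds(blk$row[ci], blk$col[ci], grid)
        n_cell <- sum(counts)
        sp_idx <- rep(present, counts)
        cell_rows[[ci]] <- data.frame(
          species_idx = sp_idx,
          latitude = b$lat_min + stats::runif(n_cell) * (b$lat_max - b$lat_min),
          longitude = b$lon_min + stats::runif(n_cell) * (b$lon_max - b$lon_min),
          cell_id = blk$cell_id[ci],
          province = p,
          stringsAsFactors = FALSE)
      }
      out[[p]] <- do.call(rbind, cell_rows)
    }
    do.call(rbind, out)
  })

  if (cfg$detection_prob < 1) {
    keep <- with_stage_seed(cfg$seed, "detection",
                            stats::runif(nrow(recs)) < cfg$detection_prob)
    recs <- recs[keep, , drop = FALSE]
  }
  rownames(recs) <- NULL

  genus <- names_df$genus[recs$species_idx]
  epithet <- names_df$epithet[recs$species_idx]
  records <- data.frame(raw_name = paste(genus, epithet),
                        genus = genus,
                        species = epithet,
                        qualifier = "none",
                        latitude = recs$latitude,
                        longitude = recs$longitude,
                        depth_m = NA_real_,
                        source = "synthetic",
                        geocoded = FALSE,
                        stringsAsFactors = FALSE)

  truth_cells <- do.call(rbind, lapply(seq_len(P), function(p)
    data.frame(cell_id = blocks[[p]]$cell_id, province = p,
               stringsAsFactors = FALSE)))
  truth_species <- data.frame(
    species = paste(names_df$genus, names_df$epithet),
    genus = names_df$genus,
    province = sp_origin,
    endemic = sp_endemic,
    stringsAsFactors = FALSE)
  truth_pools <- lapply(pools, function(idx)
    paste(names_df$genus, names_df$epithet)[idx])
  occ <- unique(recs[, c("cell_id", "species_idx")])
  truth_occupancy <- data.frame(
    cell_id = occ$cell_id,
    species = paste(names_df$genus, names_df$epithet)[occ$species_idx],
    stringsAsFactors = FALSE)
  list(records = records,
       truth = list(cells = truth_cells, species = truth_species,
                    pools = truth_pools, occupancy = truth_occupancy,
                    n_records = nrow(records)))
}

#' Corrupt clean records with configured noise
#'
#' Perturbs exactly `round(rate * n)` records per noise type (disjoint record
#' sets, deterministic per seed): qualifier insertion (`aff.`/`cf.`/
#' `indet.`), genus-level rewriting (`"Genus sp."`), single-character
#' misspellings (each recorded in an emitted synonym table mapping the typo
#' back to the accepted binomial), and out-of-range coordinates.
#'
#' @param records clean occurrence data.frame (from [generate_world()]).
#' @param noise a [noise_config()].
#' @param seed integer seed.
#' @return list with `raw` (perturbed data.frame), `synonyms` (a
#'   [synonym_table()] for the injected misspellings) and `log` (data.frame
#'   `row`, `type` of every perturbation).
#' @export
corrupt_records <- function(records, noise = noise_config(), seed = 1) {
  stopifnot(inherits(noise, "noise_config"))
  n <- nrow(records)
  n_q <- round(noise$qualifier_rate * n)
  n_sp <- round(noise$sp_rate * n)
  n_mis <- round(noise$misspelling_rate * n)
  n_bad <- round(noise$bad_coord_rate * n)
  raw <- records
  syn_raw <- character()
  syn_acc <- character()
  log <- data.frame(row = integer(), type = character(),
                    stringsAsFactors = FALSE)
  with_stage_seed(seed, "corruption", {
    hit <- sample(n, n_q + n_sp + n_mis + n_bad)
    i_q <- hit[seq_len(n_q)]
    i_sp <- hit[n_q + seq_len(n_sp)]
    i_mis <- hit[n_q + n_sp + seq_len(n_mis)]
    i_bad <- hit[n_q + n_sp + n_mis + seq_len(n_bad)]
    if (n_q > 0) {
      qual <- sample(c("aff.", "cf.", "indet."), n_q, replace = TRUE)
      raw$raw_name[i_q] <- ifelse(
        qual == "indet.",
        paste(raw$genus[i_q], qual),
        paste(raw$genus[i_q], qual, raw$species[i_q]))
    }
    if (n_sp > 0)
      raw$raw_name[i_sp] <- paste(raw$genus[i_sp], "sp.")
    if (n_mis > 0) {
      for (i in i_mis) {
        good <- paste(records$genus[i], records$species[i])
        ep <- records$species[i]
        pos <- sample(nchar(ep), 1)
        ch <- sample(setdiff(letters, substr(ep, pos, pos)), 1)
        bad_ep <- paste0(substr(ep, 1, pos - 1), ch,
                         substr(ep, pos + 1, nchar(ep)))
        raw$raw_name[i] <- paste(records$genus[i], bad_ep)
        if (!(raw$raw_name[i] %in% syn_raw)) {
          syn_raw <- c(syn_raw, raw$raw_name[i])
          syn_acc <- c(syn_acc, good)
        }
      }
    }
    if (n_bad > 0) {
      flip_lat <- stats::runif(n_bad) < 0.5
      raw$latitude[i_bad][flip_lat] <-
        sign(raw$latitude[i_bad][flip_lat] + 0.001) *
        (95 + stats::runif(sum(flip_lat)) * 30)
      raw$longitude[i_bad][!flip_lat] <-
        sign(raw$longitude[i_bad][!flip_lat] + 0.001) *
        (185 + stats::runif(sum(!flip_lat)) * 30)
    }
    log <- rbind(
      data.frame(row = i_q, type = rep("qualifier", n_q)),
      data.frame(row = i_sp, type = rep("sp", n_sp)),
      data.frame(row = i_mis, type = rep("misspelling", n_mis)),
      data.frame(row = i_bad, type = rep("bad_coord", n_bad)))
  })
  list(raw = raw, synonyms = synonym_table(syn_raw, syn_acc), log = log)
}

#' Write a synthetic world to disk
#'
#' Emits the occurrence CSV consumed by [read_occurrences()], the truth
#' sidecar CSVs (cell-province labels; species-province-endemic flags) and a
#' flat key-value config file.
#'
#' @param world result of [generate_world()].
#' @param cfg the [world_config()] used.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_world <- function(world, cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(world$records, file.path(dir, "occurrences.csv"),
                   row.names = FALSE)
  utils::write.csv(world$truth$cells, file.path(dir, "truth_cells.csv"),
                   row.names = FALSE)
  utils::write.csv(world$truth$species, file.path(dir, "truth_species.csv"),
                   row.names = FALSE)
  scal <- cfg[setdiff(names(cfg), c("overlap_matrix", "noise"))]
  keyvals <- c(
    vapply(names(scal), function(k) paste0(k, " = ", scal[[k]]), ""),
    vapply(names(cfg$noise), function(k)
      paste0("noise.", k, " = ", cfg$noise[[k]]), ""),
    paste0("overlap_offdiag = ",
           if (cfg$n_provinces > 1) cfg$overlap_matrix[1, 2] else 0))
  writeLines(keyvals, file.path(dir, "world_config.txt"))
  invisible(dir)
}
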