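#' Define an equal-angle latitude-longitude grid
#'
#' The analysis grid is a regular `cell_size`-degree graticule with half-open
#' cells `[lower, upper)` on both axes; latitude 90 is folded into the topmost
#' row so that every valid coordinate maps to exactly one cell.
#'
#' @param cell_size cell edge in degrees; must divide both 180 and 360
#'   (default 5, the resolution used for global occurrence mapping).
#' @return an object of class `grid_spec` with `n_rows` and `n_cols`.
#' @export
grid_spec <- function(cell_size = 5) {
  if (cell_size <= 0 || 180 %% cell_size != 0 || 360 %% cell_size != 0)
    stop("cell_size must be a positive divisor of 180 and 360")
  structure(
    list(cell_size = cell_size,
         lat_origin = -90, lon_origin = -180,
         n_rows = as.integer(180 / cell_size),
         n_cols = as.integer(360 / cell_size)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec: %g deg cells, %d rows x %d cols>\n",
              x$cell_size, x$n_rows, x$n_cols))
  invisible(x)
}

#' Assign coordinates to grid cells
#'
#' Rows count northwards from latitude -90, columns eastwards from longitude
#' -180. Cells are half-open on both axes; latitude 90 falls in the top row,
#' and longitudes are wrapped across the antimeridian before assignment.
#'
#' @param latitude,longitude numeric vectors of coordinates in decimal
#'   degrees; must be pre-cleaned (latitudes in \[-90, 90\]).
#' @param grid a [grid_spec()].
#' @return data.frame with integer `row`, `col` and the `cell_id` string
#'   `"r<row>c<col>"` used as the internal cell identifier.
#' @export
assign_cell <- function(latitude, longitude, grid = grid_spec()) {
  if (any(latitude < -90 | latitude > 90, na.rm = FALSE))
    stop("latitude out of range; records must be cleaned before gridding")
  lon <- normalize_lon(longitude)
  row <- pmin(floor((latitude - grid$lat_origin) / grid$cell_size) + 1L,
              grid$n_rows)           # fold lat = 90 into the top row
  col <- floor((lon - grid$lon_origin) / grid$cell_size) + 1L
  data.frame(row = as.integer(row), col = as.integer(col),
             cell_id = paste0("r", row, "c", col),
             stringsAsFactors = FALSE)
}

cell_id_to_rc <- function(cell_id) {
  m <- regmatches(cell_id, regexec("^r([0-9]+)c([0-9]+)$", cell_id))
  row <- vapply(m, function(x) as.integer(x[2]), integer(1))
  col <- vapply(m, function(x) as.integer(x[3]), integer(1))
  data.frame(row = row, col = col)
}

# Bounds (degrees) of a cell given row/col indices.
cell_bounds <- function(row, col, grid = grid_spec()) {
  s <- grid$cell_size
  data.frame(lat_min = grid$lat_origin + (row - 1) * s,
             lat_max = grid$lat_origin + row * s,
             lon_min = grid$lon_origin + (col - 1) * s,
             lon_max = grid$lon_origin + col * s)
}

# Centroid (lat, lon) of cells.
cell_centroid <- function(cell_id, grid = grid_spec()) {
  rc <- cell_id_to_rc(cell_id)
  b <- cell_bounds(rc$row, rc$col, grid)
  data.frame(lat = (b$lat_min + b$lat_max) / 2,
             lon = (b$lon_min + b$lon_max) / 2)
}

fmt_lat <- function(lat) sprintf("%g°%s", abs(lat), ifelse(lat < 0, "S", "N"))
fmt_lon <- function(lon) sprintf("%g°%s", abs(lon), ifelse(lon < 0, "W", "E"))

#' Human-readable cell labels
#'
#' Labels follow the `"35°N130°E-30°N135°E"` convention: the north-west corner
#' (maximum latitude, minimum longitude) then the south-east corner (minimum
#' latitude, maximum longitude). Zero latitude/longitude is written with
#' N/E. Labels are presentation only; `cell_id` strings are the identifiers.
#'
#' @param cell_id character vector of `"r<row>c<col>"` identifiers.
#' @param grid a [grid_spec()].
#' @return character vector of labels.
#' @seealso [parse_cell_label()]
#' @export
cell_label <- function(cell_id, grid = grid_spec()) {
  rc <- cell_id_to_rc(cell_id)
  b <- cell_bounds(rc$row, rc$col, grid)
  paste0(fmt_lat(b$lat_max), fmt_lon(b$lon_min), "-",
         fmt_lat(b$lat_min), fmt_lon(b$lon_max))
}

#' Parse a cell label back to its cell id
#'
#' @param label character vector of labels produced by [cell_label()].
#' @param grid a [grid_spec()].
#' @return character vector of `cell_id` strings.
#' @export
parse_cell_label <- function(label, grid = grid_spec()) {
  pat <- "^([0-9.]+)°([NS])([0-9.]+)°([EW])-"
  m <- regmatches(label, regexec(pat, label))
  bad <- vapply(m, length, integer(1)) == 0
  if (any(bad)) stop("unparseable cell label: ", label[bad][1])
  lat_max <- vapply(m, function(x)
    as.numeric(x[2]) * if (x[3] == "S") -1 else 1, numeric(1))
  lon_min <- vapply(m, function(x)
    as.numeric(x[4]) * if (x[5] == "W") -1 else 1, numeric(1))
  s <- grid$cell_size
  row <- as.integer((lat_max - grid$lat_origin) / s)
  col <- as.integer((lon_min - grid$lon_origin) / s) + 1L
  paste0("r", row, "c", col)
}

#' Build a binary cell-by-taxon incidence matrix
#'
#' Species-level incidence excludes genus-level records (qualifier `sp`/`spp`,
#' which carry no species epithet); genus-level incidence includes them. Rows
#' are occupied cells in row-major grid order, columns are taxa in
#' alphabetical order; taxa observed in no cell are dropped.
#'
#' @param records cleaned occurrence data.frame (see [clean_records()]).
#' @param grid a [grid_spec()].
#' @param level `"species"` or `"genus"`.
#' @return an `incidence` object: a binary integer matrix with `cell_id`
#'   rownames and taxon colnames, plus attributes `level`, `grid` and
#'   `occurrences` (per-cell record counts).
#' @export
build_incidence <- function(records, grid = grid_spec(),
                            level = c("species", "genus")) {
  level <- match.arg(level)
  if (nrow(records) == 0) {
    m <- matrix(0L, 0, 0)
    return(structure(m, level = level, grid = grid,
                     occurrences = integer(0), class = c("incidence", "matrix")))
  }
  cells <- assign_cell(records$latitude, records$longitude, grid)
  if (level == "species") {
    use <- records$qualifier == "none" & nzchar(records$species)
    taxon <- paste(records$genus, records$species)[use]
  } else {
    use <- rep(TRUE, nrow(records))
    taxon <- records$genus[use]
  }
  cid <- cells$cell_id[use]
  if (length(cid) == 0) {
    m <- matrix(0L, 0, 0)
    return(structure(m, level = level, grid = grid,
                     occurrences = integer(0),
                     class = c("incidence", "matrix")))
  }
  occ <- tapply(rep(1L, length(cid)), cid, sum)
  taxa <- sort(unique(taxon))
  rc <- cell_id_to_rc(unique(cid))
  ord <- order(rc$row, rc$col)
  cell_ids <- unique(cid)[ord]
  m <- matrix(0L, length(cell_ids), length(taxa),
              dimnames = list(cell_ids, taxa))
  m[cbind(match(cid, cell_ids), match(taxon, taxa))] <- 1L
  structure(m, level = level, grid = grid,
            occurrences = as.integer(occ[cell_ids]),
            class = c("incidence", "matrix"))
}

#' Per-cell richness and latitudinal totals
#'
#' @param incidence an incidence matrix from [build_incidence()].
#' @param bin_width width in degrees of the latitudinal summary bins
#'   (default 5).
#' @return list with `cell` (named per-cell richness, the row sums) and
#'   `latitudinal` (data.frame of taxa counts per latitude bin, taxa pooled
#'   across all cells whose row falls in the bin).
#' @export
cell_richness <- function(incidence, bin_width = 5) {
  rich <- rowSums(incidence)
  grid <- attr(incidence, "grid") %||% grid_spec()
  if (nrow(incidence) == 0)
    return(list(cell = rich,
                latitudinal = data.frame(lat_min = numeric(0),
                                         lat_max = numeric(0),
                                         richness = integer(0))))
  ctr <- cell_centroid(rownames(incidence), grid)
  bin <- floor((ctr$lat + 90) / bin_width)
  bins <- sort(unique(bin))
  lat_rich <- vapply(bins, function(b) {
    sum(colSums(incidence[bin == b, , drop = FALSE]) > 0)
  }, numeric(1))
  list(cell = rich,
       latitudinal = data.frame(lat_min = bins * bin_width - 90,
                                lat_max = (bins + 1) * bin_width - 90,
                                richness = as.integer(lat_rich)))
}

#' Filter grid cells by minimum richness
#'
#' Keeps rows (cells) whose richness is at least `min_species` — a cell with
#' exactly `min_species` taxa survives — then drops taxa left with no
#' occupied cell. Idempotent.
#'
#' @param incidence an incidence matrix from [build_incidence()].
#' @param min_species minimum row richness (default 7, the threshold used to
#'   restrict clustering to adequately sampled cells).
#' @return filtered incidence matrix with attributes preserved.
#' @export
filter_cells <- function(incidence, min_species = 7) {
  if (min_species < 1) stop("min_species must be >= 1")
  keep <- rowSums(incidence) >= min_species
  occ <- attr(incidence, "occurrences")
  m <- incidence[keep, , drop = FALSE]
  keep_col <- colSums(m) >= 1L
  m <- m[, keep_col, drop = FALSE]
  structure(m, level = attr(incidence, "level"), grid = attr(incidence, "grid"),
            occurrences = occ[keep], class = c("incidence", "matrix"))
}

#' Export grid cells as GeoJSON polygons
#'
#' Writes a FeatureCollection with one rectangular polygon per occupied cell,
#' carrying `cell_id`, `label` and `richness` properties; this drives any
#' external mapping tool.
#'
#' @param incidence an incidence matrix from [build_incidence()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_grid_geojson <- function(incidence, path) {
  grid <- attr(incidence, "grid") %||% grid_spec()
  rc <- cell_id_to_rc(rownames(incidence))
  b <- cell_bounds(rc$row, rc$col, grid)
  rich <- rowSums(incidence)
  features <- lapply(seq_len(nrow(incidence)), function(i) {
    ring <- list(c(b$lon_min[i], b$lat_min[i]), c(b$lon_max[i], b$lat_min[i]),
                 c(b$lon_max[i], b$lat_max[i]), c(b$lon_min[i], b$lat_max[i]),
                 c(b$lon_min[i], b$lat_min[i]))
    list(type = "Feature",
         properties = list(cell_id = rownames(incidence)[i],
                           label = cell_label(rownames(incidence)[i], grid),
                           richness = unname(rich[i])),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
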