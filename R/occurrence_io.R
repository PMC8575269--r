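#' Convert degrees-minutes-seconds to decimal degrees
#'
#' @param degrees,minutes,seconds numeric vectors; minutes and seconds must
#'   lie in \[0, 60).
#' @param hemisphere `"N"`, `"S"`, `"E"` or `"W"`; S and W yield negative
#'   values.
#' @return decimal degrees, precise to well below 1e-6 degree.
#' @examples
#' dms_to_decimal(30, 30, 0, "S")   # -30.5
#' @export
dms_to_decimal <- function(degrees, minutes = 0, seconds = 0,
                           hemisphere = "N") {
  if (any(minutes < 0 | minutes >= 60) || any(seconds < 0 | seconds >= 60))
    stop("minutes and seconds must lie in [0, 60)")
  if (!all(hemisphere %in% c("N", "S", "E", "W")))
    stop("hemisphere must be one of N, S, E, W")
  sgn <- ifelse(hemisphere %in% c("S", "W"), -1, 1)
  sgn * (abs(degrees) + minutes / 60 + seconds / 3600)
}

#' Construct a synonym table
#'
#' Maps raw or misspelled names to accepted binomials. Accepted names must be
#' fixed points of the mapping (no chains): an accepted name may not itself
#' appear as a raw name mapping elsewhere.
#'
#' @param raw character vector of raw (incorrect) names.
#' @param accepted character vector of accepted names, same length.
#' @return data.frame of class `synonym_table` with columns `raw`, `accepted`.
#' @export
synonym_table <- function(raw = character(), accepted = character()) {
  stopifnot(length(raw) == length(accepted))
  chained <- accepted %in% raw[raw != accepted]
  if (any(chained))
    stop("synonym chains are not allowed; accepted names must be fixed ",
         "points (offender: ", accepted[chained][1], ")")
  structure(data.frame(raw = as.character(raw),
                       accepted = as.character(accepted),
                       stringsAsFactors = FALSE),
            class = c("synonym_table", "data.frame"))
}

apply_synonyms <- function(name, synonyms) {
  if (is.null(synonyms) || nrow(synonyms) == 0) return(name)
  i <- match(name, synonyms$raw)
  ifelse(is.na(i), name, synonyms$accepted[i])
}

#' Parse and standardize a raw taxon name
#'
#' Detects open-nomenclature qualifiers (`aff.`, `cf.`, `indet.`, `sp.`,
#' `spp.`) case-insensitively, with or without trailing periods, strips them,
#' and applies the synonym table to the remaining binomial (and, for
#' genus-only names, to the genus).
#'
#' @param raw_name character vector of raw names.
#' @param synonyms optional [synonym_table()].
#' @return data.frame with columns `genus`, `species` (epithet, `""` for
#'   genus-level records), `qualifier` (one of `none`, `aff`, `cf`, `indet`,
#'   `sp`, `spp`) and `parseable` (FALSE for empty/unusable names).
#' @export
standardize_name <- function(raw_name, synonyms = NULL) {
  qualifiers <- c("aff", "cf", "indet", "sp", "spp")
  one <- function(nm) {
    toks <- strsplit(trimws(nm), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0)
      return(list(genus = "", species = "", qualifier = "none",
                  parseable = FALSE))
    bare <- tolower(sub("\\.+$", "", toks))
    qual_hit <- bare %in% qualifiers
    qualifier <- if (any(qual_hit)) bare[which(qual_hit)[1]] else "none"
    toks <- toks[!qual_hit]
    genus <- if (length(toks) >= 1) toks[1] else ""
    species <- if (length(toks) >= 2) paste(toks[-1], collapse = " ") else ""
    if (qualifier %in% c("sp", "spp")) species <- ""
    if (!nzchar(genus))
      return(list(genus = "", species = "", qualifier = qualifier,
                  parseable = FALSE))
    # synonym reconciliation after qualifier stripping
    if (nzchar(species)) {
      full <- apply_synonyms(paste(genus, species), synonyms)
      ft <- strsplit(full, "[[:space:]]+")[[1]]
      genus <- ft[1]
      species <- if (length(ft) >= 2) paste(ft[-1], collapse = " ") else ""
    } else {
      genus <- apply_synonyms(genus, synonyms)
    }
    list(genus = genus, species = species, qualifier = qualifier,
         parseable = TRUE)
  }
  out <- lapply(as.character(raw_name), one)
  data.frame(genus = vapply(out, `[[`, "", "genus"),
             species = vapply(out, `[[`, "", "species"),
             qualifier = vapply(out, `[[`, "", "qualifier"),
             parseable = vapply(out, `[[`, TRUE, "parseable"),
             stringsAsFactors = FALSE)
}

#' Read a raw occurrence table
#'
#' Reads a UTF-8 CSV or TSV occurrence table (delimiter auto-detected from
#' the header line). Required columns: `raw_name`, `latitude`, `longitude`;
#' optional: `depth_m`, `source`, `geocoded`.
#'
#' @param path file path.
#' @return data.frame of raw records.
#' @export
read_occurrences <- function(path) {
  header <- readLines(path, n = 1, encoding = "UTF-8")
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          fileEncoding = "UTF-8", comment.char = "")
  need <- c("raw_name", "latitude", "longitude")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  df
}

#' Clean raw occurrence records
#'
#' Applies the data-cleaning rules for occurrence databases: records with
#' qualifiers `aff.`, `cf.` or `indet.` are rejected; `sp.`/`spp.` records
#' are retained, flagged genus-level; unparseable names are rejected;
#' latitudes outside \[-90, 90\] and longitudes outside \[-180, 180\] are
#' rejected; surviving longitudes are normalized to \[-180, 180);
#' geocoded records are snapped to the nearest 0.5 degree; exact duplicates
#' (name + coordinates + source) are collapsed with a count. If a land mask
#' is supplied, points strictly inside land polygons are rejected.
#'
#' @param raw data.frame with at least `raw_name`, `latitude`, `longitude`;
#'   optional `depth_m`, `source`, `geocoded` columns.
#' @param synonyms optional [synonym_table()].
#' @param land_mask optional list of polygons, each a 2-column matrix of
#'   (lon, lat) vertices; point-in-polygon via [mgcv::in.out()].
#' @return list with `records` (cleaned data.frame: `raw_name`, `genus`,
#'   `species`, `qualifier`, `latitude`, `longitude`, `depth_m`, `source`,
#'   `geocoded`, `n_dup`) and `log` (rejection data.frame with the original
#'   row and a `reason` in `qualifier`, `coordinate_out_of_range`, `on_land`,
#'   `unparseable`). Row conservation: `nrow(records)` counted with
#'   duplicates (`sum(n_dup)`) plus `nrow(log)` equals `nrow(raw)`.
#' @export
clean_records <- function(raw, synonyms = NULL, land_mask = NULL) {
  need <- c("raw_name", "latitude", "longitude")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(raw)
  raw$depth_m <- if ("depth_m" %in% names(raw)) raw$depth_m else NA_real_
  raw$source <- if ("source" %in% names(raw)) raw$source else ""
  raw$geocoded <- if ("geocoded" %in% names(raw)) {
    as.logical(raw$geocoded)
  } else FALSE
  raw$geocoded[is.na(raw$geocoded)] <- FALSE

  std <- standardize_name(raw$raw_name, synonyms)
  reason <- rep(NA_character_, n)
  reason[!std$parseable] <- "unparseable"
  reason[is.na(reason) & std$qualifier %in% c("aff", "cf", "indet")] <-
    "qualifier"
  bad_coord <- is.na(raw$latitude) | is.na(raw$longitude) |
    abs(raw$latitude) > 90 | abs(raw$longitude) > 180
  reason[is.na(reason) & bad_coord] <- "coordinate_out_of_range"

  lat <- raw$latitude
  lon <- normalize_lon(raw$longitude)
  snap <- raw$geocoded & is.na(reason)
  lat[snap] <- round(lat[snap] * 2) / 2
  lon[snap] <- normalize_lon(round(lon[snap] * 2) / 2)

  if (!is.null(land_mask) && any(is.na(reason))) {
    idx <- which(is.na(reason))
    pts <- cbind(lon[idx], lat[idx])
    inside <- rep(FALSE, length(idx))
    for (poly in land_mask)
      inside <- inside | mgcv::in.out(as.matrix(poly), pts)
    reason[idx[inside]] <- "on_land"
  }

  keep <- is.na(reason)
  records <- data.frame(raw_name = raw$raw_name[keep],
                        genus = std$genus[keep],
                        species = std$species[keep],
                        qualifier = std$qualifier[keep],
                        latitude = lat[keep],
                        longitude = lon[keep],
                        depth_m = raw$depth_m[keep],
                        source = raw$source[keep],
                        geocoded = raw$geocoded[keep],
                        stringsAsFactors = FALSE)
  # collapse exact duplicates (same name + coordinates + source) with a
  # count; an existing n_dup column (already-cleaned input) is accumulated,
  # which makes cleaning idempotent
  w <- if ("n_dup" %in% names(raw)) as.integer(raw$n_dup[keep]) else
    rep(1L, nrow(records))
  key <- paste(records$raw_name, records$latitude, records$longitude,
               records$source, sep = "\r")
  first <- !duplicated(key)
  n_dup <- as.integer(tapply(w, key, sum)[key[first]])
  records <- records[first, , drop = FALSE]
  records$n_dup <- n_dup
  rownames(records) <- NULL

  log <- cbind(raw[!keep, need, drop = FALSE],
               reason = reason[!keep], row = which(!keep))
  rownames(log) <- NULL
  list(records = records, log = log)
}

#' Write cleaned records and rejection log to CSV
#'
#' @param cleaned result of [clean_records()].
#' @param records_path,log_path output file paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_cleaned <- function(cleaned, records_path = NULL, log_path = NULL) {
  if (!is.null(records_path))
    utils::write.csv(cleaned$records, records_path, row.names = FALSE)
  if (!is.null(log_path))
    utils::write.csv(cleaned$log, log_path, row.names = FALSE)
  invisible(c(records_path, log_path))
}
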