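#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used for the printed biodiversity indices (base [round()] uses
#' round-half-even and would disagree on exact ties such as 49.25).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up (in magnitude).
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalize longitudes to [-180, 180)
#'
#' @param lon numeric vector of longitudes in decimal degrees.
#' @return longitudes wrapped into the half-open interval \[-180, 180).
#' @export
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items.
#' Thin wrapper around [mclust::adjustedRandIndex()].
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return scalar ARI in \[-1, 1\]; 1 means identical partitions up to
#'   relabeling.
#' @export
ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  ka <- length(unique(a)); kb <- length(unique(b))
  # identical trivial partitions (one block, or all singletons) agree
  # perfectly, but the chance-correction denominator degenerates to 0/0
  if (ka == 1 && kb == 1) return(1)
  if (ka == length(a) && kb == length(b)) return(1)
  mclust::adjustedRandIndex(a, b)
}

# Deterministic per-stage sub-seed derived from a master seed and a stage
# name, so pipeline stages can be regenerated independently.  Kept strictly
# below 2^31 - 1 (R integers are 32-bit).
derive_seed <- function(master_seed, stage) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000003
  as.integer((abs(master_seed) %% 1000003) * 2039 + h) %% 2147483562L + 1L
}

# Run an expression with a local RNG state seeded from (master, stage).
with_stage_seed <- function(master_seed, stage, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(derive_seed(master_seed, stage))
  expr
}

# Great-circle distance in kilometres between (lat, lon) points.
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2)) / 1000
}

`%||%` <- function(a, b) if (is.null(a)) b else a
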