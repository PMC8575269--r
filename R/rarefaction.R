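#' Expected richness in a random subsample (Hurlbert rarefaction)
#'
#' Individual-based rarefaction: the expected number of species in a uniform
#' random subsample of `n` of the `N = sum(abundances)` occurrences,
#' `E[S_n] = sum_i (1 - C(N - N_i, n) / C(N, n))`, evaluated with
#' log-binomials so large `N` (1e5 and beyond) does not overflow.
#'
#' @param abundances positive integer vector of per-species occurrence
#'   counts.
#' @param n subsample size(s), each in `1..N`.
#' @param variance if `TRUE`, also return the exact hypergeometric variance
#'   of `S_n` (quadratic in the number of species).
#' @return numeric vector `E[S_n]` (same length as `n`), or if
#'   `variance = TRUE` a data.frame with columns `n`, `expected`, `variance`.
#' @examples
#' rarefy(c(2, 1), 2)   # 5/3
#' @export
rarefy <- function(abundances, n, variance = FALSE) {
  abundances <- abundances[abundances > 0]
  if (length(abundances) == 0) stop("empty abundance vector")
  N <- sum(abundances)
  if (any(n < 1 | n > N)) stop("subsample size n must lie in [1, N]")
  # q_i(n) = P(species i absent from the subsample); vectorized over species
  lq <- function(Ni, n) {
    out <- rep(-Inf, length(Ni))
    ok <- (N - Ni) >= n
    out[ok] <- lchoose(N - Ni[ok], n) - lchoose(N, n)
    out
  }
  expected <- vapply(n, function(nn)
    sum(1 - exp(lq(abundances, nn))), numeric(1))
  if (!variance) return(expected)
  vr <- vapply(n, function(nn) {
    q <- exp(lq(abundances, nn))
    v <- sum(q * (1 - q))
    if (length(abundances) > 1) {
      for (i in seq_len(length(abundances) - 1)) {
        Ni <- abundances[i]
        Nj <- abundances[(i + 1):length(abundances)]
        qij <- exp(lchoose(N - Ni - Nj, nn) - lchoose(N, nn))
        qij[(N - Ni - Nj) < nn] <- 0
        v <- v + 2 * sum(qij - q[i] * q[(i + 1):length(abundances)])
      }
    }
    v
  }, numeric(1))
  data.frame(n = n, expected = expected, variance = vr)
}

#' Build a rarefaction curve for one abundance vector
#'
#' @param abundances positive integer per-species counts.
#' @param n_points maximum number of evaluation sizes; the curve always
#'   includes `n = 1` and `n = N` and uses every integer when `N <=
#'   n_points`.
#' @return object of class `rarefaction_curve`: data.frame with `n` and
#'   `expected`, plus attributes `N`, `s_obs`.
#' @export
rarefaction_curve <- function(abundances, n_points = 512) {
  abundances <- abundances[abundances > 0]
  N <- sum(abundances)
  ns <- if (N <= n_points) seq_len(N) else
    unique(round(c(1, seq(1, N, length.out = n_points), N)))
  curve <- data.frame(n = ns, expected = rarefy(abundances, ns))
  structure(curve, N = N, s_obs = length(abundances),
            class = c("rarefaction_curve", "data.frame"))
}

# Strata used for completeness assessment: three 30-degree climatic zones
# per hemisphere, or regular latitudinal bins.
climatic_zone <- function(lat) {
  hemi <- ifelse(lat >= 0, "N", "S")
  a <- abs(lat)
  zone <- ifelse(a >= 60, "polar", ifelse(a >= 30, "temperate", "tropical"))
  paste(hemi, zone)
}

#' Rarefaction curves per latitudinal stratum
#'
#' Groups cleaned occurrence records into strata — the six 30-degree
#' climatic zones (N/S polar, temperate, tropical) or regular latitudinal
#' bins — and builds one occurrence-based rarefaction curve per non-empty
#' stratum. Record counts per species within the stratum are the abundance
#' proxy. Empty strata are omitted with a message.
#'
#' @param records cleaned occurrence data.frame (needs `genus`, `species`,
#'   `qualifier`, `latitude`).
#' @param strata `"zones"` for climatic zones or `"bins"` for latitudinal
#'   bins.
#' @param bin_width bin width in degrees when `strata = "bins"` (default 5).
#' @param n_points passed to [rarefaction_curve()].
#' @return named list of `rarefaction_curve` objects.
#' @export
rarefaction_by_stratum <- function(records, strata = c("zones", "bins"),
                                   bin_width = 5, n_points = 512) {
  strata <- match.arg(strata)
  use <- records$qualifier == "none" & nzchar(records$species)
  rec <- records[use, , drop = FALSE]
  if (nrow(rec) == 0) return(list())
  stratum <- if (strata == "zones") climatic_zone(rec$latitude) else {
    lo <- floor(rec$latitude / bin_width) * bin_width
    sprintf("[%g,%g)", lo, lo + bin_width)
  }
  sp <- paste(rec$genus, rec$species)
  out <- list()
  for (s in sort(unique(stratum))) {
    counts <- table(sp[stratum == s])
    out[[s]] <- rarefaction_curve(as.integer(counts), n_points = n_points)
  }
  out
}

#' Terminal-slope diagnostic of a rarefaction curve
#'
#' Slope of the curve over the last 10% of its n-range, in species per
#' occurrence. A well-sampled stratum approaches its asymptote, so the
#' terminal slope is near zero.
#'
#' @param curve a [rarefaction_curve()].
#' @param threshold slope below which the curve is flagged asymptotic
#'   (default 0.01 species/occurrence).
#' @return list with `slope`, `flag` (TRUE if `slope < threshold`; `NA` for
#'   a degenerate single-point curve) and `threshold`.
#' @export
asymptote_diagnostic <- function(curve, threshold = 0.01) {
  N <- attr(curve, "N")
  if (nrow(curve) < 2 || N < 2)
    return(list(slope = NA_real_, flag = NA, threshold = threshold))
  n0 <- N - 0.1 * (N - 1)
  tail_pts <- curve[curve$n >= n0, , drop = FALSE]
  if (nrow(tail_pts) < 2)
    tail_pts <- curve[(nrow(curve) - 1):nrow(curve), , drop = FALSE]
  span <- range(tail_pts$n)
  slope <- (tail_pts$expected[which.max(tail_pts$n)] -
              tail_pts$expected[which.min(tail_pts$n)]) /
    (span[2] - span[1])
  list(slope = slope, flag = slope < threshold, threshold = threshold)
}

#' Export rarefaction curves as long-format CSV
#'
#' @param curves named list from [rarefaction_by_stratum()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_rarefaction_csv <- function(curves, path) {
  long <- do.call(rbind, lapply(names(curves), function(s)
    data.frame(stratum = s, n = curves[[s]]$n,
               expected_S = curves[[s]]$expected)))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
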