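#' Demand-generation parameters
#'
#' Parameters converting reef geometry into annual coral demand. A reef of
#' area `A` (km2) is idealized as a disc of radius `r_r = sqrt(A / pi)`
#' (metres after unit conversion). Restoration targets an atoll: an annular
#' band of width `r_width` centred on the reef perimeter. Small reefs whose
#' radius is at or below `disc_threshold` are restored over the whole
#' (outward-buffered) disc instead.
#'
#' @param d_c planting density, corals per m2 restored (default 1).
#' @param r_width width of the restoration atoll in metres (default 20).
#' @param disc_threshold radius in metres at or below which the whole disc
#'   is restored (default 100).
#' @return an object of class `demand_params`.
#' @export
demand_params <- function(d_c = 1, r_width = 20, disc_threshold = 100) {
  stopifnot(is.numeric(d_c), length(d_c) == 1L, is.finite(d_c),
            is.numeric(r_width), length(r_width) == 1L, is.finite(r_width),
            is.numeric(disc_threshold), length(disc_threshold) == 1L)
  if (d_c <= 0) stop("planting density 'd_c' must be > 0", call. = FALSE)
  if (r_width <= 0) stop("'r_width' must be > 0", call. = FALSE)
  if (disc_threshold < 0) stop("'disc_threshold' must be >= 0", call. = FALSE)
  structure(list(d_c = d_c, r_width = r_width, disc_threshold = disc_threshold),
            class = "demand_params")
}

#' Equivalent-disc radius of a reef
#'
#' Inverts the disc-area formula: a reef of `area` km2 has radius
#' `sqrt(area * 1e6 / pi)` metres.
#'
#' @param area reef area(s) in km2, > 0.
#' @return radius in metres.
#' @export
#' @examples
#' reef_radius(pi * 200^2 * 1e-6) # 200 m
reef_radius <- function(area) {
  if (!is.numeric(area) || any(!is.finite(area)) || any(area <= 0)) {
    stop("reef 'area' must be finite and > 0 (km2)", call. = FALSE)
  }
  sqrt(area * 1e6 / pi)
}

#' Annual coral demand of each reef
#'
#' Computes the restored area implied by the atoll geometry and multiplies
#' by the planting density. For reef radius `r` (m) and atoll width `w`:
#' if `r <= disc_threshold` the whole buffered disc `pi (r + w/2)^2` is
#' restored; otherwise the annulus
#' `pi ((r + w/2)^2 - (r - w/2)^2) = 2 pi r w` centred on the perimeter.
#'
#' @param reefs a reef data.frame with column `area_km2` (see
#'   [read_reefs_csv()] / [generate_synthetic_reefs()]).
#' @param params a [demand_params()].
#' @return numeric vector of corals per year, one per reef.
#' @export
#' @examples
#' rf <- data.frame(id = "r1", lat = -17, lon = 146,
#'                  area_km2 = pi * 200^2 * 1e-6)
#' reef_demand(rf, demand_params()) # pi * (210^2 - 190^2) = 25132.74
reef_demand <- function(reefs, params = demand_params()) {
  stopifnot(is.data.frame(reefs), "area_km2" %in% names(reefs),
            inherits(params, "demand_params"))
  r <- reef_radius(reefs$area_km2)
  half <- params$r_width / 2
  disc <- pi * (r + half)^2
  annulus <- pi * ((r + half)^2 - (r - half)^2)
  params$d_c * ifelse(r <= params$disc_threshold, disc, annulus)
}

#' Aggregate reefs into vessel-capacity-respecting clusters
#'
#' Sweeps the reef list from north to south (latitude descending; ties
#' broken by longitude ascending, then id) and greedily accumulates
#' adjacent reefs into the current cluster while the cluster's cumulative
#' annual demand stays within the vessel capacity `s_c`. A reef whose own
#' demand exceeds `s_c` forms a singleton cluster. Cluster coordinates are
#' the unweighted arithmetic mean of member coordinates, and each cluster
#' carries an intra-cluster distance allowance (see
#' [intra_cluster_allowance()]) added to every return trip that serves it.
#'
#' @param reefs reef data.frame with columns `id`, `lat`, `lon`, `area_km2`.
#' @param s_c vessel capacity in coral units per trip, > 0.
#' @param params a [demand_params()] used to compute per-reef demands.
#' @return an object of class `reef_clusters`: a data.frame with columns
#'   `id`, `n_reefs`, `centroid_lat`, `centroid_lon`, `annual_demand`,
#'   `intra_allowance_km`, and a `members` attribute listing member reef ids
#'   per cluster in sweep order.
#' @export
sweep_cluster <- function(reefs, s_c, params = demand_params()) {
  stopifnot(is.data.frame(reefs),
            all(c("id", "lat", "lon", "area_km2") %in% names(reefs)))
  if (!is.numeric(s_c) || length(s_c) != 1L || !is.finite(s_c) || s_c <= 0) {
    stop("vessel capacity 's_c' must be a single value > 0", call. = FALSE)
  }
  if (nrow(reefs) == 0L) {
    out <- data.frame(id = character(), n_reefs = integer(),
                      centroid_lat = numeric(), centroid_lon = numeric(),
                      annual_demand = numeric(), intra_allowance_km = numeric())
    attr(out, "members") <- list()
    class(out) <- c("reef_clusters", "data.frame")
    return(out)
  }
  check_coords(reefs$lat, reefs$lon, where = "reefs")
  ord <- order(-reefs$lat, reefs$lon, as.character(reefs$id))
  reefs <- reefs[ord, , drop = FALSE]
  dem <- reef_demand(reefs, params)

  grp <- integer(nrow(reefs))
  g <- 1L
  acc <- 0
  for (k in seq_len(nrow(reefs))) {
    if (k == 1L) {
      acc <- dem[k]
    } else if (acc + dem[k] <= s_c) {
      acc <- acc + dem[k]
    } else {
      g <- g + 1L
      acc <- dem[k]
    }
    grp[k] <- g
  }

  idx <- split(seq_len(nrow(reefs)), grp)
  out <- data.frame(
    id = sprintf("cl_%03d", seq_along(idx)),
    n_reefs = vapply(idx, length, integer(1)),
    centroid_lat = vapply(idx, function(i) mean(reefs$lat[i]), numeric(1)),
    centroid_lon = vapply(idx, function(i) mean(reefs$lon[i]), numeric(1)),
    annual_demand = vapply(idx, function(i) sum(dem[i]), numeric(1)),
    row.names = NULL
  )
  out$intra_allowance_km <- vapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    2 * sum(haversine_km(out$centroid_lat[k], out$centroid_lon[k],
                         reefs$lat[i], reefs$lon[i]))
  }, numeric(1))
  attr(out, "members") <- unname(lapply(idx, function(i) as.character(reefs$id[i])))
  class(out) <- c("reef_clusters", "data.frame")
  out
}

#' Intra-cluster distance allowance
#'
#' Extra per-trip distance (km) added when a vessel serves a multi-reef
#' cluster, modelled as a round-trip star tour from the cluster centroid:
#' `2 * sum over member reefs of d(centroid, reef)`. Grows with the number
#' of demand points in the cluster; zero for a singleton cluster whose
#' centroid coincides with its reef.
#'
#' @param centroid_lat,centroid_lon cluster centroid, decimal degrees.
#' @param member_lat,member_lon member reef coordinates.
#' @return allowance in km.
#' @export
intra_cluster_allowance <- function(centroid_lat, centroid_lon,
                                    member_lat, member_lon) {
  if (length(member_lat) == 0L) stop("cluster must have >= 1 member", call. = FALSE)
  2 * sum(haversine_km(centroid_lat, centroid_lon, member_lat, member_lon))
}

#' Reproducible random subset of reefs
#'
#' Uniform sample of `n` reefs without replacement under an explicit seed;
#' the global random state is left untouched.
#'
#' @param reefs reef data.frame.
#' @param n subset size, `n <= nrow(reefs)`.
#' @param seed integer seed.
#' @return the sampled rows of `reefs` (original row order preserved).
#' @export
select_reef_subset <- function(reefs, n, seed) {
  stopifnot(is.data.frame(reefs))
  if (n > nrow(reefs)) stop("subset size 'n' exceeds number of reefs", call. = FALSE)
  keep <- with_seed(seed, sort(sample.int(nrow(reefs), n)))
  reefs[keep, , drop = FALSE]
}
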