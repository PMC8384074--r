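#' Great-circle distance between points on Earth
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' recycled to a common length.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Distances in km.
#' @examples
#' haversine_km(0, 0, 1, 0)   # ~111.19 km along the equator
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  if (!all(is.finite(lon1), is.finite(lat1), is.finite(lon2), is.finite(lat2)))
    stop("haversine_km: coordinates must be finite")
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  # clamp guards tiny negative/overshoot from floating arithmetic
  2 * 6371 * asin(sqrt(pmin(pmax(a, 0), 1)))
}

#' Connection-cost policy
#'
#' Controls how inter-cell hop costs are penalized by habitability and
#' whether the full pairwise matrix or a locally truncated one is built.
#' Non-habitable (e.g. aquatic) cells are `aquatic_factor` times as
#' difficult to cross as habitable ones (default twice).
#'
#' @param terrestrial_factor Positive multiplier for habitable cells.
#' @param aquatic_factor Positive multiplier for non-habitable cells.
#' @param mode `"full"` (all habitable pairs) or `"local"` (entries beyond
#'   `local_range_km` are dropped).
#' @param local_range_km Truncation radius for `mode = "local"`.
#' @return An object of class `cost_policy`.
#' @export
cost_policy <- function(terrestrial_factor = 1, aquatic_factor = 2,
                        mode = c("full", "local"), local_range_km = Inf) {
  mode <- match.arg(mode)
  if (terrestrial_factor <= 0 || aquatic_factor <= 0)
    stop("cost_policy: factors must be > 0")
  if (mode == "local" && !(is.finite(local_range_km) && local_range_km > 0))
    stop("cost_policy: local mode needs a positive finite local_range_km")
  structure(list(terrestrial_factor = terrestrial_factor,
                 aquatic_factor = aquatic_factor,
                 mode = mode, local_range_km = local_range_km),
            class = "cost_policy")
}

## 8-neighbour (queen) grid edges, optionally wrapping in longitude.
## Sites are row-major, latitude rows ordered north to south.
grid_edges <- function(sites, n_lon, n_lat, wrap = FALSE) {
  stopifnot(nrow(sites) == n_lon * n_lat)
  id_at <- function(r, c) (r - 1L) * n_lon + c
  from <- integer(0); to <- integer(0)
  offs <- list(c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  for (off in offs) {
    dr <- off[1L]; dc <- off[2L]
    r <- rep(seq_len(n_lat), each = n_lon)
    c <- rep(seq_len(n_lon), times = n_lat)
    r2 <- r + dr
    c2 <- c + dc
    if (wrap) c2 <- ((c2 - 1L) %% n_lon) + 1L
    keep <- r2 >= 1L & r2 <= n_lat & c2 >= 1L & c2 <= n_lon & !(r2 == r & c2 == c)
    from <- c(from, id_at(r[keep], c[keep]))
    to <- c(to, id_at(r2[keep], c2[keep]))
  }
  dup <- from == to
  from <- from[!dup]; to <- to[!dup]
  key <- paste(pmin(from, to), pmax(from, to))
  uni <- !duplicated(key)
  from <- from[uni]; to <- to[uni]
  len <- haversine_km(sites$lon[from], sites$lat[from],
                      sites$lon[to], sites$lat[to])
  data.frame(i = from, j = to, len = len)
}

#' Construct a dynamic landscape
#'
#' A dynamic landscape is a fixed grid of sites plus an ordered series of
#' environmental slices (oldest to present). Each slice carries per-site
#' temperature (normalized units, 0.01 unit = 1 degree C) and aridity in
#' \[0, 1\]; a site is habitable at a slice iff both values are non-missing.
#'
#' @param sites Data frame with columns `id`, `lon`, `lat` in row-major grid
#'   order (northernmost row first).
#' @param slices List of slices; each a list with elements `temperature` and
#'   `aridity` (numeric vectors over sites, `NA` = uninhabitable) and
#'   optionally `duration_kyr`.
#' @param n_lon,n_lat Grid dimensions.
#' @param wrap Wrap-around in longitude (global worlds).
#' @param policy A [cost_policy()].
#' @param duration_kyr Default slice duration in kyr (170, the engine's
#'   canonical time step).
#' @return An object of class `dynamic_landscape`.
#' @export
dynamic_landscape <- function(sites, slices, n_lon, n_lat, wrap = FALSE,
                              policy = cost_policy(), duration_kyr = 170) {
  if (length(slices) < 1L) stop("dynamic_landscape: need at least one slice")
  n <- n_lon * n_lat
  if (nrow(sites) != n) stop("dynamic_landscape: sites do not match grid dims")
  if (!identical(as.integer(sites$id), seq_len(n)))
    stop("dynamic_landscape: site ids must be 1..n in row-major order")
  if (!all(is.finite(sites$lon)) || !all(is.finite(sites$lat)))
    stop("dynamic_landscape: non-finite coordinates")
  n_slices <- length(slices)
  for (k in seq_len(n_slices)) {
    sl <- slices[[k]]
    if (length(sl$temperature) != n || length(sl$aridity) != n)
      stop("dynamic_landscape: slice ", k, " does not match the site set")
    ar <- sl$aridity[!is.na(sl$aridity)]
    if (length(ar) && (min(ar) < 0 || max(ar) > 1))
      stop("dynamic_landscape: aridity must lie in [0, 1]")
    if (is.null(sl$duration_kyr)) slices[[k]]$duration_kyr <- duration_kyr
    slices[[k]]$step <- n_slices - k   # counts down to 0 at present
  }
  obj <- structure(list(sites = sites, slices = slices, n_lon = n_lon,
                        n_lat = n_lat, wrap = wrap, cost_policy = policy),
                   class = "dynamic_landscape")
  obj$edges <- grid_edges(sites, n_lon, n_lat, wrap)
  obj
}

#' @export
print.dynamic_landscape <- function(x, ...) {
  cat(sprintf("dynamic_landscape: %d x %d grid (%d sites), %d slices, wrap=%s\n",
              x$n_lon, x$n_lat, nrow(x$sites), length(x$slices), x$wrap))
  hab <- habitable_sites(x, x$slices[[length(x$slices)]]$step)
  cat(sprintf("  habitable at present: %d sites\n", sum(hab)))
  invisible(x)
}

slice_for_step <- function(landscape, step) {
  n <- length(landscape$slices)
  k <- n - step
  if (k < 1L || k > n) stop("no slice for step ", step)
  landscape$slices[[k]]
}

#' Habitability mask of a slice
#'
#' A site is habitable iff its temperature and aridity are both non-missing
#' (and, when the slice carries a `mask`, the mask is `TRUE`).
#'
#' @param landscape A [dynamic_landscape()].
#' @param step Step index (0 = present).
#' @return Logical vector over sites.
#' @export
habitable_sites <- function(landscape, step) {
  sl <- slice_for_step(landscape, step)
  hab <- !is.na(sl$temperature) & !is.na(sl$aridity)
  if (!is.null(sl$mask)) hab <- hab & sl$mask
  hab
}

#' Build the connection-cost matrix of one slice
#'
#' Pairwise connection costs (km-equivalents) between habitable sites,
#' computed as shortest paths over the 8-neighbour grid graph. Each hop is
#' weighted by its haversine length times the mean of the crossing factors
#' of its two endpoint cells (`aquatic_factor` for non-habitable cells), so
#' the matrix is symmetric and paths respond to intervening barriers.
#'
#' @param landscape A [dynamic_landscape()].
#' @param step Step index of the slice.
#' @param policy A [cost_policy()]; defaults to the landscape's.
#' @return Symmetric numeric matrix over habitable sites (dimnames = site
#'   ids); `Inf` marks pairs that are unreachable or, in local mode, beyond
#'   `local_range_km`. Zero-row matrix if no site is habitable.
#' @export
build_cost_matrix <- function(landscape, step, policy = NULL) {
  if (is.null(policy)) policy <- landscape$cost_policy
  hab <- habitable_sites(landscape, step)
  idx <- which(hab)
  if (!length(idx)) {
    m <- matrix(numeric(0), 0, 0)
    return(structure(m, class = c("cost_matrix", class(m))))
  }
  ed <- landscape$edges
  f <- ifelse(hab, policy$terrestrial_factor, policy$aquatic_factor)
  w <- ed$len * (f[ed$i] + f[ed$j]) / 2
  g <- igraph::make_empty_graph(n = nrow(landscape$sites), directed = FALSE)
  g <- igraph::add_edges(g, rbind(ed$i, ed$j))
  m <- igraph::distances(g, v = idx, to = idx, weights = w,
                         algorithm = "dijkstra")
  if (policy$mode == "local") m[m > policy$local_range_km] <- Inf
  diag(m) <- 0
  dimnames(m) <- list(landscape$sites$id[idx], landscape$sites$id[idx])
  structure(m, class = c("cost_matrix", class(m)))
}

#' Export a cost matrix as sparse triplets
#'
#' @param m A matrix from [build_cost_matrix()].
#' @return Data frame `i, j, cost_km` with one row per finite off-diagonal
#'   pair (upper triangle).
#' @export
cost_matrix_triplets <- function(m) {
  if (!nrow(m)) return(data.frame(i = integer(0), j = integer(0),
                                  cost_km = numeric(0)))
  ids <- as.integer(rownames(m))
  ut <- upper.tri(m)
  keep <- ut & is.finite(m)
  idx <- which(keep, arr.ind = TRUE)
  data.frame(i = ids[idx[, 1L]], j = ids[idx[, 2L]], cost_km = m[keep])
}
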