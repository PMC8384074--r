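## Independent oracles and tiny fixture builders used across the suite.

## Brute-force connected components by boolean transitive closure.
bf_components <- function(adj) {
  n <- nrow(adj)
  reach <- adj | diag(TRUE, n)
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach > 0) || all(nxt == reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  for (i in seq_len(n)) comp[i] <- which(reach[i, ])[1L]
  comp
}

## Floyd-Warshall all-pairs shortest paths (independent of igraph).
fw_shortest <- function(w) {
  n <- nrow(w)
  d <- w
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

## Rebuild the 8-neighbour hop-weight matrix of a landscape slice from
## scratch (no shared code with the package's grid_edges).
hop_weights <- function(landscape, step, policy = landscape$cost_policy) {
  s <- landscape$sites
  n <- nrow(s)
  hab <- habitable_sites(landscape, step)
  f <- ifelse(hab, policy$terrestrial_factor, policy$aquatic_factor)
  n_lon <- landscape$n_lon
  row <- (s$id - 1L) %/% n_lon + 1L
  col <- (s$id - 1L) %% n_lon + 1L
  w <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dr <- abs(row[i] - row[j])
      dc <- abs(col[i] - col[j])
      if (landscape$wrap) dc <- min(dc, n_lon - dc)
      if (dr <= 1L && dc <= 1L) {
        len <- haversine_km(s$lon[i], s$lat[i], s$lon[j], s$lat[j])
        w[i, j] <- len * (f[i] + f[j]) / 2
      }
    }
  }
  w
}

## Small landscape from a list of temperature matrices (rows = latitude,
## north first), all-zero aridity, regular grid of `res` degrees.
toy_landscape <- function(tmats, res = 1, duration_kyr = 170,
                          policy = cost_policy(), wrap = FALSE) {
  n_lat <- nrow(tmats[[1L]]); n_lon <- ncol(tmats[[1L]])
  lons <- (seq_len(n_lon) - 0.5 - n_lon / 2) * res
  lats <- (n_lat / 2 - seq_len(n_lat) + 0.5) * res
  sites <- data.frame(id = seq_len(n_lon * n_lat),
                      lon = rep(lons, times = n_lat),
                      lat = rep(lats, each = n_lon))
  slices <- lapply(tmats, function(m) {
    tt <- as.vector(t(m))  # row-major
    aa <- ifelse(is.na(tt), NA_real_, 0)
    list(temperature = tt, aridity = aa, duration_kyr = duration_kyr)
  })
  dynamic_landscape(sites, slices, n_lon, n_lat, wrap = wrap,
                    policy = policy, duration_kyr = duration_kyr)
}

## Null model on a constant kernel: no ecology, no evolution.
null_model <- function(threshold = 6, kernel_km = 400) {
  model_config("null", threshold = threshold,
               kernel = dispersal_kernel("constant", value_km = kernel_km),
               evolution = evolution_rule(enabled = FALSE),
               ecology = ecology_rule("none"),
               divergence = divergence_rate_rule("constant"))
}

## Approximate star discrepancy of points in [0,1]^2, evaluated over the
## grid of boxes anchored at the origin with corners at the sample's
## coordinate values (the standard lower-bound evaluation).
star_discrepancy_2d <- function(pts) {
  xs <- sort(unique(c(pts[, 1L], 1)))
  ys <- sort(unique(c(pts[, 2L], 1)))
  n <- nrow(pts)
  worst <- 0
  for (x in xs) {
    inx <- pts[, 1L] <= x
    cnt <- vapply(ys, function(y) sum(inx & pts[, 2L] <= y), 0)
    worst <- max(worst, max(abs(cnt / n - x * ys)))
  }
  worst
}
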