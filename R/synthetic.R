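## Synthetic desk-scale landscapes: latitudinal-gradient worlds with
## optional deep-time dynamics, an island-ontogeny sequence, and a
## two-bank river-barrier toy. Generators are pure functions of their
## arguments, so fixtures are hash-stable across sessions.

grid_sites <- function(n_lon, n_lat, resolution_deg, lon0 = NULL) {
  if (is.null(lon0)) lon0 <- -n_lon * resolution_deg / 2
  lons <- lon0 + (seq_len(n_lon) - 0.5) * resolution_deg
  lats <- (n_lat / 2 - seq_len(n_lat) + 0.5) * resolution_deg
  data.frame(id = seq_len(n_lon * n_lat),
             lon = rep(lons, times = n_lat),
             lat = rep(lats, each = n_lon))
}

#' Latitudinal-gradient world
#'
#' A regular lon/lat grid with temperature decreasing monotonically from
#' equator to poles, an aridity bump centred on the subtropics, and
#' optional deep-time dynamics: a linear cooling trend (the present
#' equator is exactly `amplitude` colder than the oldest slice) or a
#' sinusoidal oscillation. Temperatures are in normalized units (0.01 unit
#' = 1 degree C) and clamped to \[0, 1\].
#'
#' The default desk world is 20 x 10 cells at 10 degree resolution (no
#' polar rows) over 100 time steps of 170 kyr.
#'
#' @param n_lon,n_lat Grid dimensions.
#' @param n_steps Number of slices (steps `n_steps - 1` down to 0).
#' @param resolution_deg Cell size in degrees.
#' @param t_equator,t_pole Normalized temperature at the equator and at
#'   the poleward grid edge (oldest slice).
#' @param aridity_center,aridity_width,peak_aridity Subtropical aridity
#'   band: centre and half-width in absolute degrees, and peak value.
#' @param dynamics `"static"`, `"cooling_trend"` or `"oscillation"`.
#' @param amplitude Total cooling (trend) or half-range (oscillation), in
#'   normalized units.
#' @param oscillation_period Period of the oscillation in steps.
#' @param land_fraction Fraction of cells kept as land (a deterministic
#'   hash of the site id and `seed` selects which; 1 = all land).
#' @param seed Integer folded into the land-mask hash.
#' @param duration_kyr Step duration.
#' @param wrap Longitude wrap-around.
#' @param policy A [cost_policy()].
#' @return A [dynamic_landscape()].
#' @export
latitudinal_world <- function(n_lon = 20L, n_lat = 10L, n_steps = 100L,
                              resolution_deg = 10,
                              t_equator = 0.8, t_pole = 0.1,
                              aridity_center = 25, aridity_width = 10,
                              peak_aridity = 0.5,
                              dynamics = c("cooling_trend", "static",
                                           "oscillation"),
                              amplitude = 0.1, oscillation_period = 12L,
                              land_fraction = 1, seed = 0L,
                              duration_kyr = 170, wrap = FALSE,
                              policy = cost_policy()) {
  dynamics <- match.arg(dynamics)
  stopifnot(n_lon >= 2L, n_lat >= 2L, n_steps >= 1L)
  sites <- grid_sites(n_lon, n_lat, resolution_deg)
  lat_edge <- max(abs(sites$lat)) + resolution_deg / 2
  t_base <- t_equator - (t_equator - t_pole) * abs(sites$lat) / lat_edge
  arid <- peak_aridity *
    pmax(0, 1 - abs(abs(sites$lat) - aridity_center) / aridity_width)
  land <- if (land_fraction >= 1) rep(TRUE, nrow(sites))
          else (((sites$id + as.integer(seed)) * 2654435761) %%
                  65536) / 65536 < land_fraction
  slices <- lapply(seq_len(n_steps), function(i) {
    delta <- switch(dynamics,
      static = 0,
      cooling_trend = if (n_steps == 1L) 0 else
        -amplitude * (i - 1) / (n_steps - 1),
      oscillation = amplitude * sin(2 * pi * (i - 1) / oscillation_period))
    tt <- pmin(pmax(t_base + delta, 0), 1)
    tt[!land] <- NA_real_
    aa <- arid
    aa[!land] <- NA_real_
    list(temperature = tt, aridity = aa, duration_kyr = duration_kyr)
  })
  dynamic_landscape(sites, slices, n_lon, n_lat, wrap = wrap,
                    policy = policy, duration_kyr = duration_kyr)
}

#' Island-ontogeny world
#'
#' A single oceanic island that grows to its maximum area at the midpoint
#' of the sequence and then shrinks back (triangular area profile), with a
#' configurable temporal variability of temperature. Cells within the
#' current radius of the island centre are habitable; everything else is
#' sea.
#'
#' @param n_lon,n_lat Grid dimensions.
#' @param n_steps Number of slices.
#' @param resolution_deg Cell size in degrees.
#' @param r_min,r_max Island radius (in cells) at the ends and at the
#'   midpoint of the sequence.
#' @param base_temp Normalized temperature at the island centre.
#' @param variability Amplitude of the sinusoidal temperature variability.
#' @param duration_kyr Step duration.
#' @return A [dynamic_landscape()].
#' @export
island_ontogeny <- function(n_lon = 9L, n_lat = 9L, n_steps = 41L,
                            resolution_deg = 1, r_min = 1, r_max = 4,
                            base_temp = 0.7, variability = 0.02,
                            duration_kyr = 170) {
  stopifnot(r_min >= 0, r_max >= r_min, n_steps >= 3L)
  sites <- grid_sites(n_lon, n_lat, resolution_deg)
  cr <- (n_lon + 1) / 2; rr <- (n_lat + 1) / 2
  col <- (sites$id - 1L) %% n_lon + 1L
  row <- (sites$id - 1L) %/% n_lon + 1L
  dist_cells <- sqrt((col - cr)^2 + (row - rr)^2)
  slices <- lapply(seq_len(n_steps), function(i) {
    u <- (i - 1) / (n_steps - 1)
    r_i <- r_min + (r_max - r_min) * (1 - abs(2 * u - 1))
    on_island <- dist_cells <= r_i
    tt <- base_temp - 0.2 * dist_cells / max(r_max, 1) +
      variability * sin(2 * pi * (i - 1) / 8)
    tt <- pmin(pmax(tt, 0), 1)
    tt[!on_island] <- NA_real_
    aa <- rep(0, nrow(sites))
    aa[!on_island] <- NA_real_
    list(temperature = tt, aridity = aa, duration_kyr = duration_kyr)
  })
  dynamic_landscape(sites, slices, n_lon, n_lat, wrap = FALSE,
                    duration_kyr = duration_kyr)
}

#' Two-bank river-barrier toy world
#'
#' A fixed small world: two terrestrial blocks separated by a one-cell
#' wide non-habitable river running north-south. With the default cost
#' policy the river is twice as difficult to cross as land, so a species
#' occupying both banks forms two geographic clusters whenever its
#' clustering distance falls below the river-crossing cost. The world is
#' identical across calls (no randomness).
#'
#' @param n_lon,n_lat Grid dimensions (the river occupies the middle
#'   column).
#' @param n_steps Number of identical slices.
#' @param resolution_deg Cell size in degrees.
#' @param temp Uniform normalized temperature of the land cells.
#' @param duration_kyr Step duration.
#' @param policy A [cost_policy()].
#' @return A [dynamic_landscape()].
#' @export
barrier_toy <- function(n_lon = 8L, n_lat = 6L, n_steps = 12L,
                        resolution_deg = 2, temp = 0.5,
                        duration_kyr = 170, policy = cost_policy()) {
  sites <- grid_sites(n_lon, n_lat, resolution_deg)
  river_col <- n_lon %/% 2
  col <- (sites$id - 1L) %% n_lon + 1L
  land <- col != river_col
  tt <- rep(temp, nrow(sites)); tt[!land] <- NA_real_
  aa <- rep(0, nrow(sites)); aa[!land] <- NA_real_
  slices <- rep(list(list(temperature = tt, aridity = aa,
                          duration_kyr = duration_kyr)), n_steps)
  dynamic_landscape(sites, slices, n_lon, n_lat, wrap = FALSE,
                    policy = policy, duration_kyr = duration_kyr)
}
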