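## Pattern-oriented summary statistics: latitudinal diversity gradient
## slope and curve, beta-splitting tree imbalance, normalized
## lineage-through-time differences, range-size spectra, latitude-band
## event rates, and the combined acceptance verdict.

band_index <- function(lat, band_deg) floor(abs(lat) / band_deg)

#' Latitudinal diversity gradient slope (% loss per degree)
#'
#' Mean richness per absolute-latitude band, normalized by its maximum, is
#' regressed on band-centre absolute latitude by ordinary least squares;
#' the statistic is minus the slope times 100, i.e. the percentage of
#' species lost per degree of latitude (positive = poleward decline).
#'
#' @param richness Per-site species counts.
#' @param lat Site latitudes (degrees), parallel to `richness`.
#' @param band_deg Band width in degrees (default: the grid's latitude
#'   resolution, inferred from distinct latitudes).
#' @return Slope in % per degree.
#' @export
ldg_percent_loss <- function(richness, lat, band_deg = NULL) {
  if (all(richness == 0)) stop("ldg_percent_loss: all-zero richness")
  if (is.null(band_deg)) {
    ul <- sort(unique(lat))
    band_deg <- if (length(ul) > 1L) min(diff(ul)) else 1
  }
  b <- band_index(lat, band_deg)
  mean_r <- tapply(richness, b, mean)
  if (length(mean_r) < 2L)
    stop("ldg_percent_loss: need at least two latitude bands")
  x <- (as.numeric(names(mean_r)) + 0.5) * band_deg
  y <- as.numeric(mean_r) / max(mean_r)
  -unname(stats::coef(stats::lm(y ~ x))[2L]) * 100
}

#' Correlation of the latitudinal richness curve with a reference
#'
#' The simulated curve is the per-band mean richness divided by the count
#' of habitable sites in the band (area scaling) and scaled to a maximum of
#' one (standardization); the statistic is its Pearson correlation with a
#' reference curve over the common latitude bands.
#'
#' @param richness,lat Per-site species counts and latitudes.
#' @param reference Data frame with columns `band` (band index, i.e.
#'   `floor(|lat| / band_deg)`) and `value`.
#' @param habitable Logical vector marking habitable sites (area scaling
#'   denominator); defaults to all sites.
#' @param band_deg Band width in degrees.
#' @return Pearson r.
#' @export
ldg_curve_correlation <- function(richness, lat, reference,
                                  habitable = NULL, band_deg = NULL) {
  if (is.null(band_deg)) {
    ul <- sort(unique(lat))
    band_deg <- if (length(ul) > 1L) min(diff(ul)) else 1
  }
  if (is.null(habitable)) habitable <- rep(TRUE, length(lat))
  b <- band_index(lat, band_deg)
  mean_r <- tapply(richness, b, mean)
  n_hab <- tapply(habitable, b, sum)
  curve <- as.numeric(mean_r) / pmax(as.numeric(n_hab), 1L)
  if (max(curve) > 0) curve <- curve / max(curve)
  bands <- as.numeric(names(mean_r))
  common <- intersect(bands, reference$band)
  if (length(common) < 3L)
    stop("ldg_curve_correlation: fewer than 3 common latitude bands")
  stats::cor(curve[match(common, bands)],
             reference$value[match(common, reference$band)])
}

## Log-likelihood of Aldous' beta-splitting model for one tree topology.
## For an internal node whose n descendant tips split i | n - i,
## q_beta(i | n) is proportional to
## Gamma(b+i+1) Gamma(b+n-i+1) / (Gamma(i+1) Gamma(n-i+1)), normalized by
## explicit summation over i = 1..n-1.
beta_split_loglik <- function(splits, beta) {
  ll <- 0
  for (ns in unique(splits$n)) {
    i_all <- seq_len(ns - 1L)
    logq <- lgamma(beta + i_all + 1) + lgamma(beta + ns - i_all + 1) -
      lgamma(i_all + 1) - lgamma(ns - i_all + 1)
    logZ <- max(logq) + log(sum(exp(logq - max(logq))))
    ii <- splits$i[splits$n == ns]
    ll <- ll + sum(logq[ii] - logZ)
  }
  ll
}

tree_splits <- function(tree) {
  if (!ape::is.binary(tree)) {
    warning("beta_splitting_ml: resolving polytomies arbitrarily")
    tree <- ape::multi2di(tree)
  }
  n_tip <- length(tree$tip.label)
  # number of descendant tips under every node
  n_desc <- integer(n_tip + tree$Nnode)
  n_desc[seq_len(n_tip)] <- 1L
  tree <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    n_desc[tree$edge[e, 1L]] <- n_desc[tree$edge[e, 1L]] +
      n_desc[tree$edge[e, 2L]]
  }
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  i_side <- vapply(internal, function(v)
    n_desc[kids[[as.character(v)]][1L]], 0L)
  data.frame(n = n_desc[internal], i = i_side)
}

#' Maximum-likelihood beta-splitting imbalance of a tree
#'
#' Fits Aldous' beta-splitting model to the tree topology by maximizing
#' the sum over internal nodes of the log split probabilities, with a
#' bounded one-dimensional search over beta in (-2, 10]. beta = 0
#' corresponds to Yule trees; more negative values indicate more
#' imbalanced trees. The statistic depends only on topology (invariant to
#' tip labels and branch lengths).
#'
#' @param tree An ape `phylo` with at least 3 tips; soft polytomies are
#'   resolved arbitrarily with a warning.
#' @return Fitted beta.
#' @export
beta_splitting_ml <- function(tree) {
  if (is.null(tree) || length(tree$tip.label) < 3L)
    stop("beta_splitting_ml: need a tree with >= 3 tips")
  splits <- tree_splits(tree)
  splits <- splits[splits$n > 2L | splits$i >= 1L, , drop = FALSE]
  opt <- stats::optimize(function(b) beta_split_loglik(splits, b),
                         interval = c(-2 + 1e-8, 10), maximum = TRUE,
                         tol = 1e-6)
  opt$maximum
}

ltt_curve <- function(tree) {
  n <- length(tree$tip.label)
  bt <- sort(as.numeric(ape::branching.times(tree)), decreasing = TRUE)
  depth <- bt[1L]
  if (depth <= 0) stop("nltt_difference: degenerate (zero-depth) tree")
  # normalized time of each branching, root at 0, present at 1; clamp
  # and enforce monotonicity against floating error in node depths
  times <- c(0, (depth - bt[-1L]) / depth, 1)
  times <- cummax(pmin(pmax(times, 0), 1))
  counts <- c(seq(2L, n), n) / n
  list(t = times, y = counts)
}

#' Normalized lineage-through-time difference between two trees
#'
#' Both LTT curves are normalized to time in \[0, 1\] (root to present) and
#' lineage counts in (0, 1\] (divided by the final count); the statistic is
#' the integral over \[0, 1\] of the absolute difference between the two
#' step functions, evaluated on the merged breakpoint grid. It lies in
#' \[0, 1\] and is zero iff the normalized curves coincide.
#'
#' @param tree_a,tree_b Ultrametric `phylo` trees with >= 2 tips.
#' @return Value in \[0, 1\].
#' @export
nltt_difference <- function(tree_a, tree_b) {
  if (is.null(tree_a) || is.null(tree_b) ||
      length(tree_a$tip.label) < 2L || length(tree_b$tip.label) < 2L)
    stop("nltt_difference: need two trees with >= 2 tips")
  a <- ltt_curve(tree_a)
  b <- ltt_curve(tree_b)
  grid <- sort(unique(c(a$t, b$t)))
  step_at <- function(curve, t) {
    idx <- findInterval(t, curve$t, rightmost.closed = TRUE)
    curve$y[pmax(idx, 1L)]
  }
  lefts <- grid[-length(grid)]
  widths <- diff(grid)
  sum(abs(step_at(a, lefts) - step_at(b, lefts)) * widths)
}

#' Range-size spectrum and species-range-decrease slope
#'
#' Range size is the occupied-site count times the mean cell area;
#' frequencies are binned into doubling (octave) bins of range size. The
#' SRD slope is the OLS slope of log10(frequency + 1) on the bin midpoint
#' (log2 range size); the monotone-decrease check allows a bin to exceed
#' its left neighbour by at most `tolerance` of the total species count.
#'
#' @param range_sizes Per-species range sizes (km^2), e.g. occupied-site
#'   counts times mean cell area.
#' @param tolerance Allowed increase per bin, as a fraction of the total
#'   species count.
#' @return List with `histogram` (data frame `bin, midpoint, frequency`),
#'   `srd_slope`, and `decrease_ok`.
#' @export
range_size_stats <- function(range_sizes, tolerance = 0.05) {
  if (!length(range_sizes)) stop("range_size_stats: no species")
  bins <- floor(log2(pmax(range_sizes, 1e-12)))
  bins <- bins - min(bins)
  freq <- tabulate(bins + 1L, nbins = max(bins) + 1L)
  hist <- data.frame(bin = seq_along(freq) - 1L,
                     midpoint = seq_along(freq) - 0.5,
                     frequency = freq)
  n_tot <- length(range_sizes)
  incr <- diff(freq)
  decrease_ok <- all(incr <= tolerance * n_tot)
  srd_slope <- if (nrow(hist) >= 2L)
    unname(stats::coef(stats::lm(log10(freq + 1) ~ hist$midpoint))[2L])
  else NA_real_
  list(histogram = hist, srd_slope = srd_slope, decrease_ok = decrease_ok)
}

#' Speciation, extinction and migration rates by latitude band
#'
#' Counts events per 1-Myr window within low (|lat| below the tropic line,
#' 23.45 degrees) and high (tropic line to polar line, 66.55 degrees)
#' latitudes. Speciation events are placed at the new species' origin
#' centroid, extinctions at the last centroid, and migrations are
#' colonizations whose source and target fall in different bands
#' (counted separately for low-to-high and high-to-low).
#'
#' @param genealogy Genealogy data frame of a run (with `origin_lat` and
#'   `extinction_lat`).
#' @param migrations Data frame `step, lat_from, lat_to` of colonizations.
#' @param duration_kyr Step duration in kyr.
#' @param tropic_deg,polar_deg Band boundaries in absolute degrees.
#' @return Data frame `window_myr, speciation_low, speciation_high,
#'   extinction_low, extinction_high, migration_low_high,
#'   migration_high_low`.
#' @export
band_rates <- function(genealogy, migrations, duration_kyr = 170,
                       tropic_deg = 23.45, polar_deg = 66.55) {
  myr <- duration_kyr / 1000
  band_of <- function(lat) {
    al <- abs(lat)
    ifelse(al < tropic_deg, "low", ifelse(al <= polar_deg, "high", NA))
  }
  win_of <- function(step) floor(step * myr)
  spl <- genealogy[!is.na(genealogy$parent_id), , drop = FALSE]
  ext <- genealogy[!is.na(genealogy$extinction_step), , drop = FALSE]
  max_win <- max(c(0, win_of(spl$origin_step), win_of(ext$extinction_step),
                   if (nrow(migrations)) win_of(migrations$step)))
  wins <- 0:max_win
  count <- function(w, b, target_w, target_b)
    sum(target_w == w & !is.na(target_b) & target_b == b)
  sw <- win_of(spl$origin_step); sb <- band_of(spl$origin_lat)
  ew <- win_of(ext$extinction_step); eb <- band_of(ext$extinction_lat)
  mw <- win_of(migrations$step)
  mfrom <- band_of(migrations$lat_from); mto <- band_of(migrations$lat_to)
  cross_lh <- !is.na(mfrom) & !is.na(mto) & mfrom == "low" & mto == "high"
  cross_hl <- !is.na(mfrom) & !is.na(mto) & mfrom == "high" & mto == "low"
  data.frame(
    window_myr = wins,
    speciation_low = vapply(wins, count, 0, b = "low", target_w = sw,
                            target_b = sb),
    speciation_high = vapply(wins, count, 0, b = "high", target_w = sw,
                             target_b = sb),
    extinction_low = vapply(wins, count, 0, b = "low", target_w = ew,
                            target_b = eb),
    extinction_high = vapply(wins, count, 0, b = "high", target_w = ew,
                             target_b = eb),
    migration_low_high = vapply(wins, function(w) sum(mw == w & cross_lh), 0),
    migration_high_low = vapply(wins, function(w) sum(mw == w & cross_hl), 0))
}

#' Pattern-oriented acceptance criteria
#'
#' @param ldg_range Accepted LDG slope range (% per degree).
#' @param beta_range Accepted beta-splitting range.
#' @param ldg_curve_r_min Minimum Pearson r of the latitudinal curve.
#' @param nltt_max Maximum nLTT difference.
#' @param range_decrease_tolerance Tolerance of the range-size decrease
#'   check.
#' @param min_extant Minimum species alive at present.
#' @return An object of class `pom_criteria`.
#' @export
pom_criteria <- function(ldg_range = c(1.1, 5.4),
                         beta_range = c(-1.4, -0.3),
                         ldg_curve_r_min = 0.4, nltt_max = 0.15,
                         range_decrease_tolerance = 0.05,
                         min_extant = 20L) {
  stopifnot(ldg_range[1L] <= ldg_range[2L], beta_range[1L] <= beta_range[2L])
  structure(list(ldg_range = ldg_range, beta_range = beta_range,
                 ldg_curve_r_min = ldg_curve_r_min, nltt_max = nltt_max,
                 range_decrease_tolerance = range_decrease_tolerance,
                 min_extant = min_extant), class = "pom_criteria")
}

#' Evaluate the pattern-oriented acceptance of a statistics bundle
#'
#' Flags each criterion separately and combines them: a simulation is
#' accepted when its LDG slope, tree imbalance, range-size decrease,
#' latitudinal-curve correlation and nLTT difference all fall within the
#' accepted ranges and at least `min_extant` species are alive at present.
#' A statistic passed as `NA` (unavailable) fails its criterion.
#'
#' @param stats Named list with elements `ldg`, `beta`, `range_ok`,
#'   `curve_r`, `nltt`, `extant` (any may be `NA`).
#' @param criteria A [pom_criteria()].
#' @return List of logical flags plus `combined`.
#' @export
pom_acceptance <- function(stats, criteria = pom_criteria()) {
  ok <- function(x, test) !is.na(x) && test(x)
  flags <- list(
    ldg = ok(stats$ldg, function(x)
      x >= criteria$ldg_range[1L] && x <= criteria$ldg_range[2L]),
    beta = ok(stats$beta, function(x)
      x >= criteria$beta_range[1L] && x <= criteria$beta_range[2L]),
    range = ok(stats$range_ok, isTRUE),
    curve = ok(stats$curve_r, function(x) x > criteria$ldg_curve_r_min),
    nltt = ok(stats$nltt, function(x) x < criteria$nltt_max),
    extant = ok(stats$extant, function(x) x >= criteria$min_extant))
  flags$combined <- all(unlist(flags))
  flags
}

#' Mean cell area of a landscape at one slice (km^2)
#'
#' @param landscape A [dynamic_landscape()].
#' @param step Step index.
#' @return Mean area per habitable cell, from the latitude-dependent cell
#'   geometry of a regular lon/lat grid.
#' @export
mean_cell_area_km2 <- function(landscape, step) {
  hab <- habitable_sites(landscape, step)
  s <- landscape$sites[hab, , drop = FALSE]
  lons <- sort(unique(landscape$sites$lon))
  lats <- sort(unique(landscape$sites$lat))
  dlon <- if (length(lons) > 1L) min(diff(lons)) else 1
  dlat <- if (length(lats) > 1L) min(diff(lats)) else 1
  R <- 6371
  area <- (pi / 180) * R^2 * dlon *
    abs(sin((s$lat + dlat / 2) * pi / 180) -
        sin((s$lat - dlat / 2) * pi / 180))
  mean(area)
}
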