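## The four customizable per-step processes: speciation support
## (divergence rates), dispersal, trait evolution, and ecology (niche
## suitability plus optional carrying capacities).

#' Dispersal kernel
#'
#' Either a constant (deterministic) dispersal value or a Weibull
#' distribution of dispersal distances. The defaults are the midpoints of
#' the explored ranges: shape 3.5 (range 2-5) and scale 700 km (range
#' 550-850 km), giving most draws between roughly 500 and 1500 km.
#'
#' @param family `"weibull"` or `"constant"`.
#' @param shape,scale Weibull shape (dimensionless) and scale (km).
#' @param value_km Constant dispersal value (km).
#' @return An object of class `dispersal_kernel`.
#' @export
dispersal_kernel <- function(family = c("weibull", "constant"),
                             shape = 3.5, scale = 700, value_km = NULL) {
  family <- match.arg(family)
  if (family == "weibull") {
    if (shape <= 0 || scale <= 0)
      stop("dispersal_kernel: shape and scale must be > 0")
  } else if (is.null(value_km) || value_km < 0) {
    stop("dispersal_kernel: constant kernel needs value_km >= 0")
  }
  structure(list(family = family, shape = shape, scale = scale,
                 value_km = value_km), class = "dispersal_kernel")
}

#' Draw dispersal distances
#'
#' @param kernel A [dispersal_kernel()].
#' @param n Number of i.i.d. draws.
#' @return Numeric vector of n distances (km).
#' @export
draw_dispersal <- function(kernel, n) {
  if (n < 0) stop("draw_dispersal: n must be >= 0")
  if (kernel$family == "constant") rep(kernel$value_km, n)
  else stats::rweibull(n, shape = kernel$shape, scale = kernel$scale)
}

#' Median dispersal distance of a kernel
#'
#' Used as the deterministic per-species clustering distance: the Weibull
#' median is scale * log(2)^(1/shape).
#'
#' @param kernel A [dispersal_kernel()].
#' @return Median distance (km).
#' @export
kernel_median <- function(kernel) {
  if (kernel$family == "constant") kernel$value_km
  else kernel$scale * log(2)^(1 / kernel$shape)
}

#' Divergence-rate rule
#'
#' Constant mode accumulates `base_rate` divergence units per step between
#' isolated clusters. Temperature mode makes divergence accumulate faster
#' in warmer environments: the rate rises with the species' mean occupied
#' site temperature to the power `d_power` plus a constant, anchored so the
#' warmest sites diverge `max_multiplier` (default 3) times faster than the
#' coldest.
#'
#' @param mode `"constant"` or `"temperature"`.
#' @param base_rate Baseline divergence per step.
#' @param d_power Exponent of the temperature response (explored range
#'   2-6).
#' @param max_multiplier Rate multiplier at the maximum temperature.
#' @return An object of class `divergence_rate_rule`.
#' @export
divergence_rate_rule <- function(mode = c("constant", "temperature"),
                                 base_rate = 1, d_power = 4,
                                 max_multiplier = 3) {
  mode <- match.arg(mode)
  if (base_rate < 0) stop("divergence_rate_rule: base_rate must be >= 0")
  structure(list(mode = mode, base_rate = base_rate, d_power = d_power,
                 max_multiplier = max_multiplier),
            class = "divergence_rate_rule")
}

#' Per-step divergence rate of a species
#'
#' @param rule A [divergence_rate_rule()].
#' @param mean_temp_norm Mean normalized temperature of the species'
#'   occupied sites, in \[0, 1\] (values outside are clamped with a
#'   warning).
#' @return Divergence units per step.
#' @export
divergence_rate <- function(rule, mean_temp_norm) {
  if (rule$mode == "constant") return(rule$base_rate)
  t <- mean_temp_norm
  if (is.na(t)) t <- 0
  if (t < 0 || t > 1) {
    warning("divergence_rate: temperature outside [0, 1] clamped")
    t <- min(max(t, 0), 1)
  }
  rule$base_rate * (1 + (rule$max_multiplier - 1) * t^rule$d_power)
}

#' Evolution rule
#'
#' Brownian-motion evolution of the temperature optimum: each population's
#' `t_opt` receives an independent Normal(0, sigma) increment per step
#' (sigma in normalized trait units; 0.01 unit = 1 degree C, explored range
#' 0.001-0.010). Optima are afterwards homogenized per geographic cluster
#' by an abundance-weighted mean when `homogenize` is on.
#'
#' @param sigma Per-step standard deviation of the trait increment.
#' @param homogenize Homogenize optima within clusters after ecology.
#' @param enabled Turn trait evolution off entirely (null models).
#' @return An object of class `evolution_rule`.
#' @export
evolution_rule <- function(sigma = 0.0055, homogenize = TRUE,
                           enabled = TRUE) {
  if (sigma < 0) stop("evolution_rule: sigma must be >= 0")
  structure(list(sigma = sigma, homogenize = homogenize, enabled = enabled),
            class = "evolution_rule")
}

#' Brownian-motion mutation of the temperature optimum
#'
#' @param species A species object.
#' @param sigma Standard deviation of the per-step Normal increment.
#' @return The species with perturbed `t_opt`.
#' @export
evolution_step <- function(species, sigma) {
  n <- length(species$t_opt)
  if (n && sigma > 0)
    species$t_opt <- species$t_opt + stats::rnorm(n, 0, sigma)
  species
}

#' Homogenize the temperature optimum within geographic clusters
#'
#' Sets every population of a cluster to the abundance-weighted mean
#' optimum of that cluster.
#'
#' @param species A species object.
#' @param labels Cluster labels from [cluster_sites()].
#' @return The species with homogenized `t_opt`.
#' @export
homogenize_traits <- function(species, labels) {
  if (length(unique(labels)) == length(labels)) return(species)
  w <- species$abundance
  wt <- vapply(split(seq_along(labels), labels),
               function(ii) sum(species$t_opt[ii] * w[ii]) / sum(w[ii]), 0)
  species$t_opt <- as.numeric(wt[as.character(labels)])
  species
}

#' Ecology rule
#'
#' `mode = "none"` turns ecological filtering off. `"niche"` sets each
#' population's abundance from the mismatch between its temperature
#' optimum and the site temperature. `"niche+capacity"` additionally
#' enforces a per-site carrying capacity on total abundance, either uniform
#' across sites or scaling with area energy (temperature x (1 - aridity))
#' raised to `k_power`.
#'
#' @param mode `"none"`, `"niche"` or `"niche+capacity"`.
#' @param niche_width Half-width of the suitability ramp in normalized
#'   temperature units (default 0.1, i.e. 10 degrees C).
#' @param a_max Maximum abundance of a perfectly matched population.
#' @param k_base Carrying capacity at maximum energy.
#' @param k_power Power-law scaling of capacity with energy (explored range
#'   1-4).
#' @param energy_source `"uniform"` or `"temp_aridity"`.
#' @param form Suitability shape: `"linear"` ramp or `"gaussian"`.
#' @return An object of class `ecology_rule`.
#' @export
ecology_rule <- function(mode = c("none", "niche", "niche+capacity"),
                         niche_width = 0.1, a_max = 10L, k_base = 50L,
                         k_power = 2.5,
                         energy_source = c("uniform", "temp_aridity"),
                         form = c("linear", "gaussian")) {
  mode <- match.arg(mode)
  energy_source <- match.arg(energy_source)
  form <- match.arg(form)
  if (niche_width <= 0) stop("ecology_rule: niche_width must be > 0")
  if (k_base < 1) stop("ecology_rule: k_base must be >= 1")
  structure(list(mode = mode, niche_width = niche_width,
                 a_max = as.integer(a_max), k_base = as.integer(k_base),
                 k_power = k_power, energy_source = energy_source,
                 form = form), class = "ecology_rule")
}

#' Niche suitability abundance
#'
#' Abundance declines with the mismatch between the population's
#' temperature optimum and the site temperature: a linear ramp of
#' half-width `width` (or a Gaussian of the same scale), scaled to `a_max`
#' and rounded to whole individuals. Zero abundance means local extinction.
#'
#' @param t_opt Population temperature optimum (normalized units).
#' @param site_temp Site temperature (normalized units).
#' @param width Niche half-width (normalized units).
#' @param a_max Maximum abundance.
#' @param form `"linear"` or `"gaussian"`.
#' @return Integer abundances.
#' @export
niche_abundance <- function(t_opt, site_temp, width, a_max,
                            form = c("linear", "gaussian")) {
  form <- match.arg(form)
  d <- abs(t_opt - site_temp)
  s <- if (form == "linear") pmax(0, 1 - d / width)
       else exp(-d^2 / (2 * width^2))
  as.integer(round(a_max * s))
}

#' Site carrying capacity
#'
#' @param temp_norm Normalized site temperature in \[0, 1\].
#' @param aridity Site aridity in \[0, 1\].
#' @param k_base Capacity at maximum energy.
#' @param k_power Power-law modulation of the energy scaling.
#' @param energy_source `"uniform"` (capacity identical at every site) or
#'   `"temp_aridity"` (capacity scales with temperature x (1 - aridity)).
#' @return Integer capacities (individuals), floored at 0.
#' @export
site_capacity <- function(temp_norm, aridity, k_base, k_power,
                          energy_source = c("uniform", "temp_aridity")) {
  energy_source <- match.arg(energy_source)
  if (energy_source == "uniform")
    return(rep(as.integer(k_base), length(temp_norm)))
  energy <- pmin(pmax(temp_norm, 0), 1) * (1 - pmin(pmax(aridity, 0), 1))
  pmax(as.integer(round(k_base * energy^k_power)), 0L)
}

#' Randomly reduce site abundances to the carrying capacity
#'
#' If the summed abundance exceeds `k`, single individual units are removed
#' one at a time, each drawn uniformly from the remaining individuals,
#' until the sum equals `k` (an urn process; the kept individuals follow a
#' multivariate hypergeometric distribution). Species reaching zero are
#' locally extinct.
#'
#' @param abundance Integer abundances of the species present at one site.
#' @param k Site carrying capacity (individuals).
#' @return Integer abundances summing to at most `k`.
#' @export
apply_carrying_capacity <- function(abundance, k) {
  if (k < 0) stop("apply_carrying_capacity: k must be >= 0")
  tot <- sum(abundance)
  if (tot <= k) return(abundance)
  out <- integer(length(abundance))
  left <- tot
  remaining <- as.integer(k)
  for (i in seq_along(abundance)) {
    ai <- abundance[i]
    xi <- stats::rhyper(1L, ai, left - ai, remaining)
    out[i] <- xi
    remaining <- remaining - xi
    left <- left - ai
  }
  out
}

#' Dispersal and colonization of vacant sites
#'
#' For every pair of an occupied source and a habitable site not yet
#' occupied by the species, one kernel draw is made; dispersal succeeds
#' when the connection cost does not exceed the draw. When several sources
#' reach the same vacant site the colonizer is selected uniformly at
#' random. Colonists copy their source's traits and divergence row and
#' receive a founder abundance.
#'
#' @param species A species object.
#' @param costs Cost matrix of the current slice.
#' @param kernel A [dispersal_kernel()].
#' @param habitable_ids Sorted ids of habitable sites at the current slice.
#' @param founder_abundance Abundance granted to a new colonist before its
#'   first ecology step.
#' @param pos Optional site-id to cost-row lookup.
#' @return List with `species` (updated) and `colonized` (data frame
#'   `site, source_site`).
#' @export
dispersal_step <- function(species, costs, kernel, habitable_ids,
                           founder_abundance = 5, pos = NULL) {
  empty <- data.frame(site = integer(0), source_site = integer(0))
  targets <- setdiff(habitable_ids, species$sites)
  ns <- length(species$sites); nt <- length(targets)
  if (!ns || !nt) return(list(species = species, colonized = empty))
  if (is.null(pos)) {
    ids <- as.integer(rownames(costs))
    sp_pos <- match(species$sites, ids)
    tg_pos <- match(targets, ids)
  } else {
    sp_pos <- pos[species$sites]
    tg_pos <- pos[targets]
  }
  cmat <- costs[sp_pos, tg_pos, drop = FALSE]
  draws <- matrix(draw_dispersal(kernel, ns * nt), ns, nt)
  succ <- cmat <= draws
  hit <- which(.colSums(succ, ns, nt) > 0L)
  if (!length(hit)) return(list(species = species, colonized = empty))
  src <- integer(length(hit))
  for (u in seq_along(hit)) {
    w <- which(succ[, hit[u]])
    src[u] <- if (length(w) == 1L) w else w[sample.int(length(w), 1L)]
  }
  new_sites <- targets[hit]
  sp <- add_populations(species, new_sites, src, founder_abundance)
  list(species = sp,
       colonized = data.frame(site = new_sites,
                              source_site = species$sites[src]))
}
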