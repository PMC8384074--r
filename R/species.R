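## Species state: populations (site, abundance, temperature optimum), the
## divergence structure over occupied sites, and split/merge bookkeeping.
## A species is a plain list; population vectors are parallel and kept
## sorted by site id, and the divergence matrix rows/columns follow that
## order.

new_species <- function(id, parent_id, origin_step, sites, abundance, t_opt,
                        divergence = NULL) {
  o <- order(sites)
  sites <- as.integer(sites[o])
  abundance <- abundance[o]
  t_opt <- t_opt[o]
  n <- length(sites)
  if (is.null(divergence)) divergence <- matrix(0, n, n)
  else divergence <- divergence[o, o, drop = FALSE]
  structure(list(id = as.integer(id), parent_id = parent_id,
                 origin_step = as.integer(origin_step),
                 extinction_step = NA_integer_,
                 sites = sites, abundance = abundance, t_opt = t_opt,
                 divergence = divergence),
            class = "species_state")
}

#' @export
print.species_state <- function(x, ...) {
  cat(sprintf("species %d: %d populations, total abundance %g%s\n",
              x$id, length(x$sites), sum(x$abundance),
              if (is.na(x$extinction_step)) ""
              else sprintf(" (extinct at step %d)", x$extinction_step)))
  invisible(x)
}

#' Create ancestor species
#'
#' Seeds the simulation with one or more ancestor species on a landscape
#' slice. By default a single ancestor occupies every habitable site, with
#' the temperature optimum of each population initiated to match local site
#' conditions and an all-zero divergence structure.
#'
#' @param landscape A [dynamic_landscape()].
#' @param step Step index of the initial slice.
#' @param n_ancestors Number of ancestor species.
#' @param ranges `"all_habitable"`, or a list of site-id vectors (one per
#'   ancestor).
#' @param initial_abundance Abundance of each founding population.
#' @param t_opt_rule `"match_local"` (optimum = local site temperature) or a
#'   single numeric value.
#' @return List of species objects with ids `1..n_ancestors`.
#' @export
create_ancestor_species <- function(landscape, step,
                                    n_ancestors = 1L,
                                    ranges = "all_habitable",
                                    initial_abundance = 5,
                                    t_opt_rule = "match_local") {
  sl <- slice_for_step(landscape, step)
  hab <- habitable_sites(landscape, step)
  if (identical(ranges, "all_habitable"))
    ranges <- rep(list(landscape$sites$id[hab]), n_ancestors)
  if (length(ranges) != n_ancestors)
    stop("create_ancestor_species: need one range per ancestor")
  lapply(seq_len(n_ancestors), function(k) {
    ss <- intersect(as.integer(ranges[[k]]), landscape$sites$id[hab])
    if (!length(ss))
      stop("create_ancestor_species: ancestor ", k,
           " has no habitable site in its range")
    topt <- if (identical(t_opt_rule, "match_local")) sl$temperature[ss]
            else rep(as.numeric(t_opt_rule), length(ss))
    new_species(k, NA_integer_, step, ss,
                rep(initial_abundance, length(ss)), topt)
  })
}

#' Geographic clustering of a species' occupied sites
#'
#' Labels are the connected components of the graph on occupied sites with
#' an edge wherever the connection cost is at most the clustering distance
#' (the species' dispersal capacity, by default the dispersal kernel's
#' median). Each component is labelled by its lowest site id, which makes
#' the labelling deterministic.
#'
#' @param x A species object or an integer vector of occupied site ids.
#' @param costs Cost matrix from [build_cost_matrix()].
#' @param clustering_distance_km Edge threshold in km.
#' @param pos Optional precomputed lookup from site id to row of `costs`.
#' @return Integer vector of cluster labels, parallel to the occupied sites.
#' @export
cluster_sites <- function(x, costs, clustering_distance_km, pos = NULL) {
  sites <- if (inherits(x, "species_state")) x$sites else as.integer(x)
  n <- length(sites)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(sites)
  if (is.null(pos)) {
    pos <- match(sites, as.integer(rownames(costs)))
  } else pos <- pos[sites]
  if (anyNA(pos))
    stop("cluster_sites: occupied site missing from the cost matrix")
  sub <- costs[pos, pos, drop = FALSE]
  adj <- sub <= clustering_distance_km
  comp_of <- integer(n)
  labels <- integer(n)
  for (s in seq_len(n)) {
    if (comp_of[s]) next
    comp_of[s] <- s
    frontier <- s
    while (length(frontier)) {
      nb <- which(adj[frontier[1L], ] & comp_of == 0L)
      comp_of[nb] <- s
      frontier <- c(frontier[-1L], nb)
    }
  }
  # sites are sorted ascending, so each component's seed is its minimum
  sites[comp_of]
}

#' Update the divergence structure for one step
#'
#' Pairs of populations in different geographic clusters accumulate
#' divergence at `rate`; pairs reconnected in the same cluster decay toward
#' zero at `decay_rate` (never below zero). The matrix stays symmetric with
#' a zero diagonal.
#'
#' @param divergence Symmetric numeric matrix over occupied sites.
#' @param labels Cluster labels from [cluster_sites()].
#' @param rate Non-negative divergence accumulated per step by isolated
#'   pairs (possibly temperature-dependent, see [divergence_rate()]).
#' @param decay_rate Non-negative decay per step for reconnected pairs;
#'   defaults to `rate`'s baseline of 1.
#' @return Updated divergence matrix.
#' @export
update_divergence <- function(divergence, labels, rate, decay_rate = 1) {
  if (rate < 0 || decay_rate < 0)
    stop("update_divergence: rates must be non-negative")
  same <- outer(labels, labels, "==")
  res <- divergence + rate
  if (any(same)) res[same] <- pmax(divergence[same] - decay_rate, 0)
  diag(res) <- 0
  res
}

## Minimum cross-pair divergence for every ordered cluster pair.
## Returns a k x k matrix (diagonal 0) aligned with sort(unique(labels)).
cluster_min_divergence <- function(divergence, labels) {
  uls <- sort(unique(labels))
  k <- length(uls)
  ci <- match(labels, uls)
  grp <- (rep(ci, times = length(ci)) - 1L) * k + rep(ci, each = length(ci))
  mins <- vapply(split(as.vector(divergence), grp), min, 0)
  m <- matrix(Inf, k, k)
  m[as.integer(names(mins))] <- mins
  diag(m) <- 0
  m
}

#' Split a species when divergence exceeds the speciation threshold
#'
#' Builds a graph on the species' geographic clusters with an edge wherever
#' the minimum cross-pair divergence is still below the threshold; the
#' connected components of that graph become species. The component holding
#' the largest total abundance (ties broken toward the lowest cluster
#' label) retains the parent's identity; every other component becomes a
#' new species with the next fresh id. Cross-species divergence entries are
#' dropped and within-species entries retained.
#'
#' @param species A species object.
#' @param labels Cluster labels from [cluster_sites()].
#' @param threshold Speciation threshold (divergence units); reaching the
#'   threshold (`>=`) speciates.
#' @param step Current step (recorded as the split step).
#' @param next_id First id available for new species.
#' @return List with `species` (list of one or more species objects, parent
#'   first) and `events` (data frame `child_id, parent_id, split_step`,
#'   zero rows if no split).
#' @export
split_species <- function(species, labels, threshold, step, next_id) {
  no_events <- data.frame(child_id = integer(0), parent_id = integer(0),
                          split_step = integer(0))
  uls <- sort(unique(labels))
  k <- length(uls)
  if (k == 1L)
    return(list(species = list(species), events = no_events))
  mins <- cluster_min_divergence(species$divergence, labels)
  adj <- mins < threshold
  comp_of <- integer(k)
  for (s in seq_len(k)) {
    if (comp_of[s]) next
    comp_of[s] <- s
    frontier <- s
    while (length(frontier)) {
      nb <- which(adj[frontier[1L], ] & comp_of == 0L)
      comp_of[nb] <- s
      frontier <- c(frontier[-1L], nb)
    }
  }
  comps <- sort(unique(comp_of))
  if (length(comps) == 1L)
    return(list(species = list(species), events = no_events))
  site_comp <- comp_of[match(labels, uls)]
  tot_ab <- vapply(comps, function(cc)
    sum(species$abundance[site_comp == cc]), 0)
  parent_comp <- comps[which.max(tot_ab)]  # ties -> lowest cluster label
  out <- list()
  events <- list()
  nid <- next_id
  for (cc in comps) {
    idx <- which(site_comp == cc)
    div <- species$divergence[idx, idx, drop = FALSE]
    if (cc == parent_comp) {
      sp <- species
      sp$sites <- species$sites[idx]
      sp$abundance <- species$abundance[idx]
      sp$t_opt <- species$t_opt[idx]
      sp$divergence <- div
      out <- c(list(sp), out)
    } else {
      sp <- new_species(nid, species$id, step, species$sites[idx],
                        species$abundance[idx], species$t_opt[idx], div)
      out <- c(out, list(sp))
      events[[length(events) + 1L]] <-
        data.frame(child_id = nid, parent_id = species$id, split_step = step)
      nid <- nid + 1L
    }
  }
  list(species = out,
       events = if (length(events)) do.call(rbind, events) else no_events)
}

## Insert newly colonized populations. Each colonist copies the divergence
## row of its seeding source population (divergence to the source itself is
## therefore zero), its source's trait value, and a founder abundance.
add_populations <- function(species, new_sites, src_index, founder_abundance,
                            t_opt = NULL) {
  if (!length(new_sites)) return(species)
  n <- length(species$sites)
  all_sites <- c(species$sites, as.integer(new_sites))
  o <- order(all_sites)
  ext <- c(seq_len(n), src_index)
  div <- species$divergence[ext, ext, drop = FALSE]
  diag(div) <- 0
  species$divergence <- div[o, o, drop = FALSE]
  species$sites <- all_sites[o]
  species$abundance <- c(species$abundance,
                         rep(founder_abundance, length(new_sites)))[o]
  if (is.null(t_opt)) t_opt <- species$t_opt[src_index]
  species$t_opt <- c(species$t_opt, t_opt)[o]
  species
}

## Drop populations by index; returns NULL bookkeeping to the caller, which
## must mark extinction when no site remains.
drop_populations <- function(species, idx) {
  if (!length(idx)) return(species)
  keep <- setdiff(seq_along(species$sites), idx)
  species$sites <- species$sites[keep]
  species$abundance <- species$abundance[keep]
  species$t_opt <- species$t_opt[keep]
  species$divergence <- species$divergence[keep, keep, drop = FALSE]
  species
}

## Abundance-weighted centroid latitude of a species' populations.
species_centroid_lat <- function(species, sites_df) {
  w <- species$abundance
  if (!length(w) || sum(w) == 0) w <- rep(1, length(species$sites))
  lats <- sites_df$lat[match(species$sites, sites_df$id)]
  sum(lats * w) / sum(w)
}
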