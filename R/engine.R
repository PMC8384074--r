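## The simulation engine: per-step landscape update, the four core
## processes in a fixed order, observers, abort rules, extinction
## bookkeeping, and same-seed reproducibility. Iteration order is
## documented and fixed (species ascending id, sites ascending id) so a
## single seeded RNG stream gives bit-identical outputs across runs.

#' Run configuration
#'
#' @param model A [model_config()].
#' @param seed Integer seed for the single RNG stream.
#' @param start_step First step processed (default: oldest slice).
#' @param end_step Last step processed (0 = present).
#' @param n_ancestors,ranges,initial_abundance,t_opt_rule Passed to
#'   [create_ancestor_species()].
#' @param abort_max_species_global Abort when the number of extant species
#'   exceeds this cap.
#' @param abort_max_species_per_site Abort when any site's richness exceeds
#'   this cap.
#' @param observer_every Record a snapshot every this many steps (step
#'   numbers divisible by it, so the present step 0 is always scheduled).
#' @param output_dir Optional directory; when set, tables, the Newick
#'   genealogy and the run log are written there.
#' @param record_events Keep the per-event log (speciation / extinction /
#'   colonization latitudes) needed by [band_rates()].
#' @param clustering_distance_km Clustering distance; default is the
#'   dispersal kernel's median.
#' @return An object of class `run_config`.
#' @export
run_config <- function(model, seed = 1L, start_step = NULL, end_step = 0L,
                       n_ancestors = 1L, ranges = "all_habitable",
                       initial_abundance = 5, t_opt_rule = "match_local",
                       abort_max_species_global = 50000L,
                       abort_max_species_per_site = 10000L,
                       observer_every = 10L, output_dir = NULL,
                       record_events = TRUE,
                       clustering_distance_km = NULL) {
  if (!inherits(model, "model_config")) stop("run_config: model must be a model_config")
  if (!is.null(start_step) && start_step < end_step)
    stop("run_config: start_step must be >= end_step")
  if (end_step < 0) stop("run_config: end_step must be >= 0")
  structure(list(model = model, seed = as.integer(seed),
                 start_step = start_step, end_step = as.integer(end_step),
                 n_ancestors = n_ancestors, ranges = ranges,
                 initial_abundance = initial_abundance,
                 t_opt_rule = t_opt_rule,
                 abort_max_species_global = abort_max_species_global,
                 abort_max_species_per_site = abort_max_species_per_site,
                 observer_every = as.integer(observer_every),
                 output_dir = output_dir, record_events = record_events,
                 clustering_distance_km = clustering_distance_km),
            class = "run_config")
}

## Per-site species counts over all sites of the landscape.
richness_vector <- function(pop, n_sites) {
  occ <- unlist(lapply(pop, `[[`, "sites"), use.names = FALSE)
  if (!length(occ)) return(integer(n_sites))
  tabulate(occ, nbins = n_sites)
}

## Long species table for a set of extant species at one step.
build_species_table <- function(pop, step, costs, clustering_distance, pos) {
  if (!length(pop))
    return(data.frame(step = integer(0), species_id = integer(0),
                      site_id = integer(0), abundance = numeric(0),
                      t_opt = numeric(0), cluster = integer(0)))
  rows <- lapply(pop, function(sp) {
    cl <- if (is.null(costs)) rep(NA_integer_, length(sp$sites))
          else cluster_sites(sp$sites, costs, clustering_distance, pos)
    data.frame(step = step, species_id = sp$id, site_id = sp$sites,
               abundance = sp$abundance, t_opt = sp$t_opt, cluster = cl)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Record an observer snapshot
#'
#' Pure function of the state: builds the requested artifacts (richness
#' map, species table) without mutating anything or consuming random
#' numbers, so observer settings cannot alter a run's trajectory.
#'
#' @param pop List of extant species objects.
#' @param landscape The landscape.
#' @param step Current step.
#' @param costs,clustering_distance,pos Clustering inputs for the table.
#' @return List with `step`, `richness` (per-site counts) and `species`
#'   (species table).
#' @export
observer_record <- function(pop, landscape, step, costs,
                            clustering_distance, pos) {
  list(step = step,
       richness = richness_vector(pop, nrow(landscape$sites)),
       species = build_species_table(pop, step, costs, clustering_distance,
                                     pos))
}

#' Run a simulation
#'
#' Creates the ancestor species on the first slice and iterates the
#' simulation cycle over the landscape series to the present. Each step:
#' (1) populations on newly uninhabitable sites are removed and emptied
#' species marked extinct; (2) speciation: geographic clustering, divergence
#' update, threshold splitting; (3) dispersal; (4) trait mutation;
#' (5) ecology (niche abundances, carrying capacities, local extinctions),
#' then cluster-wise trait homogenization; (6) scheduled observers.
#' Identical seed, configuration and landscape give bit-identical outputs.
#'
#' @param config A [run_config()].
#' @param landscape A [dynamic_landscape()].
#' @return An object of class `sim_output`.
#' @export
run_simulation <- function(config, landscape) {
  stopifnot(inherits(config, "run_config"),
            inherits(landscape, "dynamic_landscape"))
  model <- config$model
  n_slices <- length(landscape$slices)
  start <- if (is.null(config$start_step)) n_slices - 1L
           else as.integer(config$start_step)
  if (start > n_slices - 1L)
    stop("run_simulation: start_step has no landscape slice")
  end <- config$end_step
  set.seed(config$seed)

  n_sites <- nrow(landscape$sites)
  sites_df <- landscape$sites
  kernel <- model$kernel
  clu_d <- if (is.null(config$clustering_distance_km)) kernel_median(kernel)
           else config$clustering_distance_km
  eco <- model$ecology
  evo <- model$evolution
  founder_ab <- max(1L, as.integer(round(eco$a_max / 2)))

  ## genealogy vectors indexed by species id
  gparent <- rep(NA_integer_, 64L); gorigin <- rep(NA_integer_, 64L)
  gext <- rep(NA_integer_, 64L); glat <- rep(NA_real_, 64L)
  gext_lat <- rep(NA_real_, 64L)
  ensure_cap <- function(k) {
    while (k > length(gparent)) {
      gparent <<- c(gparent, rep(NA_integer_, length(gparent)))
      gorigin <<- c(gorigin, rep(NA_integer_, length(gorigin)))
      gext <<- c(gext, rep(NA_integer_, length(gext)))
      glat <<- c(glat, rep(NA_real_, length(glat)))
      gext_lat <<- c(gext_lat, rep(NA_real_, length(gext_lat)))
    }
  }

  mig_step <- integer(0); mig_lat_from <- numeric(0); mig_lat_to <- numeric(0)

  pop <- create_ancestor_species(landscape, start, config$n_ancestors,
                                 config$ranges, config$initial_abundance,
                                 config$t_opt_rule)
  next_id <- length(pop) + 1L
  ensure_cap(next_id)
  for (sp in pop) {
    gorigin[sp$id] <- start
    glat[sp$id] <- species_centroid_lat(sp, sites_df)
  }
  names(pop) <- vapply(pop, function(s) as.character(s$id), "")

  cost_cache <- new.env(parent = emptyenv())
  snapshots <- list()
  log_rows <- list()
  aborted <- NULL
  last_step <- start
  mark_extinct <- function(sp, step) {
    gext[sp$id] <<- step
    gext_lat[sp$id] <<- species_centroid_lat(sp, sites_df)
  }

  for (step in seq(start, end, by = -1L)) {
    last_step <- step
    sl <- slice_for_step(landscape, step)
    hab <- habitable_sites(landscape, step)
    key <- paste0("h", paste(which(hab), collapse = "."))
    cc <- cost_cache[[key]]
    if (is.null(cc)) {
      costs <- build_cost_matrix(landscape, step)
      pos <- integer(n_sites)
      pos[as.integer(rownames(costs))] <- seq_len(nrow(costs))
      cc <- list(costs = costs, pos = pos, hab_ids = sites_df$id[hab])
      cost_cache[[key]] <- cc
    }
    costs <- cc$costs; pos <- cc$pos; hab_ids <- cc$hab_ids
    temp <- sl$temperature

    ## (1) habitability update
    if (length(pop)) {
      keep <- logical(length(pop))
      for (u in seq_along(pop)) {
        sp <- pop[[u]]
        lost <- which(!hab[sp$sites])
        if (length(lost)) {
          if (length(lost) == length(sp$sites)) {
            mark_extinct(sp, step)
            keep[u] <- FALSE
            next
          }
          sp <- drop_populations(sp, lost)
          pop[[u]] <- sp
        }
        keep[u] <- TRUE
      }
      pop <- pop[keep]
    }

    ## (2) speciation: cluster, accrue divergence, split at threshold
    if (length(pop)) {
      newpop <- vector("list", length(pop))
      extra <- list()
      for (u in seq_along(pop)) {
        sp <- pop[[u]]
        labels <- cluster_sites(sp$sites, costs, clu_d, pos)
        rate <- divergence_rate(model$divergence, mean(temp[sp$sites]))
        sp$divergence <- update_divergence(sp$divergence, labels, rate,
                                           model$decay_rate)
        res <- split_species(sp, labels, model$threshold, step, next_id)
        newpop[[u]] <- res$species[[1L]]
        if (length(res$species) > 1L) {
          kids <- res$species[-1L]
          ensure_cap(next_id + length(kids))
          for (ch in kids) {
            gparent[ch$id] <- sp$id
            gorigin[ch$id] <- step
            glat[ch$id] <- species_centroid_lat(ch, sites_df)
          }
          next_id <- next_id + length(kids)
          extra <- c(extra, kids)
        }
      }
      pop <- c(newpop, extra)
      ids <- vapply(pop, `[[`, 0L, "id")
      pop <- pop[order(ids)]
      names(pop) <- as.character(sort(ids))
    }
    if (length(pop) > config$abort_max_species_global) {
      aborted <- list(step = step, reason = "global species cap")
      break
    }

    ## (3) dispersal / colonization
    if (length(pop)) {
      for (u in seq_along(pop)) {
        res <- dispersal_step(pop[[u]], costs, kernel, hab_ids, founder_ab,
                              pos)
        pop[[u]] <- res$species
        if (config$record_events && nrow(res$colonized)) {
          mig_step <- c(mig_step, rep.int(step, nrow(res$colonized)))
          mig_lat_from <- c(mig_lat_from,
                            sites_df$lat[res$colonized$source_site])
          mig_lat_to <- c(mig_lat_to, sites_df$lat[res$colonized$site])
        }
      }
    }

    ## (4) evolution: Brownian mutation of the temperature optimum
    if (evo$enabled && evo$sigma > 0) {
      for (u in seq_along(pop)) pop[[u]] <- evolution_step(pop[[u]], evo$sigma)
    }

    ## (5) ecology: niche abundances, carrying capacity, homogenization
    if (eco$mode != "none" && length(pop)) {
      for (u in seq_along(pop)) {
        sp <- pop[[u]]
        sp$abundance <- niche_abundance(sp$t_opt, temp[sp$sites],
                                        eco$niche_width, eco$a_max, eco$form)
        pop[[u]] <- sp
      }
      if (eco$mode == "niche+capacity") {
        k_all <- numeric(n_sites)
        k_all[hab_ids] <- site_capacity(temp[hab_ids], sl$aridity[hab_ids],
                                        eco$k_base, eco$k_power,
                                        eco$energy_source)
        occ_site <- unlist(lapply(pop, `[[`, "sites"), use.names = FALSE)
        occ_sp <- rep.int(seq_along(pop),
                          vapply(pop, function(s) length(s$sites), 0L))
        occ_loc <- unlist(lapply(pop, function(s) seq_along(s$sites)),
                          use.names = FALSE)
        occ_ab <- unlist(lapply(pop, `[[`, "abundance"), use.names = FALSE)
        tot_ab <- rowsum(occ_ab, occ_site)
        over_sites <- as.integer(rownames(tot_ab))[tot_ab[, 1L] >
                                                     k_all[as.integer(rownames(tot_ab))]]
        if (length(over_sites)) {
          by_site <- split(seq_along(occ_site), occ_site)
          for (s_id in sort(over_sites)) {
            ii <- by_site[[as.character(s_id)]]
            red <- apply_carrying_capacity(occ_ab[ii], k_all[s_id])
            occ_ab[ii] <- red
          }
          for (u in unique(occ_sp)) {
            sel <- occ_sp == u
            pop[[u]]$abundance[occ_loc[sel]] <- occ_ab[sel]
          }
        }
      }
      keep <- logical(length(pop))
      for (u in seq_along(pop)) {
        sp <- pop[[u]]
        dead <- which(sp$abundance <= 0)
        if (length(dead) == length(sp$sites)) {
          mark_extinct(sp, step)
          keep[u] <- FALSE
          next
        }
        if (length(dead)) pop[[u]] <- drop_populations(sp, dead)
        keep[u] <- TRUE
      }
      pop <- pop[keep]
    }
    if (evo$enabled && evo$homogenize && length(pop)) {
      for (u in seq_along(pop)) {
        sp <- pop[[u]]
        labels <- cluster_sites(sp$sites, costs, clu_d, pos)
        pop[[u]] <- homogenize_traits(sp, labels)
      }
    }

    rich <- richness_vector(pop, n_sites)
    if (max(rich) > config$abort_max_species_per_site) {
      aborted <- list(step = step, reason = "per-site species cap")
      break
    }

    ## (6) observer
    if (step %% config$observer_every == 0L) {
      snapshots[[length(snapshots) + 1L]] <-
        observer_record(pop, landscape, step, costs, clu_d, pos)
    }
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(step = step, n_species = length(pop),
                 n_sites_occupied = sum(rich > 0L))
  }

  n_created <- next_id - 1L
  genealogy <- data.frame(species_id = seq_len(n_created),
                          parent_id = gparent[seq_len(n_created)],
                          origin_step = gorigin[seq_len(n_created)],
                          extinction_step = gext[seq_len(n_created)],
                          origin_lat = glat[seq_len(n_created)],
                          extinction_lat = gext_lat[seq_len(n_created)])
  sl_last <- slice_for_step(landscape, last_step)
  key <- paste0("h", paste(which(habitable_sites(landscape, last_step)),
                           collapse = "."))
  cc <- cost_cache[[key]]
  final_table <- if (!is.null(cc))
    build_species_table(pop, last_step, cc$costs, clu_d, cc$pos)
  else build_species_table(pop, last_step, NULL, clu_d, NULL)
  duration <- sl_last$duration_kyr
  out <- structure(list(
    config = config,
    seed = config$seed,
    species = pop,
    final_step = last_step,
    final_richness = richness_vector(pop, n_sites),
    final_species_table = final_table,
    genealogy = genealogy,
    newick = genealogy_to_newick(genealogy, duration),
    snapshots = snapshots,
    log = do.call(rbind, log_rows),
    migrations = data.frame(step = mig_step, lat_from = mig_lat_from,
                            lat_to = mig_lat_to),
    aborted = aborted,
    duration_kyr = duration,
    sites = sites_df), class = "sim_output")
  if (!is.null(config$output_dir)) write_sim_output(out, config$output_dir)
  out
}

#' @export
print.sim_output <- function(x, ...) {
  n_extant <- length(x$species)
  cat(sprintf("sim_output: %d species created, %d extant at step %d%s\n",
              nrow(x$genealogy), n_extant, x$final_step,
              if (is.null(x$aborted)) ""
              else sprintf(" [ABORTED at step %d: %s]", x$aborted$step,
                           x$aborted$reason)))
  invisible(x)
}

#' @export
summary.sim_output <- function(object, ...) {
  g <- object$genealogy
  cat(sprintf("species created: %d  extant: %d  extinct: %d\n",
              nrow(g), sum(is.na(g$extinction_step)),
              sum(!is.na(g$extinction_step))))
  cat(sprintf("steps run: %d -> %d; snapshots: %d\n",
              if (nrow(object$log)) object$log$step[1L] else NA_integer_,
              object$final_step, length(object$snapshots)))
  if (!is.null(object$aborted))
    cat(sprintf("aborted at step %d (%s)\n", object$aborted$step,
                object$aborted$reason))
  rich <- object$final_richness
  cat(sprintf("final richness: max %d over %d occupied sites\n",
              max(rich), sum(rich > 0L)))
  invisible(object)
}

#' Plot the final richness map of a run
#'
#' @param x A `sim_output`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.sim_output <- function(x, ...) {
  s <- x$sites
  lons <- sort(unique(s$lon)); lats <- sort(unique(s$lat))
  z <- matrix(NA_real_, length(lons), length(lats))
  z[cbind(match(s$lon, lons), match(s$lat, lats))] <- x$final_richness
  graphics::image(lons, lats, z, xlab = "longitude", ylab = "latitude",
                  main = "species richness", ...)
  invisible(x)
}

#' Write the outputs of a run to a directory
#'
#' @param output A `sim_output`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_output <- function(output, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(output$final_species_table,
                   file.path(dir, "species_final.csv"), row.names = FALSE)
  utils::write.csv(output$genealogy, file.path(dir, "genealogy.csv"),
                   row.names = FALSE)
  utils::write.csv(output$log, file.path(dir, "run_log.csv"),
                   row.names = FALSE)
  rich <- data.frame(site_id = output$sites$id, lon = output$sites$lon,
                     lat = output$sites$lat, richness = output$final_richness)
  utils::write.csv(rich, file.path(dir, "richness_final.csv"),
                   row.names = FALSE)
  if (!is.na(output$newick))
    writeLines(output$newick, file.path(dir, "genealogy.nwk"))
  meta <- list(seed = output$seed, final_step = output$final_step,
               aborted = if (is.null(output$aborted)) "no"
                         else paste(output$aborted$reason, "at step",
                                    output$aborted$step),
               model = output$config$model$name)
  writeLines(yaml::as.yaml(meta), file.path(dir, "run_meta.yaml"))
  invisible(dir)
}
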