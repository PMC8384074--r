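## Genealogy: the speciation/extinction event log kept by the engine and
## its conversion to a phylogenetic tree. The log is a data frame with one
## row per species ever created: species_id, parent_id (NA for ancestors),
## origin_step, extinction_step (NA while extant), origin_lat.

#' Convert a genealogy to an ape phylogeny
#'
#' Builds the tree implied by the engine's speciation/extinction log. Every
#' species ever created is a tip; branch lengths are in Myr (step times
#' slice duration), extinct tips terminate at their extinction time and
#' extant tips at the present. Simultaneous splits of one parent produce
#' zero-length internal edges. With several ancestor species, lineages are
#' joined at an artificial root at the origin time.
#'
#' @param genealogy Genealogy data frame from a simulation run.
#' @param duration_kyr Duration of one step in kyr.
#' @param extant_only Drop extinct tips (yields an ultrametric tree).
#' @return An object of class `phylo`, or `NULL` when fewer than two tips
#'   remain.
#' @export
genealogy_to_phylo <- function(genealogy, duration_kyr = 170,
                               extant_only = FALSE) {
  g <- genealogy
  n <- nrow(g)
  if (n < 2L) return(NULL)
  myr <- duration_kyr / 1000
  birth <- g$origin_step * myr
  death <- ifelse(is.na(g$extinction_step), 0, g$extinction_step * myr)
  row_of <- integer(max(g$species_id))
  row_of[g$species_id] <- seq_len(n)

  ev <- which(!is.na(g$parent_id))
  ev <- ev[order(-g$origin_step[ev], g$species_id[ev])]
  n_anc <- sum(is.na(g$parent_id))
  n_internal <- length(ev) + (n_anc > 1L)
  if (!length(ev) && n_anc < 2L) return(NULL)

  cur_node <- rep(NA_integer_, n)
  cur_time <- birth
  max_edges <- length(ev) + n + 2L
  edge_from <- integer(max_edges); edge_to <- integer(max_edges)
  edge_len <- numeric(max_edges)
  ne <- 0L
  next_node <- n + 1L
  if (n_anc > 1L) {
    anc <- which(is.na(g$parent_id))
    root <- next_node; next_node <- next_node + 1L
    t0 <- max(birth[anc])
    cur_node[anc] <- root
    cur_time[anc] <- t0
  }
  for (e in ev) {
    p <- row_of[g$parent_id[e]]
    t <- birth[e]
    v <- next_node; next_node <- next_node + 1L
    if (!is.na(cur_node[p])) {
      ne <- ne + 1L
      edge_from[ne] <- cur_node[p]; edge_to[ne] <- v
      edge_len[ne] <- cur_time[p] - t
    }
    cur_node[p] <- v; cur_time[p] <- t
    cur_node[e] <- v; cur_time[e] <- t
  }
  for (s in seq_len(n)) {
    if (is.na(cur_node[s])) next
    ne <- ne + 1L
    edge_from[ne] <- cur_node[s]; edge_to[ne] <- s
    edge_len[ne] <- cur_time[s] - death[s]
  }
  edge_from <- edge_from[seq_len(ne)]; edge_to <- edge_to[seq_len(ne)]
  edge_len <- edge_len[seq_len(ne)]
  tr <- structure(list(edge = cbind(edge_from, edge_to),
                       edge.length = pmax(edge_len, 0),
                       tip.label = paste0("s", g$species_id),
                       Nnode = n_internal),
                  class = "phylo")
  attr(tr, "order") <- NULL
  tr <- ape::reorder.phylo(tr, "cladewise")
  if (extant_only) {
    drop <- which(!is.na(g$extinction_step))
    if (length(drop)) {
      if (n - length(drop) < 2L) return(NULL)
      tr <- ape::drop.tip(tr, paste0("s", g$species_id[drop]))
    }
  }
  tr
}

#' Genealogy to Newick string
#'
#' @inheritParams genealogy_to_phylo
#' @return Newick string (branch lengths in Myr), or `NA` when no tree can
#'   be formed.
#' @export
genealogy_to_newick <- function(genealogy, duration_kyr = 170,
                                extant_only = FALSE) {
  tr <- genealogy_to_phylo(genealogy, duration_kyr, extant_only)
  if (is.null(tr)) return(NA_character_)
  ape::write.tree(tr)
}
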