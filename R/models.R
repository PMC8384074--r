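## The model library: the five case-study configurations M1-M5, explored
## parameter ranges, quasi-random (Sobol) sampling of parameter space, and
## the validity filters applied to finished runs.

#' Model configuration
#'
#' Wires together the per-step process rules. Usually built through
#' [make_model()]; use this constructor directly for custom models.
#'
#' @param name Model name (`"M1"`..`"M5"` or custom).
#' @param threshold Speciation threshold (divergence units).
#' @param kernel A [dispersal_kernel()].
#' @param evolution An [evolution_rule()].
#' @param ecology An [ecology_rule()].
#' @param divergence A [divergence_rate_rule()].
#' @param decay_rate Divergence decay per step for reconnected clusters;
#'   defaults to the accumulation baseline.
#' @return An object of class `model_config`.
#' @export
model_config <- function(name, threshold, kernel, evolution, ecology,
                         divergence, decay_rate = divergence$base_rate) {
  if (threshold <= 0) stop("model_config: threshold must be > 0")
  structure(list(name = name, threshold = threshold, kernel = kernel,
                 evolution = evolution, ecology = ecology,
                 divergence = divergence, decay_rate = decay_rate),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf(
    "model_config %s: threshold=%g, kernel=%s, evolution=%s, ecology=%s, divergence=%s\n",
    x$name, x$threshold,
    if (x$kernel$family == "weibull")
      sprintf("weibull(shape=%g, scale=%g km)", x$kernel$shape, x$kernel$scale)
    else sprintf("constant(%g km)", x$kernel$value_km),
    if (x$evolution$enabled) sprintf("BM(sigma=%g)", x$evolution$sigma)
    else "off",
    x$ecology$mode, x$divergence$mode))
  invisible(x)
}

#' Explored parameter ranges
#'
#' The ranges sampled in the case-study exploration: Weibull shape
#' `phi` 2-5 and scale `psi` 550-850 km, Brownian step `sigma`
#' 0.001-0.010 (normalized units), speciation threshold 6-60 (1-10 Myr of
#' isolation at 170-kyr steps), `d_power` 2-6 and `k_power` 1-4.
#'
#' @return Named list of `c(low, high)` bounds.
#' @export
parameter_ranges <- function() {
  list(phi = c(2, 5), psi = c(550, 850), sigma = c(0.001, 0.010),
       threshold = c(6, 60), d_power = c(2, 6), k_power = c(1, 4))
}

check_range <- function(value, name, allow) {
  r <- parameter_ranges()[[name]]
  if (!allow && !is.null(r) && (value < r[1L] || value > r[2L]))
    stop("make_model: ", name, " = ", value, " outside the declared range [",
         r[1L], ", ", r[2L], "]; set allow_out_of_range = TRUE to override")
  value
}

#' Build one of the five case-study model configurations
#'
#' * `M1` - null model: ecologically equivalent sites, trait evolution and
#'   ecology off, constant divergence rate.
#' * `M2` - niche conservatism: abundance set by the temperature-niche
#'   mismatch, Brownian trait evolution.
#' * `M3` - diversification rates: as M2, plus temperature-dependent
#'   divergence (3x faster at the warmest sites, exponent `d_power`).
#' * `M4` - carrying capacity: as M2, plus a uniform per-site cap on total
#'   abundance.
#' * `M5` - ecological limits: as M4, but capacity scales with area energy
#'   (temperature and aridity).
#'
#' @param name `"M1"`..`"M5"`.
#' @param phi,psi Weibull dispersal shape and scale (km).
#' @param sigma Brownian step of the temperature optimum.
#' @param threshold Speciation threshold.
#' @param d_power Temperature exponent of the divergence rate (required for
#'   M3).
#' @param k_power Power-law scaling of capacity with energy (M4/M5).
#' @param k_base Capacity at maximum energy (M4/M5).
#' @param a_max Maximum population abundance.
#' @param niche_width Temperature niche half-width.
#' @param kernel Optional kernel overriding `phi`/`psi`.
#' @param allow_out_of_range Permit parameters outside [parameter_ranges()].
#' @return A [model_config()].
#' @export
make_model <- function(name, phi = 3.5, psi = 700, sigma = 0.0055,
                       threshold = 6, d_power = NULL, k_power = 2.5,
                       k_base = 50L, a_max = 10L, niche_width = 0.1,
                       kernel = NULL, allow_out_of_range = FALSE) {
  if (!name %in% paste0("M", 1:5))
    stop("make_model: unknown model name '", name, "'")
  check_range(phi, "phi", allow_out_of_range)
  check_range(psi, "psi", allow_out_of_range)
  check_range(sigma, "sigma", allow_out_of_range)
  check_range(threshold, "threshold", allow_out_of_range)
  check_range(k_power, "k_power", allow_out_of_range)
  if (is.null(kernel)) kernel <- dispersal_kernel("weibull", phi, psi)
  if (name == "M3") {
    if (is.null(d_power)) stop("make_model: M3 requires d_power")
    check_range(d_power, "d_power", allow_out_of_range)
  }
  div <- if (name == "M3")
    divergence_rate_rule("temperature", base_rate = 1, d_power = d_power,
                         max_multiplier = 3)
  else divergence_rate_rule("constant", base_rate = 1)
  evo <- if (name == "M1") evolution_rule(enabled = FALSE)
         else evolution_rule(sigma = sigma)
  eco <- switch(name,
    M1 = ecology_rule("none", a_max = a_max),
    M2 = ecology_rule("niche", niche_width = niche_width, a_max = a_max),
    M3 = ecology_rule("niche", niche_width = niche_width, a_max = a_max),
    M4 = ecology_rule("niche+capacity", niche_width = niche_width,
                      a_max = a_max, k_base = k_base, k_power = k_power,
                      energy_source = "uniform"),
    M5 = ecology_rule("niche+capacity", niche_width = niche_width,
                      a_max = a_max, k_base = k_base, k_power = k_power,
                      energy_source = "temp_aridity"))
  model_config(name, threshold, kernel, evo, eco, div)
}

## Sobol direction numbers (Joe-Kuo) for the first 6 dimensions; dimension
## 1 is the van der Corput sequence in base 2.
sobol_dirnum <- list(
  list(s = 1L, a = 0L, m = 1L),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L))
)

sobol_points <- function(n, d, bits = 30L) {
  if (d < 1L) stop("sobol_points: dimension must be >= 1")
  if (d > length(sobol_dirnum) + 1L)
    stop("sobol_points: at most ", length(sobol_dirnum) + 1L,
         " dimensions supported")
  if (n >= 2^bits) stop("sobol_points: n too large")
  V <- matrix(0, bits, d)  # direction integers as doubles
  V[, 1L] <- 2^(bits - seq_len(bits))
  for (j in seq_len(d - 1L)) {
    dn <- sobol_dirnum[[j]]
    s <- dn$s
    m <- as.numeric(dn$m)
    if (bits > s) {
      a_bits <- as.integer(intToBits(dn$a))[seq_len(max(s - 1L, 1L))]
      for (k in (s + 1L):bits) {
        mk <- bitwXor(as.integer(m[k - s]),
                      as.integer(m[k - s] * 2^s))
        # a_bits is LSB-first, so coefficient a_i sits at position s - i
        if (s > 1L) for (i in seq_len(s - 1L)) {
          if (a_bits[s - i] == 1L)
            mk <- bitwXor(mk, as.integer(m[k - i] * 2^i))
        }
        m[k] <- mk
      }
    }
    V[, j + 1L] <- m[seq_len(bits)] * 2^(bits - seq_len(bits))
  }
  pts <- matrix(0, n, d)
  x <- numeric(d)  # current integer state per dimension
  for (k in seq_len(n)) {
    # lowest zero bit of (k - 1)
    c_ <- 1L
    kk <- k - 1L
    while (kk %% 2L == 1L) { kk <- kk %/% 2L; c_ <- c_ + 1L }
    for (j in seq_len(d))
      x[j] <- bitwXor(as.integer(x[j]), as.integer(V[c_, j]))
    pts[k, ] <- x / 2^bits
  }
  pts
}

#' Quasi-random parameter sets from a Sobol sequence
#'
#' Returns the first `n` points of a Sobol low-discrepancy sequence (the
#' all-zeros first point is skipped; no scrambling, so sampling is fully
#' deterministic and prefix-stable) affinely mapped to the given ranges.
#'
#' @param ranges Named list of `c(low, high)` bounds, e.g.
#'   [parameter_ranges()].
#' @param n Number of parameter sets.
#' @return Data frame with one column per parameter and `n` rows.
#' @export
sobol_sample <- function(ranges, n) {
  if (n < 1L) stop("sobol_sample: n must be >= 1")
  d <- length(ranges)
  if (d < 1L) stop("sobol_sample: empty ranges")
  pts <- sobol_points(n, d)
  out <- as.data.frame(pts)
  names(out) <- names(ranges)
  for (j in seq_len(d)) {
    r <- ranges[[j]]
    if (r[1L] > r[2L]) stop("sobol_sample: low > high for ", names(ranges)[j])
    out[[j]] <- r[1L] + pts[, j] * (r[2L] - r[1L])
  }
  out
}

#' Validity filter for finished runs
#'
#' Flags the three case-study criteria separately: at least 20 species
#' extant at the present, fewer than 50,000 species in total, and fewer
#' than 10,000 species cohabiting any one site at any recorded step.
#'
#' @param output A `sim_output`.
#' @return List with `valid` (logical) and `reasons` (character vector of
#'   failed criteria, empty when valid).
#' @export
validity_filter <- function(output) {
  reasons <- character(0)
  extant <- sum(is.na(output$genealogy$extinction_step))
  if (!is.null(output$aborted))
    reasons <- c(reasons, paste0("aborted (", output$aborted$reason, ")"))
  if (is.null(output$aborted) && extant < 20L)
    reasons <- c(reasons, "min richness")
  if (nrow(output$genealogy) >= 50000L)
    reasons <- c(reasons, "global cap")
  max_site <- max(c(0L, output$final_richness,
                    unlist(lapply(output$snapshots,
                                  function(s) max(c(0L, s$richness))))))
  if (max_site >= 10000L) reasons <- c(reasons, "local cap")
  list(valid = length(reasons) == 0L, reasons = reasons)
}

#' Explore a model's parameter space
#'
#' Runs one simulation per Sobol parameter set and collects a manifest of
#' parameters, validity flags and headline outputs.
#'
#' @param name Model name (`"M1"`..`"M5"`).
#' @param n Number of parameter sets.
#' @param landscape A [dynamic_landscape()].
#' @param seed Base seed; run `i` uses `seed + i - 1`.
#' @param out_dir Optional directory; each run is written to a subdirectory
#'   and the manifest to `manifest.csv`.
#' @param ... Further arguments to [run_config()].
#' @return Manifest data frame.
#' @export
explore_model <- function(name, n, landscape, seed = 1L, out_dir = NULL,
                          ...) {
  ranges <- parameter_ranges()
  if (name != "M3") ranges$d_power <- NULL
  if (!name %in% c("M4", "M5")) ranges$k_power <- NULL
  if (name == "M1") ranges$sigma <- NULL
  params <- sobol_sample(ranges, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- as.list(params[i, , drop = FALSE])
    model <- make_model(name, phi = p$phi, psi = p$psi,
                        sigma = if (is.null(p$sigma)) 0.0055 else p$sigma,
                        threshold = p$threshold,
                        d_power = p$d_power,
                        k_power = if (is.null(p$k_power)) 2.5 else p$k_power)
    dir_i <- if (is.null(out_dir)) NULL
             else file.path(out_dir, sprintf("run_%03d", i))
    cfg <- run_config(model, seed = seed + i - 1L, output_dir = dir_i, ...)
    out <- run_simulation(cfg, landscape)
    v <- validity_filter(out)
    rows[[i]] <- cbind(data.frame(run = i, seed = cfg$seed),
                       params[i, , drop = FALSE],
                       data.frame(valid = v$valid,
                                  reasons = paste(v$reasons, collapse = "; "),
                                  n_species = nrow(out$genealogy),
                                  n_extant = length(out$species)))
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  manifest
}

#' Read a run configuration from a YAML file
#'
#' The file mirrors the [run_config()] and [make_model()] argument names:
#' a `model` block (`name`, `phi`, `psi`, `sigma`, `threshold`, `d_power`,
#' `k_power`, ...) and top-level run fields (`seed`, `start_step`,
#' `end_step`, `observer_every`, abort caps, ...).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$model) || is.null(y$model$name))
    stop("read_run_config: missing model block")
  model <- do.call(make_model, y$model)
  y$model <- NULL
  do.call(run_config, c(list(model = model), y))
}
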