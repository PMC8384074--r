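## Landscape input/output: a long-format CSV dialect
## (site_id,lon,lat,step,temperature,aridity) and a per-variable-per-step
## ESRI ASCII grid dialect (temperature_{t}.asc, aridity_{t}.asc).

landscape_from_table <- function(df, duration_kyr = 170, wrap = NULL,
                                 policy = cost_policy()) {
  need <- c("lon", "lat", "step", "temperature", "aridity")
  if (!all(need %in% names(df)))
    stop("landscape table needs columns: ", paste(need, collapse = ", "))
  lons <- sort(unique(df$lon))
  lats <- sort(unique(df$lat), decreasing = TRUE)  # north first
  n_lon <- length(lons); n_lat <- length(lats)
  sites <- data.frame(id = seq_len(n_lon * n_lat),
                      lon = rep(lons, times = n_lat),
                      lat = rep(lats, each = n_lon))
  steps <- sort(unique(df$step), decreasing = TRUE)  # oldest first
  key_all <- paste(sites$lon, sites$lat)
  if (is.null(wrap)) {
    dl <- if (n_lon > 1) min(diff(lons)) else 360
    wrap <- isTRUE(all.equal(n_lon * dl, 360))
  }
  slices <- lapply(steps, function(s) {
    sub <- df[df$step == s, , drop = FALSE]
    key <- paste(sub$lon, sub$lat)
    if (anyDuplicated(key))
      stop("duplicate site rows at step ", s)
    if (!all(key %in% key_all) || !all(key_all %in% key))
      stop("step ", s, " does not cover the common grid ",
           "(mismatched grids across slices)")
    pos <- match(key_all, key)
    list(temperature = sub$temperature[pos], aridity = sub$aridity[pos],
         duration_kyr = duration_kyr)
  })
  dynamic_landscape(sites, slices, n_lon, n_lat, wrap = wrap, policy = policy,
                    duration_kyr = duration_kyr)
}

read_asc <- function(path) {
  head6 <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head6), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% keys)) stop("malformed ASCII grid header in ", path)
  vv <- scan(path, skip = 6L, quiet = TRUE)
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  if (length(vv) != nc * nr) stop("ASCII grid body does not match header in ", path)
  vv[vv == vals["nodata_value"]] <- NA_real_
  list(values = vv,  # row-major, north row first
       n_lon = nc, n_lat = nr,
       xll = vals[["xllcorner"]], yll = vals[["yllcorner"]],
       cellsize = vals[["cellsize"]])
}

write_asc <- function(values, n_lon, n_lat, xll, yll, cellsize, path,
                      nodata = -9999) {
  v <- values
  v[is.na(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", n_lon), paste("nrows", n_lat),
               paste("xllcorner", xll), paste("yllcorner", yll),
               paste("cellsize", cellsize), paste("NODATA_value", nodata)),
             con)
  m <- matrix(v, nrow = n_lat, byrow = TRUE)
  writeLines(apply(m, 1L, paste, collapse = " "), con)
}

#' Load a landscape time series
#'
#' Accepts a long-format table (or its CSV file) with columns
#' `site_id, lon, lat, step, temperature, aridity`, or a directory holding
#' one ESRI ASCII grid per variable per step (`temperature_{t}.asc`,
#' `aridity_{t}.asc`). Both dialects produce an identical
#' [dynamic_landscape()]: slices ordered oldest to present, site ids
#' assigned row-major (northernmost row first), a site habitable at a step
#' iff all its environmental values are non-missing there.
#'
#' @param x Data frame, path to a CSV file, or path to a directory of
#'   `.asc` grids.
#' @param duration_kyr Slice duration in kyr.
#' @param wrap Longitude wrap-around; default `NULL` auto-detects a global
#'   grid (n_lon * cellsize = 360 degrees).
#' @param policy A [cost_policy()].
#' @return A [dynamic_landscape()].
#' @export
load_landscape_series <- function(x, duration_kyr = 170, wrap = NULL,
                                  policy = cost_policy()) {
  if (is.data.frame(x))
    return(landscape_from_table(x, duration_kyr, wrap, policy))
  if (!is.character(x) || length(x) != 1L)
    stop("x must be a data frame or a path")
  if (dir.exists(x)) {
    tfiles <- list.files(x, pattern = "^temperature_[0-9]+\\.asc$")
    if (!length(tfiles)) stop("no temperature_{t}.asc grids found in ", x)
    steps <- sort(as.integer(sub("^temperature_([0-9]+)\\.asc$", "\\1",
                                 tfiles)), decreasing = TRUE)
    ref <- NULL
    slices <- lapply(steps, function(s) {
      tg <- read_asc(file.path(x, sprintf("temperature_%d.asc", s)))
      af <- file.path(x, sprintf("aridity_%d.asc", s))
      if (!file.exists(af)) stop("missing aridity grid for step ", s)
      ag <- read_asc(af)
      geom <- c(tg$n_lon, tg$n_lat, tg$xll, tg$yll, tg$cellsize)
      if (is.null(ref)) ref <<- geom
      if (!isTRUE(all.equal(geom, ref)) ||
          !isTRUE(all.equal(c(ag$n_lon, ag$n_lat, ag$xll, ag$yll,
                              ag$cellsize), ref)))
        stop("grids do not share geometry across slices/variables")
      list(temperature = tg$values, aridity = ag$values,
           duration_kyr = duration_kyr)
    })
    n_lon <- as.integer(ref[1L]); n_lat <- as.integer(ref[2L])
    cs <- ref[5L]
    lons <- ref[3L] + (seq_len(n_lon) - 0.5) * cs
    lats <- ref[4L] + (rev(seq_len(n_lat)) - 0.5) * cs
    sites <- data.frame(id = seq_len(n_lon * n_lat),
                        lon = rep(lons, times = n_lat),
                        lat = rep(lats, each = n_lon))
    if (is.null(wrap)) wrap <- isTRUE(all.equal(n_lon * cs, 360))
    return(dynamic_landscape(sites, slices, n_lon, n_lat, wrap = wrap,
                             policy = policy, duration_kyr = duration_kyr))
  }
  landscape_from_table(utils::read.csv(x), duration_kyr, wrap, policy)
}

#' Write a landscape to disk
#'
#' @param landscape A [dynamic_landscape()].
#' @param path Output file (`format = "csv"`) or directory (`"asc"`).
#' @param format `"csv"` (single long table) or `"asc"` (one ASCII grid per
#'   variable per step).
#' @return `path`, invisibly.
#' @export
write_landscape <- function(landscape, path, format = c("csv", "asc")) {
  format <- match.arg(format)
  s <- landscape$sites
  if (format == "csv") {
    rows <- lapply(landscape$slices, function(sl) {
      data.frame(site_id = s$id, lon = s$lon, lat = s$lat, step = sl$step,
                 temperature = sl$temperature, aridity = sl$aridity)
    })
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    lons <- sort(unique(s$lon)); lats <- sort(unique(s$lat))
    cs <- if (length(lons) > 1) min(diff(lons)) else
      if (length(lats) > 1) min(diff(lats)) else 1
    xll <- min(lons) - cs / 2; yll <- min(lats) - cs / 2
    for (sl in landscape$slices) {
      write_asc(sl$temperature, landscape$n_lon, landscape$n_lat, xll, yll,
                cs, file.path(path, sprintf("temperature_%d.asc", sl$step)))
      write_asc(sl$aridity, landscape$n_lon, landscape$n_lat, xll, yll,
                cs, file.path(path, sprintf("aridity_%d.asc", sl$step)))
    }
  }
  invisible(path)
}
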