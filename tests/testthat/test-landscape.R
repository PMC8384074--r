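test_that("haversine distance matches closed forms and is metric-like", {
  expect_equal(haversine_km(12, 34, 12, 34), 0)
  expect_equal(haversine_km(0, 0, 1, 0), 111.195, tolerance = 1e-5)
  expect_equal(haversine_km(0, 0, 180, 0), 20015.1, tolerance = 1e-5)
  expect_error(haversine_km(NA, 0, 1, 0), "finite")
  set.seed(7)
  lon <- runif(30, -180, 180); lat <- runif(30, -90, 90)
  for (k in 1:10) {
    i <- sample(30, 3)
    ab <- haversine_km(lon[i[1]], lat[i[1]], lon[i[2]], lat[i[2]])
    ba <- haversine_km(lon[i[2]], lat[i[2]], lon[i[1]], lat[i[1]])
    ac <- haversine_km(lon[i[1]], lat[i[1]], lon[i[3]], lat[i[3]])
    cb <- haversine_km(lon[i[3]], lat[i[3]], lon[i[2]], lat[i[2]])
    expect_equal(ab, ba)
    expect_lte(ab, ac + cb + 1e-8)
  }
})

test_that("landscape loading derives habitability from missing values", {
  df <- expand.grid(lon = c(0.5, 1.5), lat = c(0.5, 1.5), step = 2:0)
  df$temperature <- 0.5
  df$aridity <- 0
  w <- load_landscape_series(df)
  expect_s3_class(w, "dynamic_landscape")
  expect_equal(nrow(w$sites), 4L)
  expect_length(w$slices, 3L)
  for (s in 0:2) expect_true(all(habitable_sites(w, s)))
  # one missing temperature value masks that site at that step only
  df$temperature[df$step == 1 & df$lon == 0.5 & df$lat == 1.5] <- NA
  w2 <- load_landscape_series(df)
  expect_equal(sum(habitable_sites(w2, 1)), 3L)
  expect_true(all(habitable_sites(w2, 0)))
  expect_true(all(habitable_sites(w2, 2)))
})

test_that("CSV and raster dialects load to the identical landscape", {
  w <- latitudinal_world(n_lon = 4, n_lat = 4, n_steps = 3,
                         land_fraction = 0.8, seed = 3)
  d_csv <- file.path(tempdir(), "w.csv")
  d_asc <- file.path(tempdir(), "w_asc")
  write_landscape(w, d_csv, "csv")
  write_landscape(w, d_asc, "asc")
  a <- load_landscape_series(d_csv)
  b <- load_landscape_series(d_asc)
  expect_equal(a$sites, b$sites)
  expect_equal(length(a$slices), length(b$slices))
  for (k in seq_along(a$slices)) {
    expect_equal(a$slices[[k]]$temperature, b$slices[[k]]$temperature,
                 tolerance = 1e-9)
    expect_equal(a$slices[[k]]$aridity, b$slices[[k]]$aridity,
                 tolerance = 1e-9)
  }
  expect_equal(a$sites$lon, w$sites$lon)
  expect_equal(a$sites$lat, w$sites$lat)
})

test_that("mismatched grids across slices are rejected", {
  df <- expand.grid(lon = c(0.5, 1.5), lat = c(0.5, 1.5), step = 1:0)
  df$temperature <- 0.5; df$aridity <- 0
  df$lon[df$step == 0][1] <- 99  # off-grid site in one slice
  expect_error(load_landscape_series(df), "grid")
})

test_that("costs between adjacent cells follow the crossing factors", {
  # one equatorial row of three cells, all land
  w <- toy_landscape(list(matrix(0.5, 1, 3)), res = 1)
  cm <- build_cost_matrix(w, 0)
  hop <- haversine_km(w$sites$lon[1], w$sites$lat[1],
                      w$sites$lon[2], w$sites$lat[2])
  expect_equal(cm["1", "2"], hop)
  # same geometry with an ocean gap in the middle: hops are equal length,
  # and the aquatic cell is twice as difficult to cross, so the total is
  # the sum of hop lengths with the ocean hop doubled (3 x hop)
  w2 <- toy_landscape(list(matrix(c(0.5, NA, 0.5), 1, 3)), res = 1)
  cm2 <- build_cost_matrix(w2, 0)
  expect_equal(dim(cm2), c(2L, 2L))
  expect_equal(cm2["1", "3"], 3 * hop, tolerance = 1e-9)
})

test_that("cost matrices equal a Floyd-Warshall oracle on random worlds", {
  set.seed(11)
  for (rep in 1:3) {
    tm <- matrix(0.5, 6, 6)
    tm[sample(36, 10)] <- NA
    w <- toy_landscape(list(tm), res = 2)
    cm <- build_cost_matrix(w, 0)
    d <- fw_shortest(hop_weights(w, 0))
    hab <- which(habitable_sites(w, 0))
    expect_equal(unclass(cm), d[hab, hab], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(unclass(cm), t(unclass(cm)))
    expect_true(all(diag(cm) == 0))
    expect_true(all(cm >= 0))
  }
})

test_that("equal factors give path costs bounded below by haversine", {
  w <- toy_landscape(list(matrix(0.5, 1, 8)), res = 1,
                     policy = cost_policy(1, 1))
  cm <- build_cost_matrix(w, 0)
  s <- w$sites
  # along a one-row equatorial strip the path cost is the sum of segment
  # lengths, which telescopes to the great-circle distance
  hops <- haversine_km(s$lon[-8], s$lat[-8], s$lon[-1], s$lat[-1])
  expect_equal(cm["1", "8"], sum(hops), tolerance = 1e-9)
  expect_equal(cm["1", "8"], haversine_km(s$lon[1], s$lat[1],
                                          s$lon[8], s$lat[8]),
               tolerance = 1e-6)
  for (i in 1:8) for (j in 1:8)
    expect_gte(cm[i, j] + 1e-9,
               haversine_km(s$lon[i], s$lat[i], s$lon[j], s$lat[j]))
})

test_that("local mode is the full matrix with long entries removed", {
  tm <- matrix(0.5, 4, 4); tm[c(2, 9)] <- NA
  w <- toy_landscape(list(tm), res = 2)
  full <- build_cost_matrix(w, 0)
  loc <- build_cost_matrix(w, 0,
                           cost_policy(mode = "local", local_range_km = 500))
  expected <- unclass(full)
  expected[expected > 500] <- Inf
  expect_equal(unclass(loc), expected)
  # triplet export drops non-finite entries and keeps the upper triangle
  tri <- cost_matrix_triplets(loc)
  expect_true(all(tri$cost_km <= 500))
  expect_true(all(tri$i < tri$j))
})

test_that("a slice with no habitable site yields an empty matrix", {
  w <- toy_landscape(list(matrix(NA_real_, 2, 2), matrix(0.5, 2, 2)))
  cm <- build_cost_matrix(w, 1)
  expect_equal(dim(cm), c(0L, 0L))
})
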