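test_that("LDG slope recovers exact linear gradients", {
  lat <- rep(0:50, each = 2)
  rich <- 100 - abs(lat)
  expect_equal(ldg_percent_loss(rich, lat, band_deg = 1), 1.0,
               tolerance = 1e-9)
  # uniform richness: zero slope
  expect_equal(ldg_percent_loss(rep(7, 20), rep(seq(5, 50, 5), 2)), 0)
  # invariant to a positive rescaling of richness (normalization)
  expect_equal(ldg_percent_loss(rich * 13, lat, band_deg = 1), 1.0,
               tolerance = 1e-9)
  # invariant to shuffling sites within a latitude band
  set.seed(2)
  lat2 <- rep(c(5, 15, 25), each = 4)
  rich2 <- c(8, 9, 10, 11, 6, 6, 7, 7, 1, 2, 3, 2)
  v1 <- ldg_percent_loss(rich2, lat2, band_deg = 10)
  idx <- unlist(lapply(split(seq_along(lat2), lat2), sample))
  v2 <- ldg_percent_loss(rich2[idx], lat2[idx], band_deg = 10)
  expect_equal(v1, v2)
  expect_error(ldg_percent_loss(rep(0, 10), rep(1:5, 2)), "all-zero")
})

test_that("latitudinal curve correlation reduces to Pearson's r", {
  lat <- rep(c(5, 15, 25, 35, 45), each = 2)
  rich <- rep(c(10, 8, 5, 3, 1), each = 2)
  bands <- 0:4
  self_ref <- data.frame(band = bands, value = c(10, 8, 5, 3, 1) / 10)
  expect_equal(ldg_curve_correlation(rich, lat, self_ref, band_deg = 10), 1)
  neg_ref <- data.frame(band = bands, value = -c(10, 8, 5, 3, 1) / 10)
  expect_equal(ldg_curve_correlation(rich, lat, neg_ref, band_deg = 10), -1)
  # hand-computed Pearson on a 5-band example
  ref <- data.frame(band = bands, value = c(0.9, 1.0, 0.3, 0.4, 0.1))
  got <- ldg_curve_correlation(rich, lat, ref, band_deg = 10)
  curve <- c(10, 8, 5, 3, 1) / 10
  expect_equal(got, cor(curve, ref$value))
  expect_error(ldg_curve_correlation(rich, lat,
                                     data.frame(band = 0:1,
                                                value = c(1, 2)),
                                     band_deg = 10), "common")
})

test_that("beta-splitting recovers imbalance against a grid-search oracle", {
  cat64 <- ape::stree(64, "left")
  bal64 <- ape::stree(64, "balanced")
  b_cat <- beta_splitting_ml(cat64)
  b_bal <- beta_splitting_ml(bal64)
  expect_lt(b_cat, -1.5)
  expect_gt(b_bal, 0)
  # brute-force grid oracle on a small tree: the ML beta lands within one
  # grid cell of the grid argmax
  oracle_ll <- function(tree, beta) {
    n_tip <- length(tree$tip.label)
    tree <- ape::reorder.phylo(tree, "postorder")
    nd <- integer(n_tip + tree$Nnode); nd[seq_len(n_tip)] <- 1L
    for (e in seq_len(nrow(tree$edge)))
      nd[tree$edge[e, 1]] <- nd[tree$edge[e, 1]] + nd[tree$edge[e, 2]]
    ll <- 0
    for (v in (n_tip + 1L):(n_tip + tree$Nnode)) {
      kk <- tree$edge[tree$edge[, 1] == v, 2]
      i <- nd[kk[1]]; n <- nd[v]
      q <- function(j) exp(lgamma(beta + j + 1) + lgamma(beta + n - j + 1) -
                             lgamma(j + 1) - lgamma(n - j + 1))
      ll <- ll + log(q(i) / sum(vapply(seq_len(n - 1), q, 0)))
    }
    ll
  }
  set.seed(4)
  for (tree in list(ape::rcoal(12), ape::stree(8, "left"),
                    ape::stree(16, "balanced"))) {
    grid <- seq(-1.99, 10, by = 0.01)
    ll <- vapply(grid, function(b) oracle_ll(tree, b), 0)
    b_hat <- beta_splitting_ml(tree)
    expect_lt(abs(b_hat - grid[which.max(ll)]), 0.02)
  }
})

test_that("beta-splitting ignores tip labels and branch lengths", {
  set.seed(10)
  tr <- ape::rcoal(32)
  b0 <- beta_splitting_ml(tr)
  tr2 <- tr
  tr2$tip.label <- sample(tr2$tip.label)
  expect_equal(beta_splitting_ml(tr2), b0)
  tr3 <- tr
  tr3$edge.length <- tr3$edge.length * 42
  expect_equal(beta_splitting_ml(tr3), b0)
  expect_error(beta_splitting_ml(ape::rcoal(2)), ">= 3 tips")
})

test_that("nLTT difference integrates the normalized step curves", {
  set.seed(21)
  t1 <- ape::rcoal(10)
  expect_equal(nltt_difference(t1, t1), 0)
  # hand-built 3-tip trees: splits at forward times (0.2, 0.8) vs
  # (0.5, 0.9) with the present at 1; the normalized curves differ by 1/3
  # on [0.75, 0.8), so the integral is 1/60
  a <- ape::read.tree(text = "((A:0.2,B:0.2):0.6,C:0.8);")
  b <- ape::read.tree(text = "((A:0.1,B:0.1):0.4,C:0.5);")
  expect_equal(nltt_difference(a, b), 1 / 60, tolerance = 1e-9)
  expect_equal(nltt_difference(b, a), nltt_difference(a, b))
  for (i in 1:20) {
    x <- ape::rcoal(sample(3:40, 1))
    y <- ape::rcoal(sample(3:40, 1))
    v <- nltt_difference(x, y)
    expect_gte(v, 0)
    expect_lte(v, 1)
  }
})

test_that("range-size spectra and the decrease rule behave as specified", {
  # all species on one site: single occupied bin, decrease check passes
  one <- range_size_stats(rep(5000, 8))
  expect_equal(nrow(one$histogram), 1L)
  expect_true(one$decrease_ok)
  # frequencies (10, 5, 2, 1) over octaves: negative slope, passes
  sizes <- rep(2^(0:3) * 1000, times = c(10, 5, 2, 1))
  rs <- range_size_stats(sizes)
  expect_equal(rs$histogram$frequency, c(10, 5, 2, 1))
  expect_lt(rs$srd_slope, 0)
  expect_true(rs$decrease_ok)
  # frequencies (5, 5, 10): the third bin exceeds by > 5% of 20 species
  bad <- rep(2^(0:2) * 1000, times = c(5, 5, 10))
  expect_false(range_size_stats(bad)$decrease_ok)
})

test_that("band rates match a hand-enumerated event log", {
  g <- data.frame(
    species_id = 1:4,
    parent_id = c(NA, 1L, 1L, 2L),
    origin_step = c(50L, 12L, 11L, 3L),
    extinction_step = c(NA, 4L, NA, NA),
    origin_lat = c(0, 10, 40, -30),
    extinction_lat = c(NA, 35, NA, NA))
  mig <- data.frame(step = c(12L, 12L, 3L),
                    lat_from = c(10, 40, -40),
                    lat_to = c(30, 45, -10))
  br <- band_rates(g, mig, duration_kyr = 170)
  # step 12 -> 2.04 Myr (window 2); step 11 -> 1.87 (window 1);
  # step 3 -> 0.51 (window 0); extinction step 4 -> 0.68 (window 0)
  expect_equal(br$speciation_low[br$window_myr == 2], 1)   # lat 10
  expect_equal(br$speciation_high[br$window_myr == 1], 1)  # lat 40
  expect_equal(br$speciation_high[br$window_myr == 0], 1)  # lat -30
  expect_equal(br$extinction_high[br$window_myr == 0], 1)  # lat 35
  expect_equal(br$migration_low_high[br$window_myr == 2], 1)
  expect_equal(br$migration_high_low[br$window_myr == 0], 1)
  # conservation: totals equal the log's event totals
  expect_equal(sum(br$speciation_low + br$speciation_high), 3)
  expect_equal(sum(br$extinction_low + br$extinction_high), 1)
  # an empty log gives an all-zero table
  g0 <- g[1, , drop = FALSE]
  br0 <- band_rates(g0, mig[0, , drop = FALSE])
  expect_true(all(br0[, -1] == 0))
})

test_that("POM acceptance combines the per-criterion flags", {
  ok <- list(ldg = 4.6, beta = -0.8, range_ok = TRUE, curve_r = 0.6,
             nltt = 0.1, extant = 25)
  f <- pom_acceptance(ok)
  expect_true(f$combined)
  expect_true(all(unlist(f)))
  f2 <- pom_acceptance(modifyList(ok, list(ldg = 0.5)))
  expect_false(f2$ldg); expect_false(f2$combined)
  f3 <- pom_acceptance(modifyList(ok, list(extant = 19)))
  expect_false(f3$extant); expect_false(f3$combined)
  f4 <- pom_acceptance(modifyList(ok, list(beta = NA)))
  expect_false(f4$beta); expect_false(f4$combined)
})
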