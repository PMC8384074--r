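test_that("divergence rate follows the temperature anchors", {
  r <- divergence_rate_rule("temperature", base_rate = 1, d_power = 2,
                            max_multiplier = 3)
  expect_equal(divergence_rate(r, 1), 3)    # 3x faster at the warmest
  expect_equal(divergence_rate(r, 0), 1)
  expect_equal(divergence_rate(r, 0.5), 1.5)
  expect_equal(divergence_rate(divergence_rate_rule("constant"), 0.9), 1)
  # monotone non-decreasing in temperature
  tt <- seq(0, 1, by = 0.05)
  vals <- vapply(tt, divergence_rate, 0, rule = r)
  expect_true(all(diff(vals) >= 0))
  expect_warning(out <- divergence_rate(r, 1.2), "clamped")
  expect_equal(out, 3)
})

test_that("dispersal kernels reproduce their closed-form moments", {
  k0 <- dispersal_kernel("constant", value_km = 500)
  expect_equal(draw_dispersal(k0, 3), c(500, 500, 500))
  expect_equal(kernel_median(k0), 500)
  kw <- dispersal_kernel("weibull", shape = 2, scale = 650)
  expect_equal(kernel_median(kw), 650 * log(2)^(1 / 2))
  set.seed(99)
  d <- draw_dispersal(kw, 1e5)
  expect_true(all(d >= 0))
  expect_equal(mean(d), 650 * gamma(1.5), tolerance = 0.01)
  expect_equal(unname(quantile(d, 0.95)), 650 * log(20)^0.5,
               tolerance = 0.02)
  expect_error(dispersal_kernel("weibull", shape = -1), "> 0")
})

test_that("dispersal colonizes reachable sites and never removes any", {
  w <- toy_landscape(list(matrix(0.5, 1, 5)), res = 1)
  cm <- build_cost_matrix(w, 0)
  sp <- create_ancestor_species(w, 0, ranges = list(3L))[[1L]]
  # zero kernel: no colonization
  res <- dispersal_step(sp, cm, dispersal_kernel("constant", value_km = 0),
                        habitable_ids = 1:5)
  expect_equal(res$species$sites, 3L)
  expect_equal(nrow(res$colonized), 0L)
  # unlimited kernel: full saturation in one step
  res <- dispersal_step(sp, cm, dispersal_kernel("constant", value_km = 1e6),
                        habitable_ids = 1:5)
  expect_equal(res$species$sites, 1:5)
  expect_equal(sort(res$colonized$site), c(1L, 2L, 4L, 5L))
  expect_true(all(res$species$abundance > 0))
})

test_that("among several successful sources the colonizer is uniform", {
  w <- toy_landscape(list(matrix(0.5, 1, 3)), res = 1)
  cm <- build_cost_matrix(w, 0)
  sp <- create_ancestor_species(w, 0, ranges = list(c(1L, 3L)))[[1L]]
  sp$t_opt <- c(0.1, 0.9)  # marks which source seeded the middle site
  kern <- dispersal_kernel("constant", value_km = 1e5)
  set.seed(123)
  wins <- 0L
  n_rep <- 4000L
  for (i in seq_len(n_rep)) {
    res <- dispersal_step(sp, cm, kern, habitable_ids = 1:3)
    t_new <- res$species$t_opt[res$species$sites == 2L]
    wins <- wins + (t_new == 0.1)
  }
  p <- binom.test(wins, n_rep, 0.5)$p.value
  expect_gt(p, 1e-4)
})

test_that("trait evolution is Brownian and homogenization abundance-weighted", {
  sp <- ecoevosim:::new_species(1L, NA_integer_, 5L, 1:2, c(3, 1),
                                c(0.2, 0.6))
  expect_equal(evolution_step(sp, 0)$t_opt, c(0.2, 0.6))
  # abundance-weighted cluster mean: (0.2*3 + 0.6*1) / 4 = 0.3
  h <- homogenize_traits(sp, c(1L, 1L))
  expect_equal(h$t_opt, c(0.3, 0.3))
  # distinct clusters stay untouched
  expect_equal(homogenize_traits(sp, c(1L, 2L))$t_opt, c(0.2, 0.6))
  # one-step increments have variance sigma^2
  big <- ecoevosim:::new_species(1L, NA_integer_, 5L, seq_len(1e4),
                                 rep(1, 1e4), rep(0.5, 1e4))
  set.seed(5)
  sigma <- 0.02
  inc <- evolution_step(big, sigma)$t_opt - 0.5
  expect_equal(var(inc), sigma^2, tolerance = 0.05)
})

test_that("niche abundance ramps down with temperature mismatch", {
  expect_equal(niche_abundance(0.5, 0.5, 0.1, 10), 10L)
  expect_equal(niche_abundance(0.5, 0.65, 0.1, 10), 0L)
  expect_equal(niche_abundance(0.5, 0.55, 0.1, 10), 5L)
  # non-increasing in the mismatch
  mis <- seq(0, 0.2, by = 0.01)
  ab <- niche_abundance(0.5 + mis, 0.5, 0.1, 10)
  expect_true(all(diff(ab) <= 0))
  abg <- niche_abundance(0.5 + mis, 0.5, 0.1, 10, form = "gaussian")
  expect_true(all(diff(abg) <= 0))
  expect_equal(abg[1], 10L)
})

test_that("site capacity scales with area energy", {
  expect_equal(site_capacity(c(0.2, 0.9), c(0, 1), 50, 2, "uniform"),
               c(50L, 50L))
  expect_equal(site_capacity(1, 0, 50, 3, "temp_aridity"), 50L)
  expect_equal(site_capacity(0.7, 1, 50, 2, "temp_aridity"), 0L)
  expect_equal(site_capacity(0.5, 0.5, 100, 2, "temp_aridity"),
               as.integer(round(100 * 0.25^2)))
})

test_that("capacity reduction removes exactly the excess individuals", {
  set.seed(31)
  expect_equal(apply_carrying_capacity(c(2, 2), 4), c(2, 2))
  red <- apply_carrying_capacity(c(5, 5), 4)
  expect_equal(sum(red), 4)
  expect_true(all(red >= 0 & red <= 5))
  for (i in 1:200) {
    ab <- sample(0:20, sample(1:6, 1), replace = TRUE)
    k <- sample(0:25, 1)
    red <- apply_carrying_capacity(ab, k)
    expect_equal(sum(red), min(sum(ab), k))
    expect_true(all(red <= ab))
  }
})

test_that("capacity reduction follows the urn (hypergeometric) law", {
  # abundances (9, 1), k = 5: the kept 5 individuals are a uniform draw
  # without replacement, so P(the singleton species goes locally
  # extinct) = 5/10 exactly
  set.seed(77)
  n_rep <- 1e4
  ext <- 0L
  for (i in seq_len(n_rep)) {
    red <- apply_carrying_capacity(c(9, 1), 5)
    ext <- ext + (red[2] == 0)
  }
  expect_equal(ext / n_rep, 0.5, tolerance = 0.04)
})
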