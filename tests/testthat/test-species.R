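test_that("ancestor creation spreads over the range with local optima", {
  tm <- matrix(seq(0.2, 0.9, length.out = 10), 2, 5)
  w <- toy_landscape(list(tm), res = 2)
  anc <- create_ancestor_species(w, 0)
  expect_length(anc, 1L)
  sp <- anc[[1L]]
  expect_equal(sp$id, 1L)
  expect_true(is.na(sp$parent_id))
  expect_length(sp$sites, 10L)
  expect_equal(sp$divergence, matrix(0, 10, 10))
  # "match local" rule: optimum equals the site temperature exactly
  sl <- w$slices[[1L]]
  expect_equal(sp$t_opt, sl$temperature[sp$sites])

  two <- create_ancestor_species(w, 0, n_ancestors = 2,
                                 ranges = list(1:5, 6:10))
  expect_equal(vapply(two, `[[`, 0L, "id"), 1:2)
  expect_true(all(is.na(vapply(two, `[[`, NA_integer_, "parent_id"))))
  expect_equal(two[[1L]]$sites, 1:5)
  expect_error(create_ancestor_species(w, 0, ranges = list(integer(0))),
               "no habitable site")
})

test_that("clustering thresholds the cost graph into components", {
  cm <- matrix(c(0, 100, 100, 0), 2, 2, dimnames = list(1:2, 1:2))
  expect_equal(cluster_sites(1:2, cm, 50), c(1L, 2L))
  expect_equal(cluster_sites(1:2, cm, 100), c(1L, 1L))
  expect_equal(cluster_sites(2L, cm, 1), 2L)
})

test_that("clustering matches a transitive-closure oracle on random instances", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(2:50, 1)
    d <- matrix(runif(n * n, 0, 1000), n, n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    dimnames(d) <- list(seq_len(n), seq_len(n))
    thr <- runif(1, 100, 600)
    labels <- cluster_sites(seq_len(n), d, thr)
    comp <- bf_components(d <= thr & !diag(TRUE, n))
    # identical partitions: labels agree iff oracle components agree
    expect_equal(outer(labels, labels, "=="), outer(comp, comp, "=="))
    # deterministic labelling by the lowest site id of each component
    expect_true(all(tapply(seq_len(n), labels, min) ==
                    as.integer(names(tapply(seq_len(n), labels, min)))))
  }
})

test_that("divergence accrues between clusters and decays within", {
  div <- matrix(0, 3, 3)
  lab <- c(1L, 1L, 3L)
  d1 <- update_divergence(div, lab, rate = 1)
  expect_equal(d1[1, 3], 1)
  expect_equal(d1[2, 3], 1)
  expect_equal(d1[1, 2], 0)
  expect_equal(d1, t(d1))
  # merged residual divergence decays to zero and never below
  div3 <- matrix(3, 2, 2); diag(div3) <- 0
  lab1 <- c(1L, 1L)
  x <- update_divergence(div3, lab1, 1)
  expect_equal(x[1, 2], 2)
  x <- update_divergence(update_divergence(x, lab1, 1), lab1, 1)
  expect_equal(x[1, 2], 0)
  x <- update_divergence(x, lab1, 1)
  expect_equal(x[1, 2], 0)
  # single cluster on an all-zero matrix is a fixed point
  expect_equal(update_divergence(matrix(0, 4, 4), rep(1L, 4), 1),
               matrix(0, 4, 4))
  expect_error(update_divergence(div, lab, -1), "non-negative")
})

test_that("species split when cross-cluster divergence reaches the threshold", {
  mk <- function(div, ab = c(1, 1)) {
    sp <- ecoevosim:::new_species(1L, NA_integer_, 10L, c(101L, 102L),
                                  ab, c(0.5, 0.5))
    sp$divergence <- div
    sp
  }
  below <- matrix(c(0, 5, 5, 0), 2, 2)
  res <- split_species(mk(below), c(101L, 102L), threshold = 6,
                       step = 4L, next_id = 2L)
  expect_length(res$species, 1L)
  expect_equal(nrow(res$events), 0L)

  at <- matrix(c(0, 6, 6, 0), 2, 2)
  res <- split_species(mk(at), c(101L, 102L), threshold = 6,
                       step = 4L, next_id = 2L)
  expect_length(res$species, 2L)
  expect_equal(res$events$child_id, 2L)
  expect_equal(res$events$parent_id, 1L)
  expect_equal(res$events$split_step, 4L)
  # retained divergence entries are all below the threshold
  for (sp in res$species)
    expect_true(all(sp$divergence < 6))
})

test_that("parent identity goes to the heaviest component", {
  sp <- ecoevosim:::new_species(7L, NA_integer_, 10L, c(1L, 2L),
                                c(1, 9), c(0.5, 0.5))
  sp$divergence <- matrix(c(0, 8, 8, 0), 2, 2)
  res <- split_species(sp, c(1L, 2L), threshold = 6, step = 3L,
                       next_id = 8L)
  keeper <- res$species[[1L]]
  expect_equal(keeper$id, 7L)
  expect_equal(keeper$sites, 2L)  # the abundance-9 population keeps the id
  expect_equal(res$species[[2L]]$id, 8L)
})

test_that("a chain of compatible clusters does not split", {
  # A-B over threshold but both connected to C below threshold:
  # one component, no split
  sp <- ecoevosim:::new_species(1L, NA_integer_, 10L, 1:3,
                                rep(1, 3), rep(0.5, 3))
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 7
  d[2, 3] <- d[3, 2] <- 3
  d[1, 3] <- d[3, 1] <- 3
  sp$divergence <- d
  res <- split_species(sp, 1:3, threshold = 6, step = 2L, next_id = 2L)
  expect_length(res$species, 1L)
  expect_equal(nrow(res$events), 0L)
})

test_that("colonists copy the divergence row of their source", {
  sp <- ecoevosim:::new_species(1L, NA_integer_, 10L, c(1L, 5L),
                                c(2, 3), c(0.4, 0.6))
  sp$divergence <- matrix(c(0, 4, 4, 0), 2, 2)
  sp2 <- ecoevosim:::add_populations(sp, new_sites = 3L, src_index = 1L,
                                     founder_abundance = 5)
  expect_equal(sp2$sites, c(1L, 3L, 5L))
  i1 <- match(1L, sp2$sites); i3 <- match(3L, sp2$sites)
  i5 <- match(5L, sp2$sites)
  expect_equal(sp2$divergence[i3, i5], 4)  # copied from source site 1
  expect_equal(sp2$divergence[i3, i1], 0)  # zero to its own source
  expect_equal(sp2$t_opt[i3], 0.4)
  expect_equal(sp2$abundance[i3], 5)
  expect_equal(sp2$divergence, t(sp2$divergence))
})
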