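test_that("dbscan_pbc equals brute-force eps-graph components on 200 random configs", {
  set.seed(101)
  for (rep in seq_len(200)) {
    m <- sample(2:120, 1L)
    box <- runif(1, 2, 8)
    eps <- runif(1, 0.05, 0.45) * box / 2
    # mix of uniform points and planted lumps to exercise both regimes
    pts <- matrix(runif(m * 3, 0, box), ncol = 3L)
    if (rep %% 2L == 0L) {
      lump <- sample(seq_len(m), ceiling(m / 3))
      pts[lump, ] <- wrap_coords(matrix(rnorm(length(lump) * 3, sd = eps),
                                        ncol = 3L), box)
    }
    got <- dbscan_pbc(pts, box, eps)
    want <- brute_force_components(pts, box, eps)
    expect_true(same_partition(got, want),
                label = sprintf("partition equality, config %d", rep))
  }
})

test_that("dbscan_pbc handles noise, straddling clusters and bad eps", {
  expect_identical(dbscan_pbc(matrix(c(1, 1, 1), 1L), 10, eps = 0.5), -1L)

  # a compact cluster straddling a box corner is one cluster, not several
  set.seed(5)
  blob <- matrix(rnorm(60, sd = 0.1), ncol = 3L)
  centered <- dbscan_pbc(wrap_coords(blob + 2.5, 5), 5, eps = 0.65)
  straddle <- dbscan_pbc(wrap_coords(blob, 5), 5, eps = 0.65)
  expect_identical(straddle, centered)
  expect_identical(unique(straddle), 0L)

  expect_error(dbscan_pbc(matrix(0, 2L, 3L), 5, eps = 2.5), "L/2")
})

test_that("dbscan_pbc recovers planted clusters and label conventions", {
  pl <- gen_planted_clusters(3, c(12, 7, 20), spread = 0.13, box_l = 14,
                             seed = 8)
  lab <- dbscan_pbc(pl$points, pl$box_l, eps = 0.65)
  expect_true(same_partition(lab, pl$labels))
  # labels are assigned by ascending smallest member index
  firsts <- vapply(sort(unique(lab[lab >= 0L])),
                   function(k) min(which(lab == k)), integer(1L))
  expect_identical(firsts, sort(firsts))

  # permuting the points permutes labels consistently
  set.seed(3)
  perm <- sample(nrow(pl$points))
  lab_p <- dbscan_pbc(pl$points[perm, ], pl$box_l, eps = 0.65)
  expect_true(same_partition(lab_p, pl$labels[perm]))
})

test_that("cluster_time_series summarizes per-frame populations", {
  # all molecules farther apart than eps
  grid <- as.matrix(expand.grid(c(1, 4, 7), c(1, 4, 7), c(1, 4, 7)))
  tr <- trajectory(array(grid, dim = c(27L, 3L, 1L)), 9, 0,
                   gen_ideal_gas(27, 9, 1, seed = 1)$topology)
  cts <- cluster_time_series(com_series(tr, "oil"), eps = 0.65)
  expect_identical(cts$summary$n_clusters, 0L)
  expect_identical(cts$summary$n_clustered, 0L)

  # a chain of points each within eps of the next forms one cluster of M
  chain <- cbind(seq(0.5, 5, by = 0.5), 1, 1)
  tr2 <- trajectory(array(chain, dim = c(10L, 3L, 1L)), 12, 0,
                    gen_ideal_gas(10, 12, 1, seed = 1)$topology)
  cts2 <- cluster_time_series(com_series(tr2, "oil"), eps = 0.65)
  expect_identical(cts2$summary$n_clusters, 1L)
  expect_identical(cts2$summary$largest, 10L)
  expect_identical(sum(cts2$sizes[[1L]]), 10L)
})

test_that("n_clustered rises in trend on the attractive-only generator", {
  tr <- gen_aggregation(aggregation_preset("hpg_like", seed = 33,
                                           steps = 2000L, stride = 20L))
  cts <- cluster_time_series(com_series(tr, "oil"), eps = 0.65)
  sm <- smooth_ma(cts$summary$n_clustered, 10L)
  n <- length(sm)
  # non-decreasing in trend: smoothed series never backslides by more than
  # one molecule and ends clearly above where it starts
  expect_gte(min(diff(sm)), -1)
  expect_gt(mean(sm[(n - 9L):n]), mean(sm[1:10]) + 3)
})

test_that("swarm radius of gyration is periodic-aware", {
  same <- matrix(rep(c(1, 2, 3), each = 4L), ncol = 3L)
  expect_equal(swarm_radius_of_gyration(same, 5), 0)
  expect_warning(swarm_radius_of_gyration(matrix(1, 1L, 3L), 5), "fewer than 2")

  # compact blob straddling a corner: equals the unwrapped Rg
  set.seed(11)
  blob <- matrix(rnorm(300, sd = 0.3), ncol = 3L)
  rg_plain <- sqrt(mean(rowSums(sweep(blob, 2L, colMeans(blob))^2)))
  rg_pbc <- swarm_radius_of_gyration(wrap_coords(blob, 6), 6)
  expect_equal(rg_pbc, rg_plain, tolerance = 1e-9)

  # invariance under global lattice translation
  shifted <- wrap_coords(blob + matrix(c(3, 3, 3), 100L, 3L, byrow = TRUE), 6)
  expect_equal(swarm_radius_of_gyration(shifted, 6), rg_pbc, tolerance = 1e-9)

  # bounded by the half-diagonal even for scattered points
  set.seed(12)
  scatter <- matrix(runif(90, 0, 6), ncol = 3L)
  expect_lte(swarm_radius_of_gyration(scatter, 6), sqrt(3) * 3)
})

test_that("swarm_series contracts on the aggregation generator", {
  tr <- gen_aggregation(aggregation_preset("hpg_like", seed = 33,
                                           steps = 2000L, stride = 20L))
  sw <- swarm_series(com_series(tr, "oil"))
  n <- nrow(sw)
  expect_true(all(sw$rg >= 0))
  expect_lt(mean(sw$rg[(n - 9L):n]), mean(sw$rg[1:10]))
})

test_that("coordination_vs_cluster_check tabulates windows", {
  ig <- gen_ideal_gas(100, 6, 40, seed = 14)
  cs <- com_series(ig, "oil")
  cts <- cluster_time_series(cs, eps = 0.65)
  r <- rdf_com(cs, bin_width = 0.05)
  cn <- coordination_number(r, 0.65)
  tab <- coordination_vs_cluster_check(cts, cn, window = 10L)
  expect_identical(nrow(tab), 4L)
  # ideal gas: mean eps-neighbors matches the rdf coordination number
  rho <- 100 / 6^3
  poisson <- rho * 4 / 3 * pi * 0.65^3
  expect_equal(mean(tab$mean_neighbors), poisson, tolerance = 0.25)
  expect_equal(cn, poisson, tolerance = 0.1)
})
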