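test_that("msd handles static, ballistic and wrapped inputs", {
  stat <- gen_brownian(5, 0, 1, 30, seed = 2)
  m0 <- msd(stat$unwrapped, lags = c(0, 5, 10), origin_stride = 1L)
  expect_equal(m0$msd, c(0, 0, 0))

  # ballistic x = v t: MSD = v^2 dt^2 exactly (3 axes at v = 1 each)
  nf <- 21L
  ball <- array(rep(0:20, each = 3L), dim = c(1L, 3L, nf))
  cs <- structure(list(coords = ball, times = 0:20,
                       box = matrix(100, nf, 3L), species = "oil",
                       wrapped = FALSE), class = "ComSeries")
  mb <- msd(cs, lags = c(0, 2, 4), origin_stride = 1L)
  expect_equal(mb$msd, 3 * c(0, 2, 4)^2)

  wrapped <- com_series(gen_brownian(3, 0.1, 0.1, 20, seed = 4, box_l = 4),
                        "oil")
  expect_error(msd(wrapped), "unwrapped")
  expect_error(msd(cs, lags = 50), "lags must lie")
})

test_that("fit_diffusion recovers slopes and flags nonlinearity", {
  # exact line MSD = 6 * 0.5 * t
  cs_line <- structure(list(lags = 0:100, lag_times = (0:100) * 0.1,
                            msd = 6 * 0.5 * (0:100) * 0.1,
                            n_samples = rep(1000L, 101L),
                            origin_stride = 1L, species = "oil"),
                       class = "MSDResult")
  fit <- fit_diffusion(cs_line)
  expect_equal(fit$d, 0.5, tolerance = 1e-12)
  expect_equal(fit$d_cm2_s, 0.5e-2, tolerance = 1e-12)
  expect_true(fit$linear)

  # quadratic (ballistic) MSD is flagged as non-linear
  cs_ball <- cs_line
  cs_ball$msd <- ((0:100) * 0.1)^2
  expect_false(fit_diffusion(cs_ball)$linear)

  expect_error(fit_diffusion(cs_line, window = c(0.001, 0.002)),
               "fewer than 3")
})

test_that("Brownian generator parameters are recovered within 5%", {
  b <- gen_brownian(1000, 1, 0.01, 2000, seed = 77)
  m <- msd(b$unwrapped, lags = seq(0, 100, by = 2), origin_stride = 5L)
  fit <- fit_diffusion(m)
  expect_equal(fit$d, 1, tolerance = 0.05)
  expect_true(fit$linear)
})

test_that("self van Hove is normalized with mode at 2 sqrt(D t)", {
  b <- gen_brownian(5000, 1, 0.01, 300, seed = 21)
  vh <- van_hove_self(b$unwrapped, lags = c(0, 40, 80, 120),
                      bin_width = 0.1, origin_stride = 2L)
  # t = 0: all mass in the first bin
  expect_equal(vh$p[1L, 1L] * vh$bin_width, 1)
  expect_true(all(vh$p[1L, -1L] == 0))
  # normalization per lag
  expect_equal(rowSums(vh$p) * vh$bin_width, rep(1, 4L), tolerance = 1e-6)
  # mode within one bin of 2 sqrt(D t) at three lags
  for (i in 2:4) {
    t <- vh$lag_times[i]
    mode_r <- vh$r[which.max(vh$p[i, ])]
    expect_lte(abs(mode_r - 2 * sqrt(t)), vh$bin_width)
  }
})

test_that("van Hove second moment equals msd exactly (shared estimator)", {
  b <- gen_brownian(200, 0.5, 0.05, 100, seed = 6)
  lags <- c(10, 30, 60)
  vh <- van_hove_self(b$unwrapped, lags = lags, origin_stride = 10L)
  m <- msd(b$unwrapped, lags = lags, origin_stride = 10L)
  expect_equal(vh$msd, m$msd, tolerance = 1e-9)
})

test_that("distinct van Hove reproduces g(r) at t = 0 bin-exactly", {
  ig <- gen_ideal_gas(150, 5, 30, seed = 15)
  cs <- com_series(ig, "oil")
  vhd <- van_hove_distinct(cs, lags = c(0, 5, 10), bin_width = 0.1,
                           origin_stride = 1L)
  g <- rdf_com(cs, bin_width = 0.1)
  # same frames, same estimator: identity up to rounding
  expect_equal(vhd$g_d[1L, ], g$g, tolerance = 1e-12)
  # ideal gas stays structureless at every lag (innermost bins carry too few
  # expected pairs for a tight bound, so check beyond 0.5 nm)
  expect_lt(max(abs(vhd$g_d[, vhd$r > 0.5] - 1)), 0.1)
  expect_message(van_hove_distinct(cs, lags = 0, r_max = 10), "truncated")
})

test_that("peak_decay starts at 1 and flags structureless input", {
  # frozen dimer configuration: a genuine first-shell peak at 0.3 nm, and
  # identical frames, so the peak ratio is identically 1
  set.seed(31)
  centers <- matrix(runif(45, 0.5, 4.5), ncol = 3L)
  dirs <- matrix(rnorm(45), ncol = 3L)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- wrap_coords(rbind(centers + 0.15 * dirs, centers - 0.15 * dirs), 5)
  frozen <- array(rep(pts, 10L), dim = c(30L, 3L, 10L))
  tr <- trajectory(frozen, 5, 0:9, gen_ideal_gas(30, 5, 1, seed = 1)$topology)
  vhd <- van_hove_distinct(com_series(tr, "oil"), lags = 0:5,
                           bin_width = 0.05, origin_stride = 1L)
  pd <- peak_decay(vhd)
  expect_equal(pd$ratio, rep(1, 6L))
  expect_false(pd$no_peak)

  # ideal gas: no detectable peak
  ig <- gen_ideal_gas(100, 5, 20, seed = 16)
  vhd2 <- van_hove_distinct(com_series(ig, "oil"), lags = c(0, 2, 4),
                            bin_width = 0.1, origin_stride = 1L)
  pd2 <- peak_decay(vhd2)
  expect_true(pd2$no_peak)
  expect_identical(pd2$ratio[1L], 1)

  expect_error(peak_decay(unclass(vhd2)), "VanHoveDistinct")
})

test_that("peak decay declines as local structure decorrelates", {
  # dense self-attracting droplet: molecules rearrange diffusively inside the
  # aggregate, so the first-shell correlation about a molecule's old position
  # washes out at long lags
  p <- aggregation_params(n_oil = 150L, n_polymer = 0L, box_l = 4.5,
                          eps_oil_oil = 3, eps_oil_polymer = 0,
                          dt = 0.01, steps = 4000L, stride = 10L, seed = 77)
  tr <- gen_aggregation(p)
  cs <- com_series(discard_frames(tr, 0.5), "oil")
  vhd <- van_hove_distinct(cs, lags = c(0L, 5L, 80L), bin_width = 0.05,
                           origin_stride = 2L)
  pd <- peak_decay(vhd)
  expect_false(pd$no_peak)
  expect_identical(pd$ratio[1L], 1)
  expect_lt(pd$ratio[3L], 0.8)          # long-lag decorrelation
  expect_lt(pd$ratio[3L], pd$ratio[2L]) # decaying, not drifting upward
})
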