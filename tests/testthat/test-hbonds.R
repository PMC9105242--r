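# Two three-atom molecules (donor O + H, acceptor O) with configurable
# geometry; species roles polymer (donor side) and terpenoid (acceptor side).
hb_fixture <- function(d_da = 0.30, angle_deg = 10, box = 5) {
  atoms <- data.frame(name = c("OD", "HD", "OA"),
                      mol = c(1L, 1L, 2L),
                      species = c("POL", "POL", "CAR"),
                      mass = c(15.999, 1.008, 15.999))
  si <- list(POL = list(role = "polymer", donors = "OD",
                        acceptors = character(),
                        hydrogens = list(OD = "HD")),
             CAR = list(role = "terpenoid", donors = character(),
                        acceptors = "OA", hydrogens = list()))
  topo <- topology(atoms, si)
  th <- angle_deg * pi / 180
  coords <- rbind(c(1, 1, 1),
                  c(1 + 0.1 * cos(th), 1 + 0.1 * sin(th), 1),
                  c(1 + d_da, 1, 1))
  list(topo = topo, coords = coords, box = rep(box, 3L))
}

test_that("detect_hbonds applies both geometric cutoffs", {
  fx <- hb_fixture(d_da = 0.30, angle_deg = 10)
  b <- detect_hbonds(fx$coords, fx$topo, fx$box)
  expect_identical(nrow(b), 1L)
  expect_identical(b$class, "polymer-compound")
  expect_equal(b$distance, 0.30, tolerance = 1e-9)
  expect_equal(b$angle, 10, tolerance = 1e-6)

  far <- hb_fixture(d_da = 0.36, angle_deg = 10)
  expect_identical(nrow(detect_hbonds(far$coords, far$topo, far$box)), 0L)

  bent <- hb_fixture(d_da = 0.30, angle_deg = 40)
  expect_identical(nrow(detect_hbonds(bent$coords, bent$topo, bent$box)), 0L)
})

test_that("bonds reach across periodic boundaries", {
  fx <- hb_fixture()
  coords <- fx$coords
  coords[1L, ] <- c(0, 1, 1)               # donor on the x = 0 face
  coords[3L, ] <- c(4.7, 1, 1)             # acceptor at min-image distance 0.3
  coords[2L, ] <- coords[1L, ] + c(-0.1, 0.0176, 0)  # H-D-A angle ~ 10 deg
  b <- detect_hbonds(coords, fx$topo, fx$box)
  expect_identical(nrow(b), 1L)
})

test_that("species without hydroxyl designations contribute no bonds", {
  fx <- hb_fixture()
  si <- fx$topo$species
  si$POL$donors <- character()
  si$POL$hydrogens <- list()
  topo2 <- topology(fx$topo$atoms, si)
  expect_identical(nrow(detect_hbonds(fx$coords, topo2, fx$box)), 0L)
})

test_that("a donor with no mapped hydrogens is an error", {
  fx <- hb_fixture()
  si <- fx$topo$species
  si$POL$hydrogens <- list()
  topo2 <- topology(fx$topo$atoms, si)
  expect_error(detect_hbonds(fx$coords, topo2, fx$box), "no mapped hydrogens")
})

test_that("hbond_criterion validates its cutoffs", {
  expect_error(hbond_criterion(d_max = -1), "> 0")
  expect_error(hbond_criterion(angle_max = 90), "\\(0, 90\\)")
})

test_that("hbond_counts tallies per class over frames", {
  fx <- hb_fixture()
  nf <- 4L
  coords <- array(rep(as.vector(fx$coords), nf), dim = c(3L, 3L, nf))
  # move the acceptor out of range in frames 3 and 4
  coords[3L, 1L, 3:4] <- 2.5
  tr <- trajectory(coords, fx$box, 0:3, fx$topo)
  hb <- hbond_counts(tr)
  expect_identical(hb$counts[["polymer-compound"]], c(1L, 1L, 0L, 0L))
  expect_identical(hb$counts[["polymer-polymer"]], rep(0L, 4L))
  # set semantics: a duplicate geometric solution is never double-counted
  expect_lte(max(vapply(hb$bonds, nrow, integer(1L))), 1L)
})

test_that("hbond_acf matches the trivial contracts", {
  always <- matrix(1L, 3L, 50L)
  acf1 <- hbond_acf(always, dt = 1)
  expect_equal(acf1$c, rep(1, 26L))

  once <- matrix(0L, 1L, 40L)
  once[1L, 1L] <- 1L
  acf0 <- hbond_acf(once, dt = 1)
  expect_equal(acf0$c[1L], 1)
  expect_true(all(acf0$c[-1L] == 0))

  empty <- hbond_acf(matrix(0L, 0L, 10L), dt = 1)
  expect_identical(empty$n_identities, 0L)
  expect_length(empty$c, 0L)
})

test_that("hbond_acf reproduces the Markov closed form within 0.02", {
  mb <- gen_markov_bonds(k_on = 0.02, k_off = 0.05, dt = 1, steps = 10000L,
                         n_chains = 100L, seed = 55)
  acf <- hbond_acf(mb$h, max_lag = 200L, dt = mb$dt)
  exact <- mb$acf_exact(acf$lag_times) / mb$acf_exact(0)
  expect_lt(max(abs(acf$c - exact)), 0.02)

  # fitted relaxation rate within 5% of k_on + k_off
  sel <- acf$c > mb$p / mb$acf_exact(0) + 0.05
  y <- log((acf$c[sel] - mb$p / mb$acf_exact(0)))
  rate <- -unname(coef(lm(y ~ acf$lag_times[sel]))[2L])
  expect_equal(rate, mb$rate, tolerance = 0.05)

  # stationarity: mean occupancy equals p within 3 binomial sigma
  n_obs <- length(mb$h)
  expect_lt(abs(mean(mb$h) - mb$p), 3 * sqrt(mb$p * (1 - mb$p) / n_obs) +
              0.005)
})

test_that("per-identity averaging is exposed and agrees for iid chains", {
  mb <- gen_markov_bonds(0.05, 0.05, dt = 1, steps = 3000L, n_chains = 50L,
                         seed = 8)
  pooled <- hbond_acf(mb$h, max_lag = 50L, dt = 1)
  per_id <- hbond_acf(mb$h, max_lag = 50L, dt = 1, per_identity = TRUE)
  expect_lt(max(abs(pooled$c - per_id$c)), 0.05)
})

test_that("integrate_acf recovers analytic integrals and flags plateaus", {
  tau0 <- 5
  lag_times <- seq(0, 80, by = 0.1)
  acf <- structure(list(lags = seq_along(lag_times) - 1L,
                        lag_times = lag_times,
                        c = exp(-lag_times / tau0),
                        n_identities = 1L, dt = 0.1), class = "HBondACF")
  res <- integrate_acf(acf)
  expect_equal(res$tau, tau0, tolerance = 0.02)
  expect_false(res$plateau)

  flat <- structure(list(lags = 0:10, lag_times = 0:10, c = rep(1, 11L),
                         n_identities = 1L, dt = 1), class = "HBondACF")
  resf <- integrate_acf(flat)
  expect_true(resf$plateau)
  expect_equal(resf$tau, 10)

  drop <- structure(list(lags = 0:1, lag_times = c(0, 2), c = c(1, 0),
                         n_identities = 1L, dt = 2), class = "HBondACF")
  expect_equal(integrate_acf(drop)$tau, 1)    # trapezoid: dt/2
})
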