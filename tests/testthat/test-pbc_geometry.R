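test_that("minimum-image displacement matches the examples", {
  expect_equal(min_image_vector(c(0.5, 0, 0), c(9.5, 0, 0), c(10, 10, 10)),
               c(-1, 0, 0))
  expect_equal(min_image_vector(c(1, 2, 3), c(1, 2, 3), 10), c(0, 0, 0))
  expect_error(min_image_displacement(c(1, 0, 0), c(-1, 5, 5)), "> 0")
})

test_that("minimum image equals the brute-force 27-image minimum", {
  set.seed(17)
  box <- c(4, 6, 9)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(60)) {
    a <- runif(3, 0, box)
    b <- runif(3, 0, box)
    mi <- min_image_vector(a, b, box)
    imgs <- sweep(shifts %*% diag(box), 2L, b - a, "+")
    expect_equal(sqrt(sum(mi^2)), min(sqrt(rowSums(imgs^2))),
                 tolerance = 1e-12)
    expect_lte(sqrt(sum(mi^2)), sqrt(sum((b - a)^2)) + 1e-12)
    expect_lte(sqrt(sum(mi^2)), sqrt(sum((box / 2)^2)) + 1e-12)
  }
})

test_that("min-image metric is symmetric and satisfies the triangle inequality", {
  set.seed(23)
  box <- 5
  mi_d <- function(a, b) sqrt(sum(min_image_vector(a, b, box)^2))
  for (i in seq_len(40)) {
    a <- runif(3, 0, box); b <- runif(3, 0, box); c <- runif(3, 0, box)
    expect_equal(mi_d(a, b), mi_d(b, a), tolerance = 1e-12)
    expect_lte(mi_d(a, c), mi_d(a, b) + mi_d(b, c) + 1e-12)
  }
})

test_that("reassemble_molecule rebuilds boundary-straddling molecules", {
  di <- matrix(c(9.8, 1, 1, 0.2, 1, 1), nrow = 2L, byrow = TRUE)
  out <- reassemble_molecule(di, 10)
  expect_equal(sqrt(sum((out[2L, ] - out[1L, ])^2)), 0.4)

  interior <- matrix(runif(12, 2, 3), ncol = 3L)
  expect_equal(reassemble_molecule(interior, 10), interior)

  # 25-atom chain built unwrapped around a box corner, then wrapped:
  # reassembly restores the unwrapped gyration radius exactly
  set.seed(4)
  steps <- matrix(rnorm(24 * 3, sd = 0.05), ncol = 3L)
  unwrapped <- rbind(c(0.05, 0.05, 0.05),
                     sweep(apply(steps, 2L, cumsum), 2L,
                           c(0.05, 0.05, 0.05), "+"))
  rg <- function(x) sqrt(mean(rowSums(sweep(x, 2L, colMeans(x))^2)))
  re <- reassemble_molecule(wrap_coords(unwrapped, 5), 5)
  expect_equal(rg(re), rg(unwrapped), tolerance = 1e-12)

  # a chained step can only exceed L/2 in norm across several axes
  stretched <- matrix(c(0, 0, 0, 4.9, 4.9, 4.9), nrow = 2L, byrow = TRUE)
  expect_warning(reassemble_molecule(stretched, 10), "stretched")
})

test_that("center_of_mass computes weighted means and validates input", {
  expect_equal(center_of_mass(matrix(c(0, 0, 0, 2, 0, 0), 2L, byrow = TRUE),
                              c(1, 1)), c(1, 0, 0))
  expect_equal(center_of_mass(matrix(c(0, 0, 0, 4, 0, 0), 2L, byrow = TRUE),
                              c(1, 3))[1L], 3)
  expect_error(center_of_mass(matrix(0, 2L, 3L), c(1, -1)), "> 0")
  expect_error(center_of_mass(matrix(0, 2L, 3L), 1), "length")
})

test_that("com_series wraps straddling molecule centers and is equivariant", {
  gro <- write_toy_gro(tempfile(fileext = ".gro"))
  st <- read_structure(gro)
  traj <- read_trajectory(gro, st$topology)
  # diatomic at x = 9.8/0.2 in a 10-box has wrapped COM at 0 = 10
  coords <- traj$coords
  coords[1L, , 1L] <- c(9.8, 1, 1)
  coords[2L, , 1L] <- c(0.2, 1, 1)
  tr2 <- trajectory(coords, c(10, 10, 10), traj$times, traj$topology)
  cs <- com_series(tr2, "OIL")
  # mass-weighted COM of the reassembled pair at x = 9.8 and 10.2, wrapped
  m <- tr2$topology$atoms$mass[1:2]
  expected <- (sum(m * c(9.8, 10.2)) / sum(m)) %% 10
  expect_equal(cs$coords[1L, 1L, 1L] %% 10, expected, tolerance = 1e-9)

  # translating every atom by a lattice vector leaves wrapped COMs unchanged
  coords3 <- coords + 10
  tr3 <- trajectory(wrap_coords(matrix(coords3[, , 1L], ncol = 3L),
                                10) |> array(dim = dim(coords)),
                    c(10, 10, 10), traj$times, traj$topology)
  cs3 <- com_series(tr3, "OIL")
  expect_equal(cs3$coords, cs$coords, tolerance = 1e-9)
})

test_that("unwrap_series inverts wrapping for continuous walks", {
  b <- gen_brownian(50, 0.5, 0.1, 300, seed = 9, box_l = 3)
  cs <- com_series(b, "oil")
  u <- unwrap_series(cs)
  expect_equal(u$coords, b$unwrapped$coords, tolerance = 1e-10)
  expect_error(unwrap_series(u), "already unwrapped")

  # a walker crossing the +x boundary repeatedly accumulates box lengths
  drift <- array(1, dim = c(1L, 3L, 31L))
  drift[1L, 1L, ] <- seq(0, 9, by = 0.3) %% 3      # 3 crossings of L = 3
  wrapped <- trajectory(drift, 3, 0:30,
                        gen_ideal_gas(1, 3, 1, seed = 1)$topology)
  cs_w <- com_series(wrapped, "oil")
  u2 <- unwrap_series(cs_w)
  expect_equal(u2$coords[1L, 1L, 31L], 9, tolerance = 1e-9)

  # static molecule stays constant
  stat <- gen_brownian(5, 0, 1, 20, seed = 2, box_l = 4)
  us <- unwrap_series(com_series(stat, "oil"))
  expect_equal(us$coords[, , 20L], us$coords[, , 1L])
})
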