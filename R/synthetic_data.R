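# Seeded synthetic-trajectory generators with known ground truth. They
# emulate the statistical structure of the simulated solutions -- dilute
# hydrophobic solutes that aggregate, amphiphilic carriers attaching to the
# aggregates, an optional carrier-carrier screened repulsion (polyelectrolyte-
# like) versus neutral carriers, free Brownian references with known D, and
# two-state on/off bond processes with known rates -- so that every analysis
# stage is testable without molecular dynamics data.

# Topology of point molecules (one atom per molecule) for generator output.
point_topology <- function(species_counts, roles) {
  n <- sum(species_counts)
  sp <- rep(names(species_counts), species_counts)
  atoms <- data.frame(name = "X", mol = seq_len(n), species = sp,
                      mass = 1, stringsAsFactors = FALSE)
  si <- lapply(names(species_counts), function(s) {
    list(role = roles[[s]], donors = character(), acceptors = character(),
         hydrogens = list())
  })
  names(si) <- names(species_counts)
  topology(atoms, si)
}

#' Ideal-gas trajectory (uniform points)
#'
#' Independent uniform points in a cubic box, redrawn each frame: the Poisson
#' reference for structure estimators (g(r) = 1, coordination =
#' rho 4/3 pi r^3).
#'
#' @param n Number of molecules (>= 1).
#' @param box_l Cubic box edge (nm).
#' @param n_frames Number of frames.
#' @param seed Integer seed (mandatory; same seed, same trajectory).
#' @param dt Frame spacing (ps), default 1.
#' @param species Species label, default "oil" with role terpenoid.
#' @return A wrapped \code{Trajectory} of single-atom molecules.
#' @export
gen_ideal_gas <- function(n, box_l, n_frames, seed, dt = 1,
                          species = "oil") {
  stopifnot(n >= 1L, n_frames >= 1L, box_l > 0)
  coords <- with_seed(seed, {
    array(stats::runif(n * 3L * n_frames, 0, box_l),
          dim = c(n, 3L, n_frames))
  })
  counts <- stats::setNames(as.integer(n), species)
  topo <- point_topology(counts, stats::setNames(list("terpenoid"), species))
  trajectory(coords, rep(box_l, 3L), (seq_len(n_frames) - 1) * dt, topo,
             wrapped = TRUE)
}

#' Brownian (free diffusion) trajectory with exact unwrapped twin
#'
#' Independent random walkers with Gaussian increments of variance 2 D dt per
#' axis: the oracle for MSD (Einstein relation MSD = 6 D t) and the self van
#' Hove function. When a box is given, the returned trajectory is wrapped and
#' the exact unwrapped twin is attached as \code{$unwrapped} (a
#' \code{ComSeries}); \code{unwrap_series} of the wrapped series reproduces
#' it exactly as long as single-frame steps stay below L/2.
#'
#' @param n Number of walkers.
#' @param d Diffusion coefficient (nm^2/ps), >= 0.
#' @param dt Time step between frames (ps).
#' @param steps Number of steps (frames = steps + 1).
#' @param seed Integer seed.
#' @param box_l Optional cubic box edge (nm). Without it the walk is
#'   unbounded and the trajectory itself is unwrapped.
#' @param species Species label, default "oil".
#' @return A \code{Trajectory}; element \code{$unwrapped} holds the exact
#'   unwrapped \code{ComSeries} twin.
#' @export
gen_brownian <- function(n, d, dt, steps, seed, box_l = NULL,
                         species = "oil") {
  stopifnot(n >= 1L, d >= 0, dt > 0, steps >= 1L)
  nf <- steps + 1L
  u <- with_seed(seed, {
    start <- if (is.null(box_l)) {
      matrix(0, n, 3L)
    } else {
      matrix(stats::runif(n * 3L, 0, box_l), n, 3L)
    }
    inc <- array(stats::rnorm(n * 3L * steps, sd = sqrt(2 * d * dt)),
                 dim = c(n, 3L, steps))
    out <- array(0, dim = c(n, 3L, nf))
    out[, , 1L] <- start
    for (f in seq_len(steps)) out[, , f + 1L] <- out[, , f] + inc[, , f]
    out
  })
  times <- (seq_len(nf) - 1) * dt
  bl <- box_l %||% (max(abs(u)) * 2 + 1)
  counts <- stats::setNames(as.integer(n), species)
  topo <- point_topology(counts, stats::setNames(list("terpenoid"), species))
  wrapped <- !is.null(box_l)
  coords <- if (wrapped) {
    w <- u
    for (f in seq_len(nf)) w[, , f] <- wrap_coords(u[, , f, drop = FALSE][, , 1L], box_l)
    w
  } else {
    u
  }
  traj <- trajectory(coords, rep(bl, 3L), times, topo, wrapped = wrapped)
  traj$unwrapped <- new_com_series(u, times, traj$box, species,
                                   wrapped = FALSE)
  traj$d <- d
  traj
}

#' Parameters for the Langevin aggregation generator
#'
#' Overdamped Brownian dynamics of point "oil" (hydrophobic solute) and
#' "polymer" (amphiphilic carrier) molecules with bounded pair forces:
#' a smoothed square-well attraction (cubic switch over the outer 30% of the
#' well range) for oil-oil and oil-polymer pairs, a soft repulsive core
#' keeping aggregates at liquid-like density, and an optional screened
#' (Yukawa-like) polymer-polymer repulsion. Repulsion on emulates a
#' partially screened polyelectrolyte carrier (dispersed small
#' carrier-centred clusters); repulsion off emulates a neutral carrier (a
#' single dominant mixed droplet). Energies are in units of kT.
#'
#' The default well depths make the carrier the primary binding site
#' (solute-carrier 6 kT versus solute-solute 1 kT), so solutes load onto the
#' carriers; with the strong repulsion off the loaded carriers condense into
#' one droplet, with it on they hold a dispersed spacing.
#'
#' @param n_oil,n_polymer Molecule counts (defaults 20 and 10; a
#'   solute-poor loading regime in which every solute molecule can sit in a
#'   carrier's attraction shell).
#' @param box_l Cubic box edge (nm), default 4.5. Must exceed 2 r_well.
#' @param d_oil,d_polymer Diffusion constants (nm^2/ps).
#' @param eps_oil_oil,eps_oil_polymer Square-well depths (kT).
#' @param r_well Attraction range (nm), default 0.65 (close-contact
#'   center-of-mass distance of the solutes).
#' @param r_core,eps_core Soft-core contact distance (nm) and strength (kT);
#'   oil-polymer contact is at 1x and polymer-polymer contact at 2x this
#'   distance (the carrier is the larger molecule).
#' @param repulsion Polymer-polymer screened repulsion on?
#' @param a_rep,lambda_rep Repulsion amplitude (kT) and screening length (nm).
#' @param dt Time step (ps). Stability guard: sqrt(2 max(D) dt) < r_well / 4.
#' @param steps,stride Total steps and save stride.
#' @param seed Integer seed (mandatory).
#' @return An \code{AggregationParams} list.
#' @export
aggregation_params <- function(n_oil = 20L, n_polymer = 10L, box_l = 4.5,
                               d_oil = 0.1, d_polymer = 0.1,
                               eps_oil_oil = 1, eps_oil_polymer = 6,
                               r_well = 0.65, r_core = 0.35, eps_core = 25,
                               repulsion = FALSE, a_rep = 70, lambda_rep = 1.1,
                               dt = 0.01, steps = 60000L, stride = 100L,
                               seed = NULL) {
  if (box_l <= 2 * r_well) stop("box_l must exceed 2 r_well", call. = FALSE)
  if (sqrt(2 * max(d_oil, d_polymer) * dt) >= r_well / 4) {
    stop("stability guard violated: sqrt(2 D dt) must be < r_well / 4",
         call. = FALSE)
  }
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  structure(list(n_oil = as.integer(n_oil), n_polymer = as.integer(n_polymer),
                 box_l = box_l, d_oil = d_oil, d_polymer = d_polymer,
                 eps_oil_oil = eps_oil_oil, eps_oil_polymer = eps_oil_polymer,
                 r_well = r_well, r_core = r_core, eps_core = eps_core,
                 repulsion = repulsion, a_rep = a_rep,
                 lambda_rep = lambda_rep, dt = dt, steps = as.integer(steps),
                 stride = as.integer(stride), seed = as.integer(seed)),
            class = "AggregationParams")
}

#' Named aggregation presets
#'
#' \code{"hpg_like"}: neutral carrier, no polymer-polymer repulsion; the
#' loaded carriers condense and the system coarsens into a single dominant
#' droplet holding most of the solute, with the large carriers forming the
#' droplet's outer scaffold (enriched toward its surface) and the solute
#' molecules nested in their attraction shells. \code{"hbpei_like"}: screened
#' polymer-polymer repulsion on; the system stays dispersed in small
#' carrier-centred clusters. The solute-carrier attraction dominating the
#' solute-solute one keeps every cluster bound to carriers, so the screened
#' carrier-carrier repulsion acts between whole clusters and blocks their
#' coalescence.
#'
#' @param name "hpg_like" or "hbpei_like".
#' @param seed Integer seed.
#' @param ... Overrides passed to \code{\link{aggregation_params}}.
#' @return An \code{AggregationParams}.
#' @export
aggregation_preset <- function(name = c("hpg_like", "hbpei_like"), seed,
                               ...) {
  name <- match.arg(name)
  if (name == "hpg_like") {
    aggregation_params(repulsion = FALSE, seed = seed, ...)
  } else {
    aggregation_params(repulsion = TRUE, seed = seed, ...)
  }
}

# Pair forces for the aggregation generator. x: n x 3 wrapped coordinates.
# Returns n x 3 force array (units kT/nm).
aggregation_forces <- function(x, species, p) {
  n <- nrow(x)
  w_sw <- 0.3 * p$r_well         # switch width
  is_oil <- species == "oil"
  # all-pairs minimum-image separation matrices d[i, j] = x_j - x_i
  d1 <- -min_image_displacement(outer(x[, 1L], x[, 1L], "-"), p$box_l)
  d2 <- -min_image_displacement(outer(x[, 2L], x[, 2L], "-"), p$box_l)
  d3 <- -min_image_displacement(outer(x[, 3L], x[, 3L], "-"), p$box_l)
  r <- sqrt(d1 * d1 + d2 * d2 + d3 * d3)
  diag(r) <- Inf
  mag <- matrix(0, n, n)         # dU/dr; force on i is +mag * d_ij / r
  # the carrier is a far larger molecule than the solute, so the
  # polymer-polymer contact (core) distance is twice the oil-oil one; each
  # attraction well keeps the same radial width r_well - r_core beyond its
  # contact distance.
  oo <- outer(is_oil, is_oil, "&")
  op <- outer(is_oil, is_oil, xor)
  pp <- outer(!is_oil, !is_oil, "&")
  core_m <- p$r_core * (oo + op + 2 * pp)
  well_m <- core_m + (p$r_well - p$r_core)
  # attraction (oil-oil, oil-polymer): smoothed square well. In the switch
  # region U = -eps * (1 - s(q)), s the cubic smoothstep, so dU/dr > 0
  # (inward force).
  epsm <- p$eps_oil_oil * oo + p$eps_oil_polymer * op
  in_sw <- which(r > well_m - w_sw & r < well_m & epsm > 0)
  if (length(in_sw) > 0L) {
    q <- (r[in_sw] - (well_m[in_sw] - w_sw)) / w_sw
    mag[in_sw] <- epsm[in_sw] * 6 * q * (1 - q) / w_sw
  }
  # soft core: U = eps_core (1 - r/core)^2 for r < core
  in_core <- which(r < core_m)
  if (length(in_core) > 0L) {
    rr <- pmax(r[in_core], 1e-9)
    mag[in_core] <- mag[in_core] -
      2 * p$eps_core * (1 - rr / core_m[in_core]) / core_m[in_core]
  }
  # screened polymer-polymer repulsion: U = A exp(-r/lambda)
  if (p$repulsion) {
    idx_pp <- which(pp & is.finite(r))
    if (length(idx_pp) > 0L) {
      mag[idx_pp] <- mag[idx_pp] -
        p$a_rep / p$lambda_rep * exp(-r[idx_pp] / p$lambda_rep)
    }
  }
  w <- mag / r                   # diag: 0 / Inf = 0
  cbind(rowSums(w * d1), rowSums(w * d2), rowSums(w * d3))
}

#' Langevin aggregation trajectory
#'
#' Integrates overdamped Langevin dynamics
#' x <- x + (D dt / kT) F + sqrt(2 D dt) xi under minimum-image pair forces
#' (see \code{\link{aggregation_params}}), saving every \code{stride}-th
#' step. All forces are bounded; particle count is conserved.
#'
#' @param params An \code{AggregationParams}.
#' @return A wrapped \code{Trajectory} with species "oil" (role terpenoid)
#'   and "polymer" (role polymer).
#' @export
gen_aggregation <- function(params) {
  stopifnot(inherits(params, "AggregationParams"))
  p <- params
  n <- p$n_oil + p$n_polymer
  species <- rep(c("oil", "polymer"), c(p$n_oil, p$n_polymer))
  d_vec <- ifelse(species == "oil", p$d_oil, p$d_polymer)
  save_at <- seq(0L, p$steps, by = p$stride)
  coords <- array(NA_real_, dim = c(n, 3L, length(save_at)))
  with_seed(p$seed, {
    x <- matrix(stats::runif(n * 3L, 0, p$box_l), n, 3L)
    k <- 1L
    if (save_at[1L] == 0L) {
      coords[, , 1L] <- x
      k <- 2L
    }
    noise_sd <- sqrt(2 * d_vec * p$dt)
    for (s in seq_len(p$steps)) {
      f <- aggregation_forces(x, species, p)
      x <- x + f * (d_vec * p$dt) +
        matrix(stats::rnorm(n * 3L), n, 3L) * noise_sd
      x <- wrap_coords(x, p$box_l)
      if (k <= length(save_at) && s == save_at[k]) {
        coords[, , k] <- x
        k <- k + 1L
      }
    }
  })
  if (any(!is.finite(coords))) {
    stop("aggregation generator produced non-finite coordinates",
         call. = FALSE)
  }
  counts <- c(oil = p$n_oil, polymer = p$n_polymer)
  topo <- point_topology(counts, list(oil = "terpenoid",
                                      polymer = "polymer"))
  traj <- trajectory(coords, rep(p$box_l, 3L), save_at * p$dt, topo,
                     wrapped = TRUE)
  traj$params <- p
  traj
}

#' Planted Gaussian clusters (clustering oracle)
#'
#' k Gaussian blobs whose centers are separated (minimum image) by at least
#' 5 (spread + eps), with the first blob centered on a box corner so that it
#' straddles all eight periodic images. DBSCAN at that eps recovers the
#' planted partition by construction.
#'
#' @param k Number of clusters.
#' @param sizes Per-cluster point counts (recycled to length k).
#' @param spread Gaussian sigma of each blob (nm).
#' @param box_l Cubic box edge (nm).
#' @param seed Integer seed.
#' @param eps Clustering scale the separation guard protects (default 0.65).
#' @return List with \code{points} (wrapped M x 3), \code{labels}
#'   (ground-truth 0-based), \code{centers}, \code{box_l}.
#' @export
gen_planted_clusters <- function(k, sizes, spread, box_l, seed, eps = 0.65) {
  stopifnot(k >= 1L, spread > 0, box_l > 0)
  sizes <- rep_len(as.integer(sizes), k)
  min_sep <- 5 * (spread + eps)
  if (min_sep >= box_l * sqrt(3) / 2 && k > 1L) {
    stop("box too small for the requested separation guard", call. = FALSE)
  }
  with_seed(seed, {
    centers <- matrix(NA_real_, k, 3L)
    centers[1L, ] <- 0          # straddles the corner
    if (k > 1L) {
      for (i in 2:k) {
        for (attempt in seq_len(10000L)) {
          cand <- stats::runif(3L, 0, box_l)
          d <- mi_dist_matrix(matrix(cand, 1L), centers[seq_len(i - 1L), ,
                                                        drop = FALSE], box_l)
          if (min(d) >= min_sep) {
            centers[i, ] <- cand
            break
          }
        }
        if (anyNA(centers[i, ])) {
          stop("could not place cluster centers; reduce k or separation",
               call. = FALSE)
        }
      }
    }
    pts <- do.call(rbind, lapply(seq_len(k), function(i) {
      matrix(stats::rnorm(sizes[i] * 3L, sd = spread), ncol = 3L) +
        matrix(centers[i, ], sizes[i], 3L, byrow = TRUE)
    }))
    list(points = wrap_coords(pts, box_l),
         labels = rep(seq_len(k) - 1L, sizes),
         centers = centers, box_l = box_l)
  })
}

#' Two-state Markov bond series (hydrogen-bond kinetics oracle)
#'
#' Independent stationary on/off chains sampled at interval dt with the exact
#' discrete-time transition kernel of the continuous-time two-state process
#' with rates k_on (off -> on) and k_off (on -> off). Initial states are
#' drawn from the equilibrium occupancy p = k_on / (k_on + k_off). The exact
#' intermittent autocorrelation C(t) = p + (1 - p) exp(-(k_on + k_off) t)
#' is attached as a closed form.
#'
#' @param k_on,k_off Rates (1/ps), k_on + k_off > 0.
#' @param dt Sampling interval (ps).
#' @param steps Number of sampled frames minus one.
#' @param n_chains Number of independent bonds.
#' @param seed Integer seed.
#' @return A \code{MarkovBonds} list: \code{h} (n_chains x frames 0/1
#'   matrix), \code{times}, \code{p}, \code{rate} (= k_on + k_off) and
#'   \code{acf_exact} (function of time).
#' @export
gen_markov_bonds <- function(k_on, k_off, dt, steps, n_chains, seed) {
  stopifnot(k_on >= 0, k_off >= 0, k_on + k_off > 0, dt > 0, steps >= 1L,
            n_chains >= 1L)
  rate <- k_on + k_off
  p <- k_on / rate
  decay <- exp(-rate * dt)
  p11 <- p + (1 - p) * decay     # P(on -> on) over dt
  p01 <- p * (1 - decay)         # P(off -> on) over dt
  nf <- steps + 1L
  h <- with_seed(seed, {
    m <- matrix(0L, n_chains, nf)
    m[, 1L] <- as.integer(stats::runif(n_chains) < p)
    for (f in 2:nf) {
      prob <- ifelse(m[, f - 1L] == 1L, p11, p01)
      m[, f] <- as.integer(stats::runif(n_chains) < prob)
    }
    m
  })
  structure(list(h = h, times = (seq_len(nf) - 1) * dt, p = p, rate = rate,
                 k_on = k_on, k_off = k_off, dt = dt,
                 acf_exact = function(t) p + (1 - p) * exp(-rate * t)),
            class = "MarkovBonds")
}
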