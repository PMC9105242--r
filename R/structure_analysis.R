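# Center-of-mass radial distribution functions with a long-range extension
# beyond half the box length, coordination numbers, first-shell detection,
# and the spherical-cap surface model for micelle-like clusters.

# --- minimum-image shell volumes --------------------------------------------
# For r <= L/2 the minimum-image shell volume equals the spherical shell
# 4/3 pi (r2^3 - r1^3). Beyond L/2 the spherical shell is clipped by the
# cubic Wigner-Seitz cell; the per-bin normalization volume is estimated once
# per box shape by Monte-Carlo sampling of the minimum-image distance
# distribution of uniform points (difference of two uniform points is uniform
# on the cell, so we sample displacement components on [-1/2, 1/2) directly),
# cached and reused. This avoids the error-prone piecewise closed forms for
# sphere-cube intersections and is validated by the ideal-gas unity test.

.shell_cache <- new.env(parent = emptyenv())

mi_shell_volumes <- function(box_l, edges, n_samples = 1e7, seed = 12345L) {
  key <- paste0("L", format(box_l, digits = 15L), "|",
                paste(format(edges, digits = 15L), collapse = ","),
                "|", n_samples, "|", seed)
  hit <- .shell_cache[[key]]
  if (!is.null(hit)) return(hit)
  v_box <- box_l^3
  exact <- 4 / 3 * pi * (edges[-1L]^3 - edges[-length(edges)]^3)
  vols <- exact
  needs_mc <- edges[-1L] > box_l / 2 + 1e-12
  if (any(needs_mc)) {
    u_edges <- edges / box_l           # scale-free: sample the unit cell
    counts <- numeric(length(edges) - 1L)
    total <- 0
    chunk <- 5e5
    n_chunks <- ceiling(n_samples / chunk)
    with_seed(seed, {
      for (i in seq_len(n_chunks)) {
        n_i <- min(chunk, n_samples - (i - 1L) * chunk)
        d <- matrix(stats::runif(3L * n_i, -0.5, 0.5), ncol = 3L)
        r <- sqrt(rowSums(d * d))
        idx <- findInterval(r, u_edges, rightmost.closed = FALSE)
        ok <- idx >= 1L & idx <= length(counts)
        counts <- counts + tabulate(idx[ok], nbins = length(counts))
        total <- total + n_i
      }
    })
    mc <- counts / total * v_box
    vols[needs_mc] <- mc[needs_mc]
  }
  .shell_cache[[key]] <- vols
  vols
}

# Histogram of minimum-image distances over ordered pairs (i from a, j from b,
# i != j skipped when exclude_self). Shared code path of rdf_com and
# van_hove_distinct so their t = 0 identity is bin-exact.
pair_hist <- function(a, b, box, edges, exclude_self) {
  d <- mi_dist_matrix(a, b, box)
  if (exclude_self) diag(d) <- NA_real_
  d <- d[!is.na(d)]
  idx <- findInterval(d, edges, rightmost.closed = FALSE)
  ok <- idx >= 1L & idx <= (length(edges) - 1L)
  tabulate(idx[ok], nbins = length(edges) - 1L)
}

#' Center-of-mass radial distribution function
#'
#' Estimates g(r) between molecular centers of mass of two species (or within
#' one species, excluding self-pairs) in a cubic periodic cell. In standard
#' mode r extends to L/2 with exact spherical-shell normalization. In
#' extended mode r reaches sqrt(3) L/2: beyond L/2 the shell normalization
#' volumes are the true minimum-image shell volumes of the cubic cell,
#' estimated by seeded Monte-Carlo sampling (cached per box shape), so that
#' g -> 1 at large r for homogeneous systems over the whole range.
#'
#' @param cs_a Wrapped \code{ComSeries} of species alpha.
#' @param cs_b Wrapped \code{ComSeries} of species beta on the same frames,
#'   or \code{NULL} for the like-species rdf of \code{cs_a}.
#' @param bin_width Bin width (nm), default 0.02.
#' @param r_max Maximum distance (nm); defaults to the mode's bound
#'   (L/2 standard, sqrt(3) L/2 extended). Exceeding the bound is an error.
#' @param extended Use the long-range extension beyond L/2?
#' @return An \code{RDFResult}: list with bin centers \code{r}, \code{g},
#'   raw pair \code{counts}, partner density \code{rho_b} (nm^-3), cumulative
#'   coordination \code{n_r} (through each bin's upper edge), \code{edges}, \code{shell_volumes},
#'   \code{extended}, and bookkeeping fields.
#' @export
rdf_com <- function(cs_a, cs_b = NULL, bin_width = 0.02, r_max = NULL,
                    extended = FALSE) {
  stopifnot(inherits(cs_a, "ComSeries"))
  like <- is.null(cs_b)
  if (like) cs_b <- cs_a
  stopifnot(inherits(cs_b, "ComSeries"))
  if (!isTRUE(cs_a$wrapped) || !isTRUE(cs_b$wrapped)) {
    stop("rdf_com requires wrapped com series", call. = FALSE)
  }
  nf <- dim(cs_a$coords)[3L]
  if (dim(cs_b$coords)[3L] != nf) {
    stop("alpha and beta series must cover the same frames", call. = FALSE)
  }
  box_l <- unique(as.vector(cs_a$box))
  if (length(box_l) != 1L) {
    stop("rdf_com requires a constant cubic box", call. = FALSE)
  }
  bound <- if (extended) sqrt(3) * box_l / 2 else box_l / 2
  if (is.null(r_max)) r_max <- bound
  if (r_max > bound + 1e-9) {
    stop(sprintf("r_max %.3f exceeds the %s-mode bound %.3f nm", r_max,
                 if (extended) "extended" else "standard", bound),
         call. = FALSE)
  }
  edges <- seq(0, r_max, by = bin_width)
  if (length(edges) < 2L) stop("r_max too small for bin_width", call. = FALSE)
  m_a <- dim(cs_a$coords)[1L]
  m_b <- dim(cs_b$coords)[1L]
  counts <- numeric(length(edges) - 1L)
  for (f in seq_len(nf)) {
    a <- matrix(cs_a$coords[, , f], ncol = 3L)
    b <- matrix(cs_b$coords[, , f], ncol = 3L)
    counts <- counts + pair_hist(a, b, box_l, edges, exclude_self = like)
  }
  v <- box_l^3
  vols <- mi_shell_volumes(box_l, edges)
  n_pairs <- m_a * (m_b - as.integer(like))
  g <- counts / (nf * n_pairs / v * vols)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  rho_b <- m_b / v
  # exact cumulative coordination: average pair count within the bin edges
  # (uses the true minimum-image shell volumes, valid beyond L/2)
  n_r <- cumsum(rho_b * g * vols)
  structure(list(pair = c(cs_a$species, cs_b$species), r = centers, g = g,
                 counts = counts, rho_b = rho_b, n_r = n_r, edges = edges,
                 shell_volumes = vols, extended = extended, box_l = box_l,
                 n_frames = nf, m_a = m_a, m_b = m_b, like = like),
            class = "RDFResult")
}

#' @export
print.RDFResult <- function(x, ...) {
  cat(sprintf("RDFResult %s-%s: %d bins to %.3f nm (%s mode), %d frames\n",
              x$pair[1L], x$pair[2L], length(x$r), max(x$edges),
              if (x$extended) "extended" else "standard", x$n_frames))
  invisible(x)
}

#' Coordination number from an rdf
#'
#' Average number of partner molecules within \code{r_cut}: the integral of
#' rho_beta g(s) over the shell volumes up to \code{r_cut}. Because it uses
#' the same (minimum-image) shell volumes as the g(r) normalization, it is
#' exact at bin edges and remains valid beyond L/2 in extended mode.
#'
#' @param rdf An \code{RDFResult}.
#' @param r_cut Cutoff distance (nm), at most the rdf's range.
#' @return Coordination number (dimensionless).
#' @export
coordination_number <- function(rdf, r_cut) {
  stopifnot(inherits(rdf, "RDFResult"))
  stopifnot_scalar_number(r_cut, "r_cut")
  if (r_cut < 0) stop("r_cut must be >= 0", call. = FALSE)
  if (r_cut > max(rdf$edges) + 1e-9) {
    stop("r_cut exceeds the rdf range", call. = FALSE)
  }
  if (r_cut == 0) return(0)
  # cumulative average pair count at the bin edges is exact; interpolate
  # linearly inside the bin containing r_cut
  n_edges <- c(0, cumsum(rdf$rho_b * rdf$g * rdf$shell_volumes))
  stats::approx(rdf$edges, n_edges, xout = r_cut, rule = 2L)$y
}

#' First coordination-shell boundary
#'
#' Locates the minimum between the first and second peaks of g(r): the g
#' values are smoothed by a centered moving average, the first local maximum
#' exceeding a height threshold is taken as the first peak, and the first
#' local minimum after it (leftmost point of a flat valley) is the shell
#' boundary. With no detectable peak (e.g. an ideal gas) an explicit
#' no-shell result is returned rather than a number.
#'
#' @param rdf An \code{RDFResult}.
#' @param smooth Moving-average window (points), default 5.
#' @param min_height Minimum smoothed peak height for a detectable first
#'   peak, default 1.1.
#' @return A \code{FirstShell}: list with \code{found}, and when found,
#'   \code{r_min}, \code{r_peak}, \code{g_peak}.
#' @export
first_shell_boundary <- function(rdf, smooth = 5L, min_height = 1.1) {
  stopifnot(inherits(rdf, "RDFResult"))
  gs <- moving_average(rdf$g, smooth)
  n <- length(gs)
  no_shell <- structure(list(found = FALSE, r_min = NA_real_,
                             r_peak = NA_real_, g_peak = NA_real_),
                        class = "FirstShell")
  if (n < 3L) return(no_shell)
  inner <- 2:(n - 1L)
  is_max <- gs[inner] > gs[inner - 1L] & gs[inner] >= gs[inner + 1L]
  peaks <- inner[is_max & gs[inner] >= min_height]
  if (length(peaks) == 0L) return(no_shell)
  p <- peaks[1L]
  after <- if (p + 1L <= n - 1L) (p + 1L):(n - 1L) else integer(0L)
  is_min <- gs[after] < gs[after - 1L] & gs[after] <= gs[after + 1L]
  mins <- after[is_min]
  if (length(mins) == 0L) return(no_shell)
  m <- mins[1L]
  structure(list(found = TRUE, r_min = rdf$r[m], r_peak = rdf$r[p],
                 g_peak = gs[p]),
            class = "FirstShell")
}

#' @export
print.FirstShell <- function(x, ...) {
  if (x$found) {
    cat(sprintf("First shell: peak at %.3f nm (g = %.2f), boundary %.3f nm\n",
                x$r_peak, x$g_peak, x$r_min))
  } else {
    cat("First shell: no detectable peak (no-shell result)\n")
  }
  invisible(x)
}

# --- spherical-cap surface model --------------------------------------------

#' Spherical-cap surface of the micelle model
#'
#' For a spherical cluster of radius R, the locus of points at distance x
#' from a probe molecule sitting on the cluster surface, intersected with the
#' cluster, is a spherical cap of area A(x) = 2 pi x^2 (1 - x / (2R)). The
#' polymer-solute pair distribution of a surface-decorated droplet is
#' proportional to this cap surface. A vanishes at x = 0 and x = 2R and is
#' maximized at x = 4R/3.
#'
#' @param x Probe distance(s), nm; must lie in [0, 2R] unless
#'   \code{strict = FALSE}.
#' @param r_cluster Cluster radius R (nm), > 0.
#' @param strict Error for x outside [0, 2R]? With \code{FALSE} the
#'   polynomial is evaluated anywhere (useful for root bracketing).
#' @return Cap surface area(s), nm^2.
#' @export
cap_area <- function(x, r_cluster, strict = TRUE) {
  stopifnot_scalar_number(r_cluster, "r_cluster", positive = TRUE)
  if (strict && (any(x < 0) || any(x > 2 * r_cluster))) {
    stop("x must lie in [0, 2R]", call. = FALSE)
  }
  2 * pi * x^2 * (1 - x / (2 * r_cluster))
}

#' Probe distance maximizing the spherical-cap surface
#'
#' Numerically maximizes A(x) on (0, 2R); the maximizer is x = 4R/3.
#'
#' @param r_cluster Cluster radius R (nm), > 0.
#' @return The maximizing distance x* (nm).
#' @export
cap_argmax <- function(r_cluster) {
  stopifnot_scalar_number(r_cluster, "r_cluster", positive = TRUE)
  opt <- stats::optimize(function(x) cap_area(x, r_cluster),
                         interval = c(0, 2 * r_cluster), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  x0 <- opt$maximum
  # polish: one bisection pass on the derivative sign via central differences
  h <- 1e-6 * r_cluster
  dA <- function(x) (cap_area(x + h, r_cluster, strict = FALSE) -
                       cap_area(x - h, r_cluster, strict = FALSE)) / (2 * h)
  lo <- max(x0 - 0.05 * r_cluster, h)
  hi <- min(x0 + 0.05 * r_cluster, 2 * r_cluster - h)
  if (dA(lo) > 0 && dA(hi) < 0) {
    x0 <- stats::uniroot(dA, c(lo, hi), tol = 1e-12)$root
  }
  x0
}
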