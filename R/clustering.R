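# DBSCAN clustering of molecular centers of mass under periodic boundary
# conditions, cluster-population time series, and the periodic-aware swarm
# radius of gyration.

# Minimum-image distance matrix between row-wise point sets A (m x 3) and
# B (n x 3). Shared by clustering, rdf and distinct van Hove estimators.
mi_dist_matrix <- function(a, b, box) {
  box <- expand_box(box)
  acc <- 0
  for (k in 1:3) {
    d <- outer(a[, k], b[, k], "-")
    d <- d - box[k] * floor(d / box[k] + 0.5)
    acc <- acc + d * d
  }
  sqrt(acc)
}

#' DBSCAN clustering with minimum-image distances
#'
#' Standard DBSCAN semantics on wrapped points in an orthorhombic periodic
#' box, with the minimum-image metric. A point is a core point when its
#' eps-neighborhood (including itself) holds at least \code{min_samples}
#' points. With the default \code{min_samples = 2} every non-noise point is a
#' core point, so the labels are exactly the connected components of the
#' eps-neighborhood graph and no border-point order ambiguity exists.
#' Cluster ids are assigned in ascending order of each cluster's smallest
#' member index, making the labeling deterministic.
#'
#' @param points M x 3 matrix of wrapped coordinates (nm).
#' @param box Box edges (nm).
#' @param eps Neighborhood radius (nm); must be < L/2 (the minimum-image
#'   metric is ill-posed for larger neighborhoods).
#' @param min_samples Core-point threshold (default 2).
#' @return Integer labels, 0-based cluster ids, -1 for noise.
#' @export
dbscan_pbc <- function(points, box, eps, min_samples = 2L) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3L)
  box <- expand_box(box)
  stopifnot_scalar_number(eps, "eps", positive = TRUE)
  if (eps >= min(box) / 2) {
    stop("eps must be < L/2 for the minimum-image metric", call. = FALSE)
  }
  if (min_samples < 1L) stop("min_samples must be >= 1", call. = FALSE)
  m <- nrow(points)
  if (m == 0L) return(integer(0L))
  d <- mi_dist_matrix(points, points, box)
  nb <- apply(d <= eps, 1L, which, simplify = FALSE)
  core <- lengths(nb) >= min_samples
  labels <- rep(-1L, m)
  assigned <- rep(FALSE, m)
  cl <- -1L
  for (i in seq_len(m)) {
    if (!core[i] || assigned[i]) next
    cl <- cl + 1L
    queue <- i
    assigned[i] <- TRUE
    labels[i] <- cl
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in nb[[p]]) {
        if (!assigned[q]) {
          assigned[q] <- TRUE
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  relabel_by_min_member(labels)
}

# Renumber cluster ids by ascending smallest member index.
relabel_by_min_member <- function(labels) {
  ids <- sort(unique(labels[labels >= 0L]))
  if (length(ids) == 0L) return(labels)
  firsts <- vapply(ids, function(k) min(which(labels == k)), integer(1L))
  remap <- integer(max(ids) + 1L)
  remap[ids[order(firsts)] + 1L] <- seq_along(ids) - 1L
  out <- labels
  out[labels >= 0L] <- remap[labels[labels >= 0L] + 1L]
  out
}

#' Cluster-population time series
#'
#' Applies \code{\link{dbscan_pbc}} to every frame of a wrapped
#' center-of-mass series and records per frame the number of clusters, the
#' number of clustered molecules, the largest cluster size, the mean number
#' of eps-neighbors per molecule, and the full cluster-size histogram.
#'
#' @param cs A wrapped \code{ComSeries}.
#' @param eps Neighborhood radius (nm).
#' @param min_samples Core threshold (default 2).
#' @return A \code{ClusterTimeSeries}: list with \code{summary} (data.frame:
#'   time, n_clusters, n_clustered, largest, mean_neighbors), \code{sizes}
#'   (list of per-frame size vectors), \code{labels} (M x n_frames matrix)
#'   and \code{params}.
#' @export
cluster_time_series <- function(cs, eps, min_samples = 2L) {
  stopifnot(inherits(cs, "ComSeries"))
  if (!isTRUE(cs$wrapped)) stop("cs must be wrapped", call. = FALSE)
  m <- dim(cs$coords)[1L]
  nf <- dim(cs$coords)[3L]
  if (m == 0L) {
    return(structure(list(summary = data.frame(), sizes = list(),
                          labels = matrix(integer(0L), 0L, 0L),
                          params = list(eps = eps, min_samples = min_samples)),
                     class = "ClusterTimeSeries"))
  }
  labels <- matrix(NA_integer_, nrow = m, ncol = nf)
  sizes <- vector("list", nf)
  summ <- data.frame(time = cs$times, n_clusters = NA_integer_,
                     n_clustered = NA_integer_, largest = NA_integer_,
                     mean_neighbors = NA_real_)
  for (f in seq_len(nf)) {
    pts <- cs$coords[, , f, drop = FALSE][, , 1L]
    if (m == 1L) pts <- matrix(pts, ncol = 3L)
    bx <- cs$box[f, ]
    lab <- dbscan_pbc(pts, bx, eps, min_samples)
    labels[, f] <- lab
    sz <- as.integer(table(lab[lab >= 0L]))
    sizes[[f]] <- sz
    d <- mi_dist_matrix(pts, pts, bx)
    summ$n_clusters[f] <- length(sz)
    summ$n_clustered[f] <- sum(sz)
    summ$largest[f] <- if (length(sz) > 0L) max(sz) else 0L
    summ$mean_neighbors[f] <- mean(rowSums(d <= eps) - 1L)
  }
  structure(list(summary = summ, sizes = sizes, labels = labels,
                 params = list(eps = eps, min_samples = min_samples)),
            class = "ClusterTimeSeries")
}

#' @export
print.ClusterTimeSeries <- function(x, ...) {
  cat(sprintf("ClusterTimeSeries: %d frames, eps = %g nm, min_samples = %d\n",
              nrow(x$summary), x$params$eps, x$params$min_samples))
  if (nrow(x$summary) > 0L) {
    last <- x$summary[nrow(x$summary), ]
    cat(sprintf("  final frame: %d clusters, %d molecules clustered, largest %d\n",
                last$n_clusters, last$n_clustered, last$largest))
  }
  invisible(x)
}

#' Swarm radius of gyration under periodic boundary conditions
#'
#' Radius of gyration of a point swarm in a periodic box, invariant under
#' global lattice translations. The swarm center is found per axis by
#' circular statistics (each coordinate mapped to an angle 2*pi*x/L, the mean
#' direction inverted back), then refined by the arithmetic mean of the
#' minimum-image deviations about it; deviations about the refined center are
#' taken by minimum image. For a compact swarm the result equals the ordinary
#' radius of gyration of the unwrapped points. Molecules are weighted
#' equally (the swarm counts molecules, not masses).
#'
#' @param points M x 3 matrix of wrapped coordinates (nm).
#' @param box Box edges (nm).
#' @return Radius of gyration (nm); 0 with a warning for fewer than 2 points.
#' @export
swarm_radius_of_gyration <- function(points, box) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3L)
  box <- expand_box(box)
  m <- nrow(points)
  if (m < 2L) {
    warning("swarm has fewer than 2 points; radius of gyration is 0",
            call. = FALSE)
    return(0)
  }
  center <- numeric(3L)
  for (k in 1:3) {
    theta <- 2 * pi * points[, k] / box[k]
    ang <- atan2(mean(sin(theta)), mean(cos(theta)))
    center[k] <- (ang * box[k] / (2 * pi)) %% box[k]
  }
  # refine: arithmetic mean of min-image deviations about the circular center
  for (rep in 1:2) {
    dev <- min_image_displacement(points - matrix(center, m, 3L, byrow = TRUE),
                                  box)
    center <- center + colMeans(dev)
  }
  dev <- min_image_displacement(points - matrix(center, m, 3L, byrow = TRUE),
                                box)
  sqrt(mean(rowSums(dev^2)))
}

#' Swarm radius-of-gyration time series
#'
#' @param cs A wrapped \code{ComSeries} (typically all terpenoid centers of
#'   mass, clustered or free).
#' @return A data.frame with columns \code{time} (ps) and \code{rg} (nm).
#' @export
swarm_series <- function(cs) {
  stopifnot(inherits(cs, "ComSeries"))
  if (!isTRUE(cs$wrapped)) stop("cs must be wrapped", call. = FALSE)
  nf <- dim(cs$coords)[3L]
  rg <- vapply(seq_len(nf), function(f) {
    pts <- cs$coords[, , f, drop = FALSE][, , 1L]
    if (dim(cs$coords)[1L] == 1L) pts <- matrix(pts, ncol = 3L)
    swarm_radius_of_gyration(pts, cs$box[f, ])
  }, numeric(1L))
  data.frame(time = cs$times, rg = rg)
}

#' Compare cluster neighbor counts with the rdf coordination number
#'
#' Tabulates, over frame windows, the mean number of eps-neighbors per
#' molecule seen by the clustering against the coordination number obtained
#' by integrating the pair distribution function up to the same cutoff.
#'
#' @param cts A \code{ClusterTimeSeries} (its \code{mean_neighbors} column is
#'   used; the eps of its params is the implied cutoff).
#' @param coordination Coordination number n(eps) from
#'   \code{\link{coordination_number}} on the matching rdf.
#' @param window Number of frames per averaging window (default 10).
#' @return data.frame with columns \code{time_start}, \code{time_end},
#'   \code{mean_neighbors}, \code{coordination}, \code{difference}.
#' @export
coordination_vs_cluster_check <- function(cts, coordination, window = 10L) {
  stopifnot(inherits(cts, "ClusterTimeSeries"))
  s <- cts$summary
  if (nrow(s) == 0L) {
    return(data.frame(time_start = numeric(0L), time_end = numeric(0L),
                      mean_neighbors = numeric(0L), coordination = numeric(0L),
                      difference = numeric(0L)))
  }
  grp <- (seq_len(nrow(s)) - 1L) %/% window
  agg <- lapply(split(seq_len(nrow(s)), grp), function(ii) {
    data.frame(time_start = s$time[ii[1L]], time_end = s$time[ii[length(ii)]],
               mean_neighbors = mean(s$mean_neighbors[ii]),
               coordination = coordination,
               difference = mean(s$mean_neighbors[ii]) - coordination)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
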