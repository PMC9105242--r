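# Minimum-image arithmetic, molecule reassembly, centers of mass and
# unwrapping for orthorhombic periodic cells. All analyses build on these.

#' Minimum-image displacement
#'
#' Displacement from point(s) \code{a} to point(s) \code{b} under the minimum
#' image convention in an orthorhombic box. Each component of the result lies
#' in \code{[-L/2, L/2)} for box edge \code{L}.
#'
#' @param a,b Numeric vectors of length 3, or n x 3 matrices (row-wise
#'   points). Units: nm.
#' @param box Box edge lengths, length-3 numeric (nm); a scalar is recycled.
#' @return Displacement(s), same shape as the inputs.
#' @examples
#' min_image_vector(c(0.5, 0, 0), c(9.5, 0, 0), c(10, 10, 10))  # -1 0 0
#' @export
min_image_vector <- function(a, b, box) {
  min_image_displacement(b - a, box)
}

#' Apply the minimum-image convention to displacement(s)
#'
#' @param d Displacement vector (length 3) or n x 3 matrix.
#' @param box Box edges (nm), length 3 or scalar.
#' @return Displacements folded so each component is in \code{[-L/2, L/2)}.
#' @export
min_image_displacement <- function(d, box) {
  box <- expand_box(box)
  if (any(box <= 0)) stop("box edges must be > 0", call. = FALSE)
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- d[, k] - box[k] * floor(d[, k] / box[k] + 0.5)
    d
  } else {
    d - box * floor(d / box + 0.5)
  }
}

expand_box <- function(box) {
  if (length(box) == 1L) box <- rep(box, 3L)
  if (length(box) != 3L) stop("box must have 3 edge lengths", call. = FALSE)
  as.numeric(box)
}

#' Wrap coordinates into the primary cell [0, L)
#'
#' @param x Length-3 vector or n x 3 matrix of coordinates (nm).
#' @param box Box edges (nm).
#' @return Coordinates wrapped into \code{[0, L)} per axis.
#' @export
wrap_coords <- function(x, box) {
  box <- expand_box(box)
  if (is.matrix(x)) {
    for (k in 1:3) x[, k] <- x[, k] - box[k] * floor(x[, k] / box[k])
    x
  } else {
    x - box * floor(x / box)
  }
}

#' Reassemble a molecule split across periodic boundaries
#'
#' Atoms are chained from the first atom: each atom is placed at the minimum
#' image position relative to the previously placed atom. This rebuilds
#' molecules crossing the box faces without needing bond information, relying
#' on contiguous atom order within the molecule (the GRO convention).
#'
#' @param coords n_atoms x 3 matrix of (possibly wrapped) coordinates (nm).
#' @param box Box edges (nm).
#' @return n_atoms x 3 matrix of contiguous coordinates. The first atom is
#'   left at its input position. A warning is issued if any chained step is
#'   longer than L/2 (unphysically stretched molecule).
#' @export
reassemble_molecule <- function(coords, box) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3L)
  n <- nrow(coords)
  if (n == 1L) return(coords)
  box <- expand_box(box)
  steps <- min_image_displacement(coords[-1L, , drop = FALSE] -
                                    coords[-n, , drop = FALSE], box)
  lens <- sqrt(rowSums(steps^2))
  if (any(lens > min(box) / 2)) {
    warning("molecule appears stretched: a chained atom-atom step exceeds L/2",
            call. = FALSE)
  }
  out <- coords
  out[-1L, ] <- matrix(rep(coords[1L, ], n - 1L), ncol = 3L, byrow = TRUE) +
    apply(steps, 2L, cumsum)
  if (n == 2L) out[2L, ] <- coords[1L, ] + steps[1L, ]
  out
}

#' Center of mass
#'
#' @param coords n x 3 coordinate matrix (nm).
#' @param masses Atomic masses (amu), length n; all > 0.
#' @return Length-3 center-of-mass position.
#' @export
center_of_mass <- function(coords, masses) {
  if (!is.matrix(coords)) coords <- matrix(coords, ncol = 3L)
  if (length(masses) != nrow(coords)) {
    stop("length(masses) must equal nrow(coords)", call. = FALSE)
  }
  if (any(masses <= 0)) stop("masses must be > 0", call. = FALSE)
  colSums(coords * masses) / sum(masses)
}

#' Per-molecule center-of-mass series for one species
#'
#' For every frame, each molecule of the species is reassembled across the
#' periodic boundaries, its mass-weighted center of mass is computed, and the
#' result is wrapped back into the primary cell.
#'
#' @param traj A \code{Trajectory}.
#' @param species Species name (character) present in the topology.
#' @return A \code{ComSeries}: list with \code{coords} (M x 3 x n_frames
#'   array, nm), \code{times} (ps), \code{box} (n_frames x 3), \code{species},
#'   and \code{wrapped = TRUE}.
#' @export
com_series <- function(traj, species) {
  stopifnot(inherits(traj, "Trajectory"))
  groups <- molecule_groups(traj$topology, species)
  if (length(groups) == 0L) {
    stop(sprintf("no molecules of species '%s' in topology", species),
         call. = FALSE)
  }
  nf <- length(traj$times)
  m <- length(groups)
  out <- array(NA_real_, dim = c(m, 3L, nf))
  masses <- traj$topology$atoms$mass
  single <- all(lengths(groups) == 1L)
  if (single) {
    idx <- vapply(groups, `[`, integer(1L), 1L)
    for (f in seq_len(nf)) {
      out[, , f] <- wrap_coords(traj$coords[idx, , f, drop = FALSE][, , 1L],
                                traj$box[f, ])
    }
  } else {
    for (f in seq_len(nf)) {
      bx <- traj$box[f, ]
      for (j in seq_len(m)) {
        ii <- groups[[j]]
        cc <- reassemble_molecule(traj$coords[ii, , f, drop = FALSE][, , 1L],
                                  bx)
        out[j, , f] <- wrap_coords(center_of_mass(cc, masses[ii]), bx)
      }
    }
  }
  new_com_series(out, traj$times, traj$box, species, wrapped = TRUE)
}

new_com_series <- function(coords, times, box, species, wrapped) {
  structure(list(coords = coords, times = as.numeric(times),
                 box = box, species = species, wrapped = wrapped),
            class = "ComSeries")
}

#' @export
print.ComSeries <- function(x, ...) {
  cat(sprintf("ComSeries: %d molecules of '%s', %d frames, %s coordinates\n",
              dim(x$coords)[1L], x$species, dim(x$coords)[3L],
              if (isTRUE(x$wrapped)) "wrapped" else "unwrapped"))
  invisible(x)
}

#' Unwrap a wrapped center-of-mass series
#'
#' Reconstructs continuous trajectories from wrapped ones: the displacement
#' between consecutive frames is taken as the minimum image of the wrapped
#' difference. Valid when no molecule moves L/2 or more between saved frames
#' (assumed, not checked -- see the methods vignette).
#'
#' @param cs A wrapped \code{ComSeries}.
#' @return The unwrapped \code{ComSeries} (first frame coordinates unchanged).
#' @export
unwrap_series <- function(cs) {
  stopifnot(inherits(cs, "ComSeries"))
  if (!isTRUE(cs$wrapped)) {
    stop("com series is already unwrapped", call. = FALSE)
  }
  w <- cs$coords
  nf <- dim(w)[3L]
  u <- w
  for (f in seq_len(nf)[-1L]) {
    d <- min_image_displacement(w[, , f, drop = FALSE][, , 1L] -
                                  w[, , f - 1L, drop = FALSE][, , 1L],
                                cs$box[f, ])
    u[, , f] <- u[, , f - 1L, drop = FALSE][, , 1L] + d
  }
  new_com_series(u, cs$times, cs$box, cs$species, wrapped = FALSE)
}
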