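# Geometric hydrogen-bond detection per frame, class-resolved counting,
# intermittent 0/1 time autocorrelation and integrated association lifetime.

#' Hydrogen-bond geometric criterion
#'
#' A donor-hydrogen-acceptor triple is a bond when the minimum-image
#' donor-acceptor distance is at most \code{d_max} and the
#' hydrogen-donor-acceptor angle is at most \code{angle_max}. The defaults
#' (0.35 nm, 30 degrees) are the GROMACS-convention geometric cutoffs.
#'
#' @param d_max Donor-acceptor distance cutoff (nm), > 0.
#' @param angle_max Hydrogen-donor-acceptor angle cutoff (degrees), in
#'   (0, 90).
#' @return An \code{HBondCriterion}.
#' @export
hbond_criterion <- function(d_max = 0.35, angle_max = 30) {
  stopifnot_scalar_number(d_max, "d_max", positive = TRUE)
  stopifnot_scalar_number(angle_max, "angle_max")
  if (angle_max <= 0 || angle_max >= 90) {
    stop("angle_max must lie in (0, 90) degrees", call. = FALSE)
  }
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "HBondCriterion")
}

# Donor table: one row per (donor atom, hydrogen atom) with molecule index.
donor_table <- function(topo) {
  at <- topo$atoms
  rows <- list()
  for (s in names(topo$species)) {
    si <- topo$species[[s]]
    dn <- si$donors %||% character()
    if (length(dn) == 0L) next
    hy <- si$hydrogens %||% list()
    for (d in dn) {
      hnames <- hy[[d]]
      if (is.null(hnames) || length(hnames) == 0L) {
        stop(sprintf("species '%s': donor '%s' has no mapped hydrogens",
                     s, d), call. = FALSE)
      }
      di <- which(at$species == s & at$name == d)
      for (h in hnames) {
        hi <- which(at$species == s & at$name == h)
        # pair donor and hydrogen within the same molecule
        mh <- match(at$mol[di], at$mol[hi])
        ok <- !is.na(mh)
        if (any(ok)) {
          rows[[length(rows) + 1L]] <- data.frame(donor = di[ok],
                                                  hydrogen = hi[mh[ok]],
                                                  mol = at$mol[di[ok]])
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(donor = integer(0L), hydrogen = integer(0L),
                      mol = integer(0L)))
  }
  do.call(rbind, rows)
}

acceptor_indices <- function(topo) {
  at <- topo$atoms
  out <- integer(0L)
  for (s in names(topo$species)) {
    ac <- topo$species[[s]]$acceptors %||% character()
    if (length(ac) > 0L) out <- c(out, which(at$species == s & at$name %in% ac))
  }
  sort(out)
}

hbond_class <- function(role_d, role_a) {
  both <- c(role_d, role_a)
  if (all(both == "polymer")) return("polymer-polymer")
  if (all(both == "terpenoid")) return("compound-compound")
  if (setequal(both, c("polymer", "terpenoid"))) return("polymer-compound")
  "other"
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates donor-hydrogen pairs against acceptor atoms (designated in the
#' topology via the species map), excluding intramolecular pairs, and applies
#' the geometric criterion with minimum-image distances.
#'
#' @param coords n_atoms x 3 coordinates of the frame (nm).
#' @param topo A \code{Topology} with donor/acceptor/hydrogen designations.
#' @param box Box edges (nm).
#' @param criterion An \code{HBondCriterion}.
#' @return data.frame with columns \code{donor}, \code{hydrogen},
#'   \code{acceptor} (atom indices), \code{distance} (nm), \code{angle}
#'   (degrees) and \code{class} (polymer-polymer, compound-compound,
#'   polymer-compound or other).
#' @export
detect_hbonds <- function(coords, topo, box, criterion = hbond_criterion()) {
  stopifnot(inherits(topo, "Topology"), inherits(criterion, "HBondCriterion"))
  dt <- donor_table(topo)
  ai <- acceptor_indices(topo)
  empty <- data.frame(donor = integer(0L), hydrogen = integer(0L),
                      acceptor = integer(0L), distance = numeric(0L),
                      angle = numeric(0L), class = character(0L),
                      stringsAsFactors = FALSE)
  if (nrow(dt) == 0L || length(ai) == 0L) return(empty)
  at <- topo$atoms
  d_da <- mi_dist_matrix(coords[dt$donor, , drop = FALSE],
                         coords[ai, , drop = FALSE], box)
  same_mol <- outer(dt$mol, at$mol[ai], "==")
  cand <- which(d_da <= criterion$d_max & !same_mol, arr.ind = TRUE)
  if (nrow(cand) == 0L) return(empty)
  di <- dt$donor[cand[, 1L]]
  hi <- dt$hydrogen[cand[, 1L]]
  aj <- ai[cand[, 2L]]
  v_dh <- min_image_displacement(coords[hi, , drop = FALSE] -
                                   coords[di, , drop = FALSE], box)
  v_da <- min_image_displacement(coords[aj, , drop = FALSE] -
                                   coords[di, , drop = FALSE], box)
  cosang <- rowSums(v_dh * v_da) /
    (sqrt(rowSums(v_dh^2)) * sqrt(rowSums(v_da^2)))
  cosang <- pmin(1, pmax(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  keep <- ang <= criterion$angle_max
  if (!any(keep)) return(empty)
  roles <- vapply(at$species, function(s) topo$species[[s]]$role %||%
                    NA_character_, character(1L))
  out <- data.frame(donor = di[keep], hydrogen = hi[keep],
                    acceptor = aj[keep],
                    distance = d_da[cand[keep, , drop = FALSE]],
                    angle = ang[keep], stringsAsFactors = FALSE)
  out$class <- mapply(hbond_class, roles[out$donor], roles[out$acceptor])
  # set semantics: one row per unique (donor, hydrogen, acceptor) triple
  out <- out[!duplicated(out[, c("donor", "hydrogen", "acceptor")]), ]
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond counts over a trajectory
#'
#' Runs \code{\link{detect_hbonds}} on every frame and records the per-class
#' bond counts and the full per-frame bond sets.
#'
#' @param traj A \code{Trajectory} whose topology carries donor, acceptor and
#'   hydrogen designations.
#' @param criterion An \code{HBondCriterion}.
#' @return An \code{HBondSeries}: list with \code{times}, \code{bonds}
#'   (per-frame data.frames), and \code{counts} (data.frame: time plus one
#'   column per bond class).
#' @export
hbond_counts <- function(traj, criterion = hbond_criterion()) {
  stopifnot(inherits(traj, "Trajectory"))
  nf <- length(traj$times)
  classes <- c("polymer-polymer", "compound-compound", "polymer-compound",
               "other")
  bonds <- vector("list", nf)
  counts <- matrix(0L, nrow = nf, ncol = length(classes),
                   dimnames = list(NULL, classes))
  for (f in seq_len(nf)) {
    b <- detect_hbonds(traj$coords[, , f, drop = FALSE][, , 1L],
                       traj$topology, traj$box[f, ], criterion)
    bonds[[f]] <- b
    if (nrow(b) > 0L) {
      tb <- table(factor(b$class, levels = classes))
      counts[f, ] <- as.integer(tb)
    }
  }
  df <- data.frame(time = traj$times, counts, check.names = FALSE)
  structure(list(times = traj$times, bonds = bonds, counts = df,
                 classes = classes, criterion = criterion),
            class = "HBondSeries")
}

# 0/1 occupancy matrix (bond identities x frames) for one class (or all).
hbond_occupancy <- function(series, class = NULL) {
  keys <- lapply(series$bonds, function(b) {
    if (nrow(b) == 0L) return(character(0L))
    bb <- if (is.null(class)) b else b[b$class == class, , drop = FALSE]
    sprintf("%d_%d_%d", bb$donor, bb$hydrogen, bb$acceptor)
  })
  ids <- unique(unlist(keys))
  h <- matrix(0L, nrow = length(ids), ncol = length(series$bonds),
              dimnames = list(ids, NULL))
  for (f in seq_along(keys)) {
    h[match(keys[[f]], ids), f] <- 1L
  }
  h
}

#' Intermittent hydrogen-bond autocorrelation
#'
#' The bond presence indicator h is 1 or 0 at each sampled frame. Pooling
#' over all bond identities ever observed (in the requested class) and all
#' time origins, C(t) = <h(t0 + t) h(t0)> / <h(t0)^2>, so C(0) = 1 by
#' construction. The intermittent definition is used: a bond that breaks and
#' reforms keeps contributing.
#'
#' @param series An \code{HBondSeries}, or directly a 0/1 matrix with one row
#'   per bond identity and one column per frame.
#' @param class Bond class to analyze (\code{NULL} pools all classes);
#'   ignored for matrix input.
#' @param max_lag Largest frame lag (default: half the frames).
#' @param dt Frame spacing (ps); taken from the series when available.
#' @param per_identity Average C per bond identity before pooling instead of
#'   pooling all products (default FALSE, pooled-identity averaging).
#' @return An \code{HBondACF}: list with \code{lags}, \code{lag_times},
#'   \code{c} and \code{n_identities}; zero identities give an empty result.
#' @export
hbond_acf <- function(series, class = NULL, max_lag = NULL, dt = NULL,
                      per_identity = FALSE) {
  if (inherits(series, "HBondSeries")) {
    h <- hbond_occupancy(series, class)
    if (is.null(dt) && length(series$times) > 1L) {
      dt <- series$times[2L] - series$times[1L]
    }
  } else if (is.matrix(series)) {
    h <- series
  } else {
    stop("series must be an HBondSeries or a 0/1 matrix", call. = FALSE)
  }
  dt <- dt %||% 1
  nf <- ncol(h)
  n_id <- nrow(h)
  if (n_id == 0L) {
    return(structure(list(lags = integer(0L), lag_times = numeric(0L),
                          c = numeric(0L), n_identities = 0L, dt = dt),
                     class = "HBondACF"))
  }
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  if (is.null(max_lag)) max_lag <- nf %/% 2L
  max_lag <- min(max_lag, nf - 1L)
  lags <- 0L:max_lag
  storage.mode(h) <- "double"
  cc <- numeric(length(lags))
  if (per_identity) {
    s0 <- rowMeans(h * h)
    use <- s0 > 0
    for (i in seq_along(lags)) {
      l <- lags[i]
      sl <- rowSums(h[, seq_len(nf - l), drop = FALSE] *
                      h[, seq_len(nf - l) + l, drop = FALSE]) / (nf - l)
      cc[i] <- mean((sl / s0)[use])
    }
  } else {
    s0 <- mean(h * h)
    for (i in seq_along(lags)) {
      l <- lags[i]
      sl <- sum(h[, seq_len(nf - l), drop = FALSE] *
                  h[, seq_len(nf - l) + l, drop = FALSE]) / (n_id * (nf - l))
      cc[i] <- sl / s0
    }
  }
  structure(list(lags = lags, lag_times = lags * dt, c = cc,
                 n_identities = n_id, dt = dt),
            class = "HBondACF")
}

#' @export
print.HBondACF <- function(x, ...) {
  if (x$n_identities == 0L) {
    cat("HBondACF: empty (no bonds ever observed in this class)\n")
  } else {
    cat(sprintf("HBondACF: %d identities, %d lags, C(0) = %g\n",
                x$n_identities, length(x$lags), x$c[1L]))
  }
  invisible(x)
}

#' Integrated hydrogen-bond timescale
#'
#' Trapezoidal integral of C(t) from 0 up to the first lag where C drops
#' below \code{threshold}, or to the last available lag if it never does (in
#' which case the plateau flag is set: the raw integral of a correlation with
#' a nonzero plateau diverges, so the reported value is a window-limited
#' lower bound).
#'
#' @param acf An \code{HBondACF}.
#' @param threshold Integration cutoff on C (default 0.01).
#' @return List with \code{tau} (ps), \code{cutoff_time}, \code{plateau}
#'   (flag) and \code{threshold}.
#' @export
integrate_acf <- function(acf, threshold = 0.01) {
  stopifnot(inherits(acf, "HBondACF"))
  if (length(acf$c) == 0L) {
    return(list(tau = NA_real_, cutoff_time = NA_real_, plateau = FALSE,
                threshold = threshold))
  }
  below <- which(acf$c < threshold)
  if (length(below) > 0L) {
    k <- below[1L]
    plateau <- FALSE
  } else {
    k <- length(acf$c)
    plateau <- TRUE
  }
  tau <- trapz(acf$lag_times[1:k], acf$c[1:k])
  list(tau = tau, cutoff_time = acf$lag_times[k], plateau = plateau,
       threshold = threshold)
}
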