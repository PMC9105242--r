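# Mean square displacement and Einstein-relation self-diffusion; self and
# distinct van Hove correlation functions; distinct-peak decay curves.

# Displacement magnitudes (nm) at an integer frame lag over all molecules and
# all time origins on the stride grid. Shared by msd() and van_hove_self() so
# their second-moment consistency is exact.
lag_displacements <- function(coords, lag, origin_stride) {
  nf <- dim(coords)[3L]
  if (lag == 0L) {
    n_orig <- length(seq(1L, nf, by = origin_stride))
    return(numeric(dim(coords)[1L] * n_orig))
  }
  origins <- seq(1L, nf - lag, by = origin_stride)
  d <- coords[, , origins + lag, drop = FALSE] -
    coords[, , origins, drop = FALSE]
  sq <- d[, 1L, , drop = FALSE]^2 + d[, 2L, , drop = FALSE]^2 +
    d[, 3L, , drop = FALSE]^2
  sqrt(as.vector(sq))
}

default_lag_grid <- function(nf, n_lags = 100L) {
  sort(unique(round(seq(0L, nf - 1L, length.out = min(nf, n_lags + 1L)))))
}

#' Mean square displacement over multiple time origins
#'
#' MSD(dt) averaged over all molecules and all time origins on a stride grid,
#' from an unwrapped center-of-mass series.
#'
#' @param cs An unwrapped \code{ComSeries} (a wrapped series is an error:
#'   wrapped coordinates do not measure transport).
#' @param lags Integer frame lags (0-based); default an even grid of about
#'   100 lags over the available range.
#' @param origin_stride Frames between time origins (default 10).
#' @return An \code{MSDResult}: list with \code{lag_times} (ps), \code{msd}
#'   (nm^2), \code{n_samples} per lag, and bookkeeping.
#' @export
msd <- function(cs, lags = NULL, origin_stride = 10L) {
  stopifnot(inherits(cs, "ComSeries"))
  if (isTRUE(cs$wrapped)) {
    stop("msd requires an unwrapped com series (see unwrap_series)",
         call. = FALSE)
  }
  nf <- dim(cs$coords)[3L]
  if (is.null(lags)) lags <- default_lag_grid(nf)
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0L) || any(lags > nf - 1L)) {
    stop("lags must lie in [0, n_frames - 1]", call. = FALSE)
  }
  dt_frame <- if (nf > 1L) cs$times[2L] - cs$times[1L] else 1
  out_msd <- numeric(length(lags))
  n_samp <- integer(length(lags))
  for (i in seq_along(lags)) {
    r <- lag_displacements(cs$coords, lags[i], origin_stride)
    out_msd[i] <- mean(r^2)
    n_samp[i] <- length(r)
  }
  structure(list(lags = lags, lag_times = lags * dt_frame, msd = out_msd,
                 n_samples = n_samp, origin_stride = origin_stride,
                 species = cs$species),
            class = "MSDResult")
}

#' Self-diffusion coefficient via the Einstein relation
#'
#' Fits a least-squares line to MSD versus lag time over a window and applies
#' the three-dimensional Einstein relation MSD = 6 D t, so D = slope / 6.
#' Units: with MSD in nm^2 and t in ps, D is in nm^2/ps;
#' 1 nm^2/ps = 1e-6 m^2/s = 1e-2 cm^2/s, so \code{d_cm2_s = d * 1e-2}.
#' A nonlinearity diagnostic (relative slope change between the window's two
#' halves) flags inputs outside the hydrodynamic (linear) regime.
#'
#' @param msd_result An \code{MSDResult}.
#' @param window Fit window: length-2 fractions of the maximum lag time
#'   (default c(0.1, 0.5), skipping short-time noise and poorly sampled
#'   tails), or absolute times (ps) when \code{fractions = FALSE}.
#' @param fractions Interpret \code{window} as fractions of the max lag?
#' @param nonlinearity_max Threshold for the linear-regime flag (default 0.1).
#' @return A \code{DiffusionFit}: list with \code{d} (nm^2/ps),
#'   \code{d_cm2_s}, \code{slope}, \code{intercept}, \code{r_squared},
#'   \code{nonlinearity}, \code{linear} (flag), \code{window} (ps).
#' @export
fit_diffusion <- function(msd_result, window = c(0.1, 0.5), fractions = TRUE,
                          nonlinearity_max = 0.1) {
  stopifnot(inherits(msd_result, "MSDResult"))
  t_all <- msd_result$lag_times
  w <- if (fractions) window * max(t_all) else window
  sel <- which(t_all >= w[1L] & t_all <= w[2L] & t_all > 0)
  if (length(sel) < 3L) {
    stop("fit window contains fewer than 3 lag points", call. = FALSE)
  }
  x <- t_all[sel]
  y <- msd_result$msd[sel]
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  # R^2 computed directly so an exactly linear input does not warn
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  half <- x <= stats::median(x)
  s1 <- unname(stats::coef(stats::lm(y[half] ~ x[half]))[2L])
  s2 <- unname(stats::coef(stats::lm(y[!half] ~ x[!half]))[2L])
  nonlin <- abs(s2 - s1) / abs(slope)
  structure(list(d = slope / 6, d_cm2_s = slope / 6 * 1e-2, slope = slope,
                 intercept = intercept, r_squared = r2, nonlinearity = nonlin,
                 linear = nonlin <= nonlinearity_max, window = range(x),
                 species = msd_result$species),
            class = "DiffusionFit")
}

#' @export
print.DiffusionFit <- function(x, ...) {
  cat(sprintf("DiffusionFit: D = %.4g nm^2/ps (%.4g x 1e-6 cm^2/s), window %.3g-%.3g ps%s\n",
              x$d, x$d_cm2_s * 1e6, x$window[1L], x$window[2L],
              if (x$linear) "" else "  [WARNING: non-linear MSD]"))
  invisible(x)
}

#' Self van Hove function (displacement distribution)
#'
#' Histograms the magnitudes of single-molecule displacements over molecules
#' and time origins and presents them as P(r; t) = 4 pi r^2 Gs(r; t),
#' normalized so that sum(P) * dr = 1 per lag: the probability density for a
#' molecule to be displaced by r, regardless of direction, within t.
#'
#' @param cs An unwrapped \code{ComSeries}.
#' @param lags Integer frame lags.
#' @param bin_width Histogram bin width (nm), default 0.05.
#' @param r_max Histogram range; defaults to covering the largest observed
#'   displacement.
#' @param origin_stride Frames between time origins (default 10).
#' @return A \code{VanHoveSelf}: list with \code{lag_times}, bin centers
#'   \code{r}, matrix \code{p} (lags x bins), exact per-lag second moment
#'   \code{msd}, and \code{n_samples}.
#' @export
van_hove_self <- function(cs, lags, bin_width = 0.05, r_max = NULL,
                          origin_stride = 10L) {
  stopifnot(inherits(cs, "ComSeries"))
  if (isTRUE(cs$wrapped)) {
    stop("van_hove_self requires an unwrapped com series", call. = FALSE)
  }
  nf <- dim(cs$coords)[3L]
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0L) || any(lags > nf - 1L)) {
    stop("lags must lie in [0, n_frames - 1]", call. = FALSE)
  }
  dt_frame <- if (nf > 1L) cs$times[2L] - cs$times[1L] else 1
  disp <- lapply(lags, function(l) lag_displacements(cs$coords, l,
                                                     origin_stride))
  if (is.null(r_max)) {
    r_max <- max(vapply(disp, function(r) if (length(r)) max(r) else 0,
                        numeric(1L))) + bin_width
  }
  edges <- seq(0, r_max + bin_width, by = bin_width)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  p <- matrix(0, nrow = length(lags), ncol = length(centers))
  m2 <- numeric(length(lags))
  ns <- integer(length(lags))
  for (i in seq_along(lags)) {
    r <- disp[[i]]
    idx <- findInterval(r, edges, rightmost.closed = FALSE)
    idx[idx > length(centers)] <- length(centers)
    idx[idx < 1L] <- 1L
    p[i, ] <- tabulate(idx, nbins = length(centers)) /
      (length(r) * bin_width)
    m2[i] <- mean(r^2)
    ns[i] <- length(r)
  }
  structure(list(lags = lags, lag_times = lags * dt_frame, r = centers,
                 p = p, msd = m2, n_samples = ns, bin_width = bin_width,
                 species = cs$species),
            class = "VanHoveSelf")
}

#' Distinct van Hove function
#'
#' For each lag t, histograms the minimum-image distances between molecule i
#' at t0 and every other molecule j != i at t0 + t, shell-normalized exactly
#' like a radial distribution function and divided by the molecular density,
#' so that Gd(r; 0)/rho reproduces g(r) bin for bin. Distances use wrapped
#' coordinates (the distinct part probes local structure, not transport).
#'
#' @param cs A wrapped \code{ComSeries}.
#' @param lags Integer frame lags (include 0 for the reference curve).
#' @param bin_width Bin width (nm), default 0.02.
#' @param r_max Maximum distance; capped at L/2 (standard minimum-image
#'   bound; larger requests are truncated with a message).
#' @param origin_stride Frames between time origins (default 10).
#' @return A \code{VanHoveDistinct}: list with \code{lag_times}, bin centers
#'   \code{r}, matrix \code{g_d} (lags x bins; the density-normalized
#'   Gd(r;t)/rho), and bookkeeping.
#' @export
van_hove_distinct <- function(cs, lags, bin_width = 0.02, r_max = NULL,
                              origin_stride = 10L) {
  stopifnot(inherits(cs, "ComSeries"))
  if (!isTRUE(cs$wrapped)) {
    stop("van_hove_distinct requires a wrapped com series", call. = FALSE)
  }
  nf <- dim(cs$coords)[3L]
  lags <- sort(unique(as.integer(lags)))
  if (any(lags < 0L) || any(lags > nf - 1L)) {
    stop("lags must lie in [0, n_frames - 1]", call. = FALSE)
  }
  box_l <- unique(as.vector(cs$box))
  if (length(box_l) != 1L) {
    stop("van_hove_distinct requires a constant cubic box", call. = FALSE)
  }
  if (is.null(r_max)) r_max <- box_l / 2
  if (r_max > box_l / 2 + 1e-9) {
    message("r_max truncated to L/2 (minimum-image bound)")
    r_max <- box_l / 2
  }
  dt_frame <- if (nf > 1L) cs$times[2L] - cs$times[1L] else 1
  edges <- seq(0, r_max, by = bin_width)
  centers <- (edges[-1L] + edges[-length(edges)]) / 2
  m <- dim(cs$coords)[1L]
  v <- box_l^3
  vols <- mi_shell_volumes(box_l, edges)
  g_d <- matrix(0, nrow = length(lags), ncol = length(centers))
  for (i in seq_along(lags)) {
    l <- lags[i]
    origins <- seq(1L, nf - l, by = origin_stride)
    counts <- numeric(length(centers))
    for (o in origins) {
      a <- matrix(cs$coords[, , o], ncol = 3L)
      b <- matrix(cs$coords[, , o + l], ncol = 3L)
      counts <- counts + pair_hist(a, b, box_l, edges, exclude_self = TRUE)
    }
    g_d[i, ] <- counts / (length(origins) * m * (m - 1L) / v * vols)
  }
  structure(list(lags = lags, lag_times = lags * dt_frame, r = centers,
                 g_d = g_d, rho = m / v, box_l = box_l, edges = edges,
                 bin_width = bin_width, species = cs$species),
            class = "VanHoveDistinct")
}

#' Peak-decay series of the distinct van Hove function
#'
#' Tracks the height of the first-shell maximum of Gd(r;t)/rho relative to
#' its t = 0 value: the rate at which the local arrangement of neighbors
#' loses structural coherence. The search window defaults to the first
#' coordination shell of the t = 0 curve (up to the minimum after its first
#' peak); without a detectable t = 0 peak, a no-peak result is flagged and
#' the ratio is reported over the full range.
#'
#' @param vhd A \code{VanHoveDistinct} whose first lag is 0.
#' @param r_window Optional length-2 numeric window (nm) overriding the
#'   auto-detected first-shell window.
#' @param min_height Peak-detection threshold on the smoothed t = 0 curve
#'   (default 1.1).
#' @return List with \code{lag_times}, \code{ratio} (ratio[1] is exactly 1),
#'   \code{h_max}, \code{r_at_max}, \code{window}, and \code{no_peak}.
#' @export
peak_decay <- function(vhd, r_window = NULL, min_height = 1.1) {
  stopifnot(inherits(vhd, "VanHoveDistinct"))
  if (vhd$lags[1L] != 0L) {
    stop("peak_decay needs the t = 0 curve as the first lag", call. = FALSE)
  }
  no_peak <- FALSE
  if (is.null(r_window)) {
    ref <- structure(list(r = vhd$r, g = vhd$g_d[1L, ], edges = vhd$edges,
                          rho_b = vhd$rho),
                     class = "RDFResult")
    fs <- first_shell_boundary(ref, min_height = min_height)
    if (fs$found) {
      r_window <- c(0, fs$r_min)
    } else {
      no_peak <- TRUE
      r_window <- range(vhd$r)
    }
  }
  sel <- which(vhd$r >= r_window[1L] & vhd$r <= r_window[2L])
  if (length(sel) == 0L) stop("empty peak window", call. = FALSE)
  h <- apply(vhd$g_d[, sel, drop = FALSE], 1L, max)
  at <- vhd$r[sel[apply(vhd$g_d[, sel, drop = FALSE], 1L, which.max)]]
  list(lag_times = vhd$lag_times, ratio = h / h[1L], h_max = h,
       r_at_max = at, window = r_window, no_peak = no_peak)
}
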