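# Oracles and shared fixtures for the test suite.

# Brute-force reference for dbscan_pbc at min_samples = 2: connected
# components of the eps-neighborhood graph under minimum-image distances,
# found by breadth-first search, labels assigned by ascending smallest member.
brute_force_components <- function(points, box, eps) {
  m <- nrow(points)
  if (m == 0L) return(integer(0L))
  d <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      dd <- min_image_displacement(points[j, ] - points[i, ], box)
      d[i, j] <- sqrt(sum(dd^2))
    }
  }
  adj <- d <= eps
  diag(adj) <- FALSE
  labels <- rep(-1L, m)
  cl <- -1L
  for (i in seq_len(m)) {
    if (labels[i] >= 0L || !any(adj[i, ])) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue) > 0L) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      for (q in which(adj[p, ])) {
        if (labels[q] < 0L) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# Canonical relabeling by order of first occurrence (noise kept at -1).
canon_labels <- function(l) {
  out <- rep(-1L, length(l))
  pos <- l >= 0L
  out[pos] <- match(l[pos], unique(l[pos]))
  out
}

# Two labelings describe the same partition (noise = -1 matched exactly)?
same_partition <- function(a, b) {
  length(a) == length(b) && identical(canon_labels(a), canon_labels(b))
}

# Centered moving average used by trend tests (window shrinks at edges).
smooth_ma <- function(x, k = 10L) {
  s <- stats::filter(x, rep(1 / k, k), sides = 2L)
  as.numeric(s[!is.na(s)])
}

# Published per-system atom totals (italic cells of the composition tables).
composition_totals <- c(
  car = 33534, thy = 30803, ter = 30011, cym = 30669, mix = 277072,
  hbpei8_7 = 106472, hbpei8_14 = 107872, hbpei8_21 = 109272,
  hbpei27_7 = 359343, hbpei27_mix = 360340,
  hpg8_10 = 56936, hpg8_20 = 58936, hpg8_30 = 60936,
  hpg27_10 = 192159, hpg27_mix = 193605
)

# Write a small two-species single- or multi-frame GRO file and return the
# path. Coordinates: one "oil" diatomic and one free particle.
write_toy_gro <- function(path, n_frames = 1L, box = c(5, 5, 5)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * 2
    writeLines(sprintf("toy frame t= %.4f", t), con)
    writeLines("    3", con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "OIL", "C1", 1L,
                       1.0 + 0.1 * (f - 1), 1.0, 1.0), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "OIL", "O1", 2L,
                       1.2 + 0.1 * (f - 1), 1.0, 1.0), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2L, "SOL", "OW", 3L,
                       3.0, 3.0, 3.0), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1L], box[2L], box[3L]), con)
  }
  path
}

# --- aggregation phenomenology metrics ---------------------------------------
# Protocol: per seed, statistics over the last 25% of saved frames.

agg_last_frames <- function(traj) {
  nf <- length(traj$times)
  seq.int(ceiling(0.75 * nf) + 1L, nf)
}

# Median (over the last 25% of frames) of the largest oil cluster's share of
# all oil molecules, plus the median cluster count.
agg_oil_cluster_stats <- function(traj, eps = 0.65) {
  cs <- com_series(traj, "oil")
  frames <- agg_last_frames(traj)
  n_oil <- dim(cs$coords)[1L]
  frac <- numeric(length(frames))
  ncl <- integer(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    lab <- dbscan_pbc(matrix(cs$coords[, , f], ncol = 3L), cs$box[f, ], eps)
    sz <- as.integer(table(lab[lab >= 0L]))
    frac[i] <- if (length(sz) > 0L) max(sz) / n_oil else 0
    ncl[i] <- length(sz)
  }
  list(largest_fraction = stats::median(frac),
       n_clusters = stats::median(ncl))
}

# Time-averaged surface enrichment of the dominant mixed aggregate: mean
# radial distance of carrier molecules minus that of solute molecules about
# the largest all-species cluster's center. Positive = carriers sit closer to
# the aggregate's boundary than the solutes.
agg_surface_enrichment <- function(traj, eps = 0.85) {
  frames <- agg_last_frames(traj)
  species <- traj$topology$atoms$species
  out <- numeric(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[i]
    pts <- traj$coords[, , f, drop = FALSE][, , 1L]
    bx <- traj$box[f, ]
    lab <- dbscan_pbc(pts, bx, eps)
    sz <- table(lab[lab >= 0L])
    if (length(sz) == 0L) {
      out[i] <- NA_real_
      next
    }
    big <- as.integer(names(sz)[which.max(sz)])
    mem <- which(lab == big)
    ref <- pts[mem[1L], ]
    dev <- min_image_displacement(
      pts[mem, , drop = FALSE] - matrix(ref, length(mem), 3L, byrow = TRUE),
      bx)
    ctr <- ref + colMeans(dev)
    d <- min_image_displacement(
      pts[mem, , drop = FALSE] - matrix(ctr, length(mem), 3L, byrow = TRUE),
      bx)
    rad <- sqrt(rowSums(d^2))
    is_oil <- species[mem] == "oil"
    if (all(is_oil) || !any(is_oil)) {
      out[i] <- NA_real_
    } else {
      out[i] <- mean(rad[!is_oil]) - mean(rad[is_oil])
    }
  }
  mean(out, na.rm = TRUE)
}
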