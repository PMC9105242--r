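# Run configuration and pipeline orchestration: read inputs, discard the
# equilibration span, run the enabled analyses, and write CSV tables plus a
# JSON run manifest echoing every parameter used.

#' Run configuration
#'
#' @param structure Path to the GRO structure file.
#' @param trajectory Path to the trajectory (multi-frame GRO).
#' @param species_map Optional path to a YAML species map.
#' @param discard_fraction Fraction of leading frames discarded as
#'   equilibration, in [0, 1); default 0.5 (analyses over the second half of
#'   the run, mirroring common practice of omitting the approach to steady
#'   state).
#' @param seed Integer seed, recorded in outputs.
#' @param outdir Output directory (created if missing).
#' @param analyses Named list of per-analysis settings; each entry is a list
#'   with at least \code{enabled} plus analysis-specific parameters. Known
#'   analyses: clusters (species, eps, min_samples), rdf (species_a,
#'   species_b, bin_width, r_max, extended), msd (species, origin_stride),
#'   vanhove (species, lags, bin_width), hbonds (d_max, angle_max, class),
#'   swarm (species).
#' @return A \code{RunConfig}.
#' @export
run_config <- function(structure, trajectory, species_map = NULL,
                       discard_fraction = 0.5, seed = 1L,
                       outdir = tempfile("oilcluster_run_"),
                       analyses = list()) {
  if (discard_fraction < 0 || discard_fraction >= 1) {
    stop("discard_fraction must lie in [0, 1)", call. = FALSE)
  }
  known <- c("clusters", "rdf", "msd", "vanhove", "hbonds", "swarm")
  bad <- setdiff(names(analyses), known)
  if (length(bad) > 0L) {
    stop(sprintf("unknown analysis key(s): %s (known: %s)",
                 paste0("analyses.", bad, collapse = ", "),
                 paste(known, collapse = ", ")), call. = FALSE)
  }
  structure(list(structure = structure, trajectory = trajectory,
                 species_map = species_map,
                 discard_fraction = discard_fraction, seed = as.integer(seed),
                 outdir = outdir, analyses = analyses),
            class = "RunConfig")
}

#' Load a run configuration from YAML
#' @param path YAML config path.
#' @return A \code{RunConfig}.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read config '%s': no such file", path),
         call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  for (key in c("structure", "trajectory")) {
    if (is.null(y[[key]])) {
      stop(sprintf("config '%s' is missing required key '%s'", path, key),
           call. = FALSE)
    }
  }
  run_config(structure = y$structure, trajectory = y$trajectory,
             species_map = y$species_map,
             discard_fraction = y$discard_fraction %||% 0.5,
             seed = y$seed %||% 1L,
             outdir = y$outdir %||% tempfile("oilcluster_run_"),
             analyses = y$analyses %||% list())
}

#' Drop the leading equilibration frames
#'
#' @param traj A \code{Trajectory}.
#' @param fraction Fraction in [0, 1); the first \code{floor(fraction * F)}
#'   frames are dropped, so fraction 0.5 on 100 frames keeps frames 50..99
#'   (0-based).
#' @return The truncated \code{Trajectory}.
#' @export
discard_frames <- function(traj, fraction) {
  stopifnot(inherits(traj, "Trajectory"))
  if (fraction < 0 || fraction >= 1) {
    stop("fraction must lie in [0, 1)", call. = FALSE)
  }
  nf <- length(traj$times)
  keep <- (floor(fraction * nf) + 1L):nf
  trajectory(traj$coords[, , keep, drop = FALSE],
             traj$box[keep, , drop = FALSE], traj$times[keep],
             traj$topology, traj$wrapped)
}

pipeline_default_species <- function(topo) {
  roles <- molecule_roles(topo)
  sp <- unique(topo$atoms$species[!duplicated(topo$atoms$mol)][roles %in%
                                                                 "terpenoid"])
  if (length(sp) == 0L) sp <- unique(topo$atoms$species)[1L]
  sp
}

#' Run the analysis pipeline
#'
#' Reads the structure and trajectory named in the config, discards the
#' equilibration span, runs every enabled analysis, writes one CSV per
#' analysis into the output directory plus a JSON manifest (parameters,
#' seed, frame range, output files) and a plain-text log.
#'
#' @param config A \code{RunConfig} (or path to a YAML config).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  for (p in c(config$structure, config$trajectory)) {
    if (!file.exists(p)) {
      stop(sprintf("cannot read '%s': no such file", p), call. = FALSE)
    }
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0L)
  log_msg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
  }
  st <- read_structure(config$structure, config$species_map)
  traj <- read_trajectory(config$trajectory, st$topology)
  nf_all <- length(traj$times)
  traj <- discard_frames(traj, config$discard_fraction)
  log_msg("read %d frames, analyzing %d after discarding fraction %.2f",
          nf_all, length(traj$times), config$discard_fraction)
  results <- list()
  outputs <- character(0L)
  write_out <- function(name, table) {
    path <- file.path(config$outdir, paste0(name, ".csv"))
    write_series(table, path)
    outputs <<- c(outputs, path)
    log_msg("wrote %s", path)
    path
  }
  an <- config$analyses
  enabled <- function(key) isTRUE(an[[key]]$enabled)

  com_cache <- list()
  get_com <- function(species) {
    key <- paste(species, collapse = "+")
    if (is.null(com_cache[[key]])) {
      cs <- com_series(traj, species)
      com_cache[[key]] <<- cs
    }
    com_cache[[key]]
  }

  if (enabled("clusters")) {
    a <- an$clusters
    sp <- a$species %||% pipeline_default_species(traj$topology)
    cts <- cluster_time_series(get_com(sp), eps = a$eps %||% 0.65,
                               min_samples = a$min_samples %||% 2L)
    results$clusters <- write_out("clusters", cts$summary)
  }
  if (enabled("rdf")) {
    a <- an$rdf
    sp_a <- a$species_a %||% pipeline_default_species(traj$topology)
    cs_a <- get_com(sp_a)
    cs_b <- if (is.null(a$species_b) || identical(a$species_b, sp_a)) {
      NULL
    } else {
      get_com(a$species_b)
    }
    r <- rdf_com(cs_a, cs_b, bin_width = a$bin_width %||% 0.02,
                 r_max = a$r_max, extended = isTRUE(a$extended))
    results$rdf <- write_out("rdf", data.frame(r = r$r, g = r$g, n_r = r$n_r))
  }
  if (enabled("msd")) {
    a <- an$msd
    sp <- a$species %||% pipeline_default_species(traj$topology)
    u <- unwrap_series(get_com(sp))
    m <- msd(u, origin_stride = a$origin_stride %||% 10L)
    results$msd <- write_out("msd", data.frame(lag_time = m$lag_times,
                                               msd = m$msd,
                                               n_samples = m$n_samples))
  }
  if (enabled("vanhove")) {
    a <- an$vanhove
    sp <- a$species %||% pipeline_default_species(traj$topology)
    cs <- get_com(sp)
    lags <- a$lags %||% default_lag_grid(length(traj$times), 8L)
    vhd <- van_hove_distinct(cs, lags, bin_width = a$bin_width %||% 0.02)
    tab <- data.frame(lag_time = rep(vhd$lag_times, each = length(vhd$r)),
                      r = rep(vhd$r, length(vhd$lag_times)),
                      g_d = as.vector(t(vhd$g_d)))
    results$vanhove <- write_out("vanhove_distinct", tab)
    pd <- peak_decay(vhd)
    results$vanhove_peaks <- write_out("vanhove_peak_decay",
                                       data.frame(lag_time = pd$lag_times,
                                                  ratio = pd$ratio))
  }
  if (enabled("hbonds")) {
    a <- an$hbonds
    crit <- hbond_criterion(a$d_max %||% 0.35, a$angle_max %||% 30)
    hb <- hbond_counts(traj, crit)
    results$hbonds <- write_out("hbond_counts", hb$counts)
    cls <- a$class %||% "polymer-compound"
    acf <- hbond_acf(hb, class = cls)
    if (acf$n_identities > 0L) {
      tau <- integrate_acf(acf)
      results$hbond_acf <- write_out("hbond_acf",
                                     data.frame(lag_time = acf$lag_times,
                                                c = acf$c))
      log_msg("integrated timescale for %s: %.3g ps%s", cls, tau$tau,
              if (tau$plateau) " (plateau, window-limited)" else "")
    } else {
      log_msg("no %s hydrogen bonds observed", cls)
    }
  }
  if (enabled("swarm")) {
    a <- an$swarm
    sp <- a$species %||% pipeline_default_species(traj$topology)
    results$swarm <- write_out("swarm", swarm_series(get_com(sp)))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("oilcluster")),
                   seed = config$seed,
                   structure = config$structure,
                   trajectory = config$trajectory,
                   discard_fraction = config$discard_fraction,
                   frames_total = nf_all,
                   frames_analyzed = length(traj$times),
                   first_analyzed_frame = nf_all - length(traj$times),
                   analyses = an,
                   outputs = outputs)
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  writeLines(log_lines, file.path(config$outdir, "run.log"))
  invisible(manifest)
}
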