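# Reading GRO structures/trajectories into the internal frame model,
# atom selection, and persisting derived series. Internal units are nm and ps
# throughout (GRO native); Angstrom appears only in report labels.

#' Construct a Topology
#'
#' @param atoms data.frame with columns \code{name} (atom name), \code{mol}
#'   (1-based molecule index), \code{species} (species/residue name) and
#'   \code{mass} (amu, > 0).
#' @param species_info Named list, one entry per species:
#'   \code{list(role =, donors =, acceptors =, hydrogens =)} where role is one
#'   of "polymer", "terpenoid", "water", "ion" (or NA), donors/acceptors are
#'   atom-name vectors and hydrogens is a named list mapping each donor atom
#'   name to the hydrogen atom names bonded to it.
#' @return A \code{Topology}.
#' @export
topology <- function(atoms, species_info = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "mol", "species", "mass") %in% names(atoms)))
  if (any(atoms$mass <= 0)) stop("atom masses must be > 0", call. = FALSE)
  sp <- unique(atoms$species)
  if (is.null(species_info)) species_info <- list()
  for (s in sp) {
    if (is.null(species_info[[s]])) {
      species_info[[s]] <- list(role = default_role(s), donors = character(),
                                acceptors = character(), hydrogens = list())
    }
  }
  # every hydrogen designation must reference an existing atom name
  for (s in names(species_info)) {
    si <- species_info[[s]]
    known <- unique(atoms$name[atoms$species == s])
    bad <- setdiff(c(si$donors %||% character(), si$acceptors %||% character(),
                     unlist(si$hydrogens %||% list())), known)
    if (length(bad) > 0L && any(atoms$species == s)) {
      stop(sprintf("species '%s': designated atoms not in topology: %s",
                   s, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(atoms = atoms, species = species_info), class = "Topology")
}

# Role guessed from common residue names; overridable by the species map.
default_role <- function(species) {
  up <- toupper(species)
  if (up %in% c("SOL", "WAT", "HOH", "TIP3", "WATER")) return("water")
  if (up %in% c("CL", "CL-", "NA", "NA+", "K", "K+", "ION")) return("ion")
  NA_character_
}

#' @export
print.Topology <- function(x, ...) {
  tab <- table(x$atoms$species[!duplicated(x$atoms$mol)])
  cat(sprintf("Topology: %d atoms, %d molecules, %d species\n",
              nrow(x$atoms), max(x$atoms$mol), length(tab)))
  for (s in names(tab)) {
    cat(sprintf("  %s: %d molecules (role %s)\n", s, tab[[s]],
                x$species[[s]]$role %||% NA))
  }
  invisible(x)
}

#' Construct a Trajectory
#'
#' @param coords n_atoms x 3 x n_frames array (nm).
#' @param box n_frames x 3 matrix of box edges (nm), or length-3 vector
#'   recycled to all frames.
#' @param times Frame times (ps), strictly increasing.
#' @param topology A \code{Topology} with one row per atom.
#' @param wrapped Logical flag: coordinates wrapped into [0, L)?
#' @return A \code{Trajectory}.
#' @export
trajectory <- function(coords, box, times, topology, wrapped = TRUE) {
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L) {
    stop("coords must be an n_atoms x 3 x n_frames array", call. = FALSE)
  }
  nf <- dim(coords)[3L]
  if (!is.matrix(box)) box <- matrix(rep(expand_box(box), each = nf), nrow = nf)
  if (any(box <= 0)) stop("box edges must be > 0", call. = FALSE)
  if (length(times) != nf) stop("length(times) must match frames", call. = FALSE)
  if (nf > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  if (nrow(topology$atoms) != dim(coords)[1L]) {
    stop("coordinate count does not match topology atom count", call. = FALSE)
  }
  structure(list(coords = coords, box = box, times = as.numeric(times),
                 topology = topology, wrapped = wrapped),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frames, t = %g..%g ps, box %s nm\n",
              dim(x$coords)[1L], length(x$times), min(x$times), max(x$times),
              paste(signif(x$box[1L, ], 4L), collapse = " x ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A \code{Trajectory}.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) length(traj$times)

# ---- GRO parsing -----------------------------------------------------------

parse_gro_box <- function(line, lineno) {
  vals <- suppressWarnings(as.numeric(strsplit(trimws(line), "\\s+")[[1L]]))
  if (length(vals) < 3L || anyNA(vals[1:3])) {
    stop(sprintf("malformed GRO box line at line %d", lineno), call. = FALSE)
  }
  if (length(vals) > 3L && any(abs(vals[-(1:3)]) > 1e-9)) {
    stop("triclinic boxes are not supported (orthorhombic cells only)",
         call. = FALSE)
  }
  vals[1:3]
}

parse_gro_time <- function(title, fallback) {
  m <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
  if (length(m) == 1L) {
    as.numeric(sub("t=\\s*", "", m))
  } else {
    fallback
  }
}

# Parse one or more concatenated GRO frames. Returns list(frames, atoms_df).
read_gro_raw <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  atoms_df <- NULL
  pos <- 1L
  fno <- 0L
  while (pos <= length(lines) && nzchar(trimws(paste(lines[pos:min(pos + 1L,
                                                length(lines))], collapse = "")))) {
    title <- lines[pos]
    if (pos + 1L > length(lines)) {
      stop(sprintf("truncated GRO file '%s': last complete frame is %d",
                   path, fno), call. = FALSE)
    }
    natoms <- suppressWarnings(as.integer(trimws(lines[pos + 1L])))
    if (is.na(natoms) || natoms < 1L) {
      stop(sprintf("malformed atom-count header at line %d", pos + 1L),
           call. = FALSE)
    }
    last <- pos + 1L + natoms + 1L
    if (last > length(lines)) {
      stop(sprintf("truncated GRO file '%s': last complete frame is %d",
                   path, fno), call. = FALSE)
    }
    atom_lines <- lines[(pos + 2L):(pos + 1L + natoms)]
    xyz <- matrix(NA_real_, nrow = natoms, ncol = 3L)
    for (i in seq_len(natoms)) {
      ln <- atom_lines[i]
      if (nchar(ln) < 44L) {
        stop(sprintf("malformed GRO atom line at line %d", pos + 1L + i),
             call. = FALSE)
      }
      xyz[i, ] <- suppressWarnings(as.numeric(c(substr(ln, 21L, 28L),
                                                substr(ln, 29L, 36L),
                                                substr(ln, 37L, 44L))))
      if (anyNA(xyz[i, ])) {
        stop(sprintf("malformed coordinates at line %d", pos + 1L + i),
             call. = FALSE)
      }
    }
    if (is.null(atoms_df)) {
      resid <- suppressWarnings(as.integer(substr(atom_lines, 1L, 5L)))
      resname <- trimws(substr(atom_lines, 6L, 10L))
      name <- trimws(substr(atom_lines, 11L, 15L))
      if (anyNA(resid)) {
        bad <- which(is.na(resid))[1L]
        stop(sprintf("malformed residue id at line %d", pos + 1L + bad),
             call. = FALSE)
      }
      # molecule index from residue-number changes (ids wrap at 100000)
      mol <- cumsum(c(TRUE, resid[-1L] != resid[-natoms] |
                        resname[-1L] != resname[-natoms]))
      atoms_df <- data.frame(name = name, mol = mol, species = resname,
                             mass = guess_mass(name),
                             stringsAsFactors = FALSE)
    }
    fno <- fno + 1L
    frames[[fno]] <- list(time = parse_gro_time(title, fno - 1),
                          box = parse_gro_box(lines[last], last),
                          coords = xyz, natoms = natoms)
    pos <- last + 1L
    while (pos <= length(lines) && !nzchar(trimws(lines[pos]))) pos <- pos + 1L
  }
  if (fno == 0L) stop(sprintf("no frames found in '%s'", path), call. = FALSE)
  list(frames = frames, atoms = atoms_df)
}

# Mass guess from the atom name's leading element symbol; the species map can
# override per-atom masses.
guess_mass <- function(names) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, F = 18.998, K = 39.098)
  tab2 <- c(CL = 35.45, NA. = 22.990, BR = 79.904, MG = 24.305, CA = 40.078,
            MW = 0.0)
  up <- toupper(gsub("^[0-9]+", "", names))
  out <- numeric(length(names))
  two <- substr(up, 1L, 2L)
  two[two == "NA"] <- "NA."
  one <- substr(up, 1L, 1L)
  hit2 <- two %in% names(tab2)
  out[hit2] <- tab2[two[hit2]]
  hit1 <- !hit2 & one %in% names(tab)
  out[hit1] <- tab[one[hit1]]
  out[!hit2 & !hit1] <- 12.011
  out
}

#' Read a GRO structure file
#'
#' Parses the first frame of a (possibly multi-frame) fixed-column GRO file
#' (coordinates in nm) into a topology skeleton plus a single frame.
#'
#' @param path Path to a GRO file.
#' @param species_map Optional species map (path or parsed list, see
#'   \code{\link{read_species_map}}) overriding roles, masses and
#'   hydrogen-bond designations.
#' @return List with elements \code{topology} and \code{frame}
#'   (a one-frame \code{Trajectory}).
#' @export
read_structure <- function(path, species_map = NULL) {
  raw <- read_gro_raw(path)
  topo <- topology(raw$atoms)
  if (!is.null(species_map)) topo <- apply_species_map(topo, species_map)
  f <- raw$frames[[1L]]
  traj <- trajectory(array(f$coords, dim = c(nrow(f$coords), 3L, 1L)),
                     f$box, f$time, topo, wrapped = TRUE)
  list(topology = topo, frame = traj)
}

#' Read a trajectory (multi-frame GRO)
#'
#' Reads all frames of a multi-frame GRO file. XTC input is not supported by
#' this package; convert to multi-frame GRO (e.g. \code{gmx trjconv}) first.
#'
#' @param path Path to a multi-frame GRO file.
#' @param topo Optional \code{Topology}; frames are checked against its atom
#'   count. When omitted, the topology is inferred from the first frame.
#' @param species_map Optional species map applied to the topology.
#' @return A \code{Trajectory} with strictly increasing times.
#' @export
read_trajectory <- function(path, topo = NULL, species_map = NULL) {
  if (grepl("\\.xtc$", path, ignore.case = TRUE)) {
    stop(paste0("XTC reading is not supported; convert '", path,
                "' to a multi-frame GRO file"), call. = FALSE)
  }
  raw <- read_gro_raw(path)
  if (is.null(topo)) {
    topo <- topology(raw$atoms)
    if (!is.null(species_map)) topo <- apply_species_map(topo, species_map)
  }
  nat <- nrow(topo$atoms)
  for (i in seq_along(raw$frames)) {
    if (raw$frames[[i]]$natoms != nat) {
      stop(sprintf("frame %d has %d atoms, expected %d", i,
                   raw$frames[[i]]$natoms, nat), call. = FALSE)
    }
  }
  nf <- length(raw$frames)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  box <- matrix(NA_real_, nrow = nf, ncol = 3L)
  times <- numeric(nf)
  for (i in seq_len(nf)) {
    coords[, , i] <- raw$frames[[i]]$coords
    box[i, ] <- raw$frames[[i]]$box
    times[i] <- raw$frames[[i]]$time
  }
  if (nf > 1L && any(diff(times) <= 0)) times <- seq_len(nf) - 1
  trajectory(coords, box, times, topo, wrapped = TRUE)
}

#' Write a trajectory as (multi-frame) GRO
#'
#' @param traj A \code{Trajectory}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_gro <- function(traj, path) {
  stopifnot(inherits(traj, "Trajectory"))
  at <- traj$topology$atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$times)) {
    writeLines(sprintf("oilcluster frame t= %.4f", traj$times[f]), con)
    writeLines(sprintf("%5d", nrow(at)), con)
    lines <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     ((at$mol - 1L) %% 99999L) + 1L,
                     substr(at$species, 1L, 5L), substr(at$name, 1L, 5L),
                     ((seq_len(nrow(at)) - 1L) %% 99999L) + 1L,
                     traj$coords[, 1L, f], traj$coords[, 2L, f],
                     traj$coords[, 3L, f])
    writeLines(lines, con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", traj$box[f, 1L], traj$box[f, 2L],
                       traj$box[f, 3L]), con)
  }
  invisible(path)
}

# ---- species map -----------------------------------------------------------

#' Read a species map file
#'
#' The species map is a YAML file assigning per-species metadata:
#' \preformatted{
#' species:
#'   CARV:
#'     role: terpenoid
#'     masses: {O1: 15.999, H12: 1.008}
#'     donors: [O1]
#'     acceptors: [O1]
#'     hydrogens: {O1: [H12]}
#' }
#'
#' @param path Path to the YAML species map.
#' @return Parsed species map (named list, one entry per species).
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read species map '%s': no such file", path),
         call. = FALSE)
  }
  sm <- yaml::read_yaml(path)
  sm$species %||% sm
}

#' Apply a species map to a topology
#'
#' Overrides roles, per-atom masses and hydrogen-bond designations of an
#' existing topology.
#'
#' @param topo A \code{Topology}.
#' @param species_map A parsed species map (list) or a path to one.
#' @return The updated \code{Topology}.
#' @export
apply_species_map <- function(topo, species_map) {
  stopifnot(inherits(topo, "Topology"))
  if (is.character(species_map)) species_map <- read_species_map(species_map)
  at <- topo$atoms
  si <- topo$species
  for (s in names(species_map)) {
    e <- species_map[[s]]
    cur <- si[[s]] %||% list(role = NA_character_, donors = character(),
                             acceptors = character(), hydrogens = list())
    if (!is.null(e$role)) {
      if (!e$role %in% c("polymer", "terpenoid", "water", "ion")) {
        stop(sprintf("species '%s': unknown role '%s'", s, e$role),
             call. = FALSE)
      }
      cur$role <- e$role
    }
    if (!is.null(e$donors)) cur$donors <- as.character(e$donors)
    if (!is.null(e$acceptors)) cur$acceptors <- as.character(e$acceptors)
    if (!is.null(e$hydrogens)) cur$hydrogens <- lapply(e$hydrogens, as.character)
    si[[s]] <- cur
    if (!is.null(e$masses)) {
      for (an in names(e$masses)) {
        at$mass[at$species == s & at$name == an] <- as.numeric(e$masses[[an]])
      }
    }
  }
  topology(at, si)
}

# ---- selections ------------------------------------------------------------

#' Select atoms by species, role and/or atom name
#'
#' Criteria combine with AND; \code{NULL} criteria are ignored. The selection
#' is deterministic and returned in ascending atom order.
#'
#' @param topo A \code{Topology}.
#' @param species,role,atom_name Optional character vectors of admissible
#'   values.
#' @return Sorted integer vector of atom indices (possibly empty).
#' @export
select_atoms <- function(topo, species = NULL, role = NULL, atom_name = NULL) {
  stopifnot(inherits(topo, "Topology"))
  at <- topo$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(species)) keep <- keep & at$species %in% species
  if (!is.null(role)) {
    roles <- vapply(at$species, function(s) {
      topo$species[[s]]$role %||% NA_character_
    }, character(1L))
    keep <- keep & !is.na(roles) & roles %in% role
  }
  if (!is.null(atom_name)) keep <- keep & at$name %in% atom_name
  unname(which(keep))
}

#' Per-molecule atom index lists for a species
#'
#' @param topo A \code{Topology}.
#' @param species Species name, or a character vector of names.
#' @return List of integer vectors, one per molecule, in molecule order.
#' @export
molecule_groups <- function(topo, species) {
  stopifnot(inherits(topo, "Topology"))
  at <- topo$atoms
  idx <- which(at$species %in% species)
  if (length(idx) == 0L) return(list())
  unname(split(idx, at$mol[idx]))
}

#' Roles of molecules, one entry per molecule
#' @param topo A \code{Topology}.
#' @return Character vector of roles indexed by molecule.
#' @export
molecule_roles <- function(topo) {
  at <- topo$atoms
  first <- !duplicated(at$mol)
  vapply(at$species[first], function(s) topo$species[[s]]$role %||%
           NA_character_, character(1L))
}

# ---- derived-series persistence -------------------------------------------

#' Write a result table as CSV
#' @param table A data.frame.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_series <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by \code{write_series}
#' @param path CSV path.
#' @return data.frame.
#' @export
read_series <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
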