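# Composition bookkeeping for the simulated solution systems: species
# specifications, per-system atom counts and polymer:terpenoid molar ratios.
# The packaged fixture file mirrors the published composition tables of the
# five terpenoid-water systems and ten polymer-terpenoid systems.

#' Species specification
#'
#' @param name Species label (e.g. "carvacrol").
#' @param role One of "polymer", "terpenoid", "water", "ion".
#' @param molecule_count Non-negative integer number of molecules.
#' @param atoms_per_molecule Positive integer.
#' @param charge_per_molecule Signed integer charge in elementary charges.
#' @return A \code{SpeciesSpec}.
#' @export
species_spec <- function(name, role, molecule_count, atoms_per_molecule,
                         charge_per_molecule = 0L) {
  if (!role %in% c("polymer", "terpenoid", "water", "ion")) {
    stop(sprintf("unknown role '%s'", role), call. = FALSE)
  }
  if (molecule_count < 0 || molecule_count != round(molecule_count)) {
    stop("molecule_count must be a non-negative integer", call. = FALSE)
  }
  if (atoms_per_molecule < 1 || atoms_per_molecule != round(atoms_per_molecule)) {
    stop("atoms_per_molecule must be a positive integer", call. = FALSE)
  }
  structure(list(name = name, role = role,
                 molecule_count = as.integer(molecule_count),
                 atoms_per_molecule = as.integer(atoms_per_molecule),
                 charge_per_molecule = as.integer(charge_per_molecule)),
            class = "SpeciesSpec")
}

#' System composition
#'
#' An ordered list of species with a label. If any species carries a nonzero
#' charge, the total charge over all species must vanish (simulated systems
#' include counterions to maintain electrical neutrality).
#'
#' @param label Text key, e.g. "hbpei27_7".
#' @param species List of \code{SpeciesSpec}, names unique.
#' @param notes Free text.
#' @return A \code{SystemComposition}.
#' @export
system_composition <- function(label, species, notes = "") {
  stopifnot(is.list(species))
  nm <- vapply(species, function(s) s$name, character(1L))
  if (anyDuplicated(nm)) stop("species names must be unique", call. = FALSE)
  q <- vapply(species, function(s) s$charge_per_molecule * s$molecule_count,
              numeric(1L))
  if (any(q != 0) && sum(q) != 0) {
    stop(sprintf("composition '%s' is not electrically neutral (total %+d e)",
                 label, sum(q)), call. = FALSE)
  }
  structure(list(label = label, species = species, notes = notes),
            class = "SystemComposition")
}

#' @export
print.SystemComposition <- function(x, ...) {
  ca <- count_atoms(x)
  cat(sprintf("SystemComposition '%s': %d species, %d atoms total\n",
              x$label, length(x$species), ca$total))
  for (s in x$species) {
    cat(sprintf("  %-12s %-9s %7d x %4d atoms\n", s$name, s$role,
                s$molecule_count, s$atoms_per_molecule))
  }
  if (nzchar(x$notes)) cat(" ", x$notes, "\n")
  invisible(x)
}

#' Atom counts per species and in total
#'
#' Per-species count is molecule_count x atoms_per_molecule; the total is the
#' sum over species (additive over disjoint species lists). An empty
#' composition gives total 0.
#'
#' @param composition A \code{SystemComposition}.
#' @return List with \code{per_species} (named integer vector) and
#'   \code{total}.
#' @export
count_atoms <- function(composition) {
  stopifnot(inherits(composition, "SystemComposition"))
  per <- vapply(composition$species, function(s) {
    as.numeric(s$molecule_count) * s$atoms_per_molecule
  }, numeric(1L))
  names(per) <- vapply(composition$species, function(s) s$name, character(1L))
  list(per_species = per, total = sum(per))
}

#' Reduced polymer : terpenoid molar ratios
#'
#' For each terpenoid species, the molecule counts of the (first) polymer
#' species and the terpenoid are divided by their greatest common divisor,
#' giving the reduced integer proportion (e.g. 27:189 -> 1:7).
#'
#' @param composition A \code{SystemComposition} containing at least one
#'   polymer species.
#' @return data.frame with columns \code{terpenoid}, \code{polymer_part},
#'   \code{terpenoid_part}.
#' @export
molar_ratios <- function(composition) {
  stopifnot(inherits(composition, "SystemComposition"))
  roles <- vapply(composition$species, function(s) s$role, character(1L))
  ip <- which(roles == "polymer")
  if (length(ip) == 0L) {
    stop(sprintf("composition '%s' has no polymer species",
                 composition$label), call. = FALSE)
  }
  np <- composition$species[[ip[1L]]]$molecule_count
  it <- which(roles == "terpenoid")
  res <- lapply(it, function(i) {
    nt <- composition$species[[i]]$molecule_count
    g <- gcd(np, nt)
    if (g == 0L) g <- 1L
    data.frame(terpenoid = composition$species[[i]]$name,
               polymer_part = np %/% g, terpenoid_part = nt %/% g,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Load system compositions from a YAML file
#'
#' Without \code{label}, all compositions in the file are returned as a named
#' list. The packaged fixture (default path) mirrors the published composition
#' tables: five terpenoid-water systems and ten polymer-terpenoid systems.
#'
#' @param path YAML file; defaults to the packaged composition tables.
#' @param label Optional system key (e.g. "hbpei27_7") to return one system.
#' @return A \code{SystemComposition}, or a named list of them.
#' @export
load_composition <- function(path = system.file("extdata", "compositions.yaml",
                                                package = "oilcluster"),
                             label = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read composition file '%s': no such file", path),
         call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  systems <- raw$systems %||% raw
  out <- lapply(names(systems), function(key) {
    sys <- systems[[key]]
    sp <- lapply(sys$species, function(e) {
      species_spec(e$name, e$role, e$molecules, e$atoms_per_molecule,
                   e$charge %||% 0L)
    })
    system_composition(key, sp, notes = sys$notes %||% "")
  })
  names(out) <- names(systems)
  if (!is.null(label)) {
    if (!label %in% names(out)) {
      stop(sprintf("no composition labelled '%s' in '%s'", label, path),
           call. = FALSE)
    }
    return(out[[label]])
  }
  out
}
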