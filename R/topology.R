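#' Declare a lipid species topology
#'
#' A topology names, for one lipid species, which atoms belong to the
#' headgroup (every atom down to and including the C2 carbon) and which to the
#' acyl chains, plus the reference atoms the analyses rely on: the phosphorus
#' atom (or the C3 surrogate used for sterols), the C2 atom, and the terminal
#' carbon of each chain. Van der Waals radii drive the occupancy-grid defect
#' analysis; atomic masses drive the interdigitation density profiles.
#'
#' @param species Species (residue) name, e.g. "POPC".
#' @param head_atoms Character vector of headgroup atom names.
#' @param tail_atoms Character vector of acyl-chain atom names.
#' @param p_atom Name of the phosphorus reference atom (C3 for cholesterol);
#'   must be a head atom.
#' @param c2_atom Name of the C2 reference atom; must be a head atom.
#' @param terminal_atoms Last carbon of each chain; all must be tail atoms.
#' @param vdw_radii Named numeric vector, atom name -> van der Waals radius
#'   (angstrom). Atoms without an entry fall back to `default_vdw`.
#' @param masses Named numeric vector, atom name -> mass (amu). Atoms without
#'   an entry fall back to a guess from the element letter.
#' @param thickness_atoms Named character vector mapping the thickness tags
#'   `P`, `C1`, `C2` to atom names of this species (sterol surrogates go
#'   here). Defaults to `c(P = p_atom, C2 = c2_atom)` plus `C1` when an atom
#'   of that name is declared.
#' @param default_vdw Fallback van der Waals radius (angstrom).
#' @return An object of class `lipid_topology`.
#' @export
lipid_topology <- function(species, head_atoms, tail_atoms,
                           p_atom, c2_atom, terminal_atoms,
                           vdw_radii = NULL, masses = NULL,
                           thickness_atoms = NULL, default_vdw = 2.0) {
  stopifnot(is.character(species), length(species) == 1L)
  head_atoms <- as.character(head_atoms)
  tail_atoms <- as.character(tail_atoms)
  if (length(intersect(head_atoms, tail_atoms)) > 0L)
    stop("head_atoms and tail_atoms of '", species, "' overlap: ",
         paste(intersect(head_atoms, tail_atoms), collapse = ", "))
  all_atoms <- c(head_atoms, tail_atoms)
  if (anyDuplicated(all_atoms))
    stop("duplicate atom names in topology '", species, "'")
  if (!(p_atom %in% head_atoms))
    stop("p_atom '", p_atom, "' of '", species, "' is not a head atom")
  if (!(c2_atom %in% head_atoms))
    stop("c2_atom '", c2_atom, "' of '", species, "' is not a head atom")
  terminal_atoms <- as.character(terminal_atoms)
  bad <- setdiff(terminal_atoms, tail_atoms)
  if (length(bad) > 0L)
    stop("terminal atoms not declared as tail atoms in '", species, "': ",
         paste(bad, collapse = ", "))

  vdw <- rep(default_vdw, length(all_atoms))
  names(vdw) <- all_atoms
  if (!is.null(vdw_radii)) vdw[names(vdw_radii)] <- vdw_radii

  m <- guess_mass(all_atoms)
  if (!is.null(masses)) m[names(masses)] <- masses

  if (is.null(thickness_atoms)) {
    thickness_atoms <- c(P = p_atom, C2 = c2_atom)
    if ("C1" %in% all_atoms) thickness_atoms["C1"] <- "C1"
  }

  structure(list(
    species = species,
    head_atoms = head_atoms,
    tail_atoms = tail_atoms,
    p_atom = p_atom,
    c2_atom = c2_atom,
    terminal_atoms = terminal_atoms,
    vdw_radii = vdw,
    masses = m,
    thickness_atoms = thickness_atoms
  ), class = "lipid_topology")
}

# Crude element guess from the first letter of an atom name (good enough for
# synthetic systems; real topologies should declare masses explicitly).
guess_mass <- function(atom_names) {
  el <- toupper(substr(atom_names, 1L, 1L))
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06)
  out <- unname(m[el])
  out[is.na(out)] <- 12.011
  names(out) <- atom_names
  out
}

#' @export
print.lipid_topology <- function(x, ...) {
  cat("<lipid_topology>", x$species, "\n")
  cat("  head:", paste(x$head_atoms, collapse = " "), "\n")
  cat("  tail:", paste(x$tail_atoms, collapse = " "), "\n")
  cat("  refs: P=", x$p_atom, " C2=", x$c2_atom,
      " terminal=", paste(x$terminal_atoms, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Bundle topologies into a set keyed by species name
#'
#' @param ... `lipid_topology` objects (or a single list of them).
#' @return Named list of class `topology_set`.
#' @export
topology_set <- function(...) {
  tops <- list(...)
  if (length(tops) == 1L && !inherits(tops[[1L]], "lipid_topology"))
    tops <- tops[[1L]]
  ok <- vapply(tops, inherits, logical(1L), "lipid_topology")
  if (!all(ok)) stop("all elements must be lipid_topology objects")
  names(tops) <- vapply(tops, `[[`, character(1L), "species")
  structure(tops, class = "topology_set")
}

#' Read a topology configuration file
#'
#' The configuration is YAML with one stanza per species:
#' ```yaml
#' POPC:
#'   head_atoms: [P, C2]
#'   tail_atoms: [C216]
#'   p_atom: P
#'   c2_atom: C2
#'   terminal_atoms: [C216]
#'   vdw_radii: {P: 1.9, C2: 1.7, C216: 1.7}
#' ```
#'
#' @param path Path to the YAML file.
#' @return A `topology_set`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  cfg <- yaml::read_yaml(path)
  tops <- lapply(names(cfg), function(sp) {
    s <- cfg[[sp]]
    lipid_topology(
      species = sp,
      head_atoms = s$head_atoms, tail_atoms = s$tail_atoms,
      p_atom = s$p_atom, c2_atom = s$c2_atom,
      terminal_atoms = s$terminal_atoms,
      vdw_radii = if (!is.null(s$vdw_radii)) unlist(s$vdw_radii),
      masses = if (!is.null(s$masses)) unlist(s$masses),
      thickness_atoms = if (!is.null(s$thickness_atoms)) unlist(s$thickness_atoms)
    )
  })
  topology_set(tops)
}

# Minimal three-atom lipid used by the synthetic lattice generator: P and C2
# in the head, a single terminal carbon CT ending the one chain.
#' Topology of the minimal synthetic three-atom lipid
#'
#' @param species Species name (default "SYN").
#' @param vdw Common van der Waals radius in angstrom.
#' @return A `lipid_topology`.
#' @export
synthetic_lipid_topology <- function(species = "SYN", vdw = 2.0) {
  lipid_topology(
    species = species,
    head_atoms = c("P", "C2"),
    tail_atoms = "CT",
    p_atom = "P", c2_atom = "C2", terminal_atoms = "CT",
    vdw_radii = c(P = vdw, C2 = vdw, CT = vdw)
  )
}
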